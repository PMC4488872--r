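#' Smooth spectra with a symmetric window
#'
#' Each spectrum (row) is replaced by its windowed smooth. Two kernels are
#' available: `moving_average` (boxcar mean, the default) and
#' `polynomial_order2` (quadratic least-squares a.k.a. Savitzky-Golay
#' smoothing). Row ends are handled by symmetric reflection padding (the
#' signal is mirrored about its end points, which are not repeated), so the
#' output grid is identical to the input grid.
#'
#' @param set a [spectra_set()].
#' @param window_points odd integer window width, `>= 3` and at most the
#'   number of wavelengths. Typical choices for NIR work are 21 or 45 points.
#' @param method smoothing kernel.
#' @return a `spectra_set` with smoothed rows on the same grid.
#' @export
smooth_spectra <- function(set, window_points,
                           method = c("moving_average", "polynomial_order2")) {
  stopifnot(inherits(set, "spectra_set"))
  method <- match.arg(method)
  m <- length(set$wavelengths)
  if (length(window_points) != 1 || window_points != round(window_points) ||
      window_points < 3 || window_points %% 2 == 0)
    .stop2("aquaphot_parameter_error",
           "window_points must be an odd integer >= 3 (got %s)",
           format(window_points))
  if (window_points > m)
    .stop2("aquaphot_parameter_error",
           "window_points (%d) exceeds the number of wavelengths (%d)",
           window_points, m)
  kern <- smoothing_kernel(window_points, method)
  out <- t(apply(set$absorbance, 1, .smooth_row, kern = kern))
  if (nrow(set$absorbance) == 1) out <- matrix(out, nrow = 1)
  if (nrow(set$absorbance) == 0) out <- set$absorbance
  spectra_set(out, set$wavelengths, set$meta)
}

# closed-form symmetric kernels; quadratic kernel is the first row of the
# local polynomial projector (t(A) A)^-1 t(A) with A = [1, x, x^2]
smoothing_kernel <- function(window_points, method) {
  h <- (window_points - 1L) / 2L
  if (method == "moving_average") return(rep(1 / window_points, window_points))
  x <- seq(-h, h)
  A <- cbind(1, x, x^2)
  coef <- solve(crossprod(A), t(A))
  as.numeric(coef[1, ])
}

.smooth_row <- function(x, kern) {
  h <- (length(kern) - 1L) / 2L
  m <- length(x)
  padded <- c(x[(h + 1):2], x, x[(m - 1):(m - h)])
  sm <- stats::filter(padded, kern, sides = 2)
  as.numeric(sm[(h + 1):(h + m)])
}

#' Fit a mean-centering model
#'
#' Stores the per-wavelength mean absorbance of the training matrix and,
#' when a reference vector is supplied, its mean. Centering consumes the
#' model intercept: predictions add the stored reference mean back.
#'
#' @param X numeric matrix (samples x wavelengths).
#' @param y optional numeric reference vector.
#' @return an object of class `centering_model` with `x_mean` and `y_mean`.
#' @export
fit_centering <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2)
    .stop2("aquaphot_degenerate_error",
           "need at least 2 samples to fit centering (got %d)", nrow(X))
  structure(list(x_mean = colMeans(X),
                 y_mean = if (is.null(y)) NULL else mean(y)),
            class = "centering_model")
}

#' Apply a centering model
#' @param model a `centering_model`.
#' @param X matrix to center with the stored training means.
#' @param y optional reference vector to center with the stored y mean.
#' @return centered matrix, or `list(X, y)` when `y` is given.
#' @export
apply_centering <- function(model, X, y = NULL) {
  stopifnot(inherits(model, "centering_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean))
    .stop2("aquaphot_shape_error", "matrix has %d columns, model expects %d",
           ncol(X), length(model$x_mean))
  Xc <- sweep(X, 2, model$x_mean)
  if (is.null(y)) return(Xc)
  list(X = Xc, y = y - model$y_mean)
}

# SVD pseudo-inverse product: pinv(X) %*% v with relative tolerance on
# singular values
.pinv_mult <- function(sv, v, tol = 1e-10) {
  keep <- sv$d > sv$d[1] * tol
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], v)) / sv$d[keep])
}

#' Fit orthogonal signal correction (OSC)
#'
#' Removes from the centered spectra the dominant variation orthogonal to
#' the centered reference values, one component at a time (Wold-style
#' iterative algorithm). Per component: the score starts as the first
#' principal-component score, is orthogonalized against `yc`, a unit-norm
#' weight vector is regressed through the tolerance-rank pseudo-inverse of
#' the (deflated) spectra, and score/weight are iterated to a fixed point
#' (relative score change below `tol`). The loading `p = X't/(t't)` then
#' deflates the spectra.
#'
#' @param Xc column-centered spectra matrix, `n >= 3`.
#' @param yc centered reference vector.
#' @param n_components number of orthogonal components to remove (default 1).
#' @param tol relative convergence tolerance on the score vector.
#' @param max_iter iteration cap per component.
#' @return an object of class `osc_model` with unit-norm `weights` (m x k),
#'   `loadings` (m x k), `n_components`, and the per-component training
#'   scores used for deflation.
#' @export
fit_osc <- function(Xc, yc, n_components = 1, tol = 1e-10, max_iter = 500) {
  Xc <- as.matrix(Xc)
  n <- nrow(Xc); m <- ncol(Xc)
  if (n < 3)
    .stop2("aquaphot_degenerate_error", "OSC needs at least 3 samples")
  if (length(yc) != n)
    .stop2("aquaphot_shape_error", "yc length %d does not match %d samples",
           length(yc), n)
  yss <- sum(yc^2)
  W <- P <- matrix(0, m, 0)
  Tm <- matrix(0, n, 0)
  X <- Xc
  for (comp in seq_len(n_components)) {
    sv <- svd(X)
    if (sv$d[1] < 1e-12)
      .stop2("aquaphot_degenerate_error",
             "spectra have (numerically) zero variance; nothing to correct")
    t_score <- sv$u[, 1] * sv$d[1]
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      t_orth <- t_score - yc * (sum(yc * t_score) / yss)
      w <- .pinv_mult(sv, t_orth)
      wn <- sqrt(sum(w^2))
      if (sqrt(sum(t_orth^2)) <= 1e-8 * sqrt(sum(t_score^2)) || wn < 1e-12) {
        # spectra are (numerically) proportional to yc: nothing orthogonal
        # to remove; return the weakest spectral direction as a null
        # component so the removed variance is ~0
        r <- max(which(sv$d > 0))
        w <- sv$v[, r]
        t_score <- as.numeric(X %*% w)
        converged <- TRUE
        break
      }
      w <- w / wn
      t_new <- as.numeric(X %*% w)
      if (sqrt(sum((t_new - t_score)^2)) <= tol * sqrt(sum(t_new^2))) {
        t_score <- t_new
        converged <- TRUE
        break
      }
      t_score <- t_new
    }
    if (!converged)
      .stop2("aquaphot_convergence_error",
             "OSC component %d did not converge in %d iterations", comp, max_iter)
    tt <- sum(t_score^2)
    # a score this far below the spectral scale is numerically null:
    # deflating with its loading would only amplify rounding noise
    p <- if (sqrt(tt) > 1e-12 * sv$d[1])
      as.numeric(crossprod(X, t_score)) / tt else numeric(m)
    X <- X - tcrossprod(t_score, p)
    W <- cbind(W, w); P <- cbind(P, p); Tm <- cbind(Tm, t_score)
  }
  structure(list(weights = W, loadings = P, n_components = n_components,
                 scores = Tm, variant = "wold_iterative_pinv"),
            class = "osc_model")
}

#' Apply a fitted OSC model
#'
#' For each stored component, the score `t = X w` (unit-norm weights) is
#' computed and `t p'` subtracted. Applying the model to its own training
#' matrix reproduces the internally deflated matrix.
#'
#' @param model an `osc_model`.
#' @param Xc centered matrix on the training grid.
#' @return the corrected matrix.
#' @export
apply_osc <- function(model, Xc) {
  stopifnot(inherits(model, "osc_model"))
  Xc <- as.matrix(Xc)
  if (ncol(Xc) != nrow(model$weights))
    .stop2("aquaphot_shape_error", "matrix has %d columns, OSC model expects %d",
           ncol(Xc), nrow(model$weights))
  for (comp in seq_len(model$n_components)) {
    t_score <- as.numeric(Xc %*% model$weights[, comp])
    Xc <- Xc - tcrossprod(t_score, model$loadings[, comp])
  }
  Xc
}
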