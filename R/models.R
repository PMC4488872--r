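new_latent_model <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> kind = %s, %d factor(s), %d wavelengths\n",
              x$kind, x$n_factors, nrow(x$x_loadings)))
  invisible(x)
}

.check_factors <- function(k, n, m) {
  kmax <- min(n - 1, m)
  if (length(k) != 1 || k != round(k) || k < 1 || k > kmax)
    .stop2("aquaphot_parameter_error",
           "number of factors must be an integer in [1, %d] (got %s)",
           kmax, format(k))
  as.integer(k)
}

# flip each component so its largest-magnitude loading element is positive
.fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis of centered spectra
#'
#' Deterministic full-rank decomposition (SVD), truncated to the leading
#' `k` components ordered by decreasing explained variance. Loadings are
#' orthonormal; each component's sign is fixed so that its
#' largest-magnitude loading element is positive.
#'
#' @param Xc column-centered matrix (n x m).
#' @param k number of components, `1 <= k <= min(n - 1, m)`.
#' @return a `latent_model` of kind `"pca"` with `scores` (n x k),
#'   `x_loadings` (m x k) and `explained_variance` (fraction per component,
#'   full spectrum of the decomposition).
#' @export
fit_pca <- function(Xc, k) {
  Xc <- as.matrix(Xc)
  k <- .check_factors(k, nrow(Xc), ncol(Xc))
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  fx <- .fix_signs(scores, loadings)
  new_latent_model("pca", scores = fx$scores, x_loadings = fx$loadings,
                   n_factors = k,
                   explained_variance = if (tot > 0) sv$d^2 / tot else sv$d * 0,
                   singular_values = sv$d)
}

#' NIPALS PLS1 regression
#'
#' Classical NIPALS partial least squares with a single response. Per
#' factor: weight `w` proportional to `X'y` (unit norm), score `t = X w`,
#' x-loading `p = X't/(t't)`, y-loading `q = y't/(t't)`, then both `X` and
#' `y` are deflated (`X <- X - t p'`, `y <- y - t q`). The regression
#' vector is `b = W (P'W)^-1 q`; coefficient vectors for every factor count
#' up to `k` are retained so nested models come for free.
#'
#' @param Xc column-centered spectra (n x m).
#' @param yc centered reference vector with nonzero variance.
#' @param k number of latent variables.
#' @param centering optional `centering_model` to embed, so
#'   [predict_regression()] can replay pretreatments on raw spectra.
#' @param osc optional `osc_model` to embed (applied after centering).
#' @return a `latent_model` of kind `"plsr"` with `scores`, `x_weights`
#'   (unit-norm columns), `x_loadings`, `y_loadings`, `regression_vector`,
#'   and `coef_per_factor` (m x k matrix of nested coefficient vectors).
#' @export
fit_plsr <- function(Xc, yc, k, centering = NULL, osc = NULL) {
  model <- .fit_pls1(Xc, yc, k)
  new_latent_model("plsr", scores = model$scores, x_weights = model$W,
                   x_loadings = model$P, y_loadings = model$q,
                   regression_vector = model$B[, model$k],
                   coef_per_factor = model$B, n_factors = model$k,
                   centering = centering, osc = osc,
                   y_deflation = TRUE)
}

.fit_pls1 <- function(Xc, yc, k) {
  Xc <- as.matrix(Xc)
  n <- nrow(Xc); m <- ncol(Xc)
  k <- .check_factors(k, n, m)
  if (length(yc) != n)
    .stop2("aquaphot_shape_error", "yc length %d does not match %d samples",
           length(yc), n)
  if (var(yc) < 1e-24)
    .stop2("aquaphot_degenerate_error", "reference values have zero variance")
  X <- Xc; y <- yc
  W <- P <- matrix(0, m, k)
  Tm <- matrix(0, n, k)
  q <- numeric(k)
  for (j in seq_len(k)) {
    w <- as.numeric(crossprod(X, y))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14)
      .stop2("aquaphot_rank_error",
             "spectra carry no covariance with the response at factor %d", j)
    w <- w / wn
    t_score <- as.numeric(X %*% w)
    tt <- sum(t_score^2)
    if (tt < 1e-28)
      .stop2("aquaphot_rank_error", "zero score variance at factor %d", j)
    p <- as.numeric(crossprod(X, t_score)) / tt
    qj <- sum(y * t_score) / tt
    X <- X - tcrossprod(t_score, p)
    y <- y - t_score * qj
    W[, j] <- w; P[, j] <- p; Tm[, j] <- t_score; q[j] <- qj
  }
  B <- matrix(0, m, k)
  for (j in seq_len(k)) {
    PW <- crossprod(P[, seq_len(j), drop = FALSE], W[, seq_len(j), drop = FALSE])
    coef <- tryCatch(solve(PW, q[seq_len(j)]),
                     error = function(e) .stop2("aquaphot_rank_error",
                                                "singular P'W at %d factors", j))
    B[, j] <- W[, seq_len(j), drop = FALSE] %*% coef
  }
  list(scores = Tm, W = W, P = P, q = q, B = B, k = k)
}

#' Principal component regression
#'
#' Least-squares regression of the centered response on the leading
#' principal-component scores of the centered spectra. Because PCA scores
#' are orthogonal, per-component slopes are independent and nested
#' coefficient vectors accumulate component by component.
#'
#' @inheritParams fit_plsr
#' @return a `latent_model` of kind `"pcr"` with the PCA `scores` and
#'   `x_loadings`, `regression_vector`, and `coef_per_factor`.
#' @export
fit_pcr <- function(Xc, yc, k, centering = NULL, osc = NULL) {
  Xc <- as.matrix(Xc)
  k <- .check_factors(k, nrow(Xc), ncol(Xc))
  if (length(yc) != nrow(Xc))
    .stop2("aquaphot_shape_error", "yc length %d does not match %d samples",
           length(yc), nrow(Xc))
  if (var(yc) < 1e-24)
    .stop2("aquaphot_degenerate_error", "reference values have zero variance")
  pca <- fit_pca(Xc, k)
  Tm <- pca$scores
  tt <- colSums(Tm^2)
  slope <- as.numeric(crossprod(Tm, yc)) / pmax(tt, 1e-300)
  slope[tt < 1e-24] <- 0
  B <- matrix(0, ncol(Xc), k)
  acc <- numeric(ncol(Xc))
  for (j in seq_len(k)) {
    acc <- acc + pca$x_loadings[, j] * slope[j]
    B[, j] <- acc
  }
  new_latent_model("pcr", scores = Tm, x_loadings = pca$x_loadings,
                   y_loadings = slope, regression_vector = B[, k],
                   coef_per_factor = B, n_factors = k,
                   explained_variance = pca$explained_variance,
                   centering = centering, osc = osc)
}

#' Predict reference values from a calibration model
#'
#' When the model embeds a `centering_model` (and optionally an
#' `osc_model`), `X_new` is taken as raw spectra and the pretreatments are
#' replayed: centering with the training means, OSC correction, then
#' `yhat = Xc b + y_mean`. Without an embedded centering model, `X_new`
#' must already be centered and predictions are returned on the centered
#' scale.
#'
#' @param model a `latent_model` of kind `"plsr"`, `"pcr"` or `"plsda"`.
#' @param X_new matrix (or single spectrum) on the training grid.
#' @param n_factors optional reduced factor count (uses the nested
#'   coefficient vectors); defaults to the fitted count.
#' @return numeric vector of predictions.
#' @export
predict_regression <- function(model, X_new, n_factors = NULL) {
  stopifnot(inherits(model, "latent_model"))
  if (!model$kind %in% c("plsr", "pcr", "plsda"))
    .stop2("aquaphot_parameter_error", "model kind '%s' has no regression vector",
           model$kind)
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  m <- nrow(model$coef_per_factor)
  if (ncol(X_new) != m)
    .stop2("aquaphot_shape_error", "spectra have %d columns, model expects %d",
           ncol(X_new), m)
  k <- n_factors %||% model$n_factors
  if (k < 1 || k > model$n_factors)
    .stop2("aquaphot_parameter_error", "n_factors must be in [1, %d]",
           model$n_factors)
  y_mean <- 0
  if (!is.null(model$centering)) {
    X_new <- apply_centering(model$centering, X_new)
    y_mean <- model$centering$y_mean %||% 0
  }
  if (!is.null(model$osc)) X_new <- apply_osc(model$osc, X_new)
  as.numeric(X_new %*% model$coef_per_factor[, k]) + y_mean
}

#' PLS discriminant analysis for two classes
#'
#' PLS1 on a 0/1 dummy response. The first class level (alphabetical for
#' character labels, factor order otherwise) is coded 0, the second 1; the
#' dummy is centered like any reference vector.
#'
#' @param Xc column-centered spectra.
#' @param labels class labels, exactly two distinct values, each with at
#'   least 2 samples.
#' @inheritParams fit_plsr
#' @return a `latent_model` of kind `"plsda"`; `classes` holds the level
#'   ordering (codes 0 and 1), `code_mean` the training dummy mean.
#' @export
fit_plsda <- function(Xc, labels, k, centering = NULL, osc = NULL) {
  f <- factor(labels)
  if (nlevels(f) > 2)
    .stop2("aquaphot_parameter_error",
           "PLS-DA supports exactly 2 classes (got %d)", nlevels(f))
  if (nlevels(f) < 2)
    .stop2("aquaphot_degenerate_error", "PLS-DA needs 2 classes, got one")
  if (any(table(f) < 2))
    .stop2("aquaphot_degenerate_error", "each class needs at least 2 samples")
  y <- as.numeric(f) - 1
  code_mean <- mean(y)
  model <- .fit_pls1(Xc, y - code_mean, k)
  if (!is.null(centering)) centering$y_mean <- code_mean
  new_latent_model("plsda", scores = model$scores, x_weights = model$W,
                   x_loadings = model$P, y_loadings = model$q,
                   regression_vector = model$B[, model$k],
                   coef_per_factor = model$B, n_factors = model$k,
                   classes = levels(f), code_mean = code_mean,
                   centering = centering, osc = osc, y_deflation = TRUE)
}

#' Classify spectra with a fitted PLS-DA model
#'
#' Predicts the dummy code and assigns the class whose code (0 or 1) is
#' nearest; a prediction of exactly 0.5 is left unassigned (`NA`).
#'
#' @param model a `latent_model` of kind `"plsda"`.
#' @param X_new spectra on the training grid (raw if the model embeds
#'   centering, centered otherwise; the centered-code offset is handled
#'   internally in the latter case).
#' @param n_factors optional reduced factor count.
#' @return character vector of class labels with `NA` for unassigned.
#' @export
classify_plsda <- function(model, X_new, n_factors = NULL) {
  stopifnot(inherits(model, "latent_model"), model$kind == "plsda")
  yhat <- predict_regression(model, X_new, n_factors)
  if (is.null(model$centering)) yhat <- yhat + model$code_mean
  out <- ifelse(yhat > 0.5, model$classes[2],
                ifelse(yhat < 0.5, model$classes[1], NA_character_))
  as.character(out)
}
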