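#' Fit a SIMCA class model
#'
#' Soft independent modeling of class analogy: one mean-centered PCA
#' submodel per class. For every ordered class pair (i, j) the samples of
#' class i are projected on class j's submodel (centered with j's mean,
#' projected on j's loadings) and the pooled residual standard deviation
#' `s(i -> j)` recorded. Degrees of freedom follow the classical pooled
#' convention: `n_i * (m - k_j)` for cross fits and
#' `(n_i - k_i - 1) * (m - k_i)` for a class on its own submodel.
#' Acceptance of new samples uses a residual-variance F-test at
#' `critical_quantile` (score-range/leverage limits are not applied; the
#' residual distance is the common core of SIMCA variants and the choice
#' is recorded in the model's `variant` field).
#'
#' @param class_matrices named list of raw (uncentered) spectra matrices,
#'   one per class, all on the same wavelength grid.
#' @param k number of principal components per class: a single shared
#'   count (the default style) or a vector with one entry per class.
#' @param critical_quantile probability of the F acceptance threshold
#'   (default 0.95).
#' @param wavelengths optional wavelength grid (nm), retained so
#'   discriminating power can be reported per wavelength.
#' @return an object of class `simca_model` with `class_labels`,
#'   `submodels` (per class: `mean`, `loadings`, `k`, `n`),
#'   `class_residual_sd`, `cross_residual_sd` (s(i -> j) with rows = data
#'   class i, columns = model class j), per-wavelength residual sds, and
#'   the per-class F acceptance thresholds.
#' @export
fit_simca <- function(class_matrices, k = 2, critical_quantile = 0.95,
                      wavelengths = NULL) {
  if (!is.list(class_matrices) || length(class_matrices) < 2)
    .stop2("aquaphot_parameter_error", "need a list of >= 2 class matrices")
  labels <- names(class_matrices)
  if (is.null(labels) || any(labels == ""))
    labels <- names(class_matrices) <- paste0("class", seq_along(class_matrices))
  nclass <- length(class_matrices)
  ks <- if (length(k) == 1) rep(as.integer(k), nclass) else as.integer(k)
  if (length(ks) != nclass)
    .stop2("aquaphot_parameter_error",
           "k must be a single count or one per class (%d classes)", nclass)
  m <- ncol(class_matrices[[1]])
  submodels <- vector("list", nclass)
  names(submodels) <- labels
  for (i in seq_len(nclass)) {
    Xi <- as.matrix(class_matrices[[i]])
    if (ncol(Xi) != m)
      .stop2("aquaphot_shape_error", "class '%s' has %d columns, expected %d",
             labels[i], ncol(Xi), m)
    if (nrow(Xi) < ks[i] + 2)
      .stop2("aquaphot_degenerate_error",
             "class '%s' needs >= k + 2 = %d samples (got %d)",
             labels[i], ks[i] + 2, nrow(Xi))
    mu <- colMeans(Xi)
    pca <- fit_pca(sweep(Xi, 2, mu), ks[i])
    submodels[[i]] <- list(mean = mu, loadings = pca$x_loadings, k = ks[i],
                           n = nrow(Xi))
  }
  cross_sd <- matrix(0, nclass, nclass, dimnames = list(labels, labels))
  lambda_sd <- array(0, dim = c(nclass, nclass, m),
                     dimnames = list(labels, labels, NULL))
  for (i in seq_len(nclass)) {
    Xi <- as.matrix(class_matrices[[i]])
    ni <- nrow(Xi)
    for (j in seq_len(nclass)) {
      E <- .simca_residuals(submodels[[j]], Xi)
      if (i == j) {
        df_pool <- (ni - ks[i] - 1) * (m - ks[i])
        df_lambda <- ni - ks[i] - 1
      } else {
        df_pool <- ni * (m - ks[j])
        df_lambda <- ni
      }
      cross_sd[i, j] <- sqrt(sum(E^2) / df_pool)
      lambda_sd[i, j, ] <- sqrt(colSums(E^2) / df_lambda)
    }
  }
  f_crit <- vapply(seq_len(nclass), function(j) {
    nj <- submodels[[j]]$n
    qf(critical_quantile, m - ks[j], (nj - ks[j] - 1) * (m - ks[j]))
  }, numeric(1))
  structure(list(class_labels = labels, submodels = submodels,
                 class_residual_sd = diag(cross_sd),
                 cross_residual_sd = cross_sd,
                 lambda_residual_sd = lambda_sd,
                 critical_quantile = critical_quantile, f_crit = f_crit,
                 wavelengths = wavelengths,
                 variant = list(threshold = "residual_F",
                                distance = "sqrt_ratio_null1",
                                leverage_limits = FALSE)),
            class = "simca_model")
}

# residual matrix of samples X against one class submodel
.simca_residuals <- function(sub, X) {
  Xc <- sweep(as.matrix(X), 2, sub$mean)
  Xc - (Xc %*% sub$loadings) %*% t(sub$loadings)
}

#' @export
print.simca_model <- function(x, ...) {
  cat(sprintf("<simca_model> %d classes (%s); k = %s; F threshold at %.2f\n",
              length(x$class_labels), paste(x$class_labels, collapse = ", "),
              paste(vapply(x$submodels, `[[`, 0L, "k"), collapse = "/"),
              x$critical_quantile))
  invisible(x)
}

#' Classify spectra with a SIMCA model
#'
#' Each sample is projected on every class submodel. Its residual standard
#' deviation `s_new = sqrt(RSS / (m - k_j))` is compared with the class's
#' own `s(j -> j)` through the variance-ratio F-test: the sample is
#' accepted by class j when `(s_new / s(j -> j))^2` is below the class
#' threshold. A sample may be accepted by several classes or by none.
#' `nearest_class` is the class with the smallest residual sd (ties broken
#' by model class order).
#'
#' @param model a `simca_model`.
#' @param X_new raw spectra matrix on the training grid.
#' @return an object of class `simca_result`: `assignments` (list of
#'   accepted class-label vectors per sample), `nearest_class` (character),
#'   and the per-sample, per-class `residual_sd` matrix.
#' @export
classify_simca <- function(model, X_new) {
  stopifnot(inherits(model, "simca_model"))
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  m <- length(model$submodels[[1]]$mean)
  if (ncol(X_new) != m)
    .stop2("aquaphot_shape_error", "spectra have %d columns, model expects %d",
           ncol(X_new), m)
  labels <- model$class_labels
  n <- nrow(X_new)
  s_new <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  accept <- matrix(FALSE, n, length(labels), dimnames = list(NULL, labels))
  for (j in seq_along(labels)) {
    sub <- model$submodels[[j]]
    E <- .simca_residuals(sub, X_new)
    s_new[, j] <- sqrt(rowSums(E^2) / (m - sub$k))
    s_jj <- model$class_residual_sd[j]
    accept[, j] <- (s_new[, j] / s_jj)^2 < model$f_crit[j]
  }
  nearest <- labels[apply(s_new, 1, which.min)]
  assignments <- lapply(seq_len(n), function(i) labels[accept[i, ]])
  structure(list(assignments = assignments, nearest_class = nearest,
                 residual_sd = s_new, accepted = accept,
                 class_labels = labels),
            class = "simca_result")
}

#' @export
print.simca_result <- function(x, ...) {
  n_multi <- sum(lengths(x$assignments) > 1)
  n_none <- sum(lengths(x$assignments) == 0)
  cat(sprintf("<simca_result> %d samples; %d unassigned, %d multi-assigned\n",
              length(x$assignments), n_none, n_multi))
  invisible(x)
}

#' SIMCA interclass distances
#'
#' Pooled residual-ratio distance between class models,
#' `d(i, j) = sqrt((s(i->j)^2 + s(j->i)^2) / (s(i->i)^2 + s(j->j)^2))`.
#' The null value for indistinguishable classes is 1 (the plain
#' square-root ratio, not the "-1" variant; the choice is flagged in the
#' model's `variant` field).
#'
#' @param model a fitted `simca_model`.
#' @return symmetric matrix of distances with unit diagonal.
#' @export
simca_interclass_distance <- function(model) {
  stopifnot(inherits(model, "simca_model"))
  s <- model$cross_residual_sd
  nclass <- nrow(s)
  d <- matrix(1, nclass, nclass, dimnames = dimnames(s))
  for (i in seq_len(nclass)) for (j in seq_len(nclass)) {
    d[i, j] <- sqrt((s[i, j]^2 + s[j, i]^2) / (s[i, i]^2 + s[j, j]^2))
  }
  d
}

#' SIMCA discriminating power
#'
#' Per-wavelength ratio of cross-class to within-class residual standard
#' deviations for a pair of classes:
#' `DP(lambda) = sqrt((s_l(1->2)^2 + s_l(2->1)^2) /
#'                    (s_l(1->1)^2 + s_l(2->2)^2))`.
#' Wavelengths with high DP drive the separation between the two class
#' models; DP is ~1 where the classes are indistinguishable.
#'
#' @param model a fitted `simca_model`.
#' @param pair indices or labels of the two classes (default the first
#'   two).
#' @return numeric vector of DP values, one per wavelength (named by
#'   wavelength when the model stores a grid).
#' @export
simca_discriminating_power <- function(model, pair = c(1, 2)) {
  stopifnot(inherits(model, "simca_model"))
  if (is.character(pair)) pair <- match(pair, model$class_labels)
  if (length(pair) != 2 || anyNA(pair))
    .stop2("aquaphot_parameter_error", "pair must name two model classes")
  s <- model$lambda_residual_sd
  i <- pair[1]; j <- pair[2]
  dp <- sqrt((s[i, j, ]^2 + s[j, i, ]^2) / (s[i, i, ]^2 + s[j, j, ]^2))
  if (!is.null(model$wavelengths)) names(dp) <- model$wavelengths
  dp
}
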