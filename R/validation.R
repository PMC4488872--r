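#' Factor cap from sample count
#'
#' To guard against overfitting, the maximum number of latent variables in
#' a calibration is one tenth of the number of samples, rounded down, with
#' a floor of one.
#'
#' @param n sample count.
#' @return integer factor cap, `max(1, floor(n / 10))`.
#' @export
max_factors <- function(n) {
  if (n < 10) return(1L)
  max(1L, as.integer(floor(n / 10)))
}

# fit centering (+ optional OSC) and a nested calibration model on a
# training split; returns a closure predicting held-out rows per factor
.fit_fold <- function(fit_kind, Xtr, ytr, k_max, osc_components) {
  cen <- fit_centering(Xtr, ytr)
  ac <- apply_centering(cen, Xtr, ytr)
  Xc <- ac$X; yc <- ac$y
  osc <- NULL
  if (osc_components > 0) {
    osc <- fit_osc(Xc, yc, osc_components)
    Xc <- apply_osc(osc, Xc)
  }
  model <- switch(fit_kind,
                  plsr = fit_plsr(Xc, yc, k_max),
                  pcr = fit_pcr(Xc, yc, k_max),
                  .stop2("aquaphot_parameter_error", "unknown fit kind '%s'",
                         fit_kind))
  function(Xte) {
    Xte <- apply_centering(cen, Xte)
    if (!is.null(osc)) Xte <- apply_osc(osc, Xte)
    (Xte %*% model$coef_per_factor) + cen$y_mean
  }
}

.cv_engine <- function(fit_kind, X, y, folds, k_max, pretreatment) {
  X <- as.matrix(X)
  n <- nrow(X)
  osc_components <- pretreatment$osc_components %||% 0
  classes <- NULL
  if (fit_kind == "plsda") {
    f <- factor(y)
    if (nlevels(f) != 2)
      .stop2("aquaphot_parameter_error", "PLS-DA cross-validation needs 2 classes")
    classes <- levels(f)
    y <- as.numeric(f) - 1
    inner_kind <- "plsr"
  } else {
    inner_kind <- fit_kind
    y <- as.numeric(y)
  }
  for (fold in folds) {
    n_train <- n - length(fold)
    if (k_max > min(n_train - 1, ncol(X)))
      .stop2("aquaphot_parameter_error",
             "k_max = %d infeasible on a fold with %d training samples",
             k_max, n_train)
  }
  preds <- matrix(NA_real_, n, k_max)
  for (fold in folds) {
    predict_fold <- .fit_fold(inner_kind, X[-fold, , drop = FALSE], y[-fold],
                              k_max, osc_components)
    preds[fold, ] <- predict_fold(X[fold, , drop = FALSE])
  }
  secv <- sqrt(colSums((y - preds)^2) / n)
  structure(list(fit_kind = fit_kind, predictions = preds, y = y,
                 per_factor_secv = secv, k_max = k_max, classes = classes,
                 n_folds = length(folds)),
            class = "cv_result")
}

#' Leave-one-out cross-validation of a calibration pipeline
#'
#' For every left-out sample the full pipeline — mean centering, optional
#' orthogonal signal correction, and the calibration model — is refit on
#' the remaining samples and the held-out spectrum predicted at every
#' factor count up to `k_max`. OSC is always refit inside the fold:
#' because it uses the reference values, fitting it once on the full set
#' would leak information into the cross-validation.
#'
#' @param fit_kind `"plsr"`, `"pcr"` or `"plsda"`.
#' @param X raw spectra matrix (already smoothed/windowed as desired).
#' @param y reference values (numeric) or, for `"plsda"`, class labels.
#' @param k_max largest factor count to evaluate (must be feasible on
#'   every fold).
#' @param pretreatment list of per-fold pretreatment settings; currently
#'   `osc_components` (default 0).
#' @return a `cv_result`: `predictions` (n x k_max, dummy-code scale for
#'   PLS-DA), `per_factor_secv`, and `classes` for PLS-DA.
#' @export
loo_crossvalidate <- function(fit_kind, X, y, k_max,
                              pretreatment = list(osc_components = 0)) {
  n <- nrow(as.matrix(X))
  if (n < 3)
    .stop2("aquaphot_degenerate_error", "need at least 3 samples for LOO")
  .cv_engine(fit_kind, X, y, as.list(seq_len(n)), k_max, pretreatment)
}

#' Leave-one-group-out cross-validation
#'
#' Hold-out validation over user-supplied groups (batches or classes):
#' each group is predicted by a pipeline refit on all remaining groups.
#' With one group per sample this reduces exactly to [loo_crossvalidate()].
#'
#' @inheritParams loo_crossvalidate
#' @param groups group labels, one per sample, at least 2 distinct.
#' @return a `cv_result` (one fold per group).
#' @export
group_holdout_validate <- function(fit_kind, X, y, groups, k_max,
                                   pretreatment = list(osc_components = 0)) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2)
    .stop2("aquaphot_parameter_error", "need at least 2 groups")
  if (length(groups) != nrow(as.matrix(X)))
    .stop2("aquaphot_shape_error", "groups length does not match sample count")
  folds <- lapply(unique(groups), function(g) which(groups == g))
  .cv_engine(fit_kind, X, y, folds, k_max, pretreatment)
}

#' Calibration and cross-validation metrics
#'
#' The headline quality numbers of a quantitative calibration: Pearson
#' correlations of the calibration fit (`r_cal`) and of the
#' cross-validated predictions (`r_val`) against the reference, the
#' standard error of calibration `SEC = sqrt(RSS_cal / (n - k - 1))` (the
#' intercept absorbed by mean centering consumes one degree of freedom),
#' and the standard error of cross-validation `SECV = sqrt(RSS_cv / n)`.
#'
#' @param y reference values.
#' @param yhat_cal fitted (calibration) predictions.
#' @param yhat_cv cross-validated predictions (may be `NULL` to skip
#'   r_val/SECV).
#' @param k number of latent variables used.
#' @return an object of class `calibration_result`.
#' @export
calibration_metrics <- function(y, yhat_cal, yhat_cv, k) {
  n <- length(y)
  if (length(yhat_cal) != n || (!is.null(yhat_cv) && length(yhat_cv) != n))
    .stop2("aquaphot_shape_error", "prediction vectors must match length(y)")
  if (n <= k + 1)
    .stop2("aquaphot_parameter_error", "need n > k + 1 (n = %d, k = %d)", n, k)
  if (var(y) < 1e-24)
    .stop2("aquaphot_degenerate_error",
           "reference values have zero variance; correlation undefined")
  sec <- sqrt(sum((y - yhat_cal)^2) / (n - k - 1))
  r_cal <- if (sd(yhat_cal) < 1e-15) 0 else cor(y, yhat_cal)
  r_val <- secv <- NULL
  if (!is.null(yhat_cv)) {
    secv <- sqrt(sum((y - yhat_cv)^2) / n)
    r_val <- if (sd(yhat_cv) < 1e-15) 0 else cor(y, yhat_cv)
  }
  structure(list(n = n, n_factors = k, r_cal = r_cal, sec = sec,
                 r_val = r_val, secv = secv,
                 predictions_cal = yhat_cal, predictions_cv = yhat_cv,
                 conventions = list(sec_df = "n - k - 1", secv_df = "n")),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> N = %d, Factor # = %d, r Cal = %.4f, SEC = %.4f",
              x$n, x$n_factors, x$r_cal, x$sec))
  if (!is.null(x$r_val))
    cat(sprintf(", r Val = %.4f, SECV = %.4f", x$r_val, x$secv))
  cat("\n")
  invisible(x)
}

#' Pick the optimum factor count
#'
#' The factor count with the lowest cross-validation error; ties go to the
#' smaller (more parsimonious) count.
#'
#' @param per_factor_secv SECV values for factor counts `1..length(...)`.
#' @param k_max optional cap (defaults to the vector length).
#' @return integer `k_opt`.
#' @export
select_factors <- function(per_factor_secv, k_max = length(per_factor_secv)) {
  if (length(per_factor_secv) == 0)
    .stop2("aquaphot_parameter_error", "empty SECV vector")
  k_max <- min(k_max, length(per_factor_secv))
  as.integer(which.min(per_factor_secv[seq_len(k_max)]))
}

#' Summarise classification performance
#'
#' Strict scoring: a sample counts as correct only when it is assigned to
#' its true class and to no other. For SIMCA results this means accepted
#' by exactly the true class; multi-accepted and unaccepted samples count
#' as incorrect. For label vectors (PLS-DA), `NA` predictions count as
#' unassigned and incorrect.
#'
#' @param true_labels character vector of true classes.
#' @param result a `simca_result`, or a character vector of predicted
#'   labels (optionally carrying a `classes` attribute).
#' @return an object of class `classification_summary` with per-class
#'   confusion counts, `ratio_correct`, `n_unassigned` and
#'   `n_multi_assigned`.
#' @export
misclassification_summary <- function(true_labels, result) {
  true_labels <- as.character(true_labels)
  n <- length(true_labels)
  if (inherits(result, "simca_result")) {
    if (length(result$assignments) != n)
      .stop2("aquaphot_shape_error", "result has %d samples, labels %d",
             length(result$assignments), n)
    if (!all(true_labels %in% result$class_labels))
      .stop2("aquaphot_label_error", "true labels outside model classes: %s",
             paste(setdiff(true_labels, result$class_labels), collapse = ", "))
    correct <- vapply(seq_len(n), function(i)
      identical(result$assignments[[i]], true_labels[i]), logical(1))
    n_unassigned <- sum(lengths(result$assignments) == 0)
    n_multi <- sum(lengths(result$assignments) > 1)
    predicted <- result$nearest_class
  } else {
    predicted <- as.character(result)
    if (length(predicted) != n)
      .stop2("aquaphot_shape_error", "predictions have length %d, labels %d",
             length(predicted), n)
    model_classes <- attr(result, "classes")
    if (!is.null(model_classes) && !all(true_labels %in% model_classes))
      .stop2("aquaphot_label_error", "true labels outside model classes: %s",
             paste(setdiff(true_labels, model_classes), collapse = ", "))
    correct <- !is.na(predicted) & predicted == true_labels
    n_unassigned <- sum(is.na(predicted))
    n_multi <- 0L
    predicted[is.na(predicted)] <- "<none>"
  }
  confusion <- table(true = true_labels, predicted = predicted)
  structure(list(n = n, n_correct = sum(correct),
                 ratio_correct = sum(correct) / n,
                 n_unassigned = n_unassigned, n_multi_assigned = n_multi,
                 confusion = confusion),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("<classification_summary> %d/%d correct (%.1f%%), %d unassigned, %d multi-assigned\n",
              x$n_correct, x$n, 100 * x$ratio_correct, x$n_unassigned,
              x$n_multi_assigned))
  print(x$confusion)
  invisible(x)
}
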