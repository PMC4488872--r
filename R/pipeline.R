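#' Build an experiment configuration
#'
#' Describes one end-to-end analysis: where the spectra come from (a
#' delimited file or a synthetic generator config), the wavelength window
#' and pretreatments, the task and model menu, the validation scheme, and
#' peak/annotation settings. The fixed processing order is smoothing ->
#' wavelength selection -> (inside every validation fold) mean centering
#' -> OSC (regression and PLS-DA only) -> model.
#'
#' @param input path to a spectra table (see [read_spectra_table()]), or
#'   `NULL` when `synthetic` is given.
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param wavelength_range length-2 numeric window in nm, or `NULL` for
#'   the full grid.
#' @param smoothing_points odd window width, or `NULL` for no smoothing.
#' @param smoothing_method `"moving_average"` or `"polynomial_order2"`.
#' @param osc_components OSC components removed inside each fold
#'   (regression/PLS-DA models only; SIMCA never uses OSC).
#' @param task `"regression"` or `"discrimination"`.
#' @param models model kinds to run: subset of `c("plsr", "pcr")` for
#'   regression, of `c("plsda", "simca")` for discrimination.
#' @param response metadata column holding the reference values
#'   (regression).
#' @param class_column metadata column holding class labels
#'   (discrimination).
#' @param validation `"loo"` or `"group"`.
#' @param group_column metadata column defining hold-out groups when
#'   `validation = "group"`.
#' @param factor_cap override of the [max_factors()] cap, or `NULL`.
#' @param simca_k principal components per SIMCA class submodel.
#' @param min_prominence peak prominence threshold (fraction of max
#'   absolute value) for regression-vector / discriminating-power peaks.
#' @param output_dir directory for the JSON report and text tables, or
#'   `NULL` to skip writing.
#' @param seed integer seed recorded in the report (and controlling any
#'   synthetic input).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(input = NULL, synthetic = NULL,
                              wavelength_range = NULL,
                              smoothing_points = NULL,
                              smoothing_method = "moving_average",
                              osc_components = 1,
                              task = c("regression", "discrimination"),
                              models = NULL,
                              response = "tt_conc",
                              class_column = "class_label",
                              validation = c("loo", "group"),
                              group_column = "batch",
                              factor_cap = NULL,
                              simca_k = 2,
                              min_prominence = 0.1,
                              output_dir = NULL,
                              seed = 1) {
  task <- match.arg(task)
  validation <- match.arg(validation)
  if (is.null(models))
    models <- if (task == "regression") c("plsr", "pcr") else c("plsda", "simca")
  allowed <- if (task == "regression") c("plsr", "pcr") else c("plsda", "simca")
  if (!all(models %in% allowed))
    .stop2("aquaphot_config_error", "models %s incompatible with task '%s'",
           paste(setdiff(models, allowed), collapse = ", "), task)
  if (is.null(input) && is.null(synthetic))
    .stop2("aquaphot_config_error", "either input or synthetic must be given")
  structure(list(input = input, synthetic = synthetic,
                 wavelength_range = wavelength_range,
                 smoothing_points = smoothing_points,
                 smoothing_method = smoothing_method,
                 osc_components = osc_components, task = task,
                 models = models, response = response,
                 class_column = class_column, validation = validation,
                 group_column = group_column, factor_cap = factor_cap,
                 simca_k = simca_k, min_prominence = min_prominence,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  # hash the scientific settings only: where the report lands is not part
  # of the analysis identity
  plain <- rapply(unclass(config)[setdiff(names(config), "output_dir")],
                  unclass, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

.peaks_for_report <- function(values, wavelengths, min_prominence) {
  pk <- detect_peaks(values, wavelengths, min_prominence)
  pk <- annotate_peaks(pk)
  pk$bands <- vapply(pk$bands, paste, "", collapse = "+")
  pk
}

# CV, factor choice, full refit and metrics for one regression model kind
.run_regression_model <- function(kind, X, y, w, config, k_cap, cv_fun) {
  cv <- cv_fun(kind, X, y, k_cap,
               pretreatment = list(osc_components = config$osc_components))
  k_opt <- select_factors(cv$per_factor_secv)
  cen <- fit_centering(X, y)
  ac <- apply_centering(cen, X, y)
  Xc <- ac$X; yc <- ac$y
  osc <- NULL
  if (config$osc_components > 0) {
    osc <- fit_osc(Xc, yc, config$osc_components)
    Xc <- apply_osc(osc, Xc)
  }
  model <- switch(kind,
                  plsr = fit_plsr(Xc, yc, k_opt, centering = cen, osc = osc),
                  pcr = fit_pcr(Xc, yc, k_opt, centering = cen, osc = osc))
  yhat_cal <- predict_regression(model, X)
  metrics <- calibration_metrics(y, yhat_cal, cv$predictions[, k_opt], k_opt)
  peaks <- .peaks_for_report(model$regression_vector, w, config$min_prominence)
  list(model_kind = kind, n = length(y), n_factors = k_opt,
       r_cal = metrics$r_cal, sec = metrics$sec,
       r_val = metrics$r_val, secv = metrics$secv,
       per_factor_secv = cv$per_factor_secv,
       predictions_cal = yhat_cal, predictions_cv = cv$predictions[, k_opt],
       regression_vector = model$regression_vector, peaks = peaks)
}

#' Run a configured experiment end-to-end
#'
#' Executes the full pipeline described by an [experiment_config()]:
#' data loading or simulation, smoothing, wavelength selection, then per
#' model — with centering and OSC refit inside every cross-validation
#' fold — model fitting, metrics, peak detection and water-band
#' annotation. When `output_dir` is set, a JSON report and a plain-text
#' calibration table are written atomically.
#'
#' @param config an [experiment_config()].
#' @return an object of class `experiment_report`: per-model results,
#'   interclass distances and discriminating power for SIMCA, peak
#'   annotations, and provenance (config hash, seed, formula-variant
#'   flags).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(config$synthetic)) {
    data <- simulate_dataset(config$synthetic)$spectra
  } else {
    if (!file.exists(config$input))
      .stop2("aquaphot_io_error", "input not found: %s", config$input)
    data <- read_spectra_table(config$input)
  }
  if (!is.null(config$smoothing_points))
    data <- smooth_spectra(data, config$smoothing_points,
                           config$smoothing_method)
  if (!is.null(config$wavelength_range))
    data <- select_wavelength_range(data, config$wavelength_range[1],
                                    config$wavelength_range[2])
  X <- data$absorbance
  w <- data$wavelengths
  n <- nrow(X)
  results <- list()
  if (config$task == "regression") {
    y <- data$meta[[config$response]]
    if (is.null(y) || anyNA(y))
      .stop2("aquaphot_config_error",
             "response column '%s' missing or incomplete", config$response)
    k_cap <- min(config$factor_cap %||% max_factors(n), n - 2, length(w))
    cv_fun <- if (config$validation == "loo") {
      function(kind, X, y, k, pretreatment)
        loo_crossvalidate(kind, X, y, k, pretreatment)
    } else {
      groups <- data$meta[[config$group_column]]
      function(kind, X, y, k, pretreatment)
        group_holdout_validate(kind, X, y, groups, k, pretreatment)
    }
    for (kind in config$models)
      results[[kind]] <- .run_regression_model(kind, X, y, w, config, k_cap,
                                               cv_fun)
  } else {
    labels <- data$meta[[config$class_column]]
    if (is.null(labels) || anyNA(labels))
      .stop2("aquaphot_config_error",
             "class column '%s' missing or incomplete", config$class_column)
    labels <- as.character(labels)
    if ("plsda" %in% config$models) {
      k_cap <- min(config$factor_cap %||% max_factors(n), n - 2, length(w))
      cv <- loo_crossvalidate("plsda", X, labels, k_cap,
                              pretreatment = list(osc_components = config$osc_components))
      k_opt <- select_factors(cv$per_factor_secv)
      pred_cv <- ifelse(cv$predictions[, k_opt] > 0.5, cv$classes[2],
                        ifelse(cv$predictions[, k_opt] < 0.5, cv$classes[1],
                               NA_character_))
      attr(pred_cv, "classes") <- cv$classes
      summary <- misclassification_summary(labels, pred_cv)
      cen <- fit_centering(X, as.numeric(factor(labels)) - 1)
      Xc <- apply_centering(cen, X)
      yc <- as.numeric(factor(labels)) - 1 - mean(as.numeric(factor(labels)) - 1)
      osc <- NULL
      if (config$osc_components > 0) {
        osc <- fit_osc(Xc, yc, config$osc_components)
        Xc <- apply_osc(osc, Xc)
      }
      model <- fit_plsda(Xc, labels, k_opt, centering = cen, osc = osc)
      peaks <- .peaks_for_report(model$regression_vector, w,
                                 config$min_prominence)
      results$plsda <- list(model_kind = "plsda", n = n, n_factors = k_opt,
                            ratio_correct = summary$ratio_correct,
                            n_correct = summary$n_correct,
                            n_unassigned = summary$n_unassigned,
                            confusion = as.data.frame(summary$confusion),
                            regression_vector = model$regression_vector,
                            peaks = peaks)
    }
    if ("simca" %in% config$models) {
      split_X <- lapply(split(seq_len(n), labels), function(i)
        X[i, , drop = FALSE])
      model <- fit_simca(split_X, k = config$simca_k, wavelengths = w)
      res <- classify_simca(model, X)
      summary <- misclassification_summary(labels, res)
      dist <- simca_interclass_distance(model)
      dp <- if (length(model$class_labels) == 2)
        simca_discriminating_power(model) else NULL
      peaks <- if (!is.null(dp))
        .peaks_for_report(dp - 1, w, config$min_prominence) else NULL
      results$simca <- list(model_kind = "simca", n = n,
                            k_per_class = vapply(model$submodels, `[[`, 0L, "k"),
                            ratio_correct = summary$ratio_correct,
                            n_correct = summary$n_correct,
                            n_unassigned = summary$n_unassigned,
                            n_multi_assigned = summary$n_multi_assigned,
                            interclass_distance = dist,
                            discriminating_power = dp, peaks = peaks,
                            variant = model$variant)
    }
  }
  report <- structure(list(version = SERIAL_VERSION, task = config$task,
                           n = n, wavelengths = range(w),
                           results = results,
                           provenance = list(config_hash = .config_hash(config),
                                             seed = config$seed,
                                             sec_df = "n - k - 1",
                                             secv_df = "n",
                                             simca_distance = "sqrt_ratio_null1")),
                      class = "experiment_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write an experiment report
#'
#' Writes `report.json` (full numeric precision) and, for regression
#' tasks, `calibration_table.txt` with the classic layout N / Model /
#' Factor # / r Cal / SEC / r Val / SECV. Files are written to a
#' temporary name then renamed, so a failed run leaves no partial report.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the report path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "report.json")
  tmp <- paste0(path, ".tmp")
  plain <- rapply(unclass(report), unclass, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE, dataframe = "columns")
  file.rename(tmp, path)
  if (report$task == "regression") {
    tab <- calibration_table(report)
    ttmp <- file.path(dir, "calibration_table.txt.tmp")
    writeLines(tab, ttmp)
    file.rename(ttmp, file.path(dir, "calibration_table.txt"))
  }
  invisible(path)
}

#' Plain-text calibration table
#'
#' Formats the regression results of a report as a fixed-width table with
#' columns N, Model, Factor #, r Cal, SEC, r Val, SECV.
#'
#' @param report an `experiment_report` from a regression task.
#' @return character vector of table lines.
#' @export
calibration_table <- function(report) {
  rows <- Filter(function(r) r$model_kind %in% c("plsr", "pcr"),
                 report$results)
  header <- sprintf("%-5s %-6s %-9s %-8s %-8s %-8s %-8s",
                    "N", "Model", "Factor #", "r Cal", "SEC", "r Val", "SECV")
  body <- vapply(rows, function(r)
    sprintf("%-5d %-6s %-9d %-8.4f %-8.4f %-8.4f %-8.4f",
            r$n, toupper(r$model_kind), r$n_factors, r$r_cal, r$sec,
            r$r_val, r$secv), character(1))
  c(header, unname(body))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> task = %s, n = %d, %g-%g nm\n",
              x$task, x$n, x$wavelengths[1], x$wavelengths[2]))
  for (r in x$results) {
    if (r$model_kind %in% c("plsr", "pcr"))
      cat(sprintf("  %s: k = %d, r Cal = %.4f, SEC = %.4f, r Val = %.4f, SECV = %.4f\n",
                  toupper(r$model_kind), r$n_factors, r$r_cal, r$sec, r$r_val,
                  r$secv))
    else
      cat(sprintf("  %s: %.1f%% correctly classified\n",
                  toupper(r$model_kind), 100 * r$ratio_correct))
  }
  invisible(x)
}
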