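SERIAL_VERSION <- "1.0"

#' Serialize a fitted model to JSON
#'
#' Writes a versioned JSON document holding every array of a
#' `latent_model` (loadings, weights, regression vector, embedded
#' centering and OSC pretreatments) at full numeric precision, so a
#' stored calibration re-applies with predictions identical to within
#' double-precision round-off.
#'
#' @param model a `latent_model`.
#' @param path destination `.json` path.
#' @return invisibly, `path`.
#' @export
serialize_latent_model <- function(model, path) {
  stopifnot(inherits(model, "latent_model"))
  doc <- list(format = "aquaphot_latent_model", version = SERIAL_VERSION,
              kind = model$kind, n_factors = model$n_factors)
  for (field in c("scores", "x_loadings", "x_weights", "y_loadings",
                  "regression_vector", "coef_per_factor",
                  "explained_variance", "classes", "code_mean",
                  "y_deflation"))
    if (!is.null(model[[field]])) doc[[field]] <- model[[field]]
  if (!is.null(model$centering))
    doc$centering <- list(x_mean = model$centering$x_mean,
                          y_mean = model$centering$y_mean)
  if (!is.null(model$osc))
    doc$osc <- list(weights = model$osc$weights,
                    loadings = model$osc$loadings,
                    n_components = model$osc$n_components,
                    variant = model$osc$variant)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized model back
#' @param path path written by [serialize_latent_model()].
#' @return the reconstructed `latent_model`.
#' @export
read_latent_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "aquaphot_latent_model"))
    .stop2("aquaphot_parse_error", "not an aquaphot model document: %s", path)
  model <- doc[setdiff(names(doc), c("format", "version", "centering", "osc"))]
  for (field in c("scores", "x_loadings", "x_weights", "coef_per_factor"))
    if (!is.null(model[[field]])) model[[field]] <- as.matrix(model[[field]])
  if (!is.null(doc$centering))
    model$centering <- structure(list(x_mean = as.numeric(doc$centering$x_mean),
                                      y_mean = doc$centering$y_mean),
                                 class = "centering_model")
  if (!is.null(doc$osc))
    model$osc <- structure(list(weights = as.matrix(doc$osc$weights),
                                loadings = as.matrix(doc$osc$loadings),
                                n_components = doc$osc$n_components,
                                variant = doc$osc$variant),
                           class = "osc_model")
  class(model) <- "latent_model"
  model
}
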