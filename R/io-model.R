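MODEL_FORMAT_VERSION <- "hairpin3d-model-1"

#' Persist and restore trained classifiers
#'
#' Models are written with a format-version tag and the classifier kind, so
#' a load under a different format fails explicitly instead of silently
#' producing a misbehaving object. A restored model predicts identically to
#' the original on any feature table.
#'
#' @param model A `hairpin_model` from [train_classifier()] or the
#'   `best_models` of [monte_carlo_cv()].
#' @param path File path.
#' @return `load_model()` returns the `hairpin_model`; `save_model()` returns
#'   `path` invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "hairpin_model")) {
    stop_schema("save_model() expects a 'hairpin_model' object")
  }
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    kind = model$kind,
    model = model
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop_input(paste0("model file not found: ", path))
  }
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop_input(paste0("corrupt or truncated model file: ", path))
  })
  if (!is.list(payload) || is.null(payload$format_version)) {
    stop_input(paste0("not a hairpin3d model file: ", path))
  }
  if (!identical(payload$format_version, MODEL_FORMAT_VERSION)) {
    stop_input(paste0(
      "model format version mismatch: file has '", payload$format_version,
      "', this package reads '", MODEL_FORMAT_VERSION, "'"
    ))
  }
  if (!payload$kind %in% c("decision_tree", "naive_bayes", "random_forest")) {
    stop_input(paste0("unknown classifier kind in model file: ", payload$kind))
  }
  payload$model
}
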