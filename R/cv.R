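#' Balanced Monte Carlo cross-validation over three classifiers
#'
#' For each repetition: draw a balanced sample from the positive and
#' negative feature tables, split it 70/30 (stratified), train every
#' requested classifier on the learning set, and evaluate it on the held-out
#' testing set. All per-repetition metric sets are recorded, and for each
#' classifier the model with the highest held-out accuracy is retained
#' (ties resolve to the smallest repetition index). Each repetition runs
#' under a seed derived deterministically from `config$seed` (see
#' [cv_config()]), so runs with equal configuration are byte-identical.
#'
#' @param pos,neg Feature tibbles for the positive (miRNA) and negative
#'   (pseudohairpin) corpora.
#' @param config A [cv_config()].
#' @return A `hairpin_cv` object with elements `metrics` (tibble of
#'   `repeats * length(classifiers)` rows), `best_models` (named list of
#'   `hairpin_model`s), `best_repetition` (named integer vector) and
#'   `config`. Use [tidy()] / [glance()] / [ggplot2::autoplot()] on it.
#' @examples
#' \donttest{
#' corpus <- simulate_corpus(synth_config(n_pos = 30, n_neg = 30, seed = 7))
#' pos <- featurize_hairpins(corpus$pos, label = "positive")
#' neg <- featurize_hairpins(corpus$neg, label = "negative")
#' cv <- monte_carlo_cv(pos, neg, cv_config(repeats = 3, seed = 7))
#' glance(cv)
#' }
#' @export
monte_carlo_cv <- function(pos, neg, config = cv_config()) {
  check_feature_table(pos)
  check_feature_table(neg)
  if (!inherits(config, "cv_config")) stop_input("config must be a cv_config()")
  metric_rows <- vector("list", config$repeats * length(config$classifiers))
  best_models <- stats::setNames(vector("list", length(config$classifiers)), config$classifiers)
  best_acc <- stats::setNames(rep(-Inf, length(config$classifiers)), config$classifiers)
  best_rep <- stats::setNames(rep(NA_integer_, length(config$classifiers)), config$classifiers)
  row_i <- 0L
  for (r in seq_len(config$repeats)) {
    seed_r <- repetition_seed(config$seed, r)
    res <- withr::with_seed(seed_r, tryCatch(
      run_repetition(pos, neg, config),
      hairpin3d_error = function(e) {
        stop_input(paste0("repetition ", r, " failed: ", conditionMessage(e)))
      }
    ))
    for (kind in config$classifiers) {
      row_i <- row_i + 1L
      m <- res$metrics[[kind]]
      metric_rows[[row_i]] <- dplyr::bind_cols(
        tibble(repetition = r, classifier = kind), m
      )
      if (m$accuracy > best_acc[[kind]]) {
        best_acc[[kind]] <- m$accuracy
        best_rep[[kind]] <- r
        model <- res$models[[kind]]
        model$metadata$trained_at_repetition <- r
        model$metadata$seed <- seed_r
        best_models[[kind]] <- model
      }
    }
  }
  structure(
    list(
      metrics = dplyr::bind_rows(metric_rows),
      best_models = best_models,
      best_repetition = best_rep,
      config = config
    ),
    class = "hairpin_cv"
  )
}

run_repetition <- function(pos, neg, config) {
  sampled <- balanced_sample(pos, neg)
  parts <- split_features(sampled, config$train_fraction)
  models <- list()
  metrics <- list()
  for (kind in config$classifiers) {
    model <- train_classifier(parts$train, kind, config)
    preds <- predict(model, parts$test)
    truth <- parts$test$label
    metrics[[kind]] <- evaluate_predictions(preds, truth)
    models[[kind]] <- model
  }
  list(models = models, metrics = metrics)
}

#' @export
print.hairpin_cv <- function(x, ...) {
  cat("<hairpin_cv>", x$config$repeats, "Monte Carlo repetitions,",
      sprintf("%.0f%%/%.0f%% split,", 100 * x$config$train_fraction,
              100 * (1 - x$config$train_fraction)),
      length(x$config$classifiers), "classifier(s)\n")
  print(glance(x))
  invisible(x)
}

#' Tidy a Monte Carlo cross-validation result
#'
#' @param x A `hairpin_cv` object.
#' @param ... Unused.
#' @return The per-repetition, per-classifier metric tibble.
#' @export
tidy.hairpin_cv <- function(x, ...) {
  x$metrics
}

#' Summarize a Monte Carlo cross-validation result per classifier
#'
#' @param x A `hairpin_cv` object.
#' @param ... Unused.
#' @return One row per classifier: median and best held-out accuracy, the
#'   repetition achieving the best, and median F-measure.
#' @export
glance.hairpin_cv <- function(x, ...) {
  out <- dplyr::summarise(
    dplyr::group_by(x$metrics, .data$classifier),
    median_accuracy = stats::median(.data$accuracy),
    best_accuracy = max(.data$accuracy),
    median_f_measure = stats::median(.data$f_measure),
    .groups = "drop"
  )
  out$best_repetition <- unname(x$best_repetition[out$classifier])
  out
}

#' Distribution of held-out metrics across repetitions
#'
#' @param object A `hairpin_cv` object.
#' @param metric Which metric column to show (default `"accuracy"`).
#' @param ... Unused.
#' @return A ggplot object (one box per classifier).
#' @export
autoplot.hairpin_cv <- function(object, metric = "accuracy", ...) {
  if (!metric %in% names(object$metrics)) {
    stop_input(paste0("unknown metric: ", metric))
  }
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$classifier, y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = paste("held-out", metric)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
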