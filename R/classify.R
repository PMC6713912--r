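#' Cross-validation configuration
#'
#' Defaults follow the study protocol: balanced sampling, a 70% learning /
#' 30% testing stratified split, and 1000-fold Monte Carlo cross-validation
#' over all three classifiers.
#'
#' @param repeats Number of Monte Carlo repetitions (default 1000).
#' @param train_fraction Fraction of each class assigned to the learning
#'   set (default 0.70).
#' @param seed Integer master seed; per-repetition seeds are derived from it
#'   (see Details).
#' @param classifiers Subset of `"decision_tree"`, `"naive_bayes"`,
#'   `"random_forest"` (default all three).
#' @param rf_trees Trees per random forest (default 100).
#' @param rf_mtry Features tried at each forest split; default
#'   `ceiling(sqrt(36)) = 6`.
#' @details Repetition `r` runs under the derived seed
#'   `(seed * 48271 + r) mod (2^31 - 1)` (a fixed multiplicative scheme), so
#'   any single repetition is independently reproducible.
#' @return A `cv_config` list.
#' @export
cv_config <- function(repeats = 1000L, train_fraction = 0.70, seed = 1L,
                      classifiers = c("decision_tree", "naive_bayes", "random_forest"),
                      rf_trees = 100L, rf_mtry = 6L) {
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1) stop_input("repeats must be a positive integer")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_input("train_fraction must lie strictly between 0 and 1")
  }
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  rf_trees <- as.integer(rf_trees)
  if (is.na(rf_trees) || rf_trees < 1) stop_input("rf_trees must be a positive integer")
  structure(
    list(
      repeats = repeats, train_fraction = train_fraction,
      seed = as.integer(seed), classifiers = classifiers,
      rf_trees = rf_trees, rf_mtry = as.integer(rf_mtry)
    ),
    class = "cv_config"
  )
}

repetition_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + r) %% 2147483647)
}

#' Draw a balanced two-class sample
#'
#' Removes class imbalance before learning by sampling, without
#' replacement, `n = min(nrow(pos), nrow(neg))` rows from each class and
#' attaching the labels `"positive"` and `"negative"`.
#'
#' @param pos,neg Feature tibbles (see [featurize_hairpins()]) with matching
#'   descriptor schemas.
#' @param seed Optional integer seed; the same seed always selects the same
#'   rows.
#' @return A labeled feature tibble with `2 * min(nrow(pos), nrow(neg))`
#'   rows, positives first.
#' @export
balanced_sample <- function(pos, neg, seed = NULL) {
  check_feature_table(pos)
  check_feature_table(neg)
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    stop_input("both classes must be non-empty for balanced sampling")
  }
  n <- min(nrow(pos), nrow(neg))
  draw <- function() {
    pi <- sort(sample.int(nrow(pos), n))
    ni <- sort(sample.int(nrow(neg), n))
    p <- pos[pi, ]
    p$label <- "positive"
    q <- neg[ni, ]
    q$label <- "negative"
    dplyr::bind_rows(p, q)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Stratified train/test split
#'
#' Splits a labeled feature table into disjoint, exhaustive learning and
#' testing sets, stratified by label. The per-class learning size is
#' `round-half-up(train_fraction * class size)`; the remainder goes to the
#' testing set.
#'
#' @param table A labeled feature tibble.
#' @param train_fraction Fraction assigned to the learning set.
#' @param seed Optional integer seed for the random partition.
#' @return A list with elements `train` and `test`.
#' @export
split_features <- function(table, train_fraction = 0.70, seed = NULL) {
  check_feature_table(table, labeled = TRUE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_input("train_fraction must lie strictly between 0 and 1")
  }
  do_split <- function() {
    train_idx <- integer(0)
    for (lab in unique(table$label)) {
      rows <- which(table$label == lab)
      if (length(rows) < 2) {
        stop_input(paste0("class '", lab, "' has fewer than 2 rows; cannot stratify"))
      }
      n_train <- floor(train_fraction * length(rows) + 0.5)
      n_train <- max(1L, min(length(rows) - 1L, n_train))
      train_idx <- c(train_idx, sample(rows, n_train))
    }
    train_idx <- sort(train_idx)
    list(train = table[train_idx, ], test = table[-train_idx, ])
  }
  if (is.null(seed)) do_split() else withr::with_seed(seed, do_split())
}

#' Train one classifier on a labeled feature table
#'
#' Fits one of the three learners on the 36-feature descriptor:
#' a single impurity-minimizing decision tree ([rpart::rpart()]), a Gaussian
#' naive-Bayes model with class priors from training frequencies
#' ([e1071::naiveBayes()], with a variance floor of `1e-9` so constant
#' features cannot produce degenerate likelihoods), or a bootstrap-aggregated
#' random forest with random feature subsetting
#' ([randomForest::randomForest()]). Training is deterministic given a seed.
#'
#' @param train_table Labeled feature tibble with both classes present.
#' @param kind `"decision_tree"`, `"naive_bayes"` or `"random_forest"`.
#' @param config A [cv_config()] supplying forest hyperparameters.
#' @param seed Optional integer seed.
#' @return A `hairpin_model` object.
#' @export
train_classifier <- function(train_table,
                             kind = c("decision_tree", "naive_bayes", "random_forest"),
                             config = cv_config(), seed = NULL) {
  kind <- match.arg(kind)
  check_feature_table(train_table, labeled = TRUE)
  if (length(unique(train_table$label)) < 2) {
    stop_input("training table contains a single class; two classes are required")
  }
  y <- factor(train_table$label, levels = c("negative", "positive"))
  x <- as.data.frame(train_table[, feature_names()])
  fit_it <- function() {
    dat <- cbind(x, .label = y)
    switch(kind,
      decision_tree = rpart::rpart(.label ~ ., data = dat, method = "class"),
      naive_bayes = {
        m <- e1071::naiveBayes(x, y)
        # variance floor: sd >= sqrt(1e-9)
        m$tables <- lapply(m$tables, function(tb) {
          tb[, 2] <- pmax(tb[, 2], sqrt(1e-9))
          tb
        })
        m
      },
      random_forest = randomForest::randomForest(
        x, y, ntree = config$rf_trees, mtry = config$rf_mtry
      )
    )
  }
  fit <- if (is.null(seed)) fit_it() else withr::with_seed(seed, fit_it())
  structure(
    list(
      kind = kind, fit = fit, schema = feature_names(),
      metadata = list(
        seed = seed, n_train = nrow(train_table),
        rf_trees = config$rf_trees, rf_mtry = config$rf_mtry,
        trained_at_repetition = NA_integer_
      )
    ),
    class = "hairpin_model"
  )
}

#' @export
print.hairpin_model <- function(x, ...) {
  cat("<hairpin_model>", x$kind, "on", length(x$schema), "features;",
      "trained on", x$metadata$n_train, "rows\n")
  invisible(x)
}

#' Predict hairpin classes with a trained model
#'
#' Scores each row with the model's positive-class probability (naive-Bayes
#' posterior, tree leaf fraction, or forest vote fraction) and labels it
#' `"miRNA"` when the score is at least 0.5 (a tie at exactly 0.5 goes to
#' the positive class), `"negative"` otherwise.
#'
#' @param object A `hairpin_model`.
#' @param newdata A feature tibble matching the model's 36-column schema.
#' @param ... Unused.
#' @return A tibble with columns `id`, `label`, `score`, `model_kind`.
#' @export
predict.hairpin_model <- function(object, newdata, ...) {
  if (!is.data.frame(newdata) || !all(object$schema %in% names(newdata))) {
    stop_schema("newdata does not match the model's feature schema")
  }
  if (nrow(newdata) == 0) {
    return(tibble(id = character(0), label = character(0),
                  score = numeric(0), model_kind = character(0)))
  }
  x <- as.data.frame(newdata[, object$schema])
  score <- switch(object$kind,
    decision_tree = unname(predict(object$fit, x, type = "prob")[, "positive"]),
    naive_bayes = unname(predict(object$fit, x, type = "raw")[, "positive"]),
    random_forest = unname(predict(object$fit, x, type = "prob")[, "positive"])
  )
  tibble(
    id = if ("id" %in% names(newdata)) newdata$id else as.character(seq_len(nrow(newdata))),
    label = ifelse(score >= 0.5, "miRNA", "negative"),
    score = score,
    model_kind = object$kind
  )
}

#' Confusion counts and classification metrics
#'
#' Compares predicted labels against true class labels (positive class =
#' miRNA) and returns the confusion counts with the standard metric suite:
#' accuracy, sensitivity (= recall), specificity, precision and F-measure.
#' A metric with a zero denominator is reported as 0 and listed in the
#' `undefined_metrics` column.
#'
#' @param predicted Character vector of predicted labels (`"miRNA"` /
#'   `"negative"`), or a prediction tibble from [predict.hairpin_model()].
#' @param truth Character vector of true labels; `"miRNA"` and `"positive"`
#'   both mark the positive class, `"negative"` the negative class.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `recall`, `f_measure`,
#'   `undefined_metrics`.
#' @examples
#' evaluate_predictions(c("miRNA", "negative"), c("miRNA", "miRNA"))
#' @export
evaluate_predictions <- function(predicted, truth) {
  if (is.data.frame(predicted)) predicted <- predicted$label
  normalize_label <- function(v) {
    v <- ifelse(v %in% c("miRNA", "positive"), "positive",
                ifelse(v == "negative", "negative", NA_character_))
    if (anyNA(v)) stop_input("labels must be 'miRNA'/'positive' or 'negative'")
    v
  }
  predicted <- normalize_label(predicted)
  truth <- normalize_label(truth)
  if (length(predicted) != length(truth)) {
    stop_input("predicted and truth must have equal length")
  }
  tp <- sum(predicted == "positive" & truth == "positive")
  fp <- sum(predicted == "positive" & truth == "negative")
  tn <- sum(predicted == "negative" & truth == "negative")
  fn <- sum(predicted == "negative" & truth == "positive")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- ratio(tp + tn, tp + tn + fp + fn)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  fm <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else {
    2 * prec * sens / (prec + sens)
  }
  vals <- c(accuracy = acc, sensitivity = sens, specificity = spec,
            precision = prec, recall = sens, f_measure = fm)
  undefined <- names(vals)[is.na(vals)]
  vals[is.na(vals)] <- 0
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = vals[["accuracy"]], sensitivity = vals[["sensitivity"]],
    specificity = vals[["specificity"]], precision = vals[["precision"]],
    recall = vals[["recall"]], f_measure = vals[["f_measure"]],
    undefined_metrics = paste(undefined, collapse = ",")
  )
}
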