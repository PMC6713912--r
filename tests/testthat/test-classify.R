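test_that("balanced_sample draws min(|pos|, |neg|) from each class, reproducibly", {
  pos <- gaussian_cloud_table(12)[1:12, ]
  neg <- gaussian_cloud_table(12)[13:24, ]
  pos$label <- NULL
  neg$label <- NULL

  out <- balanced_sample(pos, neg[1:7, ], seed = 3)
  expect_equal(nrow(out), 14)
  expect_equal(as.integer(table(out$label)["positive"]), 7)
  expect_equal(as.integer(table(out$label)["negative"]), 7)

  both <- balanced_sample(pos[1:10, ], neg[1:10, ], seed = 3)
  expect_equal(nrow(both), 20) # min equals both class sizes: everything kept

  expect_identical(balanced_sample(pos, neg, seed = 9),
                   balanced_sample(pos, neg, seed = 9))
  expect_error(balanced_sample(pos[0, ], neg), class = "hairpin3d_input_error")
})

test_that("split_features is stratified, disjoint, exhaustive, and seeded", {
  tab <- gaussian_cloud_table(50) # 100 balanced rows
  parts <- split_features(tab, 0.70, seed = 5)
  expect_equal(nrow(parts$train), 70)
  expect_equal(nrow(parts$test), 30)
  expect_equal(as.integer(table(parts$train$label)), c(35, 35))
  expect_equal(as.integer(table(parts$test$label)), c(15, 15))
  expect_length(intersect(parts$train$id, parts$test$id), 0)
  expect_setequal(c(parts$train$id, parts$test$id), tab$id)

  small <- gaussian_cloud_table(5)
  half <- split_features(small, 0.5, seed = 5)
  expect_equal(as.integer(table(half$train$label)), c(3, 3)) # round-half-up on 2.5
  expect_equal(nrow(half$test), 4)

  expect_identical(split_features(tab, 0.7, seed = 8),
                   split_features(tab, 0.7, seed = 8))

  one_row <- tab[c(1, 51:60), ]
  expect_error(split_features(one_row, 0.7), "stratify",
               class = "hairpin3d_input_error")
})

test_that("all three classifiers separate well-separated Gaussian clouds", {
  tab <- gaussian_cloud_table(50)
  parts <- split_features(tab, 0.70, seed = 41)
  for (kind in c("decision_tree", "naive_bayes", "random_forest")) {
    model <- train_classifier(parts$train, kind, seed = 42)
    acc <- evaluate_predictions(predict(model, parts$test), parts$test$label)$accuracy
    expect_gte(acc, 0.95)
  }
})

test_that("training rejects single-class tables and is seed-deterministic", {
  tab <- gaussian_cloud_table(30)
  expect_error(train_classifier(tab[tab$label == "positive", ], "decision_tree"),
               class = "hairpin3d_input_error")
  m1 <- train_classifier(tab, "random_forest", seed = 7)
  m2 <- train_classifier(tab, "random_forest", seed = 7)
  probe <- gaussian_cloud_table(25, seed = 321)
  expect_equal(predict(m1, probe), predict(m2, probe))
})

test_that("prediction labels by the 0.5 threshold with ties going positive", {
  # unsplittable training data leaves a 50/50 root leaf: score exactly 0.5
  tab <- gaussian_cloud_table(10)
  tab[, feature_names()] <- 0
  tree <- train_classifier(tab, "decision_tree")
  preds <- predict(tree, tab)
  expect_true(all(preds$score == 0.5))
  expect_true(all(preds$label == "miRNA"))

  expect_equal(nrow(predict(tree, tab[0, ])), 0)
  expect_error(predict(tree, tab[, 1:10]), class = "hairpin3d_schema_error")
})

test_that("confusion counts and the metric suite match hand calculations", {
  perfect <- evaluate_predictions(
    rep(c("miRNA", "negative"), each = 5),
    rep(c("miRNA", "negative"), each = 5)
  )
  expect_equal(perfect$tp, 5)
  expect_equal(perfect$tn, 5)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f_measure, 1)

  # tp=45, fn=5, tn=40, fp=10
  truth <- c(rep("miRNA", 50), rep("negative", 50))
  pred <- c(rep("miRNA", 45), rep("negative", 5), rep("negative", 40), rep("miRNA", 10))
  m <- evaluate_predictions(pred, truth)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(45, 5, 40, 10))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$precision, 45 / 55)
  expect_equal(m$recall, m$sensitivity)
  expect_equal(m$f_measure, 2 * (45 / 55) * 0.9 / ((45 / 55) + 0.9))

  # degenerate: nothing predicted positive -> precision undefined, reported 0
  deg <- evaluate_predictions(rep("negative", 4), rep("negative", 4))
  expect_equal(deg$precision, 0)
  expect_match(deg$undefined_metrics, "precision")
  expect_match(deg$undefined_metrics, "sensitivity") # no positives in truth either

  expect_error(evaluate_predictions("miRNA", c("miRNA", "negative")),
               class = "hairpin3d_input_error")
  expect_error(evaluate_predictions("maybe", "miRNA"),
               class = "hairpin3d_input_error")
})

test_that("metric identities hold across random confusion matrices", {
  withr::local_seed(606)
  for (i in 1:30) {
    n_pos <- sample(1:40, 1)
    n_neg <- sample(1:40, 1)
    truth <- c(rep("miRNA", n_pos), rep("negative", n_neg))
    pred <- sample(c("miRNA", "negative"), n_pos + n_neg, replace = TRUE)
    m <- evaluate_predictions(pred, truth)
    expect_equal(m$tp + m$fp + m$tn + m$fn, n_pos + n_neg)
    expect_equal(m$accuracy, (m$tp + m$tn) / (n_pos + n_neg))
    # balanced evaluation set: accuracy is the mean of sensitivity/specificity
    if (n_pos == n_neg) {
      expect_equal(m$accuracy, (m$sensitivity + m$specificity) / 2)
    }
    # label swap exchanges the two error types
    swap <- function(v) ifelse(v == "miRNA", "negative", "miRNA")
    ms <- evaluate_predictions(swap(pred), swap(truth))
    expect_equal(c(ms$tp, ms$fn, ms$tn, ms$fp), c(m$tn, m$fp, m$tp, m$fn))
    expect_equal(ms$sensitivity, m$specificity)
    expect_equal(ms$specificity, m$sensitivity)
  }
})

test_that("monte_carlo_cv records all repetitions and the best models", {
  pos <- gaussian_cloud_table(20)[1:20, ]
  neg <- gaussian_cloud_table(20)[21:40, ]
  cfg <- cv_config(repeats = 2, seed = 10)
  cv <- monte_carlo_cv(pos, neg, cfg)
  expect_s3_class(cv, "hairpin_cv")
  expect_equal(nrow(cv$metrics), 2 * 3)
  expect_length(cv$best_models, 3)

  # reported best accuracy is the column maximum; ties break to earliest
  for (kind in names(cv$best_models)) {
    col <- cv$metrics[cv$metrics$classifier == kind, ]
    expect_equal(cv$best_repetition[[kind]], col$repetition[which.max(col$accuracy)])
    expect_equal(max(col$accuracy),
                 col$accuracy[col$repetition == cv$best_repetition[[kind]]])
  }

  # byte-identical reproducibility under an equal configuration
  cv2 <- monte_carlo_cv(pos, neg, cfg)
  expect_identical(cv$metrics, cv2$metrics)

  # tidiers expose the metric table and the per-classifier summary
  expect_identical(tidy(cv), cv$metrics)
  g <- glance(cv)
  expect_setequal(g$classifier, c("decision_tree", "naive_bayes", "random_forest"))
  expect_true(all(c("median_accuracy", "best_accuracy", "best_repetition") %in% names(g)))
})

test_that("cv_config validates its protocol parameters", {
  expect_error(cv_config(repeats = 0), class = "hairpin3d_input_error")
  expect_error(cv_config(train_fraction = 1), class = "hairpin3d_input_error")
  expect_error(cv_config(classifiers = "svm"))
  cfg <- cv_config(classifiers = c("decision_tree", "naive_bayes"))
  expect_equal(cfg$classifiers, c("decision_tree", "naive_bayes"))
})
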