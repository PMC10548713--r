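# Metric arithmetic, curve sweeps, cross-validation and imbalance protocols.

test_that("threshold metrics reproduce their defining arithmetic", {
  perfect <- compute_metrics(list(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unname(perfect[c("ACC", "SEN", "SP", "MCC", "F1")]),
               c(1, 1, 1, 1, 1))

  chance <- compute_metrics(list(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(chance[["ACC"]], 0.5)
  expect_equal(chance[["MCC"]], 0)
  expect_equal(unname(chance[c("SEN", "SP", "precision", "F1")]),
               rep(0.5, 4))

  m <- compute_metrics(list(TP = 60, FP = 10, TN = 70, FN = 15))
  expect_equal(unname(m), unname(oracle_metrics(60, 10, 70, 15)),
               tolerance = 1e-12)
})

test_that("metric identities hold on random confusion counts", {
  withr::with_seed(21, {
    for (i in 1:100) {
      cnt <- as.list(stats::setNames(sample(1:200, 4, replace = TRUE),
                                     c("TP", "FP", "TN", "FN")))
      m <- compute_metrics(cnt)
      om <- oracle_metrics(cnt$TP, cnt$FP, cnt$TN, cnt$FN)
      expect_equal(unname(m), unname(om), tolerance = 1e-12)
      n <- cnt$TP + cnt$FP + cnt$TN + cnt$FN
      prev <- (cnt$TP + cnt$FN) / n
      # ACC is the prevalence-weighted mean of SEN and SP
      expect_equal(m[["ACC"]], prev * m[["SEN"]] + (1 - prev) * m[["SP"]],
                   tolerance = 1e-12)
      # F1 is the harmonic mean of precision and SEN
      expect_equal(m[["F1"]],
                   2 / (1 / m[["precision"]] + 1 / m[["SEN"]]),
                   tolerance = 1e-12)
      expect_gte(m[["MCC"]], -1); expect_lte(m[["MCC"]], 1)
    }
  })
})

test_that("zero-denominator metrics return 0 with a degenerate flag", {
  m <- compute_metrics(list(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_equal(m[["precision"]], 0)
  expect_equal(m[["MCC"]], 0)
  expect_true("precision" %in% attr(m, "degenerate"))
  expect_true("MCC" %in% attr(m, "degenerate"))
})

test_that("MCC is near zero for label-independent predictions", {
  withr::with_seed(31, {
    labels <- rep(c("positive", "negative"), each = 200)
    mccs <- replicate(200, {
      pred <- sample(c(0, 1), 400, replace = TRUE)
      compute_metrics(confusion_counts(labels, pred))[["MCC"]]
    })
    expect_lt(mean(abs(mccs)), 0.05)
  })
})

test_that("ROC sweep matches the pairwise-comparison oracle", {
  # hand-listed pairs, including a tie
  labels <- c("positive", "positive", "negative", "positive",
              "negative", "negative")
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  r <- roc_points(labels, scores)
  expect_equal(r$auc, oracle_auc(labels, scores), tolerance = 1e-12)

  withr::with_seed(41, {
    for (i in 1:100) {
      n <- sample(6:20, 1)
      labels <- sample(c("positive", "negative"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- round(stats::runif(n), 1)  # coarse grid forces ties
      expect_equal(roc_points(labels, scores)$auc,
                   oracle_auc(labels, scores), tolerance = 1e-12)
    }
  })

  expect_equal(roc_points(c("positive", "negative"), c(1, 0))$auc, 1)
  expect_equal(roc_points(rep(c("positive", "negative"), 5), rep(0.7, 10))$auc,
               0.5)
  expect_error(roc_points(rep("positive", 4), stats::runif(4)), "both classes")
})

test_that("ROC curve agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    labels <- sample(c("positive", "negative"), 80, replace = TRUE)
    scores <- stats::runif(80)
  })
  expect_equal(roc_points(labels, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(
                 labels, scores, levels = c("negative", "positive"),
                 direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("a random scorer's AUPRC approximates the positive prevalence", {
  withr::with_seed(51, {
    labels <- rep(c("positive", "negative"), c(30, 270))
    auprcs <- replicate(30, pr_points(labels, stats::runif(300))$auprc)
  })
  expect_lt(abs(mean(auprcs) - 0.1), 0.03)
})

test_that("stratified folds partition the data and preserve class ratio", {
  f <- toy_features(25, seed = 61)  # 25 + 25
  cv <- kfold_cv(f, classifier_spec("RF", n_estimators = 30, seed = 1),
                 k = 5, seed = 2)
  folds <- cv$fold_assignments
  expect_setequal(unique(folds), 1:5)
  expect_equal(length(folds), nrow(f))              # every sample assigned once
  for (fd in 1:5) {
    tab <- table(f$label[folds == fd])
    expect_equal(unname(tab[["positive"]]), 5)      # ratio within one sample
    expect_equal(unname(tab[["negative"]]), 5)
  }
  expect_equal(nrow(cv$folds), 5)
  expect_error(kfold_cv(f, k = 30), "at least k")
})

test_that("a constant majority-class predictor scores at chance on balanced data", {
  f <- toy_features(15, seed = 71)
  const <- function(x) rep(0.2, nrow(x))  # always predicts negative
  counts <- confusion_counts(f$label, const(feature_matrix(f)))
  m <- compute_metrics(counts)
  expect_equal(m[["ACC"]], 0.5)
  expect_equal(m[["SEN"]], 0)
  expect_equal(m[["SP"]], 1)
})

test_that("repeated CV reduces to kfold_cv at repeats = 1 and is stable", {
  f <- toy_features(20, seed = 81)
  spec <- classifier_spec("RF", n_estimators = 50, seed = 1)
  r1 <- repeated_cv(f, spec, k = 4, repeats = 1, seed = 5)
  single <- kfold_cv(f, spec, k = 4, seed = 5)
  expect_equal(unname(r1$summary), unname(single$summary))

  r3 <- repeated_cv(f, spec, k = 4, repeats = 3, seed = 5)
  expect_true(all(r3$summary_sd >= 0))
  for (met in names(r3$summary)) {
    expect_gte(r3$summary[[met]], min(r3$repeats[[met]]))
    expect_lte(r3$summary[[met]], max(r3$repeats[[met]]))
  }
})

test_that("repeated-CV mean accuracy is stable against a single 10-fold run", {
  win <- generate_windows(synthetic_config(n_positive = 100, n_negative = 100,
                                           signal_strength = 0.8, seed = 42))
  f <- encode_windows(win)
  spec <- classifier_spec("RF", n_estimators = 100, seed = 42)
  single <- kfold_cv(f, spec, k = 10, seed = 42)
  r3 <- repeated_cv(f, spec, k = 10, repeats = 3, seed = 42)
  expect_lt(abs(r3$summary[["ACC"]] - single$summary[["ACC"]]), 0.03)
})

test_that("imbalanced protocol balances training only and keeps test skew", {
  win <- generate_windows(synthetic_config(n_positive = 50, n_negative = 1000,
                                           signal_strength = 0.8, seed = 42))
  f <- encode_windows(win)
  res <- imbalanced_protocol(f, classifier_spec("RF", n_estimators = 50,
                                                seed = 1),
                             split = 0.7, seed = 1)
  expect_equal(unname(res$train_counts[["positive"]]), 35)
  expect_equal(unname(res$train_counts[["negative"]]), 35)
  expect_equal(unname(res$test_counts[["positive"]]), 15)
  expect_equal(unname(res$test_counts[["negative"]]), 300)
  # planted signal: AUPRC strictly above the prevalence baseline
  prevalence <- 15 / 315
  expect_gt(res$pr$auprc, prevalence)
  expect_true(all(c("recall", "precision") %in% names(res$pr$points)))
})

test_that("ablation runner covers the default 11-combination design", {
  combos <- default_ablation_combos()
  expect_length(combos, 11)
  expect_equal(combos[[11]], c("AAC", "PP", "DPC", "ITB"))

  win <- generate_windows(synthetic_config(n_positive = 20, n_negative = 20,
                                           seed = 3))
  tab <- feature_ablation(win, classifier_spec("RF", n_estimators = 30,
                                               seed = 1),
                          combos = list("AAC", c("AAC", "DPC"),
                                        c("AAC", "PP", "DPC", "ITB")),
                          k = 4, seed = 1)
  expect_equal(tab$width, c(20, 420, 434))
  expect_error(feature_ablation(win, combos = list()), "non-empty")
  expect_error(feature_ablation(win, combos = list(character(0))), "empty")
})

test_that("all feature blocks together beat the entropy-only block", {
  win <- generate_windows(synthetic_config(n_positive = 60, n_negative = 60,
                                           signal_strength = 0.8, seed = 42))
  tab <- feature_ablation(win, classifier_spec("RF", n_estimators = 100,
                                               seed = 1),
                          combos = list("ITB", c("AAC", "PP", "DPC", "ITB")),
                          k = 5, seed = 1)
  expect_gte(tab$ACC[[2]], tab$ACC[[1]])
})

test_that("tidiers expose per-fold and aggregate views", {
  f <- toy_features(15, seed = 91)
  cv <- kfold_cv(f, classifier_spec("RF", n_estimators = 30, seed = 1),
                 k = 3, seed = 1)
  td <- generics::tidy(cv)
  expect_equal(nrow(td), 3)
  gl <- generics::glance(cv)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$ACC, mean(td$ACC))
  p <- ggplot2::autoplot(cv)
  expect_s3_class(p, "ggplot")
})
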