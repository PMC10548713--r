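# Evaluation protocols: confusion-matrix metrics, ROC/PR curves, stratified
# k-fold and repeated cross-validation, the imbalance protocol with
# training-only under-sampling, and the feature-block ablation runner.

#' Confusion counts from labels and scores
#'
#' @param labels Character (`"positive"`/`"negative"`), logical, or 0/1
#'   vector of true classes.
#' @param scores Positive-class probabilities.
#' @param threshold Decision threshold on the positive-class probability.
#' @return A named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  truth <- as_binary_labels(labels)
  pred <- scores >= threshold
  list(TP = sum(pred & truth), FP = sum(pred & !truth),
       TN = sum(!pred & !truth), FN = sum(!pred & truth))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "positive"
  } else {
    as.logical(labels)
  }
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Threshold classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision, F1, and
#' Matthews correlation coefficient. Any metric whose denominator is zero
#' is reported as 0 and flagged in the `degenerate` attribute.
#'
#' @param counts Named list/vector with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `ACC`, `SEN`, `SP`, `precision`, `F1`,
#'   `MCC`, with a `degenerate` attribute naming zero-denominator metrics.
#' @export
#' @examples
#' compute_metrics(list(TP = 50, FP = 0, TN = 50, FN = 0))
compute_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  n <- tp + fp + tn + fn
  sen <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * prec * sen, prec + sen)
  mcc_den <- sqrt(fp + tp) * sqrt(fn + tp) * sqrt(tn + fp) * sqrt(fn + tn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  degen <- c(SEN = (tp + fn) == 0, SP = (tn + fp) == 0,
             precision = (tp + fp) == 0, F1 = (prec + sen) == 0,
             MCC = mcc_den == 0)
  out <- c(ACC = safe_div(tp + tn, n), SEN = sen, SP = sp,
           precision = prec, F1 = f1, MCC = mcc)
  if (any(degen)) attr(out, "degenerate") <- names(degen)[degen]
  out
}

#' ROC curve points and area under the curve
#'
#' Thresholds are swept over the unique scores (ties grouped); the curve
#' runs from (0, 0) to (1, 1) and the AUC is the trapezoidal area, which
#' equals the Mann-Whitney pairwise-comparison statistic.
#'
#' @inheritParams confusion_counts
#' @return A list with `points` (tibble `threshold`, `FPR`, `TPR`) and
#'   `auc`.
#' @export
roc_points <- function(labels, scores) {
  truth <- as_binary_labels(labels)
  check_both_classes(truth)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  grp_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(t)[grp_last]
  fp <- cumsum(!t)[grp_last]
  P <- sum(truth); N <- sum(!truth)
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = tibble::tibble(threshold = c(Inf, s[grp_last]),
                               FPR = fpr, TPR = tpr),
       auc = auc)
}

#' Precision-recall curve points and area
#'
#' Same threshold sweep as [roc_points()]; the area (AUPRC) is the
#' trapezoidal area over recall. A random scorer's AUPRC approaches the
#' positive prevalence.
#'
#' @inheritParams confusion_counts
#' @return A list with `points` (tibble `threshold`, `recall`,
#'   `precision`) and `auprc`.
#' @export
pr_points <- function(labels, scores) {
  truth <- as_binary_labels(labels)
  check_both_classes(truth)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  grp_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(t)[grp_last]
  fp <- cumsum(!t)[grp_last]
  P <- sum(truth)
  recall <- tp / P
  precision <- tp / (tp + fp)
  # anchor at the first point's precision so the curve starts at recall 0
  recall <- c(0, recall); precision <- c(precision[1], precision)
  auprc <- sum(diff(recall) *
                 (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
  list(points = tibble::tibble(threshold = c(Inf, s[grp_last]),
                               recall = recall, precision = precision),
       auprc = auprc)
}

check_both_classes <- function(truth) {
  if (all(truth) || all(!truth)) {
    stop("both classes must be present to sweep a curve", call. = FALSE)
  }
  invisible(NULL)
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin over folds, keeping the class ratio within one sample per fold.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

fold_metrics <- function(truth, prob, threshold = 0.5) {
  m <- compute_metrics(confusion_counts(truth, prob, threshold))
  c(m, AUC = roc_points(truth, prob)$auc,
    AUPRC = pr_points(truth, prob)$auprc)
}

#' Stratified k-fold cross-validation
#'
#' The dataset is partitioned into `k` stratified folds; each fold serves
#' once as the test set for a model trained on the rest. Metrics are
#' computed per fold and averaged (`aggregate = "average"`, the default),
#' or derived from the pooled confusion matrix (`"pooled"`).
#'
#' @param features Encoded feature tibble with labels.
#' @param spec A [classifier_spec()].
#' @param k Number of folds (each class must have at least `k` samples).
#' @param seed Seed for the fold assignment.
#' @param threshold Decision threshold.
#' @param aggregate `"average"` or `"pooled"`.
#' @return A `methylarg_cv` object; see [tidy.methylarg_cv()] and
#'   [glance.methylarg_cv()].
#' @export
kfold_cv <- function(features, spec = classifier_spec("RF"), k = 10,
                     seed = 1L, threshold = 0.5,
                     aggregate = c("average", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (any(table(features$label) < k)) {
    stop("every class must have at least k samples", call. = FALSE)
  }
  fold_id <- stratified_folds(features$label, k = k, seed = seed)
  per_fold <- vector("list", k)
  scores <- numeric(nrow(features))
  for (f in seq_len(k)) {
    test <- fold_id == f
    fit <- train_model(features[!test, , drop = FALSE], spec)
    prob <- stats::predict(fit, features[test, , drop = FALSE])
    scores[test] <- prob
    per_fold[[f]] <- fold_metrics(features$label[test], prob, threshold)
  }
  folds_tbl <- dplyr::bind_cols(
    tibble::tibble(fold = seq_len(k)),
    tibble::as_tibble(do.call(rbind, per_fold))
  )
  summary <- if (aggregate == "average") {
    colMeans(folds_tbl[-1])
  } else {
    fold_metrics(features$label, scores, threshold)
  }
  structure(list(folds = folds_tbl, summary = summary,
                 summary_sd = apply(folds_tbl[-1], 2, stats::sd),
                 fold_assignments = fold_id, scores = scores,
                 labels = features$label,
                 k = k, seed = seed, aggregate = aggregate, spec = spec),
            class = "methylarg_cv")
}

#' @export
print.methylarg_cv <- function(x, ...) {
  cat("<", x$k, "-fold CV, ", x$spec$algorithm, ">\n", sep = "")
  print(round(x$summary, 4))
  invisible(x)
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `repeats` independent stratified shufflings; repeat `r` (0-indexed)
#' uses seed `seed + r`, so `repeats = 1` reproduces [kfold_cv()] with the
#' same seed exactly. Reports the mean and standard deviation of each
#' metric over the per-repeat means.
#'
#' @inheritParams kfold_cv
#' @param repeats Number of repetitions (50 in the headline protocol).
#' @return A `methylarg_rcv` object with `repeats` (tibble of per-repeat
#'   means), `summary` (mean over repeats) and `summary_sd`.
#' @export
repeated_cv <- function(features, spec = classifier_spec("RF"), k = 10,
                        repeats = 50, seed = 1L, threshold = 0.5) {
  runs <- purrr::map(seq_len(repeats) - 1L, function(r) {
    cv <- kfold_cv(features, spec, k = k, seed = seed + r,
                   threshold = threshold)
    c(repeat_ = r + 1, seed = seed + r, cv$summary)
  })
  rep_tbl <- tibble::as_tibble(do.call(rbind, runs))
  metric_cols <- setdiff(names(rep_tbl), c("repeat_", "seed"))
  structure(list(repeats = rep_tbl,
                 summary = colMeans(rep_tbl[metric_cols]),
                 summary_sd = apply(rep_tbl[metric_cols], 2, stats::sd),
                 k = k, n_repeats = repeats, seed = seed, spec = spec),
            class = "methylarg_rcv")
}

#' @export
print.methylarg_rcv <- function(x, ...) {
  cat("<", x$k, "-fold CV x ", x$n_repeats, " repeats, ",
      x$spec$algorithm, ">\n", sep = "")
  print(round(x$summary, 4))
  invisible(x)
}

#' Imbalance evaluation protocol (stratified split, train-only balancing)
#'
#' Stratified `split`/`1 - split` train/test partition; random
#' under-sampling balances the *training* portion only, while the test
#' portion keeps its natural imbalance. Reports threshold metrics plus the
#' ROC and precision-recall curves of the test predictions.
#'
#' @inheritParams kfold_cv
#' @param split Training fraction (default 0.7).
#' @return A `methylarg_imbalanced` object with `metrics`, `roc`, `pr`,
#'   `train_counts`, `test_counts`.
#' @export
imbalanced_protocol <- function(features, spec = classifier_spec("RF"),
                                split = 0.7, seed = 1L, threshold = 0.5) {
  counts <- table(features$label)
  if (length(counts) < 2 || any(counts == 0)) {
    stop("both classes must be present", call. = FALSE)
  }
  is_train <- logical(nrow(features))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(features$label == cl)
      n_tr <- round(split * length(idx))
      is_train[sample(idx, n_tr)] <- TRUE
    }
  })
  if (any(table(features$label[!is_train]) == 0) ||
      any(table(features$label[is_train]) == 0)) {
    stop("a class is empty after the split", call. = FALSE)
  }
  train <- undersample(features[is_train, , drop = FALSE], seed = seed)
  fit <- train_model(train, spec)
  test <- features[!is_train, , drop = FALSE]
  prob <- stats::predict(fit, test)
  structure(list(
    metrics = fold_metrics(test$label, prob, threshold),
    roc = roc_points(test$label, prob),
    pr = pr_points(test$label, prob),
    scores = prob, labels = test$label,
    train_counts = table(train$label), test_counts = table(test$label),
    split = split, seed = seed, spec = spec
  ), class = "methylarg_imbalanced")
}

#' @export
print.methylarg_imbalanced <- function(x, ...) {
  cat("<imbalanced protocol, ", x$split * 100, "/", (1 - x$split) * 100,
      " split, ", x$spec$algorithm, ">\n", sep = "")
  cat("train:", paste(names(x$train_counts), x$train_counts, collapse = ", "),
      " test:", paste(names(x$test_counts), x$test_counts, collapse = ", "), "\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' The eleven default feature-block combinations
#'
#' The ablation design: each single block, the informative pairs and
#' triples, and the full four-block set.
#'
#' @return A list of 11 character vectors over `{AAC, DPC, ITB, PP}`.
#' @export
default_ablation_combos <- function() {
  list(
    c("AAC"),
    c("PP"),
    c("DPC"),
    c("ITB"),
    c("AAC", "PP"),
    c("AAC", "DPC"),
    c("DPC", "ITB"),
    c("AAC", "PP", "DPC"),
    c("PP", "DPC", "ITB"),
    c("AAC", "DPC", "ITB"),
    c("AAC", "PP", "DPC", "ITB")
  )
}

#' Feature-block ablation experiment
#'
#' Re-encodes the windows with each block combination and runs one
#' stratified k-fold CV per combination.
#'
#' @param windows A labeled window tibble.
#' @param spec A [classifier_spec()].
#' @param combos List of block subsets (default the eleven-row design,
#'   [default_ablation_combos()]).
#' @param k,seed,alpha CV and encoder settings.
#' @return A tibble with one row per combination: `combo`, `width`, and
#'   the averaged CV metrics.
#' @export
feature_ablation <- function(windows, spec = classifier_spec("RF"),
                             combos = default_ablation_combos(),
                             k = 10, seed = 1L, alpha = 2) {
  if (length(combos) == 0) stop("combos must be non-empty", call. = FALSE)
  rows <- purrr::map(combos, function(combo) {
    if (length(combo) == 0) stop("empty feature combo", call. = FALSE)
    combo <- match.arg(combo, c("AAC", "DPC", "ITB", "PP"), several.ok = TRUE)
    feats <- encode_windows(windows, alpha = alpha, blocks = combo)
    cv <- kfold_cv(feats, spec, k = k, seed = seed)
    width <- length(feature_names(combo))
    dplyr::bind_cols(
      tibble::tibble(combo = paste(combo, collapse = "+"), width = width),
      tibble::as_tibble(as.list(cv$summary))
    )
  })
  dplyr::bind_rows(rows)
}
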