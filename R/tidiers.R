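# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per fold with every metric.
#'
#' @param x A `methylarg_cv` object.
#' @param ... Unused.
#' @return A tibble with columns `fold`, `ACC`, `SEN`, `SP`, `precision`,
#'   `F1`, `MCC`, `AUC`, `AUPRC`.
#' @method tidy methylarg_cv
#' @export
tidy.methylarg_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation result
#'
#' @param x A `methylarg_cv` object.
#' @param ... Unused.
#' @return A one-row tibble of aggregated metrics plus `k` and `seed`.
#' @method glance methylarg_cv
#' @export
glance.methylarg_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(as.list(x$summary)),
                   tibble::tibble(k = x$k, seed = x$seed,
                                  aggregate = x$aggregate))
}

#' @rdname tidy.methylarg_cv
#' @method tidy methylarg_rcv
#' @export
tidy.methylarg_rcv <- function(x, ...) x$repeats

#' @rdname glance.methylarg_cv
#' @method glance methylarg_rcv
#' @export
glance.methylarg_rcv <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$summary))
  sds <- tibble::as_tibble(as.list(x$summary_sd))
  names(sds) <- paste0(names(sds), "_sd")
  dplyr::bind_cols(out, sds,
                   tibble::tibble(k = x$k, n_repeats = x$n_repeats,
                                  seed = x$seed))
}

#' Tidy an imbalance-protocol result
#'
#' @param x A `methylarg_imbalanced` object.
#' @param ... Unused.
#' @return A one-row tibble of test-set metrics and the class counts.
#' @method tidy methylarg_imbalanced
#' @export
tidy.methylarg_imbalanced <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(as.list(x$metrics)),
    tibble::tibble(train_positive = x$train_counts[["positive"]],
                   train_negative = x$train_counts[["negative"]],
                   test_positive = x$test_counts[["positive"]],
                   test_negative = x$test_counts[["negative"]])
  )
}

#' Tidy a feature ranking
#'
#' @param x A `methylarg_ranking` object.
#' @param ... Unused.
#' @return The ranking tibble (`feature`, `block`, `mean_abs_attribution`).
#' @method tidy methylarg_ranking
#' @export
tidy.methylarg_ranking <- function(x, ...) x$ranking

#' Plot a cross-validated ROC-style metric overview
#'
#' Per-fold metric values as points with the fold-mean as a crossbar.
#'
#' @param object A `methylarg_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methylarg_cv
#' @export
autoplot.methylarg_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, color = "firebrick") +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = sprintf("%d-fold cross-validation (%s)",
                                  object$k, object$spec$algorithm)) +
    ggplot2::theme_minimal()
}

#' Plot ROC and precision-recall curves of an imbalance-protocol run
#'
#' @param object A `methylarg_imbalanced` object.
#' @param curve `"pr"` (default; the informative curve under imbalance)
#'   or `"roc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methylarg_imbalanced
#' @export
autoplot.methylarg_imbalanced <- function(object, curve = c("pr", "roc"), ...) {
  curve <- match.arg(curve)
  if (curve == "pr") {
    prev <- mean(as_binary_labels(object$labels))
    ggplot2::ggplot(object$pr$points,
                    ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::geom_hline(yintercept = prev, linetype = "dashed") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(title = sprintf("Precision-recall (AUPRC = %.3f)",
                                    object$pr$auprc),
                    subtitle = "dashed: positive prevalence baseline") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$roc$points,
                    ggplot2::aes(x = .data$FPR, y = .data$TPR)) +
      ggplot2::geom_path() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::labs(title = sprintf("ROC (AUC = %.3f)", object$roc$auc)) +
      ggplot2::theme_minimal()
  }
}

#' Bar chart of the top-k mean absolute Shapley attributions
#'
#' @param object A `methylarg_ranking` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methylarg_ranking
#' @export
autoplot.methylarg_ranking <- function(object, ...) {
  top <- utils::head(object$ranking, object$k)
  top$feature <- factor(top$feature, levels = rev(top$feature))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$mean_abs_attribution,
                                    y = .data$feature,
                                    fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL,
                  title = sprintf("Top %d features", object$k)) +
    ggplot2::theme_minimal()
}

#' Beeswarm-style summary of Shapley attributions
#'
#' Attribution against rank for the top-k features, colored by the
#' (per-feature, min-max scaled) feature value.
#'
#' @param object A `methylarg_attr` object.
#' @param X The explained feature tibble/matrix.
#' @param k Number of features shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methylarg_attr
#' @export
autoplot.methylarg_attr <- function(object, X, k = 20, ...) {
  st <- summary_table(object, X, k = k)
  pairs <- dplyr::mutate(
    dplyr::group_by(st$pairs, .data$feature),
    scaled_value = if (diff(range(.data$value)) > 0) {
      (.data$value - min(.data$value)) / diff(range(.data$value))
    } else {
      0.5
    }
  )
  pairs <- dplyr::ungroup(pairs)
  pairs$feature <- factor(pairs$feature,
                          levels = rev(unique(st$pairs$feature)))
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$attribution,
                                      y = .data$feature,
                                      color = .data$scaled_value)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.7, size = 1) +
    ggplot2::scale_color_gradient(low = "steelblue", high = "firebrick",
                                  name = "feature value\n(scaled)") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Shapley value", y = NULL) +
    ggplot2::theme_minimal()
}
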