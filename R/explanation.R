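# Shapley-value feature attributions by seeded permutation sampling.
#
# For each explained sample x, background row b and permutation pi, features
# are flipped from their background to their sample value in the order pi;
# the attribution of feature j is the average change in model output caused
# by flipping j. Averaged over permutations and background rows the
# attributions satisfy local accuracy *exactly*:
#   base_value + sum_j attribution_j == f(x),
# because every chain telescopes from f(b) to f(x). Features equal in x and
# b are skipped (their flip cannot change the output), which makes the
# estimator cheap on sparse composition features.

model_scorer <- function(model) {
  if (inherits(model, "methylarg_model")) {
    function(x) stats::predict(model, x)
  } else if (is.function(model)) {
    model
  } else {
    stop("model must be a methylarg_model or a function(matrix) -> scores",
         call. = FALSE)
  }
}

#' Shapley-value attributions for model predictions
#'
#' Explains the positive-class probability of each row of `X` against the
#' expected output over `background`, using a permutation-sampling Shapley
#' estimator. The estimator is deterministic given `seed` and satisfies
#' local accuracy exactly (the attributions of each sample sum to the
#' model output minus `base_value`).
#'
#' @param model A `methylarg_model`, or any `function(matrix) -> numeric`
#'   scorer (useful for testing).
#' @param X Feature tibble or numeric matrix of samples to explain.
#' @param background Feature tibble/matrix used as the reference
#'   distribution (typically a subsample of the training data; at most
#'   `max_background` seeded rows are used).
#' @param n_perm Number of feature permutations per (sample, background)
#'   pair.
#' @param seed Integer seed.
#' @param max_background Cap on background rows (default 100).
#' @return A `methylarg_attr` object: `values` (samples x features matrix),
#'   `base_value`, `feature_names`, `predictions`, and background metadata.
#' @export
shap_attribution <- function(model, X, background, n_perm = 4, seed = 1L,
                             max_background = 100) {
  f <- model_scorer(model)
  xm <- if (is.matrix(X)) X else feature_matrix(X)
  bm <- if (is.matrix(background)) background else feature_matrix(background)
  if (ncol(xm) != ncol(bm)) {
    stop("X and background must have the same feature columns", call. = FALSE)
  }
  if (nrow(bm) == 0) stop("background must be non-empty", call. = FALSE)
  if (nrow(bm) > max_background) {
    keep <- withr::with_seed(seed, sample.int(nrow(bm), max_background))
    bm <- bm[keep, , drop = FALSE]
  }
  p <- ncol(xm)
  n <- nrow(xm)
  B <- nrow(bm)
  f_bg <- f(bm)
  base <- mean(f_bg)
  perms <- withr::with_seed(seed, {
    purrr::map(seq_len(n_perm), function(i) sample.int(p))
  })

  values <- matrix(0, n, p, dimnames = list(NULL, colnames(xm)))
  f_x <- f(xm)
  for (i in seq_len(n)) {
    x <- xm[i, ]
    # assemble every intermediate state of every chain into one batch
    states <- list(); chain_info <- list(); ci <- 0L
    for (b in seq_len(B)) {
      diff_j <- which(x != bm[b, ])
      for (pp in seq_len(n_perm)) {
        ord <- perms[[pp]][perms[[pp]] %in% diff_j]
        if (length(ord) == 0) { next }
        z <- matrix(rep(bm[b, ], length(ord)), nrow = length(ord), byrow = TRUE)
        for (t in seq_along(ord)) {
          z[t, ord[seq_len(t)]] <- x[ord[seq_len(t)]]
        }
        ci <- ci + 1L
        states[[ci]] <- z
        chain_info[[ci]] <- list(b = b, ord = ord)
      }
    }
    if (ci > 0L) {
      batch <- do.call(rbind, states)
      colnames(batch) <- colnames(xm)
      fv <- f(batch)
      offset <- 0L
      acc <- numeric(p)
      for (cidx in seq_len(ci)) {
        info <- chain_info[[cidx]]
        m <- length(info$ord)
        vals <- fv[(offset + 1):(offset + m)]
        prev <- c(f_bg[info$b], vals[-m])
        acc[info$ord] <- acc[info$ord] + (vals - prev)
        offset <- offset + m
      }
      values[i, ] <- acc / (B * n_perm)
    }
  }
  structure(list(values = values, base_value = base,
                 feature_names = colnames(xm), predictions = f_x,
                 background = list(size = B, n_perm = n_perm, seed = seed,
                                   target = "positive-class probability")),
            class = "methylarg_attr")
}

#' @export
print.methylarg_attr <- function(x, ...) {
  cat("<shapley attributions> ", nrow(x$values), " samples x ",
      ncol(x$values), " features, base value ",
      format(x$base_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Global feature ranking by mean absolute attribution
#'
#' @param attr A `methylarg_attr` object.
#' @param k Size of the reported top set (block tally computed over it).
#' @return A `methylarg_ranking`: `ranking` (tibble `feature`, `block`,
#'   `mean_abs_attribution`, sorted non-increasing, ties broken by feature
#'   name) and `block_tally` (top-`k` counts per block).
#' @export
rank_features <- function(attr, k = 20) {
  stopifnot(inherits(attr, "methylarg_attr"), k <= ncol(attr$values))
  mean_abs <- colMeans(abs(attr$values))
  ord <- order(-mean_abs, names(mean_abs))
  ranking <- tibble::tibble(
    feature = names(mean_abs)[ord],
    block = feature_block(names(mean_abs)[ord]),
    mean_abs_attribution = unname(mean_abs[ord])
  )
  top <- ranking$block[seq_len(k)]
  tally <- vapply(c("AAC", "DPC", "ITB", "PP"),
                  function(b) sum(top == b), integer(1))
  structure(list(ranking = ranking, block_tally = tally, k = k),
            class = "methylarg_ranking")
}

#' @export
print.methylarg_ranking <- function(x, ...) {
  cat("<feature ranking> top ", x$k, " block tally: ",
      paste(names(x$block_tally), x$block_tally, sep = "=", collapse = ", "),
      "\n", sep = "")
  print(utils::head(x$ranking, x$k))
  invisible(x)
}

#' Per-feature (value, attribution) summary for the top-k features
#'
#' Long-format data sufficient to reproduce a beeswarm-style summary plot
#' externally, plus feature-value quantiles.
#'
#' @param attr A `methylarg_attr` object.
#' @param X The feature tibble/matrix that was explained (same rows).
#' @param k Number of top features.
#' @return A list with `pairs` (tibble `feature`, `rank`, `sample`,
#'   `value`, `attribution`) and `quantiles` (per-feature value quartiles).
#' @export
summary_table <- function(attr, X, k = 20) {
  xm <- if (is.matrix(X)) X else feature_matrix(X)
  rk <- rank_features(attr, k = k)
  top <- rk$ranking$feature[seq_len(k)]
  pairs <- purrr::map2(top, seq_along(top), function(feat, r) {
    tibble::tibble(feature = feat, rank = r,
                   sample = seq_len(nrow(xm)),
                   value = xm[, feat],
                   attribution = attr$values[, feat])
  })
  pairs <- dplyr::bind_rows(pairs)
  quantiles <- dplyr::bind_rows(purrr::map(top, function(feat) {
    q <- stats::quantile(xm[, feat], c(0, 0.25, 0.5, 0.75, 1))
    tibble::tibble(feature = feat, q0 = q[1], q25 = q[2], q50 = q[3],
                   q75 = q[4], q100 = q[5])
  }))
  list(pairs = pairs, quantiles = quantiles)
}

#' Export attributions as TSV + JSON ranking
#'
#' @param attr A `methylarg_attr` object.
#' @param path Base path; writes `<path>.tsv` (samples x features) and
#'   `<path>_ranking.json`.
#' @param k Top-k size for the ranking export.
#' @return Invisibly, the two paths written.
#' @export
write_attributions <- function(attr, path, k = 20) {
  tsv <- paste0(path, ".tsv")
  readr::write_tsv(tibble::as_tibble(attr$values), tsv, progress = FALSE)
  rk <- rank_features(attr, k = k)
  js <- paste0(path, "_ranking.json")
  jsonlite::write_json(list(
    base_value = attr$base_value,
    target = attr$background$target,
    top = utils::head(rk$ranking, k),
    block_tally = as.list(rk$block_tally)
  ), js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(tsv, js))
}
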