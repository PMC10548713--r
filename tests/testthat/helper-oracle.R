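# Independent straight-from-the-definitions oracles, written as plain loops
# against the defining equations. These deliberately share no code with the
# package implementation (only the bundled constant tables, which are data).

oracle_aac <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  l <- length(chars)
  out <- numeric(20)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:20) out[i] <- sum(chars == aas[i]) / l
  names(out) <- paste0("AAC_", aas)
  out
}

oracle_dpc <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  l <- length(chars)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  out <- numeric(400)
  names(out) <- paste0("DPC_", as.vector(sapply(aas, function(a) paste0(a, aas))))
  for (i in 1:(l - 1)) {
    a <- chars[i]; b <- chars[i + 1]
    if (a %in% aas && b %in% aas) {
      nm <- paste0("DPC_", a, b)
      out[nm] <- out[nm] + 1
    }
  }
  out / l
}

oracle_entropies <- function(residues, alpha = 2, p0 = 1 / 20) {
  a <- oracle_aac(residues)
  p <- unname(a[a > 0])
  se <- 0
  for (pi in p) se <- se - pi * log2(pi)
  rel_se <- 0
  for (pi in p) rel_se <- rel_se + pi * log2(pi / p0)
  he <- 1 / (2^(1 - alpha) - 1) * (sum(p^alpha) - 1)
  rel_he <- -1 / (2^(1 - alpha) - 1) * (sum(p^alpha / p0^(alpha - 1)) - 1)
  re <- 1 / (1 - alpha) * log2(sum(p^alpha))
  rel_re <- 1 / (1 - alpha) * log2(sum(p^alpha / p0^(alpha - 1)))
  ae <- 1 / (2^(alpha - 1) - 1) * ((sum(p^(1 / alpha)))^alpha - 1)
  rel_ae <- -1 / (2^(alpha - 1) - 1) *
    ((sum(p^(1 / alpha) / p0^(1 / (alpha - 1))))^alpha - 1)
  list(SE = se, relative_SE = rel_se, information_gain = se - rel_se,
       HE = he, relative_HE = rel_he, RE = re, relative_RE = rel_re,
       AE = ae, relative_AE = rel_ae)
}

oracle_pp <- function(residues) {
  tabs <- constant_tables()
  chars <- strsplit(residues, "")[[1]]
  chars <- chars[chars != "X"]
  L <- length(chars)

  mw <- tabs$mass_water
  for (ch in chars) mw <- mw + tabs$mass[[ch]]

  gr <- 0
  for (ch in chars) gr <- gr + tabs$hydropathy[[ch]]
  gr <- gr / L

  ii <- 0
  for (i in 1:(L - 1)) ii <- ii + tabs$diwv[chars[i], chars[i + 1]]
  ii <- 10 / L * ii

  ex_red <- 5500 * sum(chars == "W") + 1490 * sum(chars == "Y")
  ex_ox <- ex_red + 125 * floor(sum(chars == "C") / 2)

  arom <- sum(chars %in% c("F", "W", "Y")) / L
  helix <- sum(chars %in% c("V", "I", "Y", "F", "W", "L")) / L
  turn <- sum(chars %in% c("N", "G", "P", "S")) / L
  sheet <- sum(chars %in% c("E", "M", "A", "L")) / L

  c(PP_pI = oracle_pi(chars), PP_MW = mw, PP_AROM = arom, PP_II = ii,
    PP_GRAVY = gr, PP_EX_RED = ex_red, PP_EX_OX = ex_ox,
    PP_HELIX = helix, PP_TURN = turn, PP_SHEET = sheet)
}

# Henderson-Hasselbalch net charge, bisected over pH in [0, 14] with the
# same stopping rule the package documents (|charge| < 1e-4 or bracket
# narrower than 0.01 pH units).
oracle_pi <- function(chars) {
  tabs <- constant_tables()
  charge_at <- function(ph) {
    q <- 1 / (1 + 10^(ph - tabs$pka[["Nterm"]])) -
      1 / (1 + 10^(tabs$pka[["Cterm"]] - ph))
    for (g in c("C", "D", "E", "Y")) {
      q <- q - sum(chars == g) / (1 + 10^(tabs$pka[[g]] - ph))
    }
    for (g in c("H", "K", "R")) {
      q <- q + sum(chars == g) / (1 + 10^(ph - tabs$pka[[g]]))
    }
    q
  }
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- charge_at(mid)
    if (abs(q) < 1e-4 || (hi - lo) < 0.01) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

oracle_encode <- function(residues, alpha = 2) {
  ent <- oracle_entropies(residues, alpha)
  c(oracle_aac(residues), oracle_dpc(residues),
    ITB_SE = ent$SE, ITB_HE = ent$HE, ITB_RE = ent$RE, ITB_AE = ent$AE,
    oracle_pp(residues))
}

oracle_metrics <- function(tp, fp, tn, fn) {
  c(ACC = (tn + tp) / (tp + fn + tn + fp),
    SEN = tp / (tp + fn),
    SP = tn / (tn + fp),
    precision = tp / (tp + fp),
    F1 = 2 * (tp / (tp + fp)) * (tp / (tp + fn)) /
      (tp / (tp + fp) + tp / (tp + fn)),
    MCC = (tp * tn - fp * fn) /
      sqrt((fp + tp) * (fn + tp)) / sqrt((tn + fp) * (fn + tn)))
}

# AUC as the pairwise-comparison (Mann-Whitney) statistic: the fraction of
# positive/negative score pairs ranked correctly, ties counting one half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == "positive" | labels == TRUE | labels == 1]
  neg <- scores[labels == "negative" | labels == FALSE | labels == 0]
  tot <- 0
  for (sp in pos) {
    for (sn in neg) {
      tot <- tot + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# Random valid windows over the standard alphabet, a fraction with terminal
# X padding, always R-centered.
random_windows <- function(n, gamma = 5, pad_frac = 0.2, seed = 1) {
  aas <- amino_acids()
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      flanks <- sample(aas, 2 * gamma, replace = TRUE)
      chars <- c(flanks[1:gamma], "R", flanks[(gamma + 1):(2 * gamma)])
      if (stats::runif(1) < pad_frac) {
        npad <- sample(1:(gamma - 1), 1)
        if (stats::runif(1) < 0.5) {
          chars[1:npad] <- "X"
        } else {
          chars[(2 * gamma + 2 - npad):(2 * gamma + 1)] <- "X"
        }
      }
      paste(chars, collapse = "")
    }, character(1))
  })
}

# Small labeled feature set with a perfectly separating planted column,
# for classifier contract tests.
toy_features <- function(n_per_class = 20, seed = 1) {
  win <- generate_windows(synthetic_config(n_positive = n_per_class,
                                           n_negative = n_per_class,
                                           signal_strength = 0.9,
                                           seed = seed))
  encode_windows(win)
}
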