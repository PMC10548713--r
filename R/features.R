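# Peptide-window feature encoding: amino-acid composition, dipeptide
# composition, information-theoretic entropies, and ProtParam-style
# physicochemical descriptors, assembled into the fixed 434-entry layout.
#
# Conventions shared by every encoder:
#   * the pad/unknown character 'X' is inert: it never contributes to a
#     numerator, and the composition denominators use the full window
#     length l (so padded windows have sub-normalized compositions);
#   * physicochemical descriptors operate on the de-padded residue string
#     and never consult 'X';
#   * 0 * log(0) := 0, all logarithms are base 2.

window_chars <- function(residues) {
  strsplit(residues, "", fixed = TRUE)[[1]]
}

depad <- function(chars) chars[chars != "X"]

#' Amino-acid composition of a peptide window
#'
#' Entry i is the count of amino acid i divided by the window length l
#' (pads included in l but never counted), ordered alphabetically by
#' one-letter code.
#'
#' @param residues Residue string (window), e.g. `"GGGGGRGGGGG"`.
#' @return Named numeric vector of length 20 (`AAC_A` ... `AAC_Y`).
#' @export
aac_vector <- function(residues) {
  chars <- window_chars(residues)
  l <- length(chars)
  counts <- tabulate(match(chars, amino_acids()), nbins = 20)
  stats::setNames(counts / l, feature_names("AAC"))
}

#' Dipeptide composition of a peptide window
#'
#' Entry for the ordered pair (a, b) is the count of adjacent occurrences
#' "a then b" divided by the window length l (not l - 1). Pairs touching a
#' pad character are not counted.
#'
#' @param residues Residue string.
#' @param denominator `"l"` (the definition used throughout) or `"l-1"`
#'   (the conventional pair count, available for sensitivity checks).
#' @return Named numeric vector of length 400 (`DPC_AA` ... `DPC_YY`,
#'   row-major over first x second residue).
#' @export
dpc_vector <- function(residues, denominator = c("l", "l-1")) {
  denominator <- match.arg(denominator)
  chars <- window_chars(residues)
  l <- length(chars)
  idx <- match(chars, amino_acids())
  m <- matrix(0L, 20, 20)
  if (l >= 2) {
    a <- idx[-l]
    b <- idx[-1]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      tab <- table(factor(a[ok], levels = 1:20), factor(b[ok], levels = 1:20))
      m <- m + unclass(tab)
    }
  }
  denom <- if (denominator == "l") l else max(1L, l - 1L)
  stats::setNames(as.vector(t(m)) / denom, feature_names("DPC"))
}

#' Composition profile of a window
#'
#' @param residues Residue string.
#' @return A list with `probabilities` (named length-20 vector, counts / l)
#'   and `effective_length` (number of non-pad residues).
#' @export
composition_profile <- function(residues) {
  chars <- window_chars(residues)
  p <- tabulate(match(chars, amino_acids()), nbins = 20) / length(chars)
  list(probabilities = stats::setNames(p, amino_acids()),
       effective_length = length(depad(chars)))
}

check_alpha <- function(alpha) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha != 1)) {
    stop("alpha must satisfy alpha > 0 and alpha != 1", call. = FALSE)
  }
  invisible(alpha)
}

#' Information-theoretic entropies of a composition profile
#'
#' Computes the nine quantities of the entropy family used by the encoder:
#' Shannon entropy (SE), relative SE against a uniform background `p0`,
#' information gain (SE - relative SE), Havrda-Charvat entropy (HE) and its
#' relative form, Renyi entropy (RE) and its relative form, and Arimoto
#' entropy (AE) and its relative form. All logarithms are base 2;
#' zero-probability terms are omitted.
#'
#' @param probabilities Numeric vector of residue probabilities (entries in
#'   `[0, 1]`, sum at most 1 for padded windows).
#' @param alpha Entropy order; must be positive and different from 1
#'   (default 2, the collision-entropy choice).
#' @param p0 Background probability of each residue (default `1/20`).
#' @return Named list with elements `SE`, `relative_SE`, `information_gain`,
#'   `HE`, `relative_HE`, `RE`, `relative_RE`, `AE`, `relative_AE`.
#' @export
#' @examples
#' entropy_block(rep(1 / 20, 20))$SE  # log2(20)
entropy_block <- function(probabilities, alpha = 2, p0 = 1 / 20) {
  check_alpha(alpha)
  p <- probabilities[probabilities > 0]
  se <- -sum(p * log2(p))
  rel_se <- sum(p * log2(p / p0))
  he <- (2^(1 - alpha) - 1)^-1 * (sum(p^alpha) - 1)
  rel_he <- -(2^(1 - alpha) - 1)^-1 * (sum(p^alpha / p0^(alpha - 1)) - 1)
  re <- (1 - alpha)^-1 * log2(sum(p^alpha))
  rel_re <- (1 - alpha)^-1 * log2(sum(p^alpha / p0^(alpha - 1)))
  ae <- (2^(alpha - 1) - 1)^-1 * (sum(p^(1 / alpha))^alpha - 1)
  rel_ae <- -(2^(alpha - 1) - 1)^-1 *
    (sum(p^(1 / alpha) / p0^(1 / (alpha - 1)))^alpha - 1)
  list(SE = se, relative_SE = rel_se, information_gain = se - rel_se,
       HE = he, relative_HE = rel_he, RE = re, relative_RE = rel_re,
       AE = ae, relative_AE = rel_ae)
}

#' The 4-entry information-theoretic feature block of a window
#'
#' `[ITB_SE, ITB_HE, ITB_RE, ITB_AE]` computed from the window's
#' composition profile. The relative forms and information gain are
#' available through [entropy_block()] but are not part of the default
#' feature layout.
#'
#' @inheritParams dpc_vector
#' @param alpha Entropy order (see [entropy_block()]).
#' @return Named numeric vector of length 4.
#' @export
itb_features <- function(residues, alpha = 2) {
  eb <- entropy_block(composition_profile(residues)$probabilities, alpha)
  stats::setNames(c(eb$SE, eb$HE, eb$RE, eb$AE), feature_names("ITB"))
}

#' Molar extinction coefficient at 280 nm
#'
#' `EX = ME(cystine) * n(cystine) + ME(Trp) * n(Trp) + ME(Tyr) * n(Tyr)`
#' with the standard assay constants (Trp 5500, Tyr 1490, cystine 125
#' M^-1 cm^-1). In the oxidized variant every cysteine pair forms a
#' cystine (`n = floor(count(C) / 2)`); reduced assumes no cystines.
#'
#' @inheritParams dpc_vector
#' @param oxidized Logical; count cystines formed by cysteine pairs?
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
extinction_coefficient <- function(residues, oxidized = FALSE) {
  chars <- depad(window_chars(residues))
  n_cy <- if (oxidized) floor(sum(chars == "C") / 2) else 0
  MOLAR_EX[["trp"]] * sum(chars == "W") +
    MOLAR_EX[["tyr"]] * sum(chars == "Y") +
    MOLAR_EX[["cystine"]] * n_cy
}

#' Instability index of a window
#'
#' `10 / L * sum(DIWV over the L - 1 adjacent dipeptides)` over the
#' de-padded residue string of length L (Guruprasad et al. 1990 weights).
#' Values above 40 indicate an unstable peptide.
#'
#' @inheritParams dpc_vector
#' @param diwv Optional replacement 20 x 20 weight matrix (rows = first
#'   residue), mainly for testing.
#' @return The instability index, with attribute `unstable` (TRUE iff
#'   value > 40).
#' @export
instability_index <- function(residues, diwv = NULL) {
  if (is.null(diwv)) diwv <- get_constant("diwv")
  chars <- depad(window_chars(residues))
  L <- length(chars)
  if (L < 2) {
    stop("instability index requires at least 2 non-pad residues", call. = FALSE)
  }
  s <- sum(diwv[cbind(chars[-L], chars[-1])])
  structure(10 / L * s, unstable = (10 / L * s) > 40)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the non-pad residues.
#'
#' @inheritParams dpc_vector
#' @return The GRAVY value.
#' @export
gravy <- function(residues) {
  chars <- depad(window_chars(residues))
  if (length(chars) == 0) {
    stop("GRAVY requires at least 1 non-pad residue", call. = FALSE)
  }
  mean(get_constant("hydropathy")[chars])
}

#' Isoelectric point by bisection on the Henderson-Hasselbalch net charge
#'
#' Net charge of the de-padded peptide (free N- and C-terminus plus the
#' ionizable side chains C, D, E, H, K, R, Y; EMBOSS pKa set) is bisected
#' over pH in `[0, 14]` until `|charge| < 1e-4` or the bracket is narrower
#' than 0.01 pH units.
#'
#' @inheritParams dpc_vector
#' @return The isoelectric point (pH units).
#' @export
isoelectric_point <- function(residues) {
  chars <- depad(window_chars(residues))
  if (length(chars) == 0) {
    stop("pI requires at least 1 non-pad residue", call. = FALSE)
  }
  pka <- get_constant("pka")
  sign <- get_constant("pka_sign")
  counts <- c(Nterm = 1, Cterm = 1,
              vapply(setdiff(names(pka), c("Nterm", "Cterm")),
                     function(a) sum(chars == a), numeric(1)))
  net_charge <- function(ph) {
    sum(vapply(names(pka), function(g) {
      if (sign[[g]] > 0) {
        counts[[g]] / (1 + 10^(ph - pka[[g]]))
      } else {
        -counts[[g]] / (1 + 10^(pka[[g]] - ph))
      }
    }, numeric(1)))
  }
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(mid)
    if (abs(q) < 1e-4 || (hi - lo) < 0.01) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' The 10-entry physicochemical feature block
#'
#' `[PP_pI, PP_MW, PP_AROM, PP_II, PP_GRAVY, PP_EX_RED, PP_EX_OX,
#' PP_HELIX, PP_TURN, PP_SHEET]` computed on the de-padded residue string:
#' isoelectric point, molecular weight (sum of average residue masses plus
#' one water), aromaticity (fraction of F/W/Y), instability index, GRAVY,
#' reduced and oxidized extinction coefficients, and the fractions of
#' residues in the helix {V,I,Y,F,W,L}, turn {N,G,P,S} and sheet
#' {E,M,A,L} classes.
#'
#' @inheritParams dpc_vector
#' @return Named numeric vector of length 10.
#' @export
pp_features <- function(residues) {
  chars <- depad(window_chars(residues))
  if (length(chars) < 2) {
    stop("physicochemical block requires at least 2 non-pad residues",
         call. = FALSE)
  }
  L <- length(chars)
  mw <- sum(get_constant("mass")[chars]) + MASS_WATER
  vals <- c(
    isoelectric_point(residues),
    mw,
    sum(chars %in% c("F", "W", "Y")) / L,
    as.numeric(instability_index(residues)),
    gravy(residues),
    extinction_coefficient(residues, oxidized = FALSE),
    extinction_coefficient(residues, oxidized = TRUE),
    sum(chars %in% SS_CLASSES$helix) / L,
    sum(chars %in% SS_CLASSES$turn) / L,
    sum(chars %in% SS_CLASSES$sheet) / L
  )
  stats::setNames(vals, feature_names("PP"))
}

#' Encode one peptide window into the feature vector
#'
#' Concatenates the requested blocks in canonical order
#' `[AAC | DPC | ITB | PP]`; the full layout has 434 entries.
#'
#' @inheritParams dpc_vector
#' @param alpha Entropy order for the ITB block.
#' @param blocks Feature blocks to include (default all four).
#' @param dpc_denominator Passed to [dpc_vector()].
#' @return Named numeric vector.
#' @export
#' @examples
#' length(encode_window("GGGGGRGGGGG"))  # 434
encode_window <- function(residues, alpha = 2,
                          blocks = c("AAC", "DPC", "ITB", "PP"),
                          dpc_denominator = c("l", "l-1")) {
  blocks <- match.arg(blocks, c("AAC", "DPC", "ITB", "PP"), several.ok = TRUE)
  dpc_denominator <- match.arg(dpc_denominator)
  out <- numeric(0)
  if ("AAC" %in% blocks) out <- c(out, aac_vector(residues))
  if ("DPC" %in% blocks) out <- c(out, dpc_vector(residues, dpc_denominator))
  if ("ITB" %in% blocks) out <- c(out, itb_features(residues, alpha))
  if ("PP" %in% blocks) out <- c(out, pp_features(residues))
  out
}

#' Encode a window dataset into a feature table
#'
#' @param windows A window tibble (see [extract_windows()] /
#'   [generate_windows()]).
#' @inheritParams encode_window
#' @param itb_extended Also append the relative entropies and information
#'   gain (`ITB_REL_SE`, `ITB_IG`, `ITB_REL_HE`, `ITB_REL_RE`,
#'   `ITB_REL_AE`) as extra trailing columns.
#' @return A tibble with `window_id`, `label`, and one column per feature
#'   in the stable layout order.
#' @export
encode_windows <- function(windows, alpha = 2,
                           blocks = c("AAC", "DPC", "ITB", "PP"),
                           dpc_denominator = c("l", "l-1"),
                           itb_extended = FALSE) {
  stopifnot(is.data.frame(windows),
            all(c("window_id", "residues", "label") %in% names(windows)))
  blocks <- match.arg(blocks, c("AAC", "DPC", "ITB", "PP"), several.ok = TRUE)
  dpc_denominator <- match.arg(dpc_denominator)
  mat <- t(vapply(windows$residues, function(r) {
    v <- encode_window(r, alpha = alpha, blocks = blocks,
                       dpc_denominator = dpc_denominator)
    if (itb_extended) {
      eb <- entropy_block(composition_profile(r)$probabilities, alpha)
      v <- c(v, ITB_REL_SE = eb$relative_SE, ITB_IG = eb$information_gain,
             ITB_REL_HE = eb$relative_HE, ITB_REL_RE = eb$relative_RE,
             ITB_REL_AE = eb$relative_AE)
    }
    v
  }, numeric(length(feature_names(blocks)) + if (itb_extended) 5 else 0)))
  rownames(mat) <- NULL
  dplyr::bind_cols(
    tibble::tibble(window_id = windows$window_id, label = windows$label),
    tibble::as_tibble(mat)
  )
}

# Numeric feature columns of an encoded table (everything except metadata).
feature_columns <- function(features) {
  setdiff(names(features), c("window_id", "source_id", "center_position",
                             "residues", "label"))
}

# Feature table -> plain numeric matrix.
feature_matrix <- function(features) {
  as.matrix(features[feature_columns(features)])
}

#' Write an encoded feature table to CSV
#'
#' Header: `window_id`, `label`, then the stable feature names.
#'
#' @param features Encoded feature tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}
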