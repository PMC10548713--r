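# Bundled constant tables (loaded once per session from inst/extdata) and the
# stable 434-entry feature layout.

.const_env <- new.env(parent = emptyenv())

#' The 20 standard amino acids, alphabetical by one-letter code
#'
#' Order used for the AAC block and the row-major DPC block.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Residues counted toward the ProtParam secondary-structure fractions.
SS_CLASSES <- list(
  helix = c("V", "I", "Y", "F", "W", "L"),
  turn  = c("N", "G", "P", "S"),
  sheet = c("E", "M", "A", "L")
)

# Molar extinction coefficients at 280 nm (M^-1 cm^-1): Trp, Tyr, cystine.
MOLAR_EX <- c(trp = 5500, tyr = 1490, cystine = 125)

MASS_WATER <- 18.01524

extdata_path <- function(file) {
  system.file("extdata", file, package = "methylarg", mustWork = TRUE)
}

read_constant_tsv <- function(file) {
  utils::read.delim(extdata_path(file), comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

load_constants <- function() {
  aas <- amino_acids()

  kd <- read_constant_tsv("hydropathy_kd.tsv")
  hydro <- stats::setNames(kd$hydropathy, kd$residue)[aas]
  stopifnot(!anyNA(hydro))

  mm <- read_constant_tsv("residue_mass_avg.tsv")
  mass <- stats::setNames(mm$mass, mm$residue)[aas]
  stopifnot(!anyNA(mass))

  dv <- read_constant_tsv("diwv.tsv")
  diwv <- as.matrix(dv[, aas])
  rownames(diwv) <- dv$first
  diwv <- diwv[aas, aas]
  stopifnot(identical(dim(diwv), c(20L, 20L)), !anyNA(diwv))

  pk <- read_constant_tsv("pka_emboss.tsv")
  pka <- stats::setNames(pk$pka, pk$group)
  pka_sign <- stats::setNames(pk$charge, pk$group)

  assign("hydropathy", hydro, envir = .const_env)
  assign("mass", mass, envir = .const_env)
  assign("diwv", diwv, envir = .const_env)
  assign("pka", pka, envir = .const_env)
  assign("pka_sign", pka_sign, envir = .const_env)
  invisible(NULL)
}

get_constant <- function(name) {
  if (!exists(name, envir = .const_env)) load_constants()
  get(name, envir = .const_env)
}

#' Constant tables used by the physicochemical descriptors
#'
#' Returns the bundled lookup tables: Kyte-Doolittle hydropathy values,
#' Expasy average residue masses, the Guruprasad et al. (1990) dipeptide
#' instability weight matrix (DIWV), the EMBOSS pKa set, the molar
#' extinction coefficients, and the secondary-structure residue classes.
#'
#' @return A named list of tables.
#' @export
constant_tables <- function() {
  list(
    hydropathy = get_constant("hydropathy"),
    mass       = get_constant("mass"),
    diwv       = get_constant("diwv"),
    pka        = get_constant("pka"),
    pka_sign   = get_constant("pka_sign"),
    molar_ex   = MOLAR_EX,
    ss_classes = SS_CLASSES,
    mass_water = MASS_WATER
  )
}

#' Stable feature names of the encoder
#'
#' The full layout has 434 entries: positions 1-20 amino-acid composition
#' (`AAC_A` ... `AAC_Y`), 21-420 dipeptide composition in row-major order
#' over first x second residue (`DPC_AA` ... `DPC_YY`), 421-424 the
#' information-theoretic block (`ITB_SE`, `ITB_HE`, `ITB_RE`, `ITB_AE`),
#' and 425-434 the physicochemical block (`PP_pI`, `PP_MW`, `PP_AROM`,
#' `PP_II`, `PP_GRAVY`, `PP_EX_RED`, `PP_EX_OX`, `PP_HELIX`, `PP_TURN`,
#' `PP_SHEET`).
#'
#' @param blocks Character subset of `c("AAC", "DPC", "ITB", "PP")` naming
#'   the blocks to include, in canonical order.
#' @return Character vector of feature names.
#' @export
#' @examples
#' length(feature_names())          # 434
#' feature_names("ITB")
feature_names <- function(blocks = c("AAC", "DPC", "ITB", "PP")) {
  blocks <- match.arg(blocks, c("AAC", "DPC", "ITB", "PP"), several.ok = TRUE)
  aas <- amino_acids()
  out <- character(0)
  if ("AAC" %in% blocks) out <- c(out, paste0("AAC_", aas))
  if ("DPC" %in% blocks) {
    pairs <- as.vector(t(outer(aas, aas, paste0)))
    out <- c(out, paste0("DPC_", pairs))
  }
  if ("ITB" %in% blocks) out <- c(out, c("ITB_SE", "ITB_HE", "ITB_RE", "ITB_AE"))
  if ("PP" %in% blocks) {
    out <- c(out, paste0("PP_", c("pI", "MW", "AROM", "II", "GRAVY",
                                  "EX_RED", "EX_OX", "HELIX", "TURN", "SHEET")))
  }
  out
}

# Block membership from a feature name prefix.
feature_block <- function(names) {
  sub("_.*$", "", names)
}
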