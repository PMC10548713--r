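# Reading protein sequences and site annotations, extracting R-centered
# peptide windows, dataset assembly and class balancing.

VALID_RESIDUES <- function() c(amino_acids(), "B", "Z", "U", "O", "X")
AMBIGUITY_CODES <- c("B", "Z", "U", "O")

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and validated against the 20 standard one-letter
#' codes plus the ambiguity codes B, Z, U, O and X. Ambiguity codes are
#' normalized to the inert pad/unknown character `X` (with a warning), since
#' the feature encoders define behavior only for the standard residues.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("FASTA file is empty or malformed: ", path,
                             call. = FALSE))
  if (length(set) == 0) {
    stop("FASTA file is empty: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(vapply(set, function(s) as.character(s)[[1]], character(1)))
  seqs <- unname(seqs)
  validate_sequences(ids, seqs)
  tibble::tibble(id = ids, sequence = normalize_ambiguity(ids, seqs))
}

validate_sequences <- function(ids, seqs) {
  ok <- paste(VALID_RESIDUES(), collapse = "")
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) {
      stop("record '", ids[[i]], "' has an empty sequence", call. = FALSE)
    }
    bad <- regexpr(paste0("[^", ok, "]"), seqs[[i]])
    if (bad > 0) {
      stop("record '", ids[[i]], "' contains illegal residue '",
           substr(seqs[[i]], bad, bad), "' at position ", bad, call. = FALSE)
    }
  }
  invisible(NULL)
}

normalize_ambiguity <- function(ids, seqs) {
  has_amb <- grepl("[BZUO]", seqs)
  if (any(has_amb)) {
    warning("ambiguity codes B/Z/U/O normalized to 'X' in record(s): ",
            paste(ids[has_amb], collapse = ", "), call. = FALSE)
    seqs <- gsub("[BZUO]", "X", seqs)
  }
  seqs
}

#' Read a site-annotation table
#'
#' Expects a TSV or CSV (delimiter auto-detected from the extension, default
#' tab) with header columns `protein_id`, `position` (1-based index of the
#' annotated arginine) and `label` (`mono` or `di`). Lines starting with `#`
#' are ignored.
#'
#' @param path Path to the annotation table.
#' @return A tibble with columns `protein_id`, `position`, `label`.
#' @export
read_site_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ann <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(ann$label %in% c("mono", "di"))) {
    stop("annotation labels must be 'mono' or 'di'", call. = FALSE)
  }
  tibble::as_tibble(ann[need])
}

#' Extract arginine-centered peptide windows
#'
#' Emits one window of length `2 * gamma + 1` per occurrence of `R` in each
#' protein. Positions falling outside the protein are padded with the inert
#' character `X`, so windows at the termini keep the fixed length.
#'
#' @param proteins A tibble with columns `id`, `sequence` (see [read_fasta()]).
#' @param gamma Window half-width; the default 5 gives 11-residue windows.
#' @return A tibble with columns `window_id`, `source_id`, `center_position`
#'   (1-based position of the central R in the source protein), `residues`
#'   and `label` (initialized to `"unlabeled"`).
#' @export
#' @examples
#' p <- tibble::tibble(id = "p1", sequence = "GGGGGRGGGGG")
#' extract_windows(p, gamma = 5)
extract_windows <- function(proteins, gamma = 5) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  if (!(is.numeric(gamma) && length(gamma) == 1 && gamma >= 1 && gamma == floor(gamma))) {
    stop("gamma must be a positive integer", call. = FALSE)
  }
  gamma <- as.integer(gamma)
  out <- purrr::pmap(proteins[c("id", "sequence")], function(id, sequence) {
    centers <- which(strsplit(sequence, "", fixed = TRUE)[[1]] == "R")
    if (length(centers) == 0) return(NULL)
    tibble::tibble(
      source_id = id,
      center_position = centers,
      residues = vapply(centers, function(ctr) {
        pad_window(sequence, ctr, gamma)
      }, character(1))
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(window_id = character(), source_id = character(),
                          center_position = integer(), residues = character(),
                          label = character()))
  }
  out$window_id <- paste0(out$source_id, "_", out$center_position)
  out$label <- "unlabeled"
  out[c("window_id", "source_id", "center_position", "residues", "label")]
}

pad_window <- function(sequence, center, gamma) {
  n <- nchar(sequence)
  lo <- center - gamma
  hi <- center + gamma
  core <- substr(sequence, max(1L, lo), min(n, hi))
  left <- strrep("X", max(0L, 1L - lo))
  right <- strrep("X", max(0L, hi - n))
  paste0(left, core, right)
}

#' Assemble a labeled window dataset from proteins and annotations
#'
#' Windows whose center is annotated with `site_class` are positives; all
#' remaining R-centered windows from the same proteins are negatives.
#' Negatives whose residue string is identical to any positive window are
#' dropped to avoid label contradictions; duplicate negatives are otherwise
#' retained.
#'
#' @param proteins A tibble with `id`, `sequence`.
#' @param annotations A tibble with `protein_id`, `position`, `label`
#'   (see [read_site_annotations()]).
#' @param gamma Window half-width (default 5).
#' @param site_class Which methylation class defines the positives:
#'   `"mono"` or `"di"`.
#' @return A tibble of labeled windows (`label` is `"positive"` or
#'   `"negative"`) with a `class_counts` attribute.
#' @export
build_dataset <- function(proteins, annotations, gamma = 5,
                          site_class = c("mono", "di")) {
  site_class <- match.arg(site_class)
  windows <- extract_windows(proteins, gamma)

  unknown <- setdiff(annotations$protein_id, proteins$id)
  if (length(unknown) > 0) {
    stop("annotation references unknown protein id(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(annotations))) {
    pid <- annotations$protein_id[[i]]
    pos <- annotations$position[[i]]
    seq <- proteins$sequence[match(pid, proteins$id)]
    if (pos < 1 || pos > nchar(seq) || substr(seq, pos, pos) != "R") {
      stop("annotation (", pid, ", ", pos, ") does not point at an 'R' residue",
           call. = FALSE)
    }
  }

  ann <- annotations[annotations$label == site_class, , drop = FALSE]
  pos_key <- paste0(ann$protein_id, "_", ann$position)
  is_pos <- windows$window_id %in% pos_key
  windows$label <- ifelse(is_pos, "positive", "negative")

  pos_strings <- unique(windows$residues[is_pos])
  drop <- !is_pos & windows$residues %in% pos_strings
  windows <- windows[!drop, , drop = FALSE]

  attr(windows, "class_counts") <- table(windows$label)
  windows
}

#' Balance classes by random under-sampling
#'
#' Reduces the majority class by uniform sampling without replacement to the
#' minority-class count; the minority class is untouched. Deterministic for
#' a given `seed`.
#'
#' @param windows A labeled window tibble (labels `"positive"`/`"negative"`).
#' @param seed Integer seed for the sampling.
#' @return The balanced tibble (row order: as in the input, minus dropped
#'   majority rows).
#' @export
undersample <- function(windows, seed) {
  stopifnot(is.data.frame(windows), "label" %in% names(windows))
  counts <- table(windows$label)
  if (length(counts) < 2 || any(counts == 0)) {
    stop("undersample requires at least one sample of each class", call. = FALSE)
  }
  if (length(unique(counts)) == 1) return(windows)
  minority <- names(counts)[which.min(counts)]
  majority <- names(counts)[which.max(counts)]
  maj_idx <- which(windows$label == majority)
  keep <- withr::with_seed(seed,
    sample(maj_idx, size = min(counts), replace = FALSE))
  out <- windows[sort(c(which(windows$label == minority), keep)), , drop = FALSE]
  attr(out, "class_counts") <- table(out$label)
  out
}

#' Write / read a window dataset as TSV
#'
#' Columns: `window_id`, `source_id`, `center_position`, `residues`, `label`.
#' On read, every residue string is checked against the expected window
#' length `2 * gamma + 1`; a mismatching row is a schema error.
#'
#' @param windows A window tibble.
#' @param path Output (or input) TSV path.
#' @param gamma Expected half-width used for validation on read.
#' @return `write_windows()` returns `path` invisibly; `read_windows()`
#'   returns the window tibble.
#' @export
write_windows <- function(windows, path) {
  readr::write_tsv(windows, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path, gamma = 5) {
  win <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("window_id", "source_id", "center_position", "residues", "label")
  if (!all(need %in% names(win))) {
    stop("window table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  expect_len <- 2L * as.integer(gamma) + 1L
  bad <- which(nchar(win$residues) != expect_len)
  if (length(bad) > 0) {
    stop("window table row ", bad[[1]], " ('", win$window_id[[bad[[1]]]],
         "') has a residue string of length ", nchar(win$residues[[bad[[1]]]]),
         ", expected ", expect_len, call. = FALSE)
  }
  tibble::as_tibble(win[need])
}

#' Write proteins to a FASTA file (60-column wrapping)
#'
#' @param proteins A tibble with `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  seqinr::write.fasta(as.list(proteins$sequence), proteins$id, path,
                      nbchar = 60, as.string = TRUE)
  invisible(path)
}
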