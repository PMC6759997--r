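#' Parse a phosphosite sequence window
#'
#' Phosphosite windows are short peptide contexts written in uppercase with
#' the single phosphorylated residue in lowercase (e.g. `"MMRQAtMDFSTPS"`).
#' The lowercase residue must be a serine, threonine or tyrosine.
#'
#' @param window character scalar of amino-acid letters with exactly one
#'   lowercase letter.
#' @return List with `offset` (1-based index of the phospho-residue within
#'   the window) and `residue` (its uppercase identity, `"S"`, `"T"` or
#'   `"Y"`).
#' @export
parse_window <- function(window) {
  if (!is.character(window) || length(window) != 1 || is.na(window) ||
      nchar(window) == 0) {
    stop("window must be a non-empty string")
  }
  chars <- strsplit(window, "")[[1]]
  if (!all(grepl("[A-Za-z]", chars))) stop("window contains non-letters")
  low <- which(chars %in% letters)
  if (length(low) == 0) stop("no lowercase phospho-residue in window")
  if (length(low) > 1) stop("multiple lowercase residues in window")
  res <- toupper(chars[low])
  if (!res %in% c("S", "T", "Y")) {
    stop("phospho-residue must be S, T or Y, got: ", chars[low])
  }
  list(offset = low, residue = res)
}

#' Infer a phosphosite's protein position by window overlap
#'
#' Given an anchor window whose phosphosite has a known 1-based protein
#' position, places a query window on the protein by unique exact overlap of
#' the uppercased sequences and returns the protein position of the query's
#' phospho-residue. The anchor's window start is `anchor_position -
#' offset + 1`; a window truncated at the N-terminus is thereby pinned at
#' protein position 1.
#'
#' @param anchor_window window string with one lowercase residue.
#' @param anchor_position declared 1-based protein position of the anchor's
#'   phospho-residue.
#' @param query_window window string with one lowercase residue.
#' @param min_overlap minimum length of the exact overlap required to accept
#'   a placement (default 8 residues).
#' @return 1-based protein position of the query's phospho-residue.
#' @export
infer_position <- function(anchor_window, anchor_position, query_window,
                           min_overlap = 8) {
  pa <- parse_window(anchor_window)
  pq <- parse_window(query_window)
  if (anchor_position < pa$offset) {
    stop("anchor window extends past the protein N-terminus")
  }
  anchor_start <- anchor_position - pa$offset + 1L
  a <- strsplit(toupper(anchor_window), "")[[1]]
  q <- strsplit(toupper(query_window), "")[[1]]
  la <- length(a)
  lq <- length(q)

  # d = query start relative to anchor start (0-based shift)
  hits <- integer(0)
  for (d in seq(-(lq - min_overlap), la - min_overlap)) {
    ov_a <- max(1L, d + 1L):min(la, d + lq)
    ov_q <- ov_a - d
    if (length(ov_a) < min_overlap) next
    if (all(a[ov_a] == q[ov_q])) hits <- c(hits, d)
  }
  if (length(hits) == 0) {
    stop("no exact overlap of >= ", min_overlap,
         " residues between query and anchor windows")
  }
  if (length(hits) > 1) {
    stop("ambiguous placement: ", length(hits), " overlap positions")
  }
  pos <- anchor_start + hits + pq$offset - 1L
  if (pos < 1) stop("inferred position extends past the N-terminus")
  as.integer(pos)
}

#' Count distinct phosphosites, optionally by species
#'
#' @param rows tibble of phosphosite annotations with columns
#'   `declared_position` and `species`; a row observed in several species
#'   carries them semicolon-separated (e.g. `"Mouse;Human"`).
#' @param species_filter optional species name; when given, only rows whose
#'   species set contains it are counted.
#' @return Number of distinct declared positions.
#' @export
count_sites <- function(rows, species_filter = NULL) {
  if (is.null(rows) || nrow(rows) == 0) return(0L)
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(species_filter)) {
    keep <- vapply(strsplit(rows$species, ";"),
                   function(s) species_filter %in% trimws(s), logical(1))
  }
  length(unique(rows$declared_position[keep]))
}

#' Scan phosphosites for 14-3-3 binding motifs
#'
#' 14-3-3 proteins bind phosphoserine/phosphothreonine ligands through two
#' consensus contexts around the phosphosite `pS/pT` at position `p`
#' (1-based, X = any residue):
#' \itemize{
#'   \item mode I, `R S X pS/pT X P`: `R` at `p-3`, `S` at `p-2`, `P` at
#'     `p+2`;
#'   \item mode II, `R X X X pS/pT X P`: `R` at `p-4`, `P` at `p+2`.
#' }
#' A site too close to a terminus for a pattern cannot match it; one site
#' may match both modes.
#'
#' @param sequence amino-acid string (uppercase).
#' @param phospho_positions integer vector of 1-based positions; the residue
#'   at each must be `S` or `T`.
#' @return Tibble with columns `motif_id` (`"modeI"`/`"modeII"`),
#'   `site_position` and `matched_span`.
#' @export
scan_14_3_3_motifs <- function(sequence, phospho_positions) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  phospho_positions <- as.integer(phospho_positions)
  if (any(phospho_positions < 1 | phospho_positions > n)) {
    stop("phospho position out of sequence range")
  }
  bad <- !s[phospho_positions] %in% c("S", "T")
  if (any(bad)) {
    stop("residue at position(s) ",
         paste(phospho_positions[bad], collapse = ", "), " is not S/T")
  }
  hits <- list()
  for (p in sort(unique(phospho_positions))) {
    if (p - 3 >= 1 && p + 2 <= n &&
        s[p - 3] == "R" && s[p - 2] == "S" && s[p + 2] == "P") {
      hits[[length(hits) + 1]] <- tibble::tibble(
        motif_id = "modeI", site_position = p,
        matched_span = substr(sequence, p - 3, p + 2))
    }
    if (p - 4 >= 1 && p + 2 <= n && s[p - 4] == "R" && s[p + 2] == "P") {
      hits[[length(hits) + 1]] <- tibble::tibble(
        motif_id = "modeII", site_position = p,
        matched_span = substr(sequence, p - 4, p + 2))
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(motif_id = character(0),
                          site_position = integer(0),
                          matched_span = character(0)))
  }
  do.call(rbind, hits)
}

#' Read a phosphosite annotation table from TSV
#'
#' Columns: `position` (site label like `"T6"` or a bare integer),
#' `peptide` (window with one lowercase residue), `species`, `source`.
#'
#' @param path path to the TSV file.
#' @return Tibble with the input columns plus parsed `residue` and
#'   `declared_position`.
#' @export
read_phospho_table <- function(path) {
  if (!file.exists(path)) stop("phosphosite table not found: ", path)
  raw <- tibble::as_tibble(
    utils::read.delim(path, check.names = FALSE, colClasses = "character"))
  req <- c("position", "peptide", "species", "source")
  if (!all(req %in% names(raw))) {
    stop("phosphosite table needs columns: ", paste(req, collapse = ", "))
  }
  lab <- raw$position
  residue <- ifelse(grepl("^[STY]", lab), substr(lab, 1, 1), NA_character_)
  pos <- as.integer(sub("^[STY]", "", lab))
  if (any(is.na(pos))) stop("unparseable position label(s)")
  for (i in seq_len(nrow(raw))) {
    pw <- parse_window(raw$peptide[i])
    if (!is.na(residue[i]) && pw$residue != residue[i]) {
      stop("row ", i, ": window phospho-residue ", pw$residue,
           " does not match position label ", lab[i])
    }
  }
  raw$residue <- residue
  raw$declared_position <- pos
  raw
}
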