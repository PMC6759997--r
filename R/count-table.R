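#' Construct a spectral-count table
#'
#' The central container of the package: a protein x sample matrix of
#' MS/MS spectral counts together with a matching matrix of unique-peptide
#' counts and the sample design (bait vs. negative-control IP, replicate
#' index). Cells for proteins not identified in a sample are 0, never
#' missing.
#'
#' @param proteins data.frame with at least an `accession` column (unique);
#'   an optional `gene_symbol` column is carried through to reports.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"bait"` or `"control"`) and `replicate_index` (integer >= 1).
#' @param spc integer matrix of non-negative spectral counts,
#'   `nrow(proteins)` x `nrow(samples)`.
#' @param unique_peptides integer matrix of the same shape; must satisfy
#'   `unique_peptides <= spc` element-wise (a spectrum matches one peptide).
#'
#' @return An object of class `spectral_count_table`: a list with elements
#'   `proteins` (tibble), `samples` (tibble), `spc` and `unique_peptides`
#'   (integer matrices with accession row names and sample_id column names).
#' @export
spectral_count_table <- function(proteins, samples, spc, unique_peptides) {
  proteins <- tibble::as_tibble(proteins)
  samples <- tibble::as_tibble(samples)
  if (!"accession" %in% names(proteins)) {
    stop("`proteins` must have an `accession` column")
  }
  if (anyDuplicated(proteins$accession)) {
    stop("duplicate accession in `proteins`: ",
         paste(unique(proteins$accession[duplicated(proteins$accession)]),
               collapse = ", "))
  }
  if (!"gene_symbol" %in% names(proteins)) {
    proteins$gene_symbol <- proteins$accession
  }
  req <- c("sample_id", "condition", "replicate_index")
  if (!all(req %in% names(samples))) {
    stop("`samples` must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(samples$condition %in% c("bait", "control"))) {
    stop("sample condition must be 'bait' or 'control'")
  }
  if (anyDuplicated(samples[, c("condition", "replicate_index")])) {
    stop("duplicate (condition, replicate_index) in design")
  }
  spc <- check_count_matrix(spc, nrow(proteins), nrow(samples), "spc")
  unique_peptides <- check_count_matrix(unique_peptides, nrow(proteins),
                                        nrow(samples), "unique_peptides")
  if (any(unique_peptides > spc)) {
    stop("unique_peptides exceeds spectral counts for some cells")
  }
  dimnames(spc) <- dimnames(unique_peptides) <-
    list(proteins$accession, samples$sample_id)
  structure(
    list(proteins = proteins, samples = samples,
         spc = spc, unique_peptides = unique_peptides),
    class = "spectral_count_table"
  )
}

check_count_matrix <- function(m, n_prot, n_samp, what) {
  m <- as.matrix(m)
  if (nrow(m) != n_prot || ncol(m) != n_samp) {
    stop(what, " must be ", n_prot, " x ", n_samp)
  }
  if (any(is.na(m))) stop(what, " contains missing values")
  if (any(m < 0)) stop(what, " contains negative counts")
  if (any(m != round(m))) stop(what, " contains non-integer counts")
  storage.mode(m) <- "integer"
  m
}

#' @export
print.spectral_count_table <- function(x, ...) {
  cat(sprintf(
    "spectral_count_table: %d proteins x %d samples (%d bait, %d control)\n",
    nrow(x$spc), ncol(x$spc),
    sum(x$samples$condition == "bait"),
    sum(x$samples$condition == "control")))
  invisible(x)
}

#' Read a protein-level spectral-count table from TSV
#'
#' Expects a tab-separated file with one row per protein: first column
#' `accession`, optional second column `gene_symbol`, then one column per
#' sample named by its `sample_id`. Empty cells are interpreted as "protein
#' not identified in this sample" and imputed as 0. A matching
#' unique-peptide table (same layout) may be supplied; when it is absent,
#' unique peptides default to the spectral counts themselves (each spectrum
#' matching a distinct peptide is an upper bound), so the downstream peptide
#' gate degenerates to a spectral-count floor.
#'
#' @param path path to the spectral-count TSV.
#' @param design data.frame with `sample_id`, `condition`, `replicate_index`
#'   describing each sample column.
#' @param peptide_path optional path to the unique-peptide TSV.
#' @return A [spectral_count_table()].
#' @export
read_count_table <- function(path, design, peptide_path = NULL) {
  parsed <- read_counts_tsv(path, design)
  if (is.null(peptide_path)) {
    up <- parsed$counts
  } else {
    pp <- read_counts_tsv(peptide_path, design)
    if (!identical(rownames(pp$counts), rownames(parsed$counts))) {
      pp$counts <- pp$counts[match(rownames(parsed$counts),
                                   rownames(pp$counts)), , drop = FALSE]
      pp$counts[is.na(pp$counts)] <- 0L
      rownames(pp$counts) <- rownames(parsed$counts)
    }
    up <- pmin(pp$counts, parsed$counts)
  }
  spectral_count_table(parsed$proteins, design, parsed$counts, up)
}

read_counts_tsv <- function(path, design) {
  if (!file.exists(path)) stop("count table not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  if (names(raw)[1] != "accession") {
    names(raw)[1] <- "accession"
  }
  has_gene <- ncol(raw) >= 2 && names(raw)[2] == "gene_symbol"
  meta_cols <- if (has_gene) 1:2 else 1
  sample_cols <- names(raw)[-meta_cols]
  unknown <- setdiff(sample_cols, design$sample_id)
  if (length(unknown)) {
    stop("unknown sample_id in header: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(design$sample_id, sample_cols)
  if (length(missing)) {
    stop("design sample(s) absent from table: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(raw$accession)) {
    stop("duplicate accession: ",
         paste(unique(raw$accession[duplicated(raw$accession)]),
               collapse = ", "))
  }
  counts <- as.matrix(raw[, design$sample_id, drop = FALSE])
  counts[is.na(counts)] <- "0"
  num <- suppressWarnings(matrix(as.numeric(counts), nrow = nrow(counts)))
  if (any(is.na(num))) stop("non-numeric count cell in ", path)
  if (any(num < 0)) stop("negative count in ", path)
  if (any(num != round(num))) stop("non-integer count in ", path)
  storage.mode(num) <- "integer"
  rownames(num) <- raw$accession
  colnames(num) <- design$sample_id
  proteins <- tibble::tibble(
    accession = raw$accession,
    gene_symbol = if (has_gene) raw$gene_symbol else raw$accession
  )
  list(proteins = proteins, counts = num)
}

#' Write a spectral-count table (and its peptide matrix) to TSV
#'
#' Inverse of [read_count_table()]; `read(write(x))` reproduces the matrices
#' exactly.
#'
#' @param table a [spectral_count_table()].
#' @param path output TSV for spectral counts.
#' @param peptide_path optional output TSV for unique-peptide counts.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, peptide_path = NULL) {
  write_one <- function(m, p) {
    df <- data.frame(accession = table$proteins$accession,
                     gene_symbol = table$proteins$gene_symbol,
                     m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_one(table$spc, path)
  if (!is.null(peptide_path)) write_one(table$unique_peptides, peptide_path)
  invisible(path)
}

#' Read protein lengths from a FASTA file
#'
#' Lengths supply the denominator term of NSAF (spectral counts are
#' normalized to protein length). The accession is the first
#' whitespace-delimited token of the header; UniProt-style headers
#' (`sp|ACC|NAME`, `tr|ACC|NAME`) are reduced to the accession field.
#'
#' @param fasta path to a protein FASTA file.
#' @return Named integer vector mapping accession to length in residues.
#' @export
read_protein_lengths <- function(fasta) {
  if (!file.exists(fasta)) stop("FASTA not found: ", fasta)
  seqs <- Biostrings::readAAStringSet(fasta)
  acc <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1)
  uni <- grepl("^(sp|tr)\\|", acc)
  acc[uni] <- vapply(strsplit(acc[uni], "\\|"), `[[`, character(1), 2)
  len <- Biostrings::width(seqs)
  if (any(len == 0)) {
    stop("empty sequence for: ", paste(acc[len == 0], collapse = ", "))
  }
  if (anyDuplicated(acc)) {
    for (a in unique(acc[duplicated(acc)])) {
      s <- unique(as.character(seqs[acc == a]))
      if (length(s) > 1) {
        stop("duplicate accession with differing sequence: ", a)
      }
    }
    keep <- !duplicated(acc)
    acc <- acc[keep]
    len <- len[keep]
  }
  stats::setNames(as.integer(len), acc)
}

#' Validate and pair a bait/control replicate design
#'
#' Checks the design is balanced (equal numbers of bait and control
#' replicates) and pairs bait and control samples by replicate index, the
#' pairing under which per-replicate IP/control spectral-count ratios are
#' computed.
#'
#' @param table a [spectral_count_table()].
#' @return A list with `n_pairs` and a tibble `pairs`
#'   (`replicate_index`, `bait_sample`, `control_sample`).
#' @export
validate_design <- function(table) {
  s <- table$samples
  bait <- s[s$condition == "bait", ]
  ctrl <- s[s$condition == "control", ]
  if (nrow(bait) == 0 || nrow(ctrl) == 0) {
    stop("design needs at least one bait and one control sample")
  }
  if (anyDuplicated(bait$replicate_index) ||
      anyDuplicated(ctrl$replicate_index)) {
    stop("duplicate replicate_index within a condition")
  }
  if (nrow(bait) != nrow(ctrl) ||
      !setequal(bait$replicate_index, ctrl$replicate_index)) {
    stop("unbalanced design: ", nrow(bait), " bait vs ",
         nrow(ctrl), " control replicates")
  }
  idx <- sort(bait$replicate_index)
  pairs <- tibble::tibble(
    replicate_index = idx,
    bait_sample = bait$sample_id[match(idx, bait$replicate_index)],
    control_sample = ctrl$sample_id[match(idx, ctrl$replicate_index)]
  )
  list(n_pairs = length(idx), pairs = pairs)
}
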