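#' Bait/control spectral-count ratio
#'
#' The per-replicate enrichment statistic: the ratio of a protein's spectral
#' count in the bait IP to its count in the paired negative-control IP.
#' With `pseudocount = 0` (default) the zero-control policy is: a protein
#' seen only in the bait IP has ratio `Inf` (it passes any finite
#' threshold), and a protein seen in neither has ratio 0. A pseudocount
#' `c > 0` switches to `(bait + c) / (control + c)`.
#'
#' @param bait_count,control_count non-negative integer vectors (recycled).
#' @param pseudocount non-negative real, default 0.
#' @return Numeric vector of ratios in `[0, Inf]`.
#' @export
spectral_ratio <- function(bait_count, control_count, pseudocount = 0) {
  if (any(bait_count < 0) || any(control_count < 0)) {
    stop("counts must be non-negative")
  }
  if (length(pseudocount) != 1 || is.na(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  if (pseudocount > 0) {
    return((bait_count + pseudocount) / (control_count + pseudocount))
  }
  ifelse(control_count > 0, bait_count / control_count,
         ifelse(bait_count > 0, Inf, 0))
}

ratio_cmp <- function(comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  if (comparator == ">=") `>=` else `>`
}

#' Classify a protein as strict / relaxed / non-interactor
#'
#' A replicate "passes" when its bait/control ratio meets the threshold AND
#' the bait IP of that replicate identified the protein with at least
#' `min_unique` unique peptides. A protein is a `strict` interactor when all
#' replicates pass, `relaxed` when exactly all-but-one pass, `none`
#' otherwise; the two sets are disjoint by construction.
#'
#' @param ratios numeric vector of per-replicate bait/control ratios.
#' @param unique_peptides integer vector of unique-peptide counts in the
#'   bait IP, one per replicate (same length as `ratios`).
#' @param threshold ratio threshold, default 5.
#' @param comparator `">="` (default, "at least 5") or `">"`.
#' @param min_unique minimum unique peptides per passing bait replicate,
#'   default 2.
#' @return `"strict"`, `"relaxed"` or `"none"`.
#' @export
classify_protein <- function(ratios, unique_peptides, threshold = 5,
                             comparator = ">=", min_unique = 2) {
  if (length(ratios) != length(unique_peptides)) {
    stop("ratios and unique_peptides must have the same length")
  }
  cmp <- ratio_cmp(comparator)
  pass <- cmp(ratios, threshold) & unique_peptides >= min_unique
  n <- length(pass)
  if (all(pass)) "strict"
  else if (sum(pass) == n - 1L && n >= 2L) "relaxed"
  else "none"
}

#' Normalized spectral abundance factor (NSAF), as percent
#'
#' Each protein's spectral count in one sample is normalized to its length
#' (residues) and expressed as a percentage of the sample total of
#' length-normalized counts; the vector sums to 100.
#'
#' @param counts non-negative spectral counts for one sample, one per
#'   protein; at least one must be positive.
#' @param lengths protein lengths in residues, all >= 1.
#' @return Numeric vector of NSAF percentages summing to 100.
#' @export
nsaf <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    stop("counts and lengths must have the same length")
  }
  if (any(lengths < 1)) stop("protein lengths must be >= 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  saf <- counts / lengths
  total <- sum(saf)
  if (total <= 0) stop("all-zero sample: NSAF undefined")
  100 * saf / total
}

#' Mean NSAF across replicates
#'
#' @param per_replicate_nsaf numeric vector of per-replicate NSAF
#'   percentages for one protein in one condition.
#' @return Arithmetic mean.
#' @export
mean_nsaf <- function(per_replicate_nsaf) {
  if (length(per_replicate_nsaf) == 0) stop("no replicates supplied")
  mean(per_replicate_nsaf)
}

#' Build the interactome table from counts and protein lengths
#'
#' Runs the full selection over a paired bait/control design: per-replicate
#' spectral-count ratios, the replicate-consistency + unique-peptide
#' classification into strict / relaxed / none, and mean NSAF in bait and
#' control.
#'
#' @param table a [spectral_count_table()] with a balanced design.
#' @param lengths named vector mapping every accession in `table` to its
#'   length in residues (see [read_protein_lengths()]).
#' @param threshold,comparator,min_unique,pseudocount see
#'   [classify_protein()] and [spectral_ratio()].
#' @return A tibble with one row per protein: `accession`, `gene_symbol`,
#'   `category`, one `ratio_r<i>` column per replicate pair, `n_pass`
#'   (replicates meeting the ratio threshold, before the peptide gate),
#'   `min_unique_peptides` (minimum across bait replicates),
#'   `nsaf_bait_pct` and `nsaf_control_pct`.
#' @export
build_interactome <- function(table, lengths, threshold = 5,
                              comparator = ">=", min_unique = 2,
                              pseudocount = 0) {
  design <- validate_design(table)
  acc <- table$proteins$accession
  miss <- setdiff(acc, names(lengths))
  if (length(miss)) {
    stop("no length for accession(s): ", paste(miss, collapse = ", "))
  }
  len <- lengths[acc]

  nsaf_mat <- apply(table$spc, 2, nsaf, lengths = len)
  bait_cols <- design$pairs$bait_sample
  ctrl_cols <- design$pairs$control_sample

  ratios <- mapply(function(b, c) {
    spectral_ratio(table$spc[, b], table$spc[, c], pseudocount)
  }, bait_cols, ctrl_cols)
  ratios <- matrix(ratios, nrow = length(acc),
                   dimnames = list(acc, NULL))
  up_bait <- table$unique_peptides[, bait_cols, drop = FALSE]

  cmp <- ratio_cmp(comparator)
  category <- character(length(acc))
  for (i in seq_along(acc)) {
    category[i] <- classify_protein(ratios[i, ], up_bait[i, ],
                                    threshold, comparator, min_unique)
  }

  out <- tibble::tibble(
    accession = acc,
    gene_symbol = table$proteins$gene_symbol,
    category = category,
    n_pass = as.integer(rowSums(cmp(ratios, threshold))),
    min_unique_peptides = as.integer(apply(up_bait, 1, min)),
    nsaf_bait_pct = rowMeans(nsaf_mat[, bait_cols, drop = FALSE]),
    nsaf_control_pct = rowMeans(nsaf_mat[, ctrl_cols, drop = FALSE])
  )
  rat <- as.data.frame(ratios)
  names(rat) <- paste0("ratio_r", design$pairs$replicate_index)
  tibble::as_tibble(cbind(out[, 1:3], rat, out[, -(1:3)]))
}

#' Rank interactome entries by mean bait NSAF
#'
#' Descending by `nsaf_bait_pct`; ties broken lexicographically by
#' accession. Adds a 1-based `rank` column.
#'
#' @param entries a tibble carrying `nsaf_bait_pct` and `accession` columns
#'   (e.g. from [build_interactome()] or [load_table1_fixture()]).
#' @return The reordered tibble with a `rank` column prepended.
#' @export
rank_by_nsaf <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) {
    return(tibble::add_column(entries, rank = integer(0), .before = 1))
  }
  ord <- order(-entries$nsaf_bait_pct, entries$accession)
  out <- entries[ord, ]
  tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1)
}
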