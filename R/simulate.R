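#' Configuration of the synthetic AP-MS generator
#'
#' Defaults emulate a triplicate bait-vs-control IP experiment: a universe
#' of 400 background proteins with log-normally distributed baseline
#' abundance around an expected control spectral count of 10, overdispersed
#' (gamma-Poisson) counts, and 20 planted true interactors enriched 20-fold
#' in the bait IP. A bait-protein row (the purified protein itself) is
#' always added with high bait-only counts.
#'
#' @param n_proteins number of background (prey-universe) proteins.
#' @param n_true number of planted true interactors (`<= n_proteins`).
#' @param fold bait enrichment of true interactors, `>= 1`.
#' @param base_mean expected (median) control spectral count.
#' @param dispersion gamma-Poisson overdispersion; counts are negative
#'   binomial with `size = 1/dispersion` (variance `mu + dispersion*mu^2`).
#' @param n_replicates replicates per condition.
#' @param peptide_ratio expected unique peptides per spectrum, in `(0, 1]`.
#' @param baseline_sdlog log-scale SD of the protein-specific baseline.
#' @param bait_fold bait-row spectral counts relative to `base_mean`.
#' @param seed integer RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 400, n_true = 20, fold = 20,
                              base_mean = 10, dispersion = 0.05,
                              n_replicates = 3, peptide_ratio = 0.3,
                              baseline_sdlog = 1, bait_fold = 50,
                              seed = 1) {
  stopifnot(n_proteins >= 1, n_true >= 0, n_true <= n_proteins,
            fold >= 1, base_mean > 0, dispersion > 0, n_replicates >= 1,
            peptide_ratio > 0, peptide_ratio <= 1, baseline_sdlog >= 0,
            bait_fold > 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_true = as.integer(n_true), fold = fold,
                 base_mean = base_mean, dispersion = dispersion,
                 n_replicates = as.integer(n_replicates),
                 peptide_ratio = peptide_ratio,
                 baseline_sdlog = baseline_sdlog, bait_fold = bait_fold,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate an AP-MS spectral-count experiment with planted interactors
#'
#' Control counts are gamma-mixed Poisson (negative binomial) around a
#' protein-specific log-normal baseline; bait counts use the same baseline
#' times `fold` for the planted true interactors. Unique-peptide counts are
#' a binomial thinning of the spectral counts, floored at 1 whenever the
#' spectral count is positive. Protein lengths are uniform on 100-1500
#' residues. The bait-protein row `BAIT` gets high bait-only counts and zero
#' control counts. Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return List with `table` (a [spectral_count_table()]), `truth`
#'   (class `simulation_truth`: `true_interactors`, `bait_accession`,
#'   `config`) and `lengths` (named vector, NSAF denominators).
#' @export
simulate_apms <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must come from simulation_config()")
  }
  set.seed(config$seed)
  n <- config$n_proteins
  k <- config$n_replicates
  acc <- sprintf("PROT%04d", seq_len(n))
  true_acc <- sort(sample(acc, config$n_true))
  size <- 1 / config$dispersion

  baseline <- stats::rlnorm(n, meanlog = log(config$base_mean),
                            sdlog = config$baseline_sdlog)
  mu_bait <- baseline * ifelse(acc %in% true_acc, config$fold, 1)

  ctrl <- matrix(stats::rnbinom(n * k, mu = rep(baseline, k), size = size),
                 nrow = n)
  bait <- matrix(stats::rnbinom(n * k, mu = rep(mu_bait, k), size = size),
                 nrow = n)

  bait_ctrl <- rep(0L, k)
  bait_bait <- stats::rnbinom(k, mu = config$bait_fold * config$base_mean,
                              size = size)
  spc <- rbind(cbind(bait, ctrl),
               c(bait_bait, bait_ctrl))
  acc_all <- c(acc, "BAIT")

  up <- matrix(0L, nrow(spc), ncol(spc))
  pos <- spc > 0
  up[pos] <- pmin(spc[pos],
                  pmax(1L, stats::rbinom(sum(pos), spc[pos],
                                         config$peptide_ratio)))

  samples <- tibble::tibble(
    sample_id = c(paste0("bait_", seq_len(k)), paste0("ctrl_", seq_len(k))),
    condition = rep(c("bait", "control"), each = k),
    replicate_index = rep(seq_len(k), 2)
  )
  proteins <- tibble::tibble(accession = acc_all, gene_symbol = acc_all)
  lengths <- stats::setNames(sample(100:1500, n + 1, replace = TRUE),
                             acc_all)
  table <- spectral_count_table(proteins, samples, spc, up)
  truth <- structure(list(true_interactors = true_acc,
                          bait_accession = "BAIT", config = config),
                     class = "simulation_truth")
  list(table = table, truth = truth, lengths = lengths)
}

#' Evaluate recovery of planted interactors
#'
#' Compares the strict set called by [build_interactome()] against the
#' planted truth. The bait-protein row is excluded from both sides: it is
#' the purified protein, not a prey.
#'
#' @param entries interactome tibble from [build_interactome()].
#' @param truth `simulation_truth` from [simulate_apms()].
#' @return List with `sensitivity` (recall of planted interactors),
#'   `specificity` (true-negative rate over non-planted preys) and `fdr`
#'   (fraction of the strict set that is not planted; 0 when the strict set
#'   is empty).
#' @export
evaluate_recovery <- function(entries, truth) {
  if (!inherits(truth, "simulation_truth")) {
    stop("truth must come from simulate_apms()")
  }
  if (length(truth$true_interactors) == 0) {
    stop("empty truth set: sensitivity undefined")
  }
  prey <- setdiff(entries$accession, truth$bait_accession)
  strict <- intersect(entries$accession[entries$category == "strict"], prey)
  truth_set <- truth$true_interactors
  tp <- length(intersect(strict, truth_set))
  fp <- length(setdiff(strict, truth_set))
  neg <- setdiff(prey, truth_set)
  list(
    sensitivity = tp / length(truth_set),
    specificity = if (length(neg)) 1 - fp / length(neg) else NA_real_,
    fdr = fp / max(length(strict), 1)
  )
}

#' Simulate paired two-channel ROI intensities with known correlation
#'
#' Each ROI draws `pixels` paired intensities from a bivariate Gaussian with
#' population correlation `true_r`, shifted to a positive intensity scale
#' (mean 100, SD 15) and clamped at 0.
#'
#' @param n_roi number of ROIs.
#' @param pixels pixels per ROI (>= 3).
#' @param true_r population correlation in `[-1, 1]`.
#' @param seed integer RNG seed.
#' @param condition label stored on every ROI.
#' @return List of [roi_measurement()] objects.
#' @export
simulate_coloc <- function(n_roi, pixels, true_r, seed, condition = "sim") {
  if (abs(true_r) > 1) stop("true_r must be in [-1, 1]")
  if (pixels < 3) stop("need at least 3 pixels per ROI")
  set.seed(seed)
  lapply(seq_len(n_roi), function(i) {
    z1 <- stats::rnorm(pixels)
    z2 <- true_r * z1 + sqrt(1 - true_r^2) * stats::rnorm(pixels)
    roi_measurement(sprintf("roi_%03d", i), condition,
                    pmax(100 + 15 * z1, 0), pmax(100 + 15 * z2, 0))
  })
}
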