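# Independent brute-force oracles used to cross-check the implementation.

# Re-evaluation of the selection rule text for one protein: per replicate,
# the bait/control ratio (zero-control -> Inf when bait seen, else 0) must
# meet the threshold and the bait IP must carry >= min_unique peptides;
# strict = all replicates, relaxed = exactly all-but-one.
oracle_classify <- function(bait, ctrl, up, threshold = 5,
                            comparator = ">=", min_unique = 2) {
  k <- length(bait)
  pass <- logical(k)
  for (r in seq_len(k)) {
    ratio <- if (ctrl[r] > 0) {
      bait[r] / ctrl[r]
    } else if (bait[r] > 0) Inf else 0
    ok <- if (comparator == ">=") ratio >= threshold else ratio > threshold
    pass[r] <- ok && up[r] >= min_unique
  }
  np <- sum(pass)
  if (np == k) "strict" else if (np == k - 1) "relaxed" else "none"
}

# Sliding-pattern motif oracle: tries every start position of the literal
# 6-mer (mode I) / 7-mer (mode II) consensus instead of anchoring on the
# phosphosite.
oracle_motif_scan <- function(sequence, positions) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  rows <- list()
  for (start in seq_len(n)) {
    if (start + 5 <= n) {
      w <- chars[start:(start + 5)]
      p <- start + 3
      if (w[1] == "R" && w[2] == "S" && w[4] %in% c("S", "T") &&
          w[6] == "P" && p %in% positions) {
        rows[[length(rows) + 1]] <- data.frame(motif_id = "modeI",
                                               site_position = p)
      }
    }
    if (start + 6 <= n) {
      w <- chars[start:(start + 6)]
      p <- start + 4
      if (w[1] == "R" && w[5] %in% c("S", "T") && w[7] == "P" &&
          p %in% positions) {
        rows[[length(rows) + 1]] <- data.frame(motif_id = "modeII",
                                               site_position = p)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(motif_id = character(0), site_position = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$site_position, out$motif_id), , drop = FALSE]
}

# Exact two-sided Mann-Whitney p by enumeration over group relabelings,
# with U computed by pair counting on the raw values (not ranks).
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  mid <- na * (n - na) / 2
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
}

# Monte-Carlo estimate of the filter's expected strict-set size under the
# null (no enrichment): independent re-implementation of the generative
# model (gamma-mixed Poisson via rgamma + rpois) and of the rule text.
oracle_null_strict_mean <- function(config, n_rep, seed) {
  set.seed(seed)
  n <- config$n_proteins
  k <- config$n_replicates
  size <- 1 / config$dispersion
  draw <- function(lam) {
    rate <- matrix(rgamma(n * k, shape = size, scale = rep(lam, k) / size),
                   nrow = n)
    matrix(rpois(n * k, rate), nrow = n)
  }
  thin <- function(m) {
    u <- m
    sel <- m > 0
    u[sel] <- pmin(m[sel], pmax(1L, rbinom(sum(sel), m[sel],
                                           config$peptide_ratio)))
    u
  }
  vapply(seq_len(n_rep), function(it) {
    lam <- exp(rnorm(n, log(config$base_mean), config$baseline_sdlog))
    ctrl <- draw(lam)
    bait <- draw(lam)  # fold = 1: exchangeable with control
    up <- thin(bait)
    ratio <- ifelse(ctrl > 0, bait / ctrl, ifelse(bait > 0, Inf, 0))
    pass <- ratio >= 5 & up >= 2
    sum(rowSums(pass) == k)
  }, numeric(1))
}

# Tiny random count tables for property tests.
random_count_table <- function(n_prot, n_rep = 3, seed = 1,
                               lambda_ctrl = 4, lambda_bait = 8) {
  set.seed(seed)
  acc <- sprintf("P%02d", seq_len(n_prot))
  samples <- tibble::tibble(
    sample_id = c(paste0("b", seq_len(n_rep)), paste0("c", seq_len(n_rep))),
    condition = rep(c("bait", "control"), each = n_rep),
    replicate_index = rep(seq_len(n_rep), 2)
  )
  spc <- cbind(matrix(rpois(n_prot * n_rep, lambda_bait), n_prot),
               matrix(rpois(n_prot * n_rep, lambda_ctrl), n_prot))
  # keep every sample column non-degenerate for NSAF
  spc[1, spc[1, ] == 0] <- 1L
  up <- matrix(0L, n_prot, 2 * n_rep)
  sel <- spc > 0
  up[sel] <- pmin(spc[sel], 1L + rbinom(sum(sel), spc[sel] - 1L, 0.5))
  tab <- spectral_count_table(tibble::tibble(accession = acc),
                              samples, spc, up)
  lengths <- stats::setNames(sample(100:900, n_prot), acc)
  list(table = tab, lengths = lengths)
}

# Poly-alanine FASTA matching a named length vector (NSAF only needs L).
fasta_from_lengths <- function(lengths, path) {
  lines <- unlist(lapply(names(lengths), function(a) {
    c(paste0(">", a), paste(rep("A", lengths[[a]]), collapse = ""))
  }))
  writeLines(lines, path)
  path
}
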