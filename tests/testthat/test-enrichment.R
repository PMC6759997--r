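test_that("spectral ratios follow the zero-control and pseudocount policy", {
  expect_identical(spectral_ratio(10, 2), 5)
  expect_identical(spectral_ratio(7, 0), Inf)
  expect_identical(spectral_ratio(0, 0), 0)
  expect_identical(spectral_ratio(7, 0, pseudocount = 1), 8)
  expect_equal(spectral_ratio(c(10, 7, 0), c(2, 0, 0)), c(5, Inf, 0))
  expect_error(spectral_ratio(-1, 2), "non-negative")
  expect_error(spectral_ratio(1, 2, pseudocount = -1), "non-negative")
})

test_that("classification follows the replicate-consistency rule table", {
  expect_identical(classify_protein(c(10, 8, 12), c(3, 3, 2)), "strict")
  expect_identical(classify_protein(c(10, 8, 2), c(3, 3, 3)), "relaxed")
  expect_identical(classify_protein(c(10, 2, 2), c(3, 3, 3)), "none")
  expect_identical(classify_protein(c(Inf, 6, 7), c(2, 2, 2)), "strict")
  # peptide gate demotes a ratio-passing replicate
  expect_identical(classify_protein(c(10, 8, 12), c(3, 3, 1)), "relaxed")
  expect_identical(classify_protein(c(10, 8, 12), c(1, 1, 3)), "none")
  # boundary: comparator choice at exactly the threshold
  expect_identical(classify_protein(c(5, 5, 5), c(2, 2, 2)), "strict")
  expect_identical(classify_protein(c(5, 5, 5), c(2, 2, 2),
                                    comparator = ">"), "none")
  expect_error(classify_protein(c(1, 2), c(1, 2, 3)), "same length")
})

test_that("NSAF matches hand-computed values and is a percent composition", {
  expect_equal(nsaf(c(10, 5), c(100, 50)), c(50, 50))
  expect_equal(nsaf(c(10, 10), c(100, 50)), c(100 / 3, 200 / 3))
  expect_equal(nsaf(c(7, 0), c(123, 456)), c(100, 0))
  expect_error(nsaf(c(0, 0), c(10, 10)), "all-zero")
  expect_error(nsaf(c(1, 2), c(0, 10)), ">= 1")

  expect_equal(mean_nsaf(c(2, 3, 4)), 3)
  expect_equal(mean_nsaf(1.5), 1.5)
  expect_error(mean_nsaf(numeric(0)), "no replicates")

  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    counts <- rpois(n, 5)
    counts[sample(n, 1)] <- counts[sample(n, 1)] + 1L  # ensure nonzero
    lens <- sample(50:2000, n)
    v <- nsaf(counts, lens)
    expect_equal(sum(v), 100, tolerance = 1e-12)
    expect_true(all(v >= 0))
    # scale invariance: multiplying the sample by a positive integer
    expect_equal(nsaf(counts * sample(2:9, 1), lens), v)
  }
})

test_that("build_interactome recovers planted fixtures", {
  # one 10-fold protein among flat background
  samples <- tibble::tibble(
    sample_id = c("b1", "b2", "b3", "c1", "c2", "c3"),
    condition = rep(c("bait", "control"), each = 3),
    replicate_index = rep(1:3, 2))
  prot <- tibble::tibble(accession = c("HIT", "P1", "P2"))
  spc <- rbind(c(50, 50, 50, 5, 5, 5),
               c(10, 10, 10, 10, 10, 10),
               c(8, 8, 8, 9, 9, 9))
  up <- matrix(3L, 3, 6)
  tab <- spectral_count_table(prot, samples, spc, up)
  lens <- c(HIT = 300L, P1 = 400L, P2 = 500L)
  ent <- build_interactome(tab, lens)
  expect_identical(ent$category, c("strict", "none", "none"))
  expect_equal(ent$ratio_r1, c(10, 1, 8 / 9))

  # identical bait and control matrices: ratio 1 everywhere
  spc2 <- cbind(spc[, 4:6], spc[, 4:6])
  tab2 <- spectral_count_table(prot, samples, spc2, up)
  ent2 <- build_interactome(tab2, lens)
  expect_true(all(ent2$category == "none"))

  # passing in exactly 2 of 3 replicates -> relaxed
  spc3 <- spc
  spc3[1, 3] <- 10  # ratio 2 in replicate 3
  tab3 <- spectral_count_table(prot, samples, spc3, up)
  expect_identical(build_interactome(tab3, lens)$category[1], "relaxed")
})

test_that("category assignment matches the brute-force rule oracle", {
  for (seed in 1:30) {
    rt <- random_count_table(sample(2:6, 1), seed = seed)
    d <- validate_design(rt$table)
    ent <- build_interactome(rt$table, rt$lengths)
    for (i in seq_along(ent$accession)) {
      acc <- ent$accession[i]
      expected <- oracle_classify(
        rt$table$spc[acc, d$pairs$bait_sample],
        rt$table$spc[acc, d$pairs$control_sample],
        rt$table$unique_peptides[acc, d$pairs$bait_sample])
      expect_identical(ent$category[i], expected)
    }
  }
})

test_that("raising the ratio threshold never grows the strict set", {
  for (seed in 1:10) {
    rt <- random_count_table(12, seed = seed, lambda_bait = 20)
    prev_strict <- NULL
    for (thr in c(2, 5, 8, 20)) {
      ent <- build_interactome(rt$table, rt$lengths, threshold = thr)
      strict <- ent$accession[ent$category == "strict"]
      either <- ent$accession[ent$category %in% c("strict", "relaxed")]
      expect_length(intersect(strict, either), length(strict))
      if (!is.null(prev_strict)) {
        expect_true(all(strict %in% prev_strict))
      }
      prev_strict <- strict
    }
  }
})

test_that("NSAF ranking reproduces the published table order", {
  t1 <- load_table1_fixture()
  tpe <- rank_by_nsaf(t1[t1$fraction == "TPE", ])
  ne <- rank_by_nsaf(t1[t1$fraction == "NE", ])
  expect_identical(tpe$gene_symbol[1], "YWHAE")
  expect_equal(tpe$nsaf_bait_pct[1], 2.64)
  expect_identical(ne$gene_symbol[1], "VIM")
  expect_equal(ne$nsaf_bait_pct[1], 1.11)
  expect_true(all(diff(tpe$nsaf_bait_pct) <= 0))
  expect_identical(tpe$rank, 1:22)

  empty <- rank_by_nsaf(tibble::tibble(accession = character(0),
                                       nsaf_bait_pct = numeric(0)))
  expect_identical(nrow(empty), 0L)

  # ties break lexicographically by accession
  tied <- tibble::tibble(accession = c("B", "A"), nsaf_bait_pct = c(1, 1))
  expect_identical(rank_by_nsaf(tied)$accession, c("A", "B"))
})
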