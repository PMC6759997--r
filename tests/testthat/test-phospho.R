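test_that("phosphosite windows parse to offset and residue", {
  expect_identical(parse_window("MMRQAtMDFSTPS"), list(offset = 6L, residue = "T"))
  expect_identical(parse_window("TQsLPPITLGNNFLTASHR"), list(offset = 3L, residue = "S"))
  expect_error(parse_window("ABCDEF"), "no lowercase")
  expect_error(parse_window("AbCdEF"), "multiple lowercase")
  expect_error(parse_window("AAmAA"), "must be S, T or Y")
  expect_error(parse_window(""), "non-empty")
})

test_that("parsing then re-annotating reproduces the window", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:50) {
    n <- sample(7:21, 1)
    w <- sample(aa, n, replace = TRUE)
    k <- sample(n, 1)
    w[k] <- sample(c("s", "t", "y"), 1)
    win <- paste(w, collapse = "")
    p <- parse_window(win)
    rebuilt <- strsplit(toupper(win), "")[[1]]
    rebuilt[p$offset] <- tolower(p$residue)
    expect_identical(paste(rebuilt, collapse = ""), win)
  }
})

test_that("window-overlap alignment reproduces published site positions", {
  # N-terminally truncated anchor pinned at protein position 1
  expect_identical(infer_position("MMRQAtMDFSTPS", 6, "QATMDFStPSVFDQQ"), 11L)
  # mouse neighbor pair around the C-terminal phosphosite cluster
  expect_identical(infer_position("MAQRSQKsRSEQDLL", 473, "QRSQKSRsEQDLLNN"), 475L)
  expect_error(infer_position("MMRQAtMDFSTPS", 6, "WWWWWyWWWWW"),
               "no exact overlap")
  # a homopolymeric context admits many placements
  expect_error(
    infer_position(paste0("t", strrep("A", 15)), 1,
                   paste0(strrep("A", 15), "s")),
    "ambiguous")
})

test_that("position inference is symmetric between anchor and query", {
  pairs <- list(
    list(a = "MMRQAtMDFSTPS", pa = 6L, q = "QATMDFStPSVFDQQ", pq = 11L),
    list(a = "MAQRSQKsRSEQDLL", pa = 473L, q = "QRSQKSRsEQDLLNN", pq = 475L))
  for (p in pairs) {
    expect_identical(infer_position(p$a, p$pa, p$q), p$pq)
    expect_identical(infer_position(p$q, p$pq, p$a), p$pa)
  }
})

test_that("distinct-site counting respects the species filter", {
  t2 <- load_table2_fixture()
  expect_identical(nrow(t2), 6L)
  expect_identical(count_sites(t2, "Human"), 5L)
  expect_identical(count_sites(t2), 6L)
  expect_identical(count_sites(t2, "Mouse"), 2L)
  expect_identical(count_sites(t2[0, ]), 0L)
  expect_setequal(t2$declared_position, c(6L, 11L, 189L, 436L, 473L, 475L))
})

test_that("14-3-3 motif scanning matches the constructed examples", {
  h1 <- scan_14_3_3_motifs("AARSASAPAA", 6)
  expect_identical(h1$motif_id, "modeI")
  expect_identical(h1$matched_span, "RSASAP")
  h2 <- scan_14_3_3_motifs("ARAAASAPAA", 6)
  expect_identical(h2$motif_id, "modeII")
  expect_identical(h2$matched_span, "RAAASAP")
  expect_identical(nrow(scan_14_3_3_motifs("AAAASAAAAA", 5)), 0L)
  # both modes at once: R at p-4 and p-3, S at p-2, P at p+2
  h3 <- scan_14_3_3_motifs("RRSATAPAA", 5)
  expect_setequal(h3$motif_id, c("modeI", "modeII"))
  # too close to a terminus for either pattern
  expect_identical(nrow(scan_14_3_3_motifs("SRP", 1)), 0L)
  expect_error(scan_14_3_3_motifs("AARSASAPAA", 20), "out of")
  expect_error(scan_14_3_3_motifs("AARSASAPAA", 1), "not S/T")
})

test_that("motif scan agrees with a sliding-pattern oracle", {
  set.seed(14)
  alphabet <- c(strsplit("ACDEFGHIKLMNQVWY", "")[[1]],
                rep(c("R", "S", "T", "P"), 4))  # enrich motif letters
  for (i in 1:200) {
    n <- sample(10:200, 1)
    seqv <- sample(alphabet, n, replace = TRUE)
    sq <- paste(seqv, collapse = "")
    st <- which(seqv %in% c("S", "T"))
    if (!length(st)) next
    k <- min(length(st), sample(1:6, 1))
    pos <- sort(st[sample.int(length(st), k)])
    got <- scan_14_3_3_motifs(sq, pos)
    got <- got[order(got$site_position, got$motif_id), ]
    want <- oracle_motif_scan(sq, pos)
    expect_identical(as.integer(got$site_position),
                     as.integer(want$site_position))
    expect_identical(as.character(got$motif_id),
                     as.character(want$motif_id))
  }
})

test_that("phosphosite tables reject inconsistent annotation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tpeptide\tspecies\tsource",
               "S10\tAAAtAAA\tHuman\tdb"), path)
  expect_error(read_phospho_table(path), "does not match")
  writeLines(c("position\tpeptide\tspecies\tsource",
               "T4\tAAAtAAA\tHuman\tdb"), path)
  tab <- read_phospho_table(path)
  expect_identical(tab$declared_position, 4L)
  expect_identical(tab$residue, "T")
})
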