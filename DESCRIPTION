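Package: apmstools
Title: Spectral-Count Scoring of AP-MS Interactomes, Phosphosite Windows,
    and ROI Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for affinity-purification mass-spectrometry (AP-MS)
    interactome analysis from protein-level spectral-count tables:
    bait-versus-control spectral-count ratio filtering with replicate
    consistency and a unique-peptide gate, NSAF (normalized spectral
    abundance factor) quantitation and ranking, parsing of phosphosite
    sequence windows with inference of absolute site positions by window
    overlap, scanning for 14-3-3 mode I/II binding motifs, and per-ROI
    Pearson colocalization quantification with exact Mann-Whitney group
    comparison. Includes a seeded synthetic AP-MS data generator with
    planted interactors for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
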