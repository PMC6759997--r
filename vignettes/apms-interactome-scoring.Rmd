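---
title: "Scoring AP-MS interactomes from spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring AP-MS interactomes from spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmstools)
```

## The problem and the model

In affinity-purification mass spectrometry (AP-MS), a tagged bait protein
is immunoprecipitated and the co-purifying proteins are identified by
tandem MS. Every pull-down also recovers background: sticky or highly
abundant proteins that bind the resin or the tag. The standard desk-scale
defence, implemented here, compares the bait IP against a mock (negative
control) IP run in parallel replicates, using **spectral counts** — the
number of MS/MS spectra matched to a protein in one run — as the abundance
proxy.

For protein $i$ and replicate $r$, the enrichment statistic is the ratio

$$\rho_{ir} = \frac{\mathrm{SpC}^{\mathrm{bait}}_{ir}}{\mathrm{SpC}^{\mathrm{ctrl}}_{ir}},$$

with the zero-control convention $\rho = \infty$ when the protein is seen
only in the bait IP (a protein absent from every control must remain
selectable; most published high-confidence partners have control NSAF
0.00) and $\rho = 0$ when it is seen in neither. An optional pseudocount
$c$ switches to $(\mathrm{SpC}^{\mathrm{bait}} + c)/(\mathrm{SpC}^{\mathrm{ctrl}} + c)$;
it defaults to 0 so that the infinity convention, not shrinkage, governs
control-absent proteins.

A replicate **passes** for protein $i$ when $\rho_{ir} \ge 5$ *and* the
bait IP of that replicate identified the protein with at least 2 unique
peptides. A protein is a **strict** interactor when all replicates pass,
**relaxed** when exactly all-but-one pass, and background otherwise. The
two categories are disjoint by construction, and the strict set can only
shrink as the threshold rises.

Two choices here were genuinely open:

* *Comparator.* The selection rule is phrased both as "ratio > 5" and as
  "at least 5" in its sources. We default to `>=` (the inclusive reading)
  and expose `comparator = ">"` in every scoring function, so either
  convention is one argument away. Integer-count ratios rarely land
  exactly on 5, so the two comparators differ only on boundary cases.
* *Peptide gate granularity.* Whether the two-unique-peptide requirement
  applies per replicate or to the pooled identification is unstated in
  the rule's sources. We apply it per replicate, folded into the same
  per-replicate pass indicator as the ratio. This is the stricter reading,
  keeps strict/relaxed disjoint, and makes the classification a function
  of per-replicate evidence only.

Relative abundance within a sample is quantified by the **normalized
spectral abundance factor** (NSAF), expressed as a percent:

$$\mathrm{NSAF}_i = 100 \times \frac{\mathrm{SpC}_i / L_i}{\sum_j \mathrm{SpC}_j / L_j},$$

where $L_i$ is the protein length in residues (longer proteins yield more
tryptic peptides, hence more spectra, at equal molarity). Each sample's
NSAF vector sums to 100 and is invariant to rescaling all counts in that
sample; interactors are reported ranked by mean bait NSAF, with ties broken
lexicographically by accession (the ranking's sources do not specify a
tie rule).

```{r score}
sim <- simulate_apms(simulation_config(seed = 1))
entries <- build_interactome(sim$table, sim$lengths)
head(rank_by_nsaf(entries), 4)
evaluate_recovery(entries, sim$truth)
```

## Phosphosite windows and 14-3-3 motifs

Phosphosite annotations are exchanged as short sequence windows with the
phosphorylated residue in lowercase (`"QATMDFStPSVFDQQ"`). Databases mix
two window conventions: centered ±7-residue windows, truncated at the
protein termini, and tryptic peptides. `parse_window()` accepts any
single-lowercase peptide; `infer_position()` converts window-local to
absolute protein coordinates by anchoring on a neighboring window whose
site position is known, requiring a *unique* exact overlap of at least 8
residues (shorter overlaps are too often spurious in 15-mers; ambiguous
placements are refused rather than guessed). The anchor's window start is
`declared_position - offset + 1`, which automatically pins an N-terminally
truncated window at position 1.

```{r windows}
infer_position("MMRQAtMDFSTPS", 6, "QATMDFStPSVFDQQ")
infer_position("MAQRSQKsRSEQDLL", 473, "QRSQKSRsEQDLLNN")
count_sites(load_table2_fixture(), species_filter = "Human")
```

14-3-3 proteins bind phosphoserine/threonine ligands through two literal
consensus contexts, scanned by `scan_14_3_3_motifs()` around supplied
phosphosites: mode I `R-S-X-pS/pT-X-P` and mode II `R-X-X-X-pS/pT-X-P`.
Only these literal patterns are implemented; machine-learned 14-3-3 site
predictors are external tools and out of scope. A site may match both
modes, and a site too close to a terminus for a pattern cannot match it.

One packaged annotation row deserves a note: the S475 site was first
described in mouse, but the packaged table records it as established in
both species (`"Mouse;Human"`) because the phosphopeptide data behind
these tools detected it in human extracts. Counting human sites therefore
yields five distinct positions and counting without a species filter six.

## ROI colocalization

Colocalization of two fluorescence channels is quantified per region of
interest (one ROI = one cell, typically $n = 10$ per condition) as the
Pearson correlation of paired pixel intensities after scalar background
subtraction (`max(I - b, 0)`). The background scalar is caller-supplied
or estimated as a low percentile of the image (default 5th); how the
background was extracted is not specified by the procedure this follows,
so it is a parameter, not a fixed rule. Whether correlation should be
computed on all ROI pixels or only above-threshold pixels is likewise
unspecified; we use all pixels and treat any masking as the caller's
responsibility.

Conditions are compared with a two-sided Mann–Whitney test. With 10 ROIs
per condition the sample is deep inside the exact regime, so for groups of
up to 12 the exact null distribution is used — via the rank-sum
distribution when there are no ties and by complete enumeration of group
assignments when there are (enumeration capped at 5×10^5 combinations);
larger groups fall back to the normal approximation with continuity and
tie corrections. Stars follow the convention `****` ≤ 1e-4, `***` ≤ 1e-3,
`**` ≤ 0.01, `*` ≤ 0.05, `ns` otherwise.

```{r coloc}
rois_a <- simulate_coloc(10, 400, 0.8, seed = 2, condition = "transfected")
rois_b <- simulate_coloc(10, 400, 0.2, seed = 3, condition = "untransfected")
compare_conditions(vapply(rois_a, pearson_roi, numeric(1)),
                   vapply(rois_b, pearson_roi, numeric(1)))
```

## What the synthetic generator emulates — and what it does not

`simulate_apms()` generates the triplicate bait-vs-control design the
scoring stage expects:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 400 | prey-universe size |
| `n_true` | 20 | planted true interactors |
| `fold` | 20 | bait enrichment of true interactors |
| `base_mean` | 10 | median control spectral count |
| `dispersion` | 0.05 | gamma-Poisson overdispersion (`size = 1/dispersion`) |
| `n_replicates` | 3 | replicates per condition |
| `peptide_ratio` | 0.3 | expected unique peptides per spectrum |
| `baseline_sdlog` | 1 | log-SD of protein-specific baseline abundance |
| `bait_fold` | 50 | bait-row counts relative to `base_mean` |

Protein-specific baselines are log-normal (spectral counts span orders of
magnitude across a pull-down), counts are gamma-mixed Poisson rather than
pure Poisson because IP replicates are overdispersed and the filter must
be exercised under the harder model, and unique-peptide counts are a
binomial thinning of spectral counts floored at 1 — identified proteins
have at least one peptide. A bait-protein row with high bait-only counts
mimics the bait band itself and must always be called strict. Lengths are
uniform on 100–1500 residues.

The generator does **not** emulate shared-peptide ambiguity, protein
inference, run-to-run identification dropout beyond count sampling,
contaminant structure (keratins, resin-binders are just background rows),
or any dependency between abundance and identifiability. Passing recovery
tests therefore show the *filter arithmetic* is right under a realistic
count model — not that the thresholds are optimal for any particular
instrument or search pipeline.

At the defaults the strict filter recovers ≥ 90% of planted interactors
with empirical FDR ≤ 10% (averaged over 20 seeds), and at `fold = 1` the
strict set is consistent with an independent Monte-Carlo estimate of the
filter's null false-positive expectation. Those problem sizes (400
proteins × 6 samples, 20 seeds) keep the whole validation suite under a
minute while leaving the binomial noise on recovery rates well below the
margins being tested.

## Numerical and degenerate-input choices

* NSAF requires at least one nonzero count per sample; an all-zero sample
  is an error, not a silent zero vector.
* Missing cells in count tables are zeros by definition (a protein not
  identified in a sample has no spectra); negative or fractional counts
  are rejected at ingest.
* Unique-peptide tables are optional at ingest; when absent, unique
  peptides default to the spectral counts (an upper bound — each spectrum
  matches at most one distinct peptide), which weakens the peptide gate to
  a spectral-count floor and is flagged in the function documentation.
* Pearson r is undefined on a constant channel (as after subtracting a
  background at or above the whole signal); this errors rather than
  returning `NA`.
* `infer_position()` refuses peptides it cannot place uniquely — tryptic
  peptides with no 8-residue overlap with an anchored window simply cannot
  be localized without the full sequence.
* Replicates are paired bait↔control by replicate index; an unbalanced
  design is an error because the per-replicate ratio is undefined.

## Limitations

The scoring stage starts at protein-level count tables: database search,
FDR control at the peptide level, and protein inference are upstream and
out of scope, as are probabilistic interaction scorers (SAINT, CompPASS),
pathway enrichment, and interaction-database cross-referencing. Published
headline interactome sizes depend on reprocessing deposited raw spectra
against a specific database version and are not reproducible from printed
tables; the packaged fixtures carry the published NSAF-ranked top lists
instead, and the package's correctness claims rest on the worked examples
and the property suite exercised in `tests/`.
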