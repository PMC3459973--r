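---
title: "Calling allele-specific protein binding from SILAC label-swap pull-downs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling allele-specific protein binding from SILAC label-swap pull-downs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppull)
```

## The experimental design this package models

Most disease-associated SNPs fall in non-coding DNA, where a plausible
mechanism is that the nucleotide exchange strengthens or destroys a
transcription-factor binding site. A quantitative DNA-bait pull-down screen
tests this directly: roughly 50-bp synthetic duplexes carrying either allele
of a SNP are immobilised and incubated with nuclear extract, and bound
proteins are read out by quantitative mass spectrometry. Because the two
extracts are SILAC-labelled (one grown on heavy arginine/lysine, one on
light), the two allele pull-downs can be pooled and every peptide reports a
heavy/light (H/L) ratio.

Each SNP is screened twice with swapped labels:

* **forward** — heavy extract on the allele-1 bait, light on allele 2;
* **reverse** — the labels switched.

This label swap is the screen's central control. A genuine allele-specific
binder inverts its H/L ratio between the two orientations; the mass of
nonspecific DNA- and bead-binders sits at a ratio of 1 in both; and
unlabelled contaminants (keratins and other environmental protein) are
light-only, hence **below 1 in both orientations** — they violate the
inversion symmetry and can be recognised as such. Plotting each protein's
forward ratio against its reverse ratio yields the two-dimensional
interaction plot: allele-1 binders in one off-diagonal quadrant, allele-2
binders in the opposite one, contaminants in the lower-left, background at
the origin.

Each orientation is a pair of physical pull-downs (one bait per extract),
so a panel of 12 SNPs costs 4 × 12 = 48 pull-downs; `pulldown_plan()`
enumerates them.

## From peptide evidence to protein log-ratios

`aggregate_evidence()` turns a peptide-level evidence table into protein
quantifications:

* a protein is retained only with **≥ 2 quantitation events and ≥ 1 unique
  peptide** in the experiment — single-event identifications are too
  unstable to test;
* the protein H/L log2 ratio is the **median** of its peptide log2 ratios
  (even counts: mean of the central pair), robust against a single aberrant
  peptide;
* the *oriented* log-ratio re-expresses H/L on the fixed allele1/allele2
  scale (negated in reverse experiments), so the two orientations of a pair
  can be compared directly.

Ratios are handled in log2 throughout — SILAC ratios are ratio-scale
quantities and only symmetric in log space — and reported fold changes are
`2^|log2 ratio|`.

`normalize_quants()` median-centres the oriented log-ratios of each
experiment (default on, minimum 20 proteins). The extracts are mixed 1:1
and the large majority of proteins bind both baits equally, so the bulk
median estimates the mixing offset. The raw H/L column is deliberately left
uncentred: the contaminant signature is defined on raw ratios.

## The outlier statistic and its calibration

With hundreds to thousands of background proteins per experiment, the
experiment itself supplies the null distribution. `outlier_pvalues()`
computes, per protein, a robust z-score of the oriented log-ratio: the
centre is the experiment median, and each side has its own scale, the
distance from the median to the 84.13th (one-sigma) percentile on the
right and to the 15.87th on the left. Asymmetric scales matter because
pull-down ratio clouds are routinely skewed by the binder tail itself.

The p-value is the upper-tail normal probability of the signed z — the
one-sided p for *allele-1 preference*. Under the null it is uniform on
(0, 1); a strong allele-2 binder shows `p` near 1, and its own one-sided
tail is `1 - p`. We report this single uniform quantity rather than the
folded "tail in the protein's own direction" (which lives on (0, 0.5] and
is not a valid p-value) and let the combination step pick the tail.

`combine_pvalues()` enforces the label-swap logic: a protein is callable
only when both orientations prefer the same allele. When the directions
agree, the two direction-consistent tails are combined by Fisher's method
(chi-square, 4 df) and the result is **doubled** (capped at 1); when they
disagree, the combined p is 1. The doubling is the Bonferroni price of
having tested both directional alternatives — without it, the combined
value is measurably anti-conservative under the simulated null, because
conditioning on direction agreement forces both tails below 0.5. With it,
the deep null tail matches its nominal level (a property the test suite
checks both analytically on exact uniforms and through the full simulation
path), which is what justifies applying the fixed `p < 1e-7` cutoff
directly. That threshold is a screen-wide stringency convention rather
than an FDR procedure; it is configurable, and at the simulated depths a
tenfold binder with ten peptides reaches combined p-values around 1e-130,
so the call is insensitive to the exact cutoff over many orders of
magnitude.

The p floor of 1e-300 simply keeps logarithms finite.

## Quadrant classification

`call_interactions()` assigns exactly one class per protein quantified in
both orientations, with this precedence:

1. **contaminant** — raw H/L below 1 in both orientations *and* clearly
   separated from the bulk in both (forward low tail and reverse high tail
   each significant at `contaminant_alpha`, default 0.01). The raw-ratio
   condition alone is deliberately insufficient: about a quarter of the
   background cloud sits marginally below ratio 1 in both orientations by
   sampling noise alone, and calling those contaminants would misclassify
   a large fraction of honest background. The significance condition
   restricts the class to proteins that are genuinely displaced from the
   cloud, as true unlabelled contaminants are.
2. **specific_allele1 / specific_allele2** — combined p below the threshold
   with agreeing directions; the common sign picks the allele.
3. **background** — everything else.

Proteins seen in only one orientation are **not_callable**: the design's
evidence requirement is significance in *both* pull-downs.

The exported plot coordinates follow the conventional layout: x is the
forward oriented log2(allele1/allele2) ratio, y the reverse *raw* log2
H/L — allele-1 binders fall lower-right, allele-2 binders upper-left,
contaminants lower-left. The fold-change estimate is the geometric mean
across the pair, `2^((|forward| + |reverse|)/2)` on oriented log-ratios.

## The synthetic-evidence generator

Every downstream stage is testable without raw mass-spectrometry data
because `simulate_pair()` / `simulate_study()` generate evidence with known
ground truth. The generator emulates, per experiment:

* `n_background = 1000` nonspecific proteins at true ratio 1;
* `n_contaminants = 50` unlabelled proteins at
  `contaminant_hl_ratio = 0.2` in *both* orientations;
* spiked binders (`binder_spec()`) with a chosen preferred allele, fold
  change and per-experiment peptide count;
* peptide log2 ratios with Normal(0, `peptide_noise_sd = 0.3`) noise —
  multiplicative, lognormal noise, since peptide-level SILAC ratio scatter
  is symmetric in log space;
* peptides per protein from a truncated geometric (minimum 1) with mean 3,
  a realistic depth for a single-run pull-down where most background
  identifications rest on a handful of peptides; intensities are
  log-uniform over 1e6–1e9;
* 90% of peptides flagged unique, so the unique-peptide filter actually
  filters.

The seed is mandatory and every draw derives from it, so runs are
byte-reproducible. The defaults produce the familiar interaction-plot
clouds at desk scale: a dense origin cluster, a contaminant cluster in the
lower-left, and binder outliers.

What the generator does **not** model: shared peptides across proteins
(hence no protein-group inference), intensity-dependent ratio variance,
missing-value mechanisms beyond the peptide-count draw, and
spectrum/search-level artefacts. Passing tests therefore demonstrate the
statistical pipeline's behaviour under its stated noise model, not
robustness to every failure mode of real evidence tables; the ingest mode
exists precisely so real MaxQuant-style exports can be run through the same
stages.

`example_design()` mirrors the structure of the type 1 diabetes screen that
motivates the shipped panel: binders spiked at nine SNPs (including a
five-fold binder on rs12722508 allele A and an eight-fold binder on
rs41295061 allele A, with `SIM_`-prefixed identifiers to flag their
synthetic origin) and three SNPs left silent.

## Motif scanning

`scan_motif()` matches IUPAC consensus strings (degeneracy-set matching,
e.g. B = C/G/T), not position-weight matrices — the deposited consensus
sequence is what the screen's motif follow-up checks. Both strands are
scanned; minus-strand hits are found by matching the reverse-complemented
consensus and are reported at plus-strand 0-based offsets, so both alleles
and both strands share one coordinate frame and SNP overlap is a simple
interval test (the SNP offset within a bait is the left-flank length).
`differential_report()` counts SNP-overlapping hits per allele at 0 and 1
mismatches and flags a motif as differential when perfect-hit presence
differs between alleles — the "site created or destroyed by the SNP"
readout. The 1-mismatch mode exists because near-consensus sites with a
single mismatch are a recurring observation in such screens.

The shipped consensus fixtures are CREB1 (`TGACG`) and the murine RUNX1
consensus (`TGTGGBH`); other motifs are supplied as a two-column TSV.

## Validation statistics

`ddct()` implements relative qPCR quantification: replicate-mean
delta-Ct (target − reference) per sample, delta-delta-Ct against the
control sample, expression `2^(-ddct)`, with spread as the standard
deviation of replicate-wise delta-delta-Ct values. Machine offsets cancel
by construction.

`allele_activation()` normalises firefly by renilla per replicate, computes
per-replicate percent change of the knock-down condition against the mock
mean for each allele, and compares the alleles with a two-sided Welch
t-test on those replicate percent changes. The underlying report of such
assays rarely names its test; the Welch choice (no equal-variance
assumption, per-replicate percent changes) is this package's documented
convention, not a reproduction of any particular published p-value.

## Numerical and design choices, in brief

* Coordinates 0-based half-open everywhere; sequences uppercased on parse.
* Concatemer junctions: units ligated head-to-tail, the 2-nt overhang
  filled once per junction (`copies*L + (copies-1)*2` for the default
  overhang). Overhangs must be A/T-only (strand-specific fill-in labelling
  with a modified dATP) and non-palindromic (a palindromic overhang would
  also ligate head-to-head); `TT` is the default, `GG` and `AT` are
  rejected.
* Quantile type is R's default (type 7); even-count medians average the
  central pair; ties at the exact median get direction 0 and are not
  callable.
* Degenerate inputs fail loudly: zero spread in the ratio distribution is
  an error, fewer than 20 proteins skip normalisation with a warning and
  refuse the outlier test.
* Problem sizes in the test suite and acceptance script (10,000-protein
  null studies over 50 seeds, 20-seed recovery and invariance sweeps) are
  chosen to exercise deep tails while completing a desk-scale run in a few
  minutes; larger nulls only sharpen the same checks.
* A perfectly calibrated per-experiment KS uniformity check at alpha 0.01
  still rejects ~1% of experiments by construction, so the suite requires
  at least 95% of experiments to pass rather than literally all.

## Known limitations

* The outlier test presumes a dominant, roughly lognormal background; a
  screen where most proteins bind allele-specifically would violate the
  null construction.
* Protein inference is out of scope: evidence rows are taken at their
  stated protein assignment, and complexes (a heterodimer enriched
  together) appear as separate calls.
* Consensus matching is binary; affinity gradations that a PWM would score
  are invisible.
* The 1e-7 convention controls the family-wise error only implicitly
  through its stringency; an explicit Bonferroni column is easy to add
  downstream from the exported tables.
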