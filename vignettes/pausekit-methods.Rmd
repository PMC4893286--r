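---
title: "Methods: estimating and analysing RNAP2 promoter-proximal pausing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and analysing RNAP2 promoter-proximal pausing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and numerical choices
behind `pausekit`, in the spirit of a statistical-methods appendix. It
states no empirical result that the package's tests and
`scripts/acceptance.R` do not themselves compute.

## The pausing-index model

RNAP2 ChIP-seq coverage at an actively regulated gene concentrates in
two compartments: a sharp promoter-proximal accumulation of engaged but
paused polymerase, and a broad, lower plateau of elongating polymerase
across the gene body. The pausing index summarises their ratio:

$$
\mathrm{PI} \;=\;
\frac{\mathrm{ReadCount(TSSR)}/L_1}{\mathrm{ReadCount(GeneBody)}/L_2},
\qquad L_1 = 350\ \mathrm{bp},\quad L_2 = \mathrm{gene\ length} + 2700\ \mathrm{bp},
$$

with the TSSR spanning promoter offsets −50..+300 bp and the gene body
running from +300 bp to 3 kb past the TES. Both counts are converted to
reads per million mapped per bp (rpm/bp) and background-subtracted
against the matched input library before the ratio is taken, so the PI
of a gene is also the ratio of its two background-subtracted densities.

Assumptions worth keeping in mind:

* **A read is a point.** Each read contributes only its strand-adjusted
  5′ position (start for `+` reads, `end − 1` for `-` reads). This makes
  the PCR-duplicate collapse — one count per (chromosome, 5′ position,
  strand) — unambiguous, and sidesteps fragment-length modelling.
  Spliced alignments are treated the same way; the 3 kb gene-body
  extension makes the statistic robust to where exactly elongating
  signal ends.
* **Coordinates are 0-based half-open** (the BED convention)
  throughout. For a minus-strand transcript the stored TSS is the BED
  end coordinate, so the first transcribed base is `tss − 1`; the
  strand-aware region arithmetic in `tssr_region()` /
  `gene_body_region()` follows from that single rule, and the ±500 bp
  promoter window reduces to `[tss − 500, tss + 500)` on both strands.
* **Missing is a value.** A gene whose background-subtracted gene-body
  density is non-positive has no meaningful ratio; its PI is missing and
  the gene counts as non-paused. The paused call itself is strict:
  PI > 2, so a gene at exactly the threshold is non-paused.

## Eligibility and isoform consolidation

Genes that overlap another gene, lie within 3 kb of one, or are shorter
than 1 kb are removed before estimation (`eligible_genes()`); spans are
unions over a gene's isoforms and the distance test is strand-blind.
Among a gene's surviving isoforms the one with the strongest TSSR RNAP2
density wins, provided that density reaches 0.001 rpm/bp — the floor is
applied to the *background-subtracted* value, a choice the interface
exposes (`tssr_floor`). Failing that, an isoform whose ±500 bp promoter
shows at least fourfold H3K4me3 ChIP/input enrichment is rescued
(strongest ratio wins; the input density is floored at one
read-equivalent so the ratio is defined at zero input). The fourfold
cutoff is adopted as a fixed constant, not re-derived. Isoforms sharing
the winning TSS resolve to the longest. Genes failing both routes get no
PI.

Cross-sample sets rank genes by PI within each sample (ties averaged,
missing PIs sharing the bottom rank), take per-gene median ranks, and
split the genes paused in at least one sample into upper and lower
halves; with an odd count the extra gene goes to the high half.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pi_threshold` | 2 | ratio | conventional paused/non-paused boundary |
| `tssr_floor` | 0.001 | rpm/bp | minimum TSSR signal to trust an isoform |
| `h3k4me3_fold` | 4 | ratio | promoter-mark rescue threshold |
| `fpkm_min` | 1 | FPKM | expression floor (≥ 1, not > 1) |
| `fold_change` | 2 | ratio | stimulus-response and density-change calls |
| `window` (profiles) | ±2000 | bp | TSS metagene extent; 50 bp bins (10 bp for deeply sequenced nucleosome data) |
| `n_bins` (hexbin) | 50 | hexagons across x | visual default |

## Downstream analyses

**Promoter composition.** GC content excludes N bases from numerator
and denominator. The CpG ratio on a 1000 bp promoter counts overlapping
CG *and* GC dinucleotides over the product of C and G frequencies — a
palindromic numerator, so the ratio is reverse-complement invariant and
single-strand counting is self-consistent. K-mer enrichment counts
overlapping occurrences of every 5- or 6-mer on the promoter strand and
compares paused versus other promoters with a two-sided Mann–Whitney U
test; the score is ±(−log10 p) with a positive sign when counts are
greater among paused promoters *or when no difference is detected*.
P-values are floored at 1e−300 so no infinities are emitted. TSSR
densities can be GC-corrected by removing a smoothing-spline fit of
log10 density on TSSR GC content and re-centring at the global mean.

**Expression coupling.** The PI–expression trend is a cubic smoothing
spline of log10 FPKM on log10 PI with GCV-chosen smoothness (df = 4 in
aggregate mode, to emphasise the overall hill shape over tail
wiggliness). Running 25/75 % quantile bands use a sliding window of
`max(51, 0.05 n)` genes (forced odd — the window size is a package
choice; only the procedure is prescribed), smoothed and then clipped so
the lower band never exceeds the mean curve nor the upper band falls
below it, which stabilises sparse extremes. Quantile bin edges
everywhere use the linear-interpolation sample-quantile definition.
Single-cell variability is the per-gene CV (sample SD over mean) across
cells among expressed genes (mean FPKM ≥ 1), compared between paused and
non-paused genes within 20 % expression quantiles. Stimulus-response
classification works on fold changes against the time-0 baseline; a gene
must reach FPKM ≥ 1 at some time point to be considered, `early` means a
≥ 2-fold rise within 1 h, `late` a rise only afterwards, `down` a
≥ 2-fold drop, and a gene qualifying in both directions is labelled by
its first qualifying event in time (ties go to the up event). A zero
baseline followed by signal counts as an up event. `non_responsive`
additionally requires expression at every time point with all folds
strictly inside (0.5, 2); expressed-but-intermittent, non-responsive
genes fall into `excluded` to keep the labels exhaustive. PI-shift tests
subsample the non-responsive class, without replacement and
seed-deterministically, to the responsive-class size before testing, and
all p-values pass a Bonferroni family-wise gate.

**Density landscape.** Hexagonal binning assigns each gene to the
nearest centre of two offset rectangular lattices (row spacing
$\sqrt{3}/2$ of the cell width in scaled units), which is exactly the
hexagonal Voronoi partition; per-bin counts always conserve the gene
total and genes with missing overlay values contribute to counts but not
means. The TSSR→gene-body trend is a smoothing spline on the log10
scale; its inflection is the maximum of the second derivative evaluated
on a 512-point grid over the interior 5th–95th percentile of the fitted
x data (boundary curvature of splines is an artifact; ties take the
smallest x). A curvature floor of 0.1 flags effectively straight trends
— fitted lines sit orders of magnitude below it, genuine breakpoints
well above — so callers can distinguish "no inflection" from a located
one.

**Chromatin features.** Promoter mark enrichment is
log2((chip + ε)/(input + ε)) in rpm/bp with ε one read-equivalent per
region per library, which keeps every value finite; these log2 ratios
(not subtracted differences) feed an ordinary least-squares model of
log2 PI, optionally with log10 FPKM as a covariate. The fit requires ten
genes per predictor, errors on rank-deficient designs naming the
offending columns, and attaches a warning when the predictor condition
number exceeds 1e6. No regularisation: the coefficients themselves are
the readout. TSS profiles average per-bin rpm over genes, strand-aware
(upstream left), smoothed by local regression with span 0.1. The
density-change classifier labels genes by > 2-fold TSSR increase and/or
> 2-fold gene-body decrease between conditions, with a symmetric
absolute-fold mode behind a flag.

**Shared statistics.** The Mann–Whitney implementation delegates to
R's `wilcox.test`, forcing the exact branch for tie-free samples with
n1 + n2 ≤ 20 and the tie- and continuity-corrected normal approximation
otherwise; the tests pin the exact branch to full permutation
enumeration. The 4096-way k-mer scan uses an in-package vectorised
normal-approximation path verified against `wilcox.test` to 1e−12.
Fisher gene-set enrichment is the one-sided hypergeometric tail.
Multiple testing follows the package-wide policy: a Bonferroni gate for
small families, Storey q-values (smoother π₀ over λ = 0.05..0.95,
df = 3) for families larger than ten, falling back to
Benjamini–Hochberg with π₀ = 1 when the π₀ estimate leaves (0, 1] — the
fallback is recorded on the result.

## The synthetic-data generator

The generator exists so that every stage has planted ground truth:

* `generate_annotation()` lays alternating-strand genes (2–10 kb,
  ≥ 10 kb apart) on one synthetic chromosome and can inject labelled
  eligibility violations (overlapping pairs, < 3 kb pairs, 900 bp
  genes). Promoters are drawn per-position at a per-gene GC target with
  k-mers planted greedily at non-overlapping positions so every planted
  copy survives.
* `simulate_chip_library()` treats the chromosome as a subset of a
  20-fold larger genome: 80 % of ChIP reads are genome-wide uniform
  background (a typical ChIP background share) of which only the
  on-chromosome fraction is stored, while `mapped_total` records the
  full library — the chromosome-subset convention of `read_library`.
  Signal reads give each gene a TSSR per-bp rate equal to planted PI
  times its gene-body rate. Signal 5′ ends are drawn *without
  replacement* over (position, strand) slots, modelling distinct
  crosslinked fragments, so the PCR-duplicate collapse removes only the
  duplicates injected at `duplication_rate`; saturation can still occur
  when a region's slot capacity is exhausted, which compresses the very
  top of the PI range — visible, and quantified, in the recovery
  statistics.
* `simulate_expression()` provides log-normal bulk FPKM; single-cell
  values as gene mean × multiplicative gamma noise with group-dependent
  dispersion (CV = √dispersion independent of the mean — a
  gamma-mixed, negative-binomial-like model whose zero-dispersion limit
  is exactly deterministic); and fold-change-driven time courses per
  planted response class.
* `simulate_enrichment_model()` draws standard-normal mark enrichments
  and builds log2 PI = Xβ + noise for coefficient-recovery checks;
  `simulate_mark_library()` produces read-level promoter-mark libraries.

What the generator does **not** emulate — and therefore what passing
tests do not certify about real data: sequence-composition read bias,
fragment-length structure, chromosome-scale coverage waves, isoform
complexity beyond shared-TSS alternatives, mappability gaps, and
cell-type heterogeneity. Results on real libraries depend on upstream
alignment and read filtering, which are out of scope.

## Problem sizes and determinism

The standard study sizes used by the test suite and the acceptance
script are 500 genes × 2 × 10⁶ reads for PI recovery, 500 + 500
promoters for the motif scan, 2000 genes for landscape and regression
recovery (100 replicate fits for the inflection), 1000 genes × 100
cells for the CV analysis with a 200-replicate null calibration, and a
300-gene end-to-end pipeline — sizes at which the planted effects are
comfortably identifiable while a full run stays interactive. Every
stochastic step is a pure function of its parameters and an explicit
seed; the pipeline stamps the seed into every output header and
byte-identical reruns are part of the acceptance checks.

## Known limitations

* PI is undefined (missing) wherever background subtraction leaves a
  non-positive gene-body density; heavily input-dominated genes are
  silently non-paused rather than imputed.
* The duplicate collapse bounds usable TSSR signal by 700 slots
  (350 bp × 2 strands); extremely deep libraries saturate and compress
  high PI values, in the package as in the underlying protocol.
* The H3K4me3 rescue route and the 0.001 rpm/bp floor are fixed
  conventions; sensitivity to them is the user's to explore via the
  exposed parameters.
* `classify_response` assigns one label per gene; oscillating genes are
  labelled by their first qualifying event, not modelled dynamically.
* Hexbin output is a table of bin centres and summaries; rendering is
  left to the caller.
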