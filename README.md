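# pausekit

Promoter-proximal pausing of RNA polymerase II (RNAP2) — the stalling of
engaged polymerase a few tens of base pairs downstream of the
transcription start site — is a rate-limiting, regulated step of
metazoan transcription. `pausekit` is an R toolkit for quantifying
pausing from RNAP2 ChIP-seq-style read data and relating it to promoter
sequence composition, gene expression, single-cell expression
variability, stimulus response, and chromatin features. It is aimed at
computational genomicists who have aligned-read intervals (BED), gene
models (BED12/refFlat), and expression tables (FPKM), and who want a
tested, deterministic implementation of the full analysis rather than a
collection of one-off scripts.

## The statistic

For each gene the **pausing index** (also called the traveling ratio) is

```
PI = ( ReadCount(TSSR) / L1 ) / ( ReadCount(GeneBody) / L2 )
```

where the TSS region (TSSR) spans −50 to +300 bp around the TSS
(L1 = 350 bp always) and the gene body spans +300 bp downstream of the
TSS to 3 kb past the transcription end site (L2 = gene length + 2700 bp).
Read counts are PCR-deduplicated strand-adjusted 5′ positions,
normalized per region length and per million mapped reads (rpm/bp), and
background-subtracted against a matched input library. Genes are called
**paused** when PI > 2.

Around this core the package implements:

* eligibility filtering (genes overlapping, within 3 kb of, or shorter
  than 1 kb are removed) and isoform consolidation (strongest TSSR
  signal ≥ 0.001 rpm/bp, with an H3K4me3 ≥ 4-fold promoter-enrichment
  rescue route);
* promoter composition: GC content, CpG ratio, GC-correction of TSSR
  densities, and signed −log10(p) Mann–Whitney enrichment of all 4^k
  k-mers between paused and non-paused promoters;
* expression coupling: paused/expressed overlap, the hill-shaped
  PI–expression smoothing-spline trend with running 25/75 % quantile
  bands, single-cell coefficient-of-variation analysis by expression
  quintile, stimulus-response classification (early / late / down /
  non-responsive) and PI-shift tests with matched subsampling;
* the TSSR × gene-body density landscape: hexagonal binning with a
  third-variable overlay, the log-scale trend spline, and
  inflection-point detection by maximum second derivative;
* chromatin features: log2 promoter mark enrichment, an OLS model of
  log2 PI on mark enrichments, TSS metagene profiles, and a
  density-change classifier for perturbation experiments;
* a synthetic-data generator that plants known pausing indices, motifs,
  dispersion groups, response classes, and regression coefficients, so
  every stage is testable offline with ground truth.

## Worked example

```r
library(pausekit)

ann <- generate_annotation(200, seed = 42)          # synthetic genome
set.seed(43)
planted <- exp(runif(200, log(0.25), log(32)))      # true pausing indices
libs <- simulate_chip_library(ann$genes, planted, depth = 5e5,
                              chrom_length = ann$chrom_length, seed = 44)
pt <- pause_index(ann$genes, libs$chip, libs$input) # the estimator
summary(pt)
```

```
Genes: 200
Assigned PI: 193 (96.5%)
Paused: 118 (61.1% of assigned)
Selection routes:

rnap2_tssr unassigned
       193          7
PI quartiles:
         0%         25%         50%         75%        100%
 0.06826555  0.96318447  3.36913873  9.26409503 35.48666667
```

193 of 200 genes receive a PI (7 fall below the TSSR signal floor after
background subtraction and have no H3K4me3 library to rescue them), and
61 % of assigned genes are paused — as expected, since the planted PI
distribution is log-uniform on [0.25, 32] and a bit over half of that
mass lies above 2. The estimates track the planted truth closely:

```r
ok <- !is.na(pt$pi)
cor(planted[ok], pt$pi[ok], method = "spearman")
#> [1] 0.986
```

`run_pipeline(pause_config(out = "run", seed = 1))` executes the whole
synthetic study — simulation, PI estimation, k-mer scan, expression
coupling, landscape, chromatin model — writing seed-stamped TSVs and a
manifest; reruns with an unchanged configuration are skipped. A thin
command-line wrapper with `run` / `simulate` / `pi` / `kmers`
subcommands is installed at `inst/scripts/pausekit.R`.

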