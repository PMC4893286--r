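Package: pausekit
Title: RNA Polymerase II Promoter-Proximal Pausing Analysis from ChIP-Seq Read Densities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the pausing index (traveling ratio) of RNA polymerase II
    from ChIP-seq style aligned-read intervals: background-subtracted read
    densities in the TSS region (-50 to +300 bp) and gene body (+300 bp to
    3 kb past the TES), isoform consolidation with an H3K4me3 rescue rule,
    eligibility filtering, and paused-gene calling at a pausing-index
    threshold of 2. Downstream analyses couple pausing to promoter sequence
    composition (GC content, CpG ratio, signed k-mer enrichment), gene
    expression (hill-shaped trend splines, single-cell coefficient of
    variation, stimulus-response classification with pausing-index shift
    tests), the TSSR/gene-body density landscape (hexagonal binning, trend
    spline, inflection detection), and chromatin-mark regression on log2
    pausing index. A deterministic synthetic-data generator plants known
    pausing indices, motifs, dispersion groups, response classes, and model
    coefficients so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
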