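Package: rededit
Title: RNA Editome Detection, Filtering and Differential Editing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and analysis of RNA:DNA differences (RDDs) from
    per-site base-count (pileup) tables, centred on A-to-I RNA editing.
    Implements a deterministic candidate-site caller with coverage,
    frequency and base-quality thresholds; an annotation and exclusion
    cascade (genomic region, repeat class with Alu exemption, dbSNP with
    known-editing-site rescue, pseudogene, homopolymer proximity, flank
    mappability, recoding consequences) with a full accounting ledger;
    phenotype-group editomes under a 50 percent presence rule with global
    (Wilcoxon signed-rank) and per-site (Kolmogorov-Smirnov-gated t or
    Mann-Whitney) comparisons; median-of-ratios count normalization with
    editing-expression Pearson correlation analyses; Fisher/EASE gene-set
    over-representation; amplicon cDNA-versus-gDNA validation calling and
    2^-ddCt relative quantification; and a synthetic-data generator that
    emits a miniature genome, annotation tracks, pileups and counts with
    fully known planted truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    nortest,
    withr
Config/testthat/edition: 3
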