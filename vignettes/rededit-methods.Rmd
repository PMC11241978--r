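---
title: "Calling and comparing RNA editomes: models, parameters and design choices"
author: "rededit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing RNA editomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rededit)
```

## Scope and data model

`rededit` analyses RNA:DNA differences (RDDs) — the twelve ordered
reference-to-alternate mismatch types observed in RNA relative to a genome —
with A-to-I editing (read out as A>G, or T>C on the minus strand) as the
signal of interest. The canonical sequencing input is the **pileup table**:
per contig, position, and sample, the four base counts, the mean base quality
per allele class, and a count of reads excluded as duplicates or
vendor-failed. Working from per-site counts rather than reads keeps every
decision the base-level thresholds need while avoiding alignment machinery;
an optional Rsamtools front-end (`pileup_from_sam()`) produces the table from
SAM/BAM with MAPQ and duplicate/QC-fail read filtering. Internally all
coordinates are 1-based inclusive (the GenomicRanges convention); BED files
are converted at the boundary, and all emitted tables are 1-based.

## The caller

Per site and sample, excluded reads are ignored, allele classes with mean
base quality below `min_quality` (default 25) are discarded, and the
alternate allele is the highest-count retained non-reference allele, ties
broken lexicographically A<C<G<T and recorded. A candidate requires retained
depth ≥ `min_coverage` (10), alternate reads ≥ `min_alt_reads` (2), and
frequency ≥ `min_frequency` (0.10). Choices worth noting:

* **Frequency denominator** is the full retained depth (all quality-passing
  bases), not ref+alt only: the editing frequency is the fraction of reads at
  the site carrying the edited base.
* **`min_alt_reads` = 2** is our floor against singleton sequencing errors;
  the stated coverage/frequency thresholds alone would admit one alternate
  read at depth 10. It is configurable down to 1.
* **Monotonicity caveat.** Raising the coverage, frequency or alt-read
  thresholds can only remove candidates (a property the tests enforce).
  The base-quality floor is the exception: discarding a low-quality
  *reference* allele shrinks the denominator, so a stricter quality floor can
  promote a site past the frequency cutoff. This is inherent to the
  retained-depth denominator, not a defect.
* An optional per-sample QC pre-filter (`qc_filter_samples()`) drops
  libraries with < 60 % uniquely mapped or > 60 % duplicate reads; the
  thresholds are ours (the upstream criterion is qualitative) and
  configurable.

## Annotation and the exclusion cascade

Region classification uses a fixed precedence — exonic (CDS) > 3'UTR > 5'UTR
> ncRNA > NMD/processed transcript > intronic > upstream > downstream >
other — with 1 kb strand-aware up/downstream windows. The precedence order
and window size are our determinism choices (the category list itself is
standard); both are configurable. Sites in minus-strand genes have their RDD
re-expressed in transcript orientation (genomic T>C becomes A>G), and CDS
sites get a recoding consequence by resolving the codon in coding
orientation and translating with the standard genetic code.

Sequence-context annotations:

* **Homopolymer proximity**: a run of ≥ 5 identical bases within 2 bases of
  the site (distance 0 when inside the run). Both numbers are common-practice
  defaults (`min_run`, `near_window`), since no quantitative definition is
  standard.
* **Flank mappability**: the number of genomic placements of the ±100 bp
  flank with identity > 0.90, found by exact 20-mer seeds centred on the site
  and extended without gaps; the self-placement counts, so the value is ≥ 1.
  This is a deterministic, dependency-free approximation of a local aligner's
  report; gapped similarity is out of scope, and only the forward strand is
  scanned (the generator's duplications are same-strand).

Both are **annotations, not filters, by default** — the cascade can be asked
to filter on them, but the default pipeline only annotates, reflecting their
diagnostic role.

The exclusion cascade runs in fixed order: (1) pseudogene overlap, (2) a SNP
record not rescued by known-editing-catalog membership, (3) simple-repeat or
low-complexity location outside Alu. Each removed site is attributed to its
*first* failing filter and the ledger satisfies
`input = retained + Σ removals` exactly on every run (asserted in code). Two
consequences of taking the rescue rule literally: a truly edited site at a
SNP position that is absent from the catalog is lost; and an Alu site inside
a nested low-complexity interval is retained (Alu takes precedence in repeat
classification).

## Editomes and differential editing

A site enters a group editome when observed — called and filter-passing — in
at least half the group's samples (`presence_threshold = 0.5`). Mean
frequencies are computed **over observed samples only**: absence reflects
non-detection (coverage, sampling), not zero editing. The absent-as-zero
alternative is available (`absent_as_zero = TRUE`) but changes the estimand.

The global comparison pairs per-site mean frequencies by site identity over
sites present in **both** group editomes and applies Wilcoxon's signed-rank
test (zero differences dropped; exact null up to 25 non-zero pairs, else a
continuity-corrected normal approximation). Pairing by shared site is our
reading of a signed-rank (paired) design whose pairing unit was not spelled
out; an unpaired comparison can be had by testing the two editomes' mean
frequency vectors directly.

Per-site differential editing gates the test choice on normality: a
Kolmogorov–Smirnov test of each group against a normal with sample-estimated
mean/SD at α = 0.05; if either group rejects (or has zero variance), a
Mann–Whitney test (exact when min(n) ≤ 8 without ties, tie-corrected normal
approximation otherwise), else a Welch t-test (chosen over Student for
robustness to unequal variances). The estimated-parameter bias of the plain
KS screen is known and accepted; a Lilliefors-corrected screen is available
(`lilliefors = TRUE`, via the nortest package when installed). Sites observed
in fewer than 3 samples per group are skipped and counted. DEdit status is
raw p < 0.05 by design — the upstream definition uses unadjusted p-values —
and a Benjamini–Hochberg column is emitted alongside for users who want it.
The editing fold change is `log2(mean_case/mean_control)` over observed
samples.

## Expression integration

Counts are normalized with median-of-ratios size factors (factors rescaled to
geometric mean 1) — the standard count normalization, implemented directly;
no shrinkage or Wald machinery is reproduced, because the quantities consumed
downstream are normalized means, a log2FC with pseudocount 1, and the same
KS-gated test as editing, with the ≥ 0.5 |log2FC| cutoff defining
differential expression.

Editing–expression association is Pearson correlation across samples, pooled
over groups, with the r > 0.5 ∧ p < 0.05 significance rule (p from the exact
t-transform of r). Three analyses share this kernel: ADAR-homolog expression
vs per-sample overall mean editing; gene-level expression vs the mean
frequency over the gene's DEdit sites; and per-site variants (samples missing
a site are dropped pairwise, results with n < 3 flagged). **Scale:** by
default expression enters as log2(normalized + 1). The generator couples
expression to editing on the log scale, and under a log link the Pearson
correlation computed on raw counts decays with cohort size (asymptotically
r = s/√(e^{s²}−1) for log-slope s — about 0.27 at s = 2) even when the
coupling is strong; the log scale is where the count model is linear and
where correlation reflects coupling strength. `log2_counts = FALSE` gives the
raw-scale correlation. A cross-gene log2FC-vs-log2FC correlation
(`log2fc_correlation()`) is provided as a secondary, one-value-per-gene
report.

## Over-representation

`enrich()` tests DEdit transcripts against GMT gene sets with the exact
hypergeometric upper tail and the conservative EASE variant (one overlapping
gene removed before the tail; identically 1 at k = 1). EASE is the ranking
and FDR statistic, mirroring the defaults of the annotation tool it
replaces; both p-values are reported. The default background is the genes
carrying at least one retained editing site — the population actually at
risk of being called DEdit; a whole-annotation background is a caller
choice. External term catalogs are deliberately not bundled: the statistic,
not any particular term collection, is in scope.

## Targeted validation

Amplicon pileups are expected to come from uniquely mapped reads with
MAPQ > 20 and duplicates/vendor-fails excluded. A site is a validated
editing site (is_res) in a sample when the cDNA alternate fraction is ≥ 0.10
and the paired gDNA is reference-homozygous: alternate fraction ≤ 1 % at
depth ≥ 50. The homozygosity thresholds are ours (appropriate for
amplicon-scale depth, configurable); the comparison itself is the paired-DNA
analogue of the dbSNP exclusion and rejects every planted genomic variant
regardless of its cDNA fraction. Verification (is_res in ≥ 1 sample) and
alteration validation (verification plus group p < 0.05 from the shared
KS-gated machinery) are reported as separate flags. `ddct()` implements
ΔCt = Ct_target − Ct_reference, ΔΔCt against the calibrator-group mean, and
fold = 2^−ΔΔCt, which is exactly invertible (log2 fold = −ΔΔCt to machine
precision).

## The synthetic generator

`synthetic_config()` fixes the study conditions the tests and acceptance
script run under; its defaults are the reference conditions and are not
tuned per test:

| parameter | default | meaning |
|---|---|---|
| samples | 20 per group | two phenotype groups |
| depth | NB(mean 50, size 5) | per-site read depth |
| true sites | 200, Beta(2,5) baseline | planted A-to-I frequencies |
| global_shift | 0 | additive group-2 frequency change |
| region mix | 50 % intronic, 20 % 3'UTR, 10 % exonic, 10 % ncRNA, 5 % 5'UTR, 5 % NMD/processed | planted region classes |
| Alu fraction | 0.7 | intronic/3'UTR sites inside Alu |
| error rate | 1e-3 | per-base error at unplanted positions |
| SNP artifacts | 20, HW allele freq 0.3 | genotype 0/0.5/1 in cDNA **and** gDNA |
| homopolymer artifacts | 20, alt quality ~Q18 | removed by the Q25 floor |
| pseudogene copies | 2 (+10 multimap sites) | verbatim gene copies, flank multiplicity 2 |
| low-coverage artifacts | 10 at 8 % depth | fail the coverage floor |
| known catalog | 50 % of true sites | drives the catalog-overlap QC |

The genome is a single contig with alternating-strand genes (UTRs, split CDS,
introns; a few ncRNA and processed-transcript genes), Alu/simple/low-
complexity intervals placed in introns and 3'UTRs, and everything emitted as
FASTA/GTF-subset/BED/VCF-lite/TSV. Editing counts are Binomial(depth, planted
group frequency); base qualities are Gaussian around Q35 (Q18 for
homopolymer-artifact alternates). Expression is negative binomial (size 10)
around lognormal gene means, with coupled genes (defaults: two ADAR-like
genes, log-slopes 2.0 and 1.5 on the standardized per-sample mean editing).
Because the criterion the generator serves is a *region-composition* shift
between groups and a single additive shift cannot produce one, two dials —
`frac_intronic_lost` (intronic sites silenced in group 2) and
`frac_utr3_gained` (3'UTR sites present only in group 2) — implement it;
both default to 0.

Everything is seeded (per-stage derived streams) and byte-deterministic:
identical configs produce identical files.

**What passing tests do and do not show.** The generator emulates the
statistical skeleton the analysis assumes — binomial sampling around
per-site frequencies, NB coverage and counts, genotype-consistent SNPs,
quality-separable artifacts, repeat-borne editing. It does not emulate
alignment error beyond the pseudogene construction, splice-aware coverage,
strand-specific library artifacts, per-cycle quality decay, batch effects, or
biological covariance between sites (sites are independent given the group).
Recovery and error-rate results on synthetic data therefore validate the
*pipeline's logic and statistics*, not performance on any real cohort.

## Numerical and testing choices

Statistical kernels call base R (`t.test`, `wilcox.test`, `ks.test`,
`phyper`, `cor.test`); the test suite pins them against independent
enumeration oracles — all 2^n sign patterns for the signed-rank test, full
arrangement enumeration for Mann–Whitney, explicit pmf summation for the
hypergeometric tail, and all n! orderings for the Pearson permutation null —
plus a brute-force re-count oracle for the caller and a sliding-window
identity scan for flank mappability. Degenerate inputs are defined, not
errors: empty spectra are flagged; both-groups-constant comparisons return
p = 1; zero-variance correlations are flagged without a p-value.

The suite's problem sizes are the package's choices: the default study
conditions (20/group, 200 sites, 100 kb genome) for recovery, artifact
rejection and effect-size checks; 2 000 null sites for the type-I band
0.05 ± 3·√(0.05·0.95/2000); 20 regenerated cohorts for the global-reduction
profile; 50 replicate expression draws at 46 + 46 samples for coupling
detection; and a reduced configuration (30 kb, 5/group) for the byte-level
determinism check, which compares every emitted file.

## Known limitations

Single-contig generator layouts; forward-strand-only mappability scan;
annotate-only homopolymer/mappability by default; no hyper-editing cluster
detection; no editing QTLs or covariate-adjusted models; SAM-derived pileups
carry a quality floor rather than true per-allele mean qualities; the
dbSNP-rescue rule discards uncatalogued true sites at SNP positions by
design.
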