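## Shared fixtures. The default-condition simulation is expensive, so it is
## generated once per test session and reused read-only across test files.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(...) {
  args <- list(genome_length = 40000, n_genes = 10, n_samples_per_group = 6,
               n_true_sites = 60, n_snp_artifacts = 8,
               n_homopolymer_artifacts = 6, n_pseudogene_copies = 1,
               n_pseudogene_sites = 4, n_low_coverage_artifacts = 4)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

## one small genome + pileups (seed 11), memoised
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- small_config(seed = 11)
    g <- make_genome(cfg)
    sim <- simulate_pileups(g, cfg)
    .fixtures$small <- list(cfg = cfg, genome = g, sim = sim,
                            groups = stats::setNames(sim$samples$group,
                                                     sim$samples$sample))
  }
  .fixtures$small
}

## the default (study-condition) dataset run through call+annotate+filter
default_run <- function() {
  if (is.null(.fixtures$default)) {
    cfg <- synthetic_config(seed = 101)
    g <- make_genome(cfg)
    sim <- simulate_pileups(g, cfg)
    cand <- call_sites(sim$pileup, reference = g$sequence)
    ann <- annotate_sites(cand, g$genes, g$sequence, snps = g$snps,
                          known = g$known, pseudogenes = g$pseudogenes,
                          repeats = g$repeats)
    fl <- apply_filters(ann)
    groups <- stats::setNames(sim$samples$group, sim$samples$sample)
    sm <- build_site_matrix(fl$retained, samples = sim$samples$sample)
    .fixtures$default <- list(cfg = cfg, genome = g, sim = sim, cand = cand,
                              ann = ann, fl = fl, sm = sm, groups = groups)
  }
  .fixtures$default
}

## single pileup row builder for caller unit tests
pileup_row <- function(ref, counts, quals, pos = 100, contig = "chr1",
                       sample = "S1", n_excluded = 0) {
  get0q <- function(b) if (b %in% names(counts)) counts[[b]] else 0L
  getq <- function(b) if (b %in% names(quals)) quals[[b]] else NA_real_
  data.frame(contig = contig, pos = pos, ref = ref, sample = sample,
             nA = get0q("A"), nC = get0q("C"), nG = get0q("G"), nT = get0q("T"),
             qA = getq("A"), qC = getq("C"), qG = getq("G"), qT = getq("T"),
             n_excluded = n_excluded, stringsAsFactors = FALSE)
}

## random pileup table for oracle-equivalence checks
random_pileup <- function(n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  counts <- matrix(rpois(4 * n, 4), n, 4, dimnames = list(NULL, bases))
  counts[cbind(seq_len(n), match(ref, bases))] <-
    counts[cbind(seq_len(n), match(ref, bases))] + rpois(n, 20)
  quals <- matrix(round(runif(4 * n, 15, 40), 1), n, 4)
  quals[counts == 0] <- NA
  data.frame(contig = "chr1", pos = seq_len(n), ref = ref, sample = "S1",
             nA = counts[, 1], nC = counts[, 2], nG = counts[, 3],
             nT = counts[, 4], qA = quals[, 1], qC = quals[, 2],
             qG = quals[, 3], qT = quals[, 4], n_excluded = rpois(n, 2),
             stringsAsFactors = FALSE)
}

## minimal hand-built gene-model table for region/recoding unit tests
tiny_gene_models <- function() {
  row <- function(feature, start, end, strand, gid, tid, name, bio)
    data.frame(contig = "chrT", source = "test", feature = feature,
               start = start, end = end, strand = strand, gene_id = gid,
               transcript_id = tid, gene_name = name, biotype = bio,
               stringsAsFactors = FALSE)
  rbind(
    ## plus-strand coding gene: 5'UTR 101-130, CDS 131-160 + 201-230 (intron
    ## 161-200), 3'UTR 231-300
    row("gene", 101, 300, "+", "gX", NA, "GX", "protein_coding"),
    row("transcript", 101, 300, "+", "gX", "tX", "GX", "protein_coding"),
    row("exon", 101, 160, "+", "gX", "tX", "GX", "protein_coding"),
    row("exon", 201, 300, "+", "gX", "tX", "GX", "protein_coding"),
    row("five_prime_utr", 101, 130, "+", "gX", "tX", "GX", "protein_coding"),
    row("CDS", 131, 160, "+", "gX", "tX", "GX", "protein_coding"),
    row("CDS", 201, 230, "+", "gX", "tX", "GX", "protein_coding"),
    row("three_prime_utr", 231, 300, "+", "gX", "tX", "GX", "protein_coding"),
    ## overlapping second transcript whose intron spans 251-300 (tests the
    ## 3'UTR > intronic precedence)
    row("gene", 101, 500, "+", "gY", NA, "GY", "protein_coding"),
    row("transcript", 101, 500, "+", "gY", "tY", "GY", "protein_coding"),
    row("exon", 101, 240, "+", "gY", "tY", "GY", "protein_coding"),
    row("exon", 401, 500, "+", "gY", "tY", "GY", "protein_coding"),
    ## minus-strand coding gene further along: CDS 601-660
    row("gene", 601, 700, "-", "gZ", NA, "GZ", "protein_coding"),
    row("transcript", 601, 700, "-", "gZ", "tZ", "GZ", "protein_coding"),
    row("exon", 601, 700, "-", "gZ", "tZ", "GZ", "protein_coding"),
    row("CDS", 601, 660, "-", "gZ", "tZ", "GZ", "protein_coding"))
}
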