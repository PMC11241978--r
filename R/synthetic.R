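## Synthetic editome generator: a miniature genome with gene models, repeat
## architecture (Alu/simple/low-complexity), SNPs, pseudogene copies and
## planted editing truth; per-sample pileups with negative-binomial coverage
## and binomial editing; and an expression matrix with editing-coupled genes.
## Everything is seeded and byte-deterministic, and the planted TruthSet is
## the oracle all downstream acceptance checks run against.

#' Configuration for the synthetic editome generator
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: two phenotype groups of 20 samples, negative-binomial coverage with
#' mean 50 (size 5), 200 true A-to-I sites with Beta(2,5) baseline
#' frequencies, 1e-3 per-base sequencing error, Hardy-Weinberg SNP artifacts
#' at allele frequency 0.3, and half of the true sites present in the known
#' editing-site catalog.
#'
#' @param genome_length contig length in bases (single contig).
#' @param n_genes number of genes laid out along the contig.
#' @param n_samples_per_group samples per phenotype group (two groups).
#' @param coverage_mean,coverage_dispersion negative-binomial mean and size
#'   for per-site read depth.
#' @param baseline_freq_alpha,baseline_freq_beta Beta parameters for per-site
#'   baseline (group 1) editing frequency.
#' @param global_shift additive frequency change applied to group 2
#'   (may be negative); planted frequencies are clipped to \[0,1\].
#' @param n_true_sites number of planted true editing sites.
#' @param n_snp_artifacts germline SNP artifact sites (in the SNP track,
#'   absent from the known catalog).
#' @param n_homopolymer_artifacts low-quality mismatch sites adjacent to a
#'   planted homopolymer run.
#' @param n_pseudogene_copies verbatim copies of one gene placed in
#'   intergenic space (true multi-mapping flanks).
#' @param n_pseudogene_sites "multimap" artifact sites planted inside the
#'   pseudogene copies.
#' @param n_low_coverage_artifacts sites simulated at ~8\% of normal depth.
#' @param region_mix named proportions over region classes for true sites.
#' @param alu_fraction fraction of intronic/3'UTR true sites placed inside
#'   Alu intervals (human A-to-I editing is predominantly Alu-borne).
#' @param known_fraction fraction of true sites written to the known
#'   editing-site catalog.
#' @param error_rate per-base sequencing error rate at unplanted positions.
#' @param dup_rate expected fraction of reads flagged duplicate/vendor-failed
#'   (reported in the pileup `n_excluded` column).
#' @param hw_allele_freq Hardy-Weinberg alternate-allele frequency for SNP
#'   artifacts.
#' @param frac_intronic_lost fraction of intronic true sites silenced
#'   (frequency 0) in group 2 — a region-composition shift dial.
#' @param frac_utr3_gained fraction of 3'UTR true sites present only in
#'   group 2 (frequency 0 in group 1).
#' @param coupling_genes named numeric vector: gene name -> coupling slope of
#'   log expression on the standardized per-sample mean editing frequency.
#' @param adar_like_genes genes treated as ADAR homologs (positively coupled).
#' @param seed integer RNG seed; identical configs give byte-identical files.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(genome_length = 100000L,
                             n_genes = 30L,
                             n_samples_per_group = 20L,
                             coverage_mean = 50,
                             coverage_dispersion = 5,
                             baseline_freq_alpha = 2,
                             baseline_freq_beta = 5,
                             global_shift = 0,
                             n_true_sites = 200L,
                             n_snp_artifacts = 20L,
                             n_homopolymer_artifacts = 20L,
                             n_pseudogene_copies = 2L,
                             n_pseudogene_sites = 10L,
                             n_low_coverage_artifacts = 10L,
                             region_mix = c("intronic" = 0.50, "3'UTR" = 0.20,
                                            "exonic" = 0.10, "5'UTR" = 0.05,
                                            "ncRNA" = 0.10,
                                            "NMD/processed_transcript" = 0.05),
                             alu_fraction = 0.7,
                             known_fraction = 0.5,
                             error_rate = 1e-3,
                             dup_rate = 0.05,
                             hw_allele_freq = 0.3,
                             frac_intronic_lost = 0,
                             frac_utr3_gained = 0,
                             coupling_genes = c(ADAR1 = 2.0, ADAR2 = 1.5),
                             adar_like_genes = c("ADAR1", "ADAR2"),
                             seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
              baseline_freq_alpha = baseline_freq_alpha,
              baseline_freq_beta = baseline_freq_beta,
              global_shift = global_shift,
              n_true_sites = as.integer(n_true_sites),
              n_snp_artifacts = as.integer(n_snp_artifacts),
              n_homopolymer_artifacts = as.integer(n_homopolymer_artifacts),
              n_pseudogene_copies = as.integer(n_pseudogene_copies),
              n_pseudogene_sites = as.integer(n_pseudogene_sites),
              n_low_coverage_artifacts = as.integer(n_low_coverage_artifacts),
              region_mix = region_mix, alu_fraction = alu_fraction,
              known_fraction = known_fraction, error_rate = error_rate,
              dup_rate = dup_rate, hw_allele_freq = hw_allele_freq,
              frac_intronic_lost = frac_intronic_lost,
              frac_utr3_gained = frac_utr3_gained,
              coupling_genes = coupling_genes, adar_like_genes = adar_like_genes,
              seed = as.integer(seed))
  counts <- cfg[c("genome_length", "n_genes", "n_samples_per_group", "n_true_sites",
                  "n_snp_artifacts", "n_homopolymer_artifacts", "n_pseudogene_copies",
                  "n_pseudogene_sites", "n_low_coverage_artifacts")]
  if (any(unlist(counts) < 0)) stopf("synthetic_config: counts must be >= 0")
  if (cfg$genome_length < 10000) stopf("synthetic_config: genome_length must be >= 10 kb")
  if (cfg$baseline_freq_alpha <= 0 || cfg$baseline_freq_beta <= 0)
    stopf("synthetic_config: Beta parameters must be positive")
  if (abs(sum(region_mix) - 1) > 1e-6) stopf("synthetic_config: region_mix must sum to 1")
  for (p in c("alu_fraction", "known_fraction", "error_rate", "dup_rate",
              "hw_allele_freq", "frac_intronic_lost", "frac_utr3_gained"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("synthetic_config: %s must be in [0,1]", p)
  structure(cfg, class = "synthetic_config")
}

set_seed_stage <- function(seed, stage) {
  ## distinct deterministic streams per generator stage
  set.seed((seed + 7919L * stage) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

## mirror a relative interval within a span of length L (minus-strand layout)
mirror_iv <- function(s, e, L) c(L - e + 1L, L - s + 1L)

CODING_SPAN <- 2150L
NC_SPAN <- 600L
GENE_GAP <- 1000L

coding_template <- function(strand) {
  ## relative 1-based feature intervals of a coding gene (span 2150)
  f <- list(five_prime_utr = rbind(c(1L, 150L)),
            CDS = rbind(c(151L, 300L), c(801L, 1100L), c(1601L, 1750L)),
            three_prime_utr = rbind(c(1751L, 2150L)),
            exon = rbind(c(1L, 300L), c(801L, 1100L), c(1601L, 2150L)),
            intron = rbind(c(301L, 800L), c(1101L, 1600L)))
  if (strand == "-")
    f <- lapply(f, function(m) {
      m2 <- t(apply(m, 1, function(r) mirror_iv(r[1], r[2], CODING_SPAN)))
      m2[order(m2[, 1]), , drop = FALSE]
    })
  f
}

#' Generate a miniature genome with annotation tracks and planted truth
#'
#' Lays out alternating-strand genes (protein-coding with UTRs/CDS/introns,
#' plus ncRNA and processed-transcript genes), places Alu, simple-repeat and
#' low-complexity intervals, copies one gene into intergenic space as a
#' pseudogene, and plants true editing sites (A on the gene strand) together
#' with SNP, homopolymer, multi-mapping and low-coverage artifact classes.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory; when given, writes
#'   `genome.fa`, `genes.gtf`, `repeats.bed`, `pseudogenes.bed`, `snps.vcf`,
#'   `known_sites.tsv`, `truth_sites.tsv`, `truth_artifacts.tsv`.
#' @return object of class `synthetic_genome`: list with `sequence`
#'   (Biostrings::DNAStringSet), `contig`, `genes` (gene-model data.frame),
#'   `repeats`, `pseudogenes`, `snps`, `known`, and `truth` (class
#'   `truth_set` with `true_sites`, `artifact_sites`, `coupled_genes`,
#'   `adar_like_genes`).
#' @export
make_genome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set_seed_stage(cfg$seed, 1L)
  contig <- "chr1"
  L <- cfg$genome_length

  n_nc <- max(1L, cfg$n_genes %/% 10L)
  n_pt <- if (cfg$n_genes >= 8L) max(1L, cfg$n_genes %/% 20L) else 0L
  n_coding <- cfg$n_genes - n_nc - n_pt
  if (n_coding < 3L) stopf("make_genome: need at least 3 coding genes (n_genes too small)")

  spans <- c(rep(CODING_SPAN, n_coding), rep(NC_SPAN, n_nc + n_pt))
  tail_needed <- cfg$n_pseudogene_copies * (CODING_SPAN + 200L) +
    cfg$n_homopolymer_artifacts * 20L + 500L
  required <- sum(spans) + (cfg$n_genes + 1L) * GENE_GAP + tail_needed
  if (required > L)
    stopf("make_genome: infeasible packing — need %d bases, genome_length is %d",
          required, L)

  seqc <- sample(BASES, L, replace = TRUE)

  ## ---- gene layout -------------------------------------------------------
  biotype <- c(rep("protein_coding", n_coding), rep("ncRNA", n_nc),
               rep("processed_transcript", n_pt))
  gene_name <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  gene_name[seq_along(cfg$adar_like_genes)] <- cfg$adar_like_genes
  strand <- rep(c("+", "-"), length.out = cfg$n_genes)

  gm <- list(); reps <- list()
  pools <- list()  # per-class position/gene pools
  add_pool <- function(class, pos, gi) {
    if (!length(pos)) return()
    pools[[class]][[length(pools[[class]]) + 1L]] <<-
      data.frame(pos = pos, gene = gene_name[gi], strand = strand[gi],
                 stringsAsFactors = FALSE)
  }
  for (cl in c("intron_alu", "intron_plain", "utr3_alu", "utr3_plain",
               "cds", "utr5", "ncRNA", "NMD/processed_transcript"))
    pools[[cl]] <- list()

  cursor <- GENE_GAP + 1L
  gene_rows <- function(gi, start, end, feats) {
    gid <- sprintf("g%03d", gi); tid <- sprintf("t%03d", gi)
    rows <- list(data.frame(contig = contig, source = "synthetic",
                            feature = c("gene", "transcript"),
                            start = start, end = end, strand = strand[gi],
                            gene_id = gid, transcript_id = c(NA, tid),
                            gene_name = gene_name[gi], biotype = biotype[gi],
                            stringsAsFactors = FALSE))
    for (ft in names(feats)) {
      m <- feats[[ft]]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, source = "synthetic", feature = ft,
        start = start + m[, 1] - 1L, end = start + m[, 2] - 1L,
        strand = strand[gi], gene_id = gid, transcript_id = tid,
        gene_name = gene_name[gi], biotype = biotype[gi],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  for (gi in seq_len(cfg$n_genes)) {
    if (biotype[gi] == "protein_coding") {
      start <- cursor; end <- cursor + CODING_SPAN - 1L
      tpl <- coding_template(strand[gi])
      gm[[gi]] <- gene_rows(gi, start, end,
                            tpl[c("exon", "CDS", "five_prime_utr", "three_prime_utr")])
      introns <- tpl$intron + start - 1L
      iA <- introns[1, ]; iB <- introns[2, ]
      alu <- c(iA[1] + 100L, iA[1] + 399L)
      srep <- c(iB[1] + 50L, iB[1] + 109L)
      lcom <- c(iB[1] + 150L, iB[1] + 209L)
      reps[[length(reps) + 1L]] <- data.frame(
        contig = contig, start = c(alu[1], srep[1], lcom[1]),
        end = c(alu[2], srep[2], lcom[2]),
        name = sprintf("rep_g%03d_%s", gi, c("alu", "sr", "lc")),
        class = c("Alu", "Simple_repeat", "Low_complexity"),
        stringsAsFactors = FALSE)
      u3 <- tpl$three_prime_utr[1, ] + start - 1L
      utr3_alu <- NULL
      if (gi %% 2L == 0L) {
        utr3_alu <- c(u3[1] + 125L, u3[1] + 274L)
        reps[[length(reps) + 1L]] <- data.frame(
          contig = contig, start = utr3_alu[1], end = utr3_alu[2],
          name = sprintf("rep_g%03d_u3alu", gi), class = "Alu",
          stringsAsFactors = FALSE)
      }
      add_pool("intron_alu", alu[1]:alu[2], gi)
      plain <- setdiff(c(iA[1]:iA[2], iB[1]:iB[2]),
                       c(alu[1]:alu[2], srep[1]:srep[2], lcom[1]:lcom[2]))
      add_pool("intron_plain", plain, gi)
      u3_pos <- u3[1]:u3[2]
      if (!is.null(utr3_alu)) {
        add_pool("utr3_alu", utr3_alu[1]:utr3_alu[2], gi)
        u3_pos <- setdiff(u3_pos, utr3_alu[1]:utr3_alu[2])
      }
      add_pool("utr3_plain", u3_pos, gi)
      cds <- tpl$CDS + start - 1L
      add_pool("cds", unlist(apply(cds, 1, function(r) r[1]:r[2], simplify = FALSE)), gi)
      u5 <- tpl$five_prime_utr[1, ] + start - 1L
      add_pool("utr5", u5[1]:u5[2], gi)
      cursor <- end + GENE_GAP + 1L
    } else {
      start <- cursor; end <- cursor + NC_SPAN - 1L
      gm[[gi]] <- gene_rows(gi, start, end, list(exon = rbind(c(1L, NC_SPAN))))
      cls <- if (biotype[gi] == "ncRNA") "ncRNA" else "NMD/processed_transcript"
      add_pool(cls, start:end, gi)
      cursor <- end + GENE_GAP + 1L
    }
  }
  gm <- do.call(rbind, gm)
  tail_start <- cursor

  ## ---- true sites --------------------------------------------------------
  used <- rep(FALSE, L)
  pools <- lapply(pools, function(x) if (length(x)) do.call(rbind, x) else NULL)
  draw <- function(pool_df, n) {
    if (is.null(pool_df)) pool_df <- data.frame(pos = integer(), gene = character(),
                                                strand = character())
    ok <- pool_df[!used[pool_df$pos], , drop = FALSE]
    if (nrow(ok) < n)
      stopf("make_genome: infeasible packing — pool exhausted (need %d, have %d)",
            n, nrow(ok))
    sel <- ok[sample.int(nrow(ok), n), , drop = FALSE]
    used[sel$pos] <<- TRUE
    sel
  }

  n_per <- floor(cfg$region_mix * cfg$n_true_sites)
  n_per[1] <- n_per[1] + cfg$n_true_sites - sum(n_per)
  true_list <- list()
  for (cl in names(n_per)) {
    n_cl <- n_per[[cl]]
    if (n_cl == 0) next
    if (cl %in% c("intronic", "3'UTR")) {
      n_alu <- round(cfg$alu_fraction * n_cl)
      key <- if (cl == "intronic") "intron" else "utr3"
      sel <- rbind(draw(pools[[paste0(key, "_alu")]], n_alu),
                   draw(pools[[paste0(key, "_plain")]], n_cl - n_alu))
    } else {
      key <- switch(cl, exonic = "cds", `5'UTR` = "utr5", cl)
      sel <- draw(pools[[key]], n_cl)
    }
    sel$region_class <- cl
    true_list[[cl]] <- sel
  }
  true <- do.call(rbind, true_list)
  rownames(true) <- NULL
  ## plant an editable adenosine on the gene strand
  seqc[true$pos] <- ifelse(true$strand == "+", "A", "T")
  g1 <- clip01(stats::rbeta(nrow(true), cfg$baseline_freq_alpha, cfg$baseline_freq_beta))
  g1 <- pmin(pmax(g1, 0.02), 0.98)
  g2 <- clip01(g1 + cfg$global_shift)
  if (cfg$frac_intronic_lost > 0) {
    idx <- which(true$region_class == "intronic")
    lost <- idx[seq_len(round(cfg$frac_intronic_lost * length(idx)))]
    g2[lost] <- 0
  }
  if (cfg$frac_utr3_gained > 0) {
    idx <- which(true$region_class == "3'UTR")
    gained <- idx[seq_len(round(cfg$frac_utr3_gained * length(idx)))]
    g1[gained] <- 0
    g2[gained] <- pmax(g2[gained], 0.3)
  }
  true_sites <- data.frame(contig = contig, pos = true$pos, strand = true$strand,
                           ref = seqc[true$pos],
                           alt = ifelse(true$strand == "+", "G", "C"),
                           group1_freq = g1, group2_freq = g2,
                           gene = true$gene, region_class = true$region_class,
                           stringsAsFactors = FALSE)
  true_sites <- true_sites[order(true_sites$pos), ]
  rownames(true_sites) <- NULL

  ## ---- artifacts ---------------------------------------------------------
  art <- list()
  if (cfg$n_snp_artifacts > 0) {
    sel <- draw(pools$intron_plain, cfg$n_snp_artifacts)
    seqc[sel$pos] <- "A"
    art$snp <- data.frame(contig = contig, pos = sel$pos, artifact_class = "snp",
                          ref = "A", alt = "G", freq = NA_real_,
                          stringsAsFactors = FALSE)
  }
  if (cfg$n_low_coverage_artifacts > 0) {
    sel <- draw(pools$intron_plain, cfg$n_low_coverage_artifacts)
    seqc[sel$pos] <- "A"
    art$low_coverage <- data.frame(contig = contig, pos = sel$pos,
                                   artifact_class = "low_coverage",
                                   ref = "A", alt = "G", freq = 0.3,
                                   stringsAsFactors = FALSE)
  }

  ## pseudogene copies (verbatim copy of a coding gene into the tail)
  src_gi <- min(3L, n_coding)
  src_rows <- gm[gm$feature == "gene" & gm$gene_id == sprintf("g%03d", src_gi), ]
  pseudo <- NULL; pg_cursor <- tail_start
  if (cfg$n_pseudogene_copies > 0) {
    pg <- list()
    for (k in seq_len(cfg$n_pseudogene_copies)) {
      s <- pg_cursor; e <- s + CODING_SPAN - 1L
      seqc[s:e] <- seqc[src_rows$start:src_rows$end]
      pg[[k]] <- data.frame(contig = contig, start = s, end = e,
                            name = sprintf("psi_g%03d_%d", src_gi, k),
                            class = "pseudogene", stringsAsFactors = FALSE)
      pg_cursor <- e + 200L + 1L
    }
    pseudo <- do.call(rbind, pg)
    if (cfg$n_pseudogene_sites > 0) {
      interior <- unlist(lapply(seq_len(nrow(pseudo)), function(k)
        (pseudo$start[k] + 60L):(pseudo$end[k] - 60L)))
      interior <- interior[seqc[interior] == "A" & !used[interior]]
      sel <- interior[sample.int(length(interior),
                                 min(cfg$n_pseudogene_sites, length(interior)))]
      used[sel] <- TRUE
      art$multimap <- data.frame(contig = contig, pos = sel,
                                 artifact_class = "multimap",
                                 ref = "A", alt = "G", freq = 0.3,
                                 stringsAsFactors = FALSE)
    }
  }

  ## homopolymer-adjacent low-quality artifacts, in tail intergenic space
  if (cfg$n_homopolymer_artifacts > 0) {
    hp_pos <- pg_cursor + 10L + 20L * (seq_len(cfg$n_homopolymer_artifacts) - 1L)
    if (max(hp_pos) > L - 300L) stopf("make_genome: infeasible packing for homopolymers")
    for (p in hp_pos) seqc[(p - 5L):(p - 1L)] <- "A"
    seqc[hp_pos] <- "C"
    used[hp_pos] <- TRUE
    art$homopolymer <- data.frame(contig = contig, pos = hp_pos,
                                  artifact_class = "homopolymer_error",
                                  ref = "C", alt = "T", freq = 0.3,
                                  stringsAsFactors = FALSE)
    ## an unrelated repeat class in the far tail
    reps[[length(reps) + 1L]] <- data.frame(
      contig = contig, start = L - 250L, end = L - 51L,
      name = "rep_tail_other", class = "Other_repeat", stringsAsFactors = FALSE)
  }
  artifact_sites <- do.call(rbind, art)
  rownames(artifact_sites) <- NULL
  repeats <- do.call(rbind, reps)

  ## ---- tracks ------------------------------------------------------------
  snps <- if (!is.null(art$snp))
    data.frame(contig = contig, pos = art$snp$pos,
               id = sprintf("rs%06d", seq_len(nrow(art$snp))),
               ref = art$snp$ref, alt = art$snp$alt, stringsAsFactors = FALSE)
  else data.frame(contig = character(), pos = integer(), id = character(),
                  ref = character(), alt = character())
  n_known <- round(cfg$known_fraction * nrow(true_sites))
  known_idx <- sort(sample.int(nrow(true_sites), n_known))
  known <- true_sites[known_idx, c("contig", "pos", "ref", "alt")]
  rownames(known) <- NULL

  truth <- structure(list(true_sites = true_sites, artifact_sites = artifact_sites,
                          coupled_genes = cfg$coupling_genes,
                          adar_like_genes = cfg$adar_like_genes,
                          known_idx = known_idx),
                     class = "truth_set")
  seq_dss <- Biostrings::DNAStringSet(paste(seqc, collapse = ""))
  names(seq_dss) <- contig
  gen <- structure(list(sequence = seq_dss, contig = contig, genes = gm,
                        repeats = repeats, pseudogenes = pseudo, snps = snps,
                        known = known, truth = truth, config = cfg),
                   class = "synthetic_genome")
  if (!is.null(dir)) write_genome(gen, dir)
  gen
}

#' Write a synthetic genome bundle to disk
#' @param genome a `synthetic_genome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome$sequence, file.path(dir, "genome.fa"))
  write_gene_models(genome$genes, file.path(dir, "genes.gtf"))
  write_bed(genome$repeats, file.path(dir, "repeats.bed"))
  if (!is.null(genome$pseudogenes))
    write_bed(genome$pseudogenes, file.path(dir, "pseudogenes.bed"))
  write_vcf_lite(genome$snps, file.path(dir, "snps.vcf"))
  write_known_sites(genome$known, file.path(dir, "known_sites.tsv"))
  write_tsv(genome$truth$true_sites, file.path(dir, "truth_sites.tsv"))
  write_tsv(genome$truth$artifact_sites, file.path(dir, "truth_artifacts.tsv"))
  invisible(dir)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %s (%d bp), %d genes, %d repeat intervals\n",
              x$contig, Biostrings::width(x$sequence)[1],
              sum(x$genes$feature == "gene"), nrow(x$repeats)))
  cat(sprintf("planted truth: %d true sites, %d artifact sites\n",
              nrow(x$truth$true_sites), nrow(x$truth$artifact_sites)))
  invisible(x)
}

hw_genotypes <- function(n, p) {
  ## genotype dosage 0/1/2 under Hardy-Weinberg equilibrium
  sample(0:2, n, replace = TRUE, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
}

rq <- function(n, mean) round(stats::rnorm(n, mean, 2), 1)

build_pileup_rows <- function(contig, pos, ref, alt, depth, alt_n, q_alt_mean,
                              sample, dup_rate) {
  n <- length(pos)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  quals <- matrix(NA_real_, n, 4, dimnames = list(NULL, BASES))
  ref_n <- depth - alt_n
  counts[cbind(seq_len(n), match(ref, BASES))] <- as.integer(ref_n)
  ai <- match(alt, BASES)
  counts[cbind(seq_len(n), ai)] <- counts[cbind(seq_len(n), ai)] + as.integer(alt_n)
  quals[cbind(seq_len(n), match(ref, BASES))] <- ifelse(ref_n > 0, rq(n, 35), NA)
  qalt <- rep(NA_real_, n)
  has_alt <- alt_n > 0
  qalt[has_alt] <- rq(sum(has_alt), q_alt_mean[has_alt])
  quals[cbind(seq_len(n), ai)] <- qalt
  data.frame(contig = contig, pos = pos, ref = ref, sample = sample,
             nA = counts[, 1], nC = counts[, 2], nG = counts[, 3], nT = counts[, 4],
             qA = quals[, 1], qC = quals[, 2], qG = quals[, 3], qT = quals[, 4],
             n_excluded = stats::rbinom(n, depth, dup_rate),
             stringsAsFactors = FALSE)
}

#' Simulate per-sample RNA pileups (and paired gDNA for a validation subset)
#'
#' Depth is negative binomial; edited-base counts are binomial at the planted
#' group frequency; SNP artifacts receive a per-sample Hardy-Weinberg
#' genotype applied identically to cDNA and gDNA; homopolymer artifacts get
#' low-quality (mean Q18) alternate bases; sequencing errors are planted at
#' unoccupied positions at `error_rate`.
#'
#' @param genome a `synthetic_genome`.
#' @param config the same [synthetic_config()]; defaults to the one inside
#'   `genome`.
#' @param n_validation_sites number of true sites (plus all SNP artifacts)
#'   that also receive a paired gDNA pileup.
#' @return object of class `synthetic_pileups`: list with `pileup` (RNA
#'   pileup data.frame over all samples), `gdna` (paired genomic pileup over
#'   the validation subset), `samples` (sample/group table), `mean_editing`
#'   (per-sample mean observed frequency over true sites), `genotypes`
#'   (SNP-artifact dosage matrix), `validation_sites`.
#' @export
simulate_pileups <- function(genome, config = genome$config,
                             n_validation_sites = 30L) {
  cfg <- config
  set_seed_stage(cfg$seed, 2L)
  truth <- genome$truth
  contig <- genome$contig
  seqc <- strsplit(as.character(genome$sequence[[1]]), "")[[1]]
  L <- length(seqc)
  ts <- truth$true_sites
  as_ <- truth$artifact_sites
  if (nrow(ts) && any(seqc[ts$pos] != ts$ref))
    stopf("simulate_pileups: truth sites do not lie on the reference")

  n <- cfg$n_samples_per_group
  samples <- data.frame(
    sample = c(sprintf("CTL%02d", seq_len(n)), sprintf("ALS%02d", seq_len(n))),
    group = rep(c("control", "case"), each = n), stringsAsFactors = FALSE)

  snp <- as_[as_$artifact_class == "snp", , drop = FALSE]
  genotypes <- if (nrow(snp))
    matrix(hw_genotypes(nrow(snp) * nrow(samples), cfg$hw_allele_freq),
           nrow(snp), nrow(samples),
           dimnames = list(site_key(snp$contig, snp$pos), samples$sample))
  else NULL

  planted <- rbind(
    if (nrow(ts)) data.frame(pos = ts$pos, ref = ts$ref, alt = ts$alt,
                             class = "true", f1 = ts$group1_freq,
                             f2 = ts$group2_freq, covm = 1, qm = 35),
    if (nrow(as_)) data.frame(pos = as_$pos, ref = as_$ref, alt = as_$alt,
                              class = as_$artifact_class, f1 = as_$freq,
                              f2 = as_$freq,
                              covm = ifelse(as_$artifact_class == "low_coverage",
                                            0.08, 1),
                              qm = ifelse(as_$artifact_class == "homopolymer_error",
                                          18, 35)))
  planted_pos <- planted$pos
  snp_rows <- which(planted$class == "snp")

  mean_editing <- numeric(nrow(samples))
  names(mean_editing) <- samples$sample
  out <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    grp <- samples$group[j]
    np <- nrow(planted)
    depth <- stats::rnbinom(np, mu = cfg$coverage_mean * planted$covm,
                            size = cfg$coverage_dispersion)
    freq <- if (grp == "control") planted$f1 else planted$f2
    if (length(snp_rows)) freq[snp_rows] <- genotypes[, j] / 2
    alt_n <- stats::rbinom(np, depth, freq)
    rows <- build_pileup_rows(contig, planted_pos, planted$ref, planted$alt,
                              depth, alt_n, planted$qm, samples$sample[j],
                              cfg$dup_rate)
    ## sequencing error at unplanted positions
    edepth <- stats::rnbinom(L, mu = cfg$coverage_mean, size = cfg$coverage_dispersion)
    err <- stats::rbinom(L, edepth, cfg$error_rate)
    err[planted_pos] <- 0L
    epos <- which(err > 0L)
    if (length(epos)) {
      eref <- seqc[epos]
      ealt <- vapply(eref, function(r) sample(setdiff(BASES, r), 1), "")
      erows <- build_pileup_rows(contig, epos, eref, ealt, edepth[epos],
                                 err[epos], rep(35, length(epos)),
                                 samples$sample[j], cfg$dup_rate)
      rows <- rbind(rows, erows)
    }
    rows <- rows[order(rows$pos), ]
    out[[j]] <- rows
    ti <- which(planted$class == "true")
    obs <- alt_n[ti] / pmax(depth[ti], 1L)
    mean_editing[j] <- mean(obs[depth[ti] > 0])
  }
  pileup <- do.call(rbind, out)
  rownames(pileup) <- NULL

  ## paired gDNA over the validation subset: true sites are reference-
  ## homozygous (error only); SNP artifacts show their genotype fraction
  nv <- min(n_validation_sites, nrow(ts))
  vt_idx <- if (nv > 0) sort(sample.int(nrow(ts), nv)) else integer()
  vsites <- rbind(
    if (length(vt_idx)) data.frame(pos = ts$pos[vt_idx], ref = ts$ref[vt_idx],
                                   alt = ts$alt[vt_idx], class = "true"),
    if (nrow(snp)) data.frame(pos = snp$pos, ref = snp$ref, alt = snp$alt,
                              class = "snp"))
  gd <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    nvv <- nrow(vsites)
    depth <- stats::rnbinom(nvv, mu = cfg$coverage_mean, size = cfg$coverage_dispersion)
    ## true sites: reference-homozygous up to sequencing error; SNPs: genotype/2
    gfreq <- rep(cfg$error_rate, nvv)
    is_snp <- vsites$class == "snp"
    if (any(is_snp))
      gfreq[is_snp] <- genotypes[match(vsites$pos[is_snp], snp$pos), j] / 2
    alt_n <- stats::rbinom(nvv, depth, gfreq)
    gd[[j]] <- build_pileup_rows(contig, vsites$pos, vsites$ref, vsites$alt,
                                 depth, alt_n, rep(35, nvv),
                                 samples$sample[j], cfg$dup_rate)
  }
  gdna <- do.call(rbind, gd)
  rownames(gdna) <- NULL

  structure(list(pileup = pileup, gdna = gdna, samples = samples,
                 mean_editing = mean_editing, genotypes = genotypes,
                 validation_sites = vsites),
            class = "synthetic_pileups")
}

#' Simulate a gene-by-sample expression counts matrix
#'
#' Counts are negative binomial around gene-specific means. For coupled genes
#' (including the designated ADAR-like genes) the log mean is
#' `base + slope * z`, where `z` is the standardized per-sample mean editing
#' frequency; uncoupled genes are independent of editing.
#'
#' @param genome a `synthetic_genome`.
#' @param mean_editing named per-sample mean editing frequencies (e.g. from
#'   [simulate_pileups()]).
#' @param config the generator config.
#' @param nb_size negative-binomial size (inverse dispersion) of counts.
#' @return integer matrix, genes x samples.
#' @export
simulate_expression <- function(genome, mean_editing, config = genome$config,
                                nb_size = 10) {
  cfg <- config
  set_seed_stage(cfg$seed, 3L)
  genes <- unique(genome$genes$gene_name[genome$genes$feature == "gene"])
  ns <- length(mean_editing)
  z <- as.numeric(scale(mean_editing))
  if (any(!is.finite(z))) z <- rep(0, ns)
  base_mu <- exp(stats::rnorm(length(genes), log(300), 0.7))
  slopes <- rep(0, length(genes))
  names(slopes) <- genes
  cg <- cfg$coupling_genes[names(cfg$coupling_genes) %in% genes]
  slopes[names(cg)] <- cg
  mu <- exp(log(base_mu) + outer(slopes, z))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = nb_size),
                   nrow = length(genes),
                   dimnames = list(genes, names(mean_editing)))
  counts
}

#' Simulate paired amplicon cDNA/gDNA pileups for targeted validation
#'
#' Fresh validation cohorts (default 3 samples per group, amplicon depth
#' 5000) over a subset of the planted true sites; gDNA is reference-
#' homozygous at true sites and carries Hardy-Weinberg genotypes at SNP
#' artifact sites.
#'
#' @param genome a `synthetic_genome`.
#' @param n_sites number of true sites on the amplicon panel.
#' @param n_per_group validation samples per group.
#' @param coverage amplicon depth (negative-binomial mean).
#' @param include_snps include the SNP artifact sites on the panel.
#' @param config generator config.
#' @return list with `cdna`, `gdna` pileup data.frames, `samples`, and
#'   `panel` (the site table with planted group frequencies).
#' @export
simulate_validation <- function(genome, n_sites = 30L, n_per_group = 3L,
                                coverage = 5000, include_snps = TRUE,
                                config = genome$config) {
  cfg <- config
  set_seed_stage(cfg$seed, 4L)
  ts <- genome$truth$true_sites
  idx <- sort(sample.int(nrow(ts), min(n_sites, nrow(ts))))
  panel <- data.frame(pos = ts$pos[idx], ref = ts$ref[idx], alt = ts$alt[idx],
                      f1 = ts$group1_freq[idx], f2 = ts$group2_freq[idx],
                      class = "true", stringsAsFactors = FALSE)
  snp <- genome$truth$artifact_sites
  snp <- snp[snp$artifact_class == "snp", , drop = FALSE]
  if (include_snps && nrow(snp))
    panel <- rbind(panel, data.frame(pos = snp$pos, ref = snp$ref, alt = snp$alt,
                                     f1 = NA, f2 = NA, class = "snp",
                                     stringsAsFactors = FALSE))
  samples <- data.frame(
    sample = c(sprintf("VC%02d", seq_len(n_per_group)),
               sprintf("VA%02d", seq_len(n_per_group))),
    group = rep(c("control", "case"), each = n_per_group),
    stringsAsFactors = FALSE)
  genos <- matrix(hw_genotypes(nrow(panel) * nrow(samples), cfg$hw_allele_freq),
                  nrow(panel), nrow(samples))
  cd <- gd <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    np <- nrow(panel)
    f <- if (samples$group[j] == "control") panel$f1 else panel$f2
    f[panel$class == "snp"] <- genos[panel$class == "snp", j] / 2
    dep_c <- stats::rnbinom(np, mu = coverage, size = cfg$coverage_dispersion * 4)
    cd[[j]] <- build_pileup_rows(genome$contig, panel$pos, panel$ref, panel$alt,
                                 dep_c, stats::rbinom(np, dep_c, f),
                                 rep(35, np), samples$sample[j], cfg$dup_rate)
    gf <- ifelse(panel$class == "snp", genos[, j] / 2, cfg$error_rate)
    dep_g <- stats::rnbinom(np, mu = coverage, size = cfg$coverage_dispersion * 4)
    gd[[j]] <- build_pileup_rows(genome$contig, panel$pos, panel$ref, panel$alt,
                                 dep_g, stats::rbinom(np, dep_g, gf),
                                 rep(35, np), samples$sample[j], cfg$dup_rate)
  }
  list(cdna = do.call(rbind, cd), gdna = do.call(rbind, gd),
       samples = samples, panel = panel)
}

#' Simulate a qPCR Ct table for one target gene
#'
#' The target's delta-Ct decreases with the sample's editing level at
#' `slope` cycles per unit editing frequency (expression up with editing);
#' the reference gene is stable.
#'
#' @param editing named per-sample editing levels.
#' @param groups named group labels per sample.
#' @param target,reference gene labels for the Ct rows.
#' @param slope cycles of delta-Ct decrease per unit editing.
#' @param noise_sd replicate noise (cycles).
#' @param seed RNG seed.
#' @return data.frame (sample, gene, Ct, replicate) plus a `group` column.
#' @export
simulate_ct <- function(editing, groups, target = "TARGET", reference = "GAPDH",
                        slope = 6, noise_sd = 0.15, seed = 1L) {
  set_seed_stage(seed, 5L)
  ns <- length(editing)
  ct_ref <- stats::rnorm(ns, 15, 0.1)
  dct <- 8 - slope * editing + stats::rnorm(ns, 0, noise_sd)
  df <- rbind(
    data.frame(sample = names(editing), gene = target, Ct = round(ct_ref + dct, 3),
               replicate = 1L, group = unname(groups[names(editing)])),
    data.frame(sample = names(editing), gene = reference, Ct = round(ct_ref, 3),
               replicate = 1L, group = unname(groups[names(editing)])))
  rownames(df) <- NULL
  df
}

#' Build a synthetic GMT gene-set collection with one planted term
#'
#' A fraction of the focus genes (e.g. differentially edited genes) is
#' concentrated into the first ("planted") term; the remaining terms are
#' random draws from the universe.
#'
#' @param universe all gene names.
#' @param focus genes to over-represent in the planted term.
#' @param n_sets total number of terms.
#' @param planted_fraction fraction of `focus` placed in the planted term.
#' @param set_size size of the random terms.
#' @param seed RNG seed.
#' @return named list of gene vectors (GMT-compatible); the planted term is
#'   named `"planted_synapse_like"`.
#' @export
make_gene_sets <- function(universe, focus, n_sets = 10L, planted_fraction = 0.8,
                           set_size = 8L, seed = 1L) {
  set_seed_stage(seed, 6L)
  n_f <- max(1L, round(planted_fraction * length(focus)))
  planted <- sort(sample(focus, n_f))
  sets <- list(planted_synapse_like = planted)
  for (k in seq_len(n_sets - 1L))
    sets[[sprintf("random_term_%02d", k)]] <-
      sort(sample(universe, min(set_size, length(universe))))
  attr(sets, "description") <- names(sets)
  sets
}
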