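test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(genome_length = 5000), "10 kb")
  expect_error(synthetic_config(n_true_sites = -1), "counts")
  expect_error(synthetic_config(baseline_freq_alpha = 0), "Beta")
  expect_error(synthetic_config(alu_fraction = 1.5), "alu_fraction")
  ## infeasible packing of the requested features is a sizing error
  expect_error(make_genome(synthetic_config(genome_length = 10000, n_genes = 30)),
               "packing")
})

test_that("identical config gives byte-identical emitted files", {
  cfg <- small_config(seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_genome(cfg, dir = d1)
  make_genome(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("planted truth matches the emitted annotation", {
  fx <- small_sim()
  g <- fx$genome
  ts <- g$truth$true_sites
  expect_equal(nrow(ts), fx$cfg$n_true_sites)
  ## truth and artifacts are disjoint
  expect_length(intersect(ts$pos, g$truth$artifact_sites$pos), 0)
  ## the reference carries an editable A on the gene strand
  seqc <- strsplit(as.character(g$sequence[[1]]), "")[[1]]
  expect_true(all(seqc[ts$pos] == ifelse(ts$strand == "+", "A", "T")))
  ## region classes match an independent classification of the same sites
  cls <- classify_region(ts[c("contig", "pos")], g$genes)
  expect_equal(cls$region_class, ts$region_class)
  ## planted frequencies are proper probabilities
  expect_true(all(ts$group1_freq >= 0 & ts$group1_freq <= 1))
  expect_true(all(ts$group2_freq >= 0 & ts$group2_freq <= 1))
})

test_that("pseudogene copies create true multi-mapping flanks", {
  fx <- small_sim()
  g <- fx$genome
  expect_equal(nrow(g$pseudogenes), 1L)
  mm <- g$truth$artifact_sites[g$truth$artifact_sites$artifact_class == "multimap", ]
  expect_gt(nrow(mm), 0)
  counts <- flank_multiplicity(mm[1, , drop = FALSE], g$sequence)
  expect_equal(counts, 2L)
})

test_that("observed frequencies converge on the planted truth", {
  fx <- small_sim()
  ts <- fx$genome$truth$true_sites
  pu <- fx$sim$pileup
  ctl <- fx$sim$samples$sample[fx$sim$samples$group == "control"]
  ## pick planted sites with mid-range frequency and pool control samples
  idx <- which(ts$group1_freq > 0.2 & ts$group1_freq < 0.8)[1:10]
  for (i in idx) {
    rows <- pu[pu$pos == ts$pos[i] & pu$sample %in% ctl, ]
    alt_col <- paste0("n", ts$alt[i])
    depth <- rowSums(rows[c("nA", "nC", "nG", "nT")])
    est <- sum(rows[[alt_col]]) / sum(depth)
    se <- sqrt(ts$group1_freq[i] * (1 - ts$group1_freq[i]) / sum(depth))
    expect_lt(abs(est - ts$group1_freq[i]), 3 * se + 1e-9)
  }
})

test_that("zero planted frequency and zero error rate give all-reference pileups", {
  cfg <- small_config(seed = 3, error_rate = 0, hw_allele_freq = 0,
                      n_homopolymer_artifacts = 0, n_pseudogene_sites = 0,
                      n_low_coverage_artifacts = 0)
  g <- make_genome(cfg)
  g$truth$true_sites$group1_freq[] <- 0
  g$truth$true_sites$group2_freq[] <- 0
  sim <- simulate_pileups(g, cfg)
  counts <- as.matrix(sim$pileup[c("nA", "nC", "nG", "nT")])
  ref_n <- counts[cbind(seq_len(nrow(counts)), match(sim$pileup$ref, c("A", "C", "G", "T")))]
  expect_equal(sum(counts) - sum(ref_n), 0)
})

test_that("SNP artifacts are concordant between cDNA and gDNA", {
  fx <- small_sim()
  g <- fx$genome
  snp <- g$truth$artifact_sites[g$truth$artifact_sites$artifact_class == "snp", ]
  pu <- fx$sim$pileup; gd <- fx$sim$gdna
  frac <- function(d, pos, s, alt) {
    r <- d[d$pos == pos & d$sample == s, ]
    depth <- sum(r[c("nA", "nC", "nG", "nT")])
    if (depth < 30) return(NA)
    r[[paste0("n", alt)]] / depth
  }
  checked <- 0
  for (i in seq_len(min(4, nrow(snp)))) {
    for (s in fx$sim$samples$sample[1:4]) {
      fc <- frac(pu, snp$pos[i], s, snp$alt[i])
      fg <- frac(gd, snp$pos[i], s, snp$alt[i])
      if (is.na(fc) || is.na(fg)) next
      expect_lt(abs(fc - fg), 0.3)    # same genotype, binomial noise only
      checked <- checked + 1
    }
  }
  expect_gt(checked, 4)
  ## gDNA at true sites is reference-homozygous up to the error rate
  tv <- fx$sim$validation_sites
  true_pos <- tv$pos[tv$class == "true"]
  gtrue <- gd[gd$pos %in% true_pos, ]
  depth <- rowSums(gtrue[c("nA", "nC", "nG", "nT")])
  altn <- mapply(function(i, alt) gtrue[[paste0("n", alt)]][i],
                 seq_len(nrow(gtrue)), tv$alt[match(gtrue$pos, tv$pos)])
  expect_lt(sum(altn) / sum(depth), 0.01)
})

test_that("expression matrix has the right shape and couples only coupled genes", {
  fx <- small_sim()
  counts <- simulate_expression(fx$genome, fx$sim$mean_editing, fx$cfg)
  expect_equal(dim(counts), c(fx$cfg$n_genes, 2 * fx$cfg$n_samples_per_group))
  expect_true(all(counts >= 0))
  ## uncoupled genes: correlations centred on zero
  cfg0 <- small_config(seed = 4, coupling_genes = c())
  g0 <- make_genome(cfg0)
  sim0 <- simulate_pileups(g0, cfg0)
  c0 <- simulate_expression(g0, sim0$mean_editing, cfg0)
  rs <- apply(c0, 1, function(x) cor(x, sim0$mean_editing))
  expect_lt(abs(mean(rs)), 0.25)
})

test_that("Ct simulation produces a target tracking editing and a stable reference", {
  ed <- c(a = 0.1, b = 0.3, c = 0.5, d = 0.2, e = 0.4, f = 0.6)
  gr <- stats::setNames(rep(c("control", "case"), each = 3), names(ed))
  ct <- simulate_ct(ed, gr, slope = 6, noise_sd = 0.01, seed = 2)
  expect_setequal(unique(ct$gene), c("TARGET", "GAPDH"))
  dd <- ddct(ct, target = "TARGET")
  expect_gt(cor(dd$fold, ed[dd$sample]), 0.9)
})
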