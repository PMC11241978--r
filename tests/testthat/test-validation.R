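vrow <- function(ref, counts, pos, sample, alt = NULL) {
  r <- pileup_row(ref, counts, as.list(stats::setNames(rep(35, length(counts)),
                                                       names(counts))),
                  pos = pos, sample = sample)
  if (!is.null(alt)) r$alt <- alt
  r
}

test_that("cDNA/gDNA calling: worked examples", {
  ## fraction exactly 0.10 with clean gDNA -> validated editing site
  cdna <- vrow("A", list(A = 45L, G = 5L), 100, "v1", alt = "G")
  gdna <- vrow("A", list(A = 60L), 100, "v1", alt = "G")
  calls <- call_validated_sites(cdna, gdna)
  expect_true(calls$is_res)

  ## heterozygote signature in gDNA blocks the call
  gdna_het <- vrow("A", list(A = 30L, G = 30L), 100, "v1", alt = "G")
  expect_false(call_validated_sites(cdna, gdna_het)$is_res)

  ## cDNA fraction below the 10% cutoff
  cdna_low <- vrow("A", list(A = 48L, G = 2L), 100, "v1", alt = "G")
  expect_false(call_validated_sites(cdna_low, gdna)$is_res)

  ## inadequate gDNA depth blocks a genotype call
  gdna_thin <- vrow("A", list(A = 20L), 100, "v1", alt = "G")
  expect_false(call_validated_sites(cdna, gdna_thin)$is_res)

  ## missing gDNA mate: sample skipped with a warning
  gdna_other <- vrow("A", list(A = 60L), 100, "v2", alt = "G")
  expect_warning(res <- call_validated_sites(cdna, gdna_other), "gDNA mate")
  expect_equal(nrow(res), 0L)
})

test_that("with a clean gDNA and no error floor, is_res is exactly the 10% rule", {
  fracs <- c(0.02, 0.08, 0.099, 0.10, 0.101, 0.3, 0.9)
  cdna <- do.call(rbind, lapply(seq_along(fracs), function(i) {
    alt <- round(1000 * fracs[i]); vrow("A", list(A = 1000L - alt, G = alt),
                                        i, "v1", alt = "G")
  }))
  gdna <- do.call(rbind, lapply(seq_along(fracs), function(i)
    vrow("A", list(A = 1000L), i, "v1", alt = "G")))
  calls <- call_validated_sites(cdna, gdna, gdna_max_alt = 0)
  expect_equal(calls$is_res, fracs >= 0.10)
})

test_that("planted gDNA variants are never called editing, at any cDNA fraction", {
  fx <- small_sim()
  val <- simulate_validation(fx$genome, n_sites = 12)
  calls <- call_validated_sites(val$cdna, val$gdna)
  snp_pos <- val$panel$pos[val$panel$class == "snp"]
  carriers <- calls[calls$pos %in% snp_pos & !is.na(calls$gdna_fraction) &
                      calls$gdna_fraction > 0.2, ]
  expect_gt(nrow(carriers), 0)
  expect_false(any(carriers$is_res))
  ## true sites with adequate cDNA fraction validate
  true_pos <- val$panel$pos[val$panel$class == "true" & val$panel$f1 >= 0.15]
  tcalls <- calls[calls$pos %in% true_pos, ]
  expect_gt(mean(tcalls$is_res), 0.8)
})

test_that("group comparison at validated sites reuses the exact MW fixture", {
  cdna <- do.call(rbind, lapply(seq_len(6), function(j) {
    f <- c(0.10, 0.12, 0.15, 0.20, 0.22, 0.25)[j]
    alt <- round(1000 * f)
    vrow("A", list(A = 1000L - alt, G = alt), 7, sprintf("v%d", j), alt = "G")
  }))
  gdna <- do.call(rbind, lapply(seq_len(6), function(j)
    vrow("A", list(A = 1000L), 7, sprintf("v%d", j), alt = "G")))
  calls <- call_validated_sites(cdna, gdna)
  groups <- stats::setNames(rep(c("case", "control"), each = 3),
                            sprintf("v%d", 1:6))
  cmp <- compare_validation_groups(calls, groups, force = "mann_whitney")
  expect_equal(cmp$p_value, 0.1)
  expect_true(cmp$verified_res)
  expect_false(cmp$validated_alteration)      # p = 0.1 is not < 0.05

  ## identical fractions across groups: p = 1, nothing validated
  cdna_same <- do.call(rbind, lapply(seq_len(6), function(j)
    vrow("A", list(A = 800L, G = 200L), 9, sprintf("v%d", j), alt = "G")))
  gdna_same <- do.call(rbind, lapply(seq_len(6), function(j)
    vrow("A", list(A = 1000L), 9, sprintf("v%d", j), alt = "G")))
  cmp <- compare_validation_groups(call_validated_sites(cdna_same, gdna_same),
                                   groups)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$validated_alteration)
  expect_error(compare_validation_groups(calls, groups[c(1, 2, 4)]), "sizes")
})

test_that("ddCt closed form: worked cases and exact invertibility", {
  ct <- data.frame(
    sample = c("t1", "c1", "c2"),
    gene = rep(c("TGT", "GAPDH"), each = 3),
    Ct = c(20, 22, 21.5, 15, 15, 14.5),
    group = rep(c("case", "control", "control"), 2))
  res <- ddct(ct, target = "TGT", reference = "GAPDH", calibrator = "control")
  ## calibrator mean dCt = 7, treated sample dCt = 5 -> ddCt = -2, fold = 4
  expect_equal(res$ddct[res$sample == "t1"], -2)
  expect_equal(res$fold[res$sample == "t1"], 4.0)
  ## a calibrator sample sitting at the calibrator mean has fold exactly 1
  expect_equal(res$dct[res$sample == "c1"], 7)
  expect_equal(res$fold[res$sample == "c1"], 1.0)
  ## ddCt = 1 -> fold = 0.5, and log2(fold) = -ddCt to machine precision
  expect_equal(2^(-1), 0.5)
  expect_equal(log2(res$fold), -res$ddct, tolerance = 1e-15)
  ## missing reference Ct: sample skipped with warning
  ct_miss <- ct[!(ct$sample == "t1" & ct$gene == "GAPDH"), ]
  expect_warning(res2 <- ddct(ct_miss, target = "TGT"), "missing reference")
  expect_false("t1" %in% res2$sample)
})

test_that("fold-editing correlation reports per group with small-n caveats", {
  fold <- c(a = 1, b = 2, c = 3, d = 1.5, e = 2.5, f = 3.5)
  ed <- c(a = 0.1, b = 0.2, c = 0.3, d = 0.15, e = 0.25, f = 0.35)
  groups <- stats::setNames(rep(c("control", "case"), each = 3), names(fold))
  res <- validation_correlation(fold, ed, groups)
  expect_equal(res$r[res$scope == "pooled"], 1)
  expect_equal(res$r2[res$scope == "pooled"], 1)
  expect_true(all(res$small_n[res$scope != "pooled"]))   # n = 3 per group
  ## anti-correlated fixture
  res2 <- validation_correlation(fold, -ed + 1, groups)
  expect_equal(res2$r[res2$scope == "pooled"], -1)
})
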