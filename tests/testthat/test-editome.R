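## helper: site matrix straight from a frequency matrix
sm_from_freq <- function(freq, depth = NULL) {
  sites <- data.frame(contig = "chr1", pos = seq_len(nrow(freq)),
                      ref = "A", alt = "G", rdd_type = "A>G",
                      stringsAsFactors = FALSE)
  rownames(freq) <- paste0("chr1:", seq_len(nrow(freq)))
  if (is.null(depth)) depth <- freq * 0 + 50
  structure(list(freq = freq, depth = depth, sites = sites),
            class = "site_matrix")
}

test_that("group presence rule: at least half the group's samples", {
  freq <- rbind(c(0.2, 0.4, NA, NA),     # 2/4 = 50% -> retained
                c(0.3, NA, NA, NA))      # 1/4 -> dropped
  colnames(freq) <- paste0("s", 1:4)
  groups <- stats::setNames(rep("control", 4), paste0("s", 1:4))
  ed <- build_group_editome(sm_from_freq(freq), groups)$control
  expect_equal(ed$n_events, 1L)
  expect_equal(ed$sites$mean_freq, 0.3)  # mean over observed samples only
  expect_error(build_group_editome(sm_from_freq(freq),
                                   stats::setNames("control", "s1")),
               "< 2 samples")
})

test_that("absent-as-zero mode changes the mean, not the membership", {
  freq <- rbind(c(0.2, 0.4, NA, NA))
  colnames(freq) <- paste0("s", 1:4)
  groups <- stats::setNames(rep("g", 4), paste0("s", 1:4))
  ed0 <- build_group_editome(sm_from_freq(freq), groups,
                             absent_as_zero = TRUE)$g
  expect_equal(ed0$sites$mean_freq, 0.15)
})

test_that("global comparison: degenerate, exact small-n, and enumeration oracle", {
  mk_ed <- function(freqs, group) {
    freq <- matrix(rep(freqs, 2), ncol = 2,
                   dimnames = list(paste0("chr1:", seq_along(freqs)), c("a", "b")))
    sites <- data.frame(contig = "chr1", pos = seq_along(freqs),
                        mean_freq = freqs)
    structure(list(group = group, sites = sites, freq = freq,
                   n_events = length(freqs)), class = "group_editome")
  }
  ## identical paired frequencies -> all zero differences -> degenerate p = 1
  a <- mk_ed(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7), "A")
  res <- suppressWarnings(compare_global(a, a))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)

  ## 5 pairs, all differences positive: exact two-sided p = 2/32
  b <- mk_ed(c(0.1, 0.2, 0.3, 0.4, 0.5), "A")
  c5 <- mk_ed(c(0.15, 0.27, 0.33, 0.49, 0.52), "B")
  res <- suppressWarnings(compare_global(c5, b))
  expect_equal(res$p_value, 2 / 32)
  expect_equal(res$p_value, wsr_exact_oracle(c5$sites$mean_freq - b$sites$mean_freq))

  ## general agreement with the sign-pattern enumeration oracle
  set.seed(21)
  for (n in c(6, 9, 12)) {
    x <- round(runif(n, 0.1, 0.9), 3)
    d <- round(runif(n, -0.2, 0.2), 4)
    d[d == 0] <- 0.01
    y <- x - d
    res <- suppressWarnings(compare_global(mk_ed(x, "A"), mk_ed(y, "B")))
    expect_equal(res$p_value, wsr_exact_oracle(x - y), tolerance = 1e-12)
  }
  disjoint <- mk_ed(c(0.2, 0.3), "B")
  rownames(disjoint$freq) <- c("chr9:1", "chr9:2")
  disjoint$sites$contig <- "chr9"
  expect_error(compare_global(mk_ed(c(0.1, 0.2), "A"), disjoint), "no shared")
})

test_that("genomic distribution percentages behave and sum to 100", {
  sites <- data.frame(region_class = c("intronic", "intronic", "intronic", "3'UTR"))
  d <- genomic_distribution(sites)
  expect_equal(d$percent[d$region_class == "intronic"], 75)
  expect_equal(d$percent[d$region_class == "3'UTR"], 25)
  expect_equal(sum(d$percent), 100)
  d1 <- genomic_distribution(data.frame(region_class = rep("intronic", 5)))
  expect_equal(d1$percent[d1$region_class == "intronic"], 100)
})

test_that("differential editing: worked examples and exact MW agreement", {
  ## {0.10,0.12,0.15} vs {0.20,0.22,0.25}: U = 0, exact two-sided p = 0.1
  freq <- rbind(c(0.10, 0.12, 0.15, 0.20, 0.22, 0.25))
  colnames(freq) <- paste0("s", 1:6)
  groups <- stats::setNames(rep(c("case", "control"), each = 3), paste0("s", 1:6))
  res <- differential_editing(sm_from_freq(freq), groups, force = "mann_whitney")
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value,
               mw_exact_oracle(c(0.10, 0.12, 0.15), c(0.20, 0.22, 0.25)))
  expect_equal(res$test_used, "mann_whitney")

  ## identical groups: p = 1, log2fc = 0
  freq <- rbind(rep(0.3, 6))
  colnames(freq) <- paste0("s", 1:6)
  res <- differential_editing(sm_from_freq(freq), groups)
  expect_equal(res$p_value, 1)
  expect_equal(res$editing_log2fc, 0)

  ## mean 0.30 vs 0.15 -> editing log2FC = 1
  freq <- rbind(c(0.25, 0.30, 0.35, 0.10, 0.15, 0.20))
  colnames(freq) <- paste0("s", 1:6)
  res <- differential_editing(sm_from_freq(freq), groups)
  expect_equal(res$editing_log2fc, 1)
  expect_equal(res$mean_freq_case, 0.30)
  expect_equal(res$direction, "up")

  ## sites observed in fewer than 3 samples per group are skipped
  freq <- rbind(c(0.1, NA, NA, 0.2, 0.3, 0.4))
  colnames(freq) <- paste0("s", 1:6)
  res <- differential_editing(sm_from_freq(freq), groups)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "skipped"), 1L)
})

test_that("Mann-Whitney kernel matches full-arrangement enumeration", {
  set.seed(33)
  for (rep in 1:6) {
    n1 <- sample(3:6, 1); n2 <- sample(3:8, 1)
    v <- round(runif(n1 + n2), 6)
    while (anyDuplicated(v)) v <- round(runif(n1 + n2), 6)
    x <- v[1:n1]; y <- v[-(1:n1)]
    got <- ks_gated_test(x, y, force = "mann_whitney")
    expect_equal(got$p_value, mw_exact_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("t branch matches the closed-form Welch test", {
  set.seed(7)
  x <- rnorm(10, 0.3, 0.05); y <- rnorm(12, 0.25, 0.04)
  got <- ks_gated_test(x, y, force = "t")
  expect_equal(got$p_value, t.test(x, y)$p.value)
})

test_that("adding a constant to both groups leaves the MW p unchanged", {
  set.seed(5)
  x <- runif(8); y <- runif(9)
  p1 <- ks_gated_test(x, y, force = "mann_whitney")$p_value
  p2 <- ks_gated_test(x + 0.17, y + 0.17, force = "mann_whitney")$p_value
  expect_equal(p1, p2)
})

test_that("KS gate routes non-normal groups to Mann-Whitney", {
  set.seed(13)
  x <- rnorm(20, 0.5, 0.05)
  y <- rnorm(20, 0.5, 0.05)
  expect_equal(ks_gated_test(x, y)$test_used, "t")
  xb <- c(rep(0.101, 10), rep(0.899, 10))   # strongly bimodal
  expect_equal(ks_gated_test(xb, y)$test_used, "mann_whitney")
  ## zero-variance group counts as non-normal
  expect_equal(ks_gated_test(rep(0.3, 10), y)$test_used, "mann_whitney")
  ## both groups constant and equal: defined degenerate result
  res <- ks_gated_test(rep(0.2, 5), rep(0.2, 5))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("gene-level summary aggregates DEdit sites per gene", {
  rec <- data.frame(contig = "chr1", pos = 1:5,
                    gene_name = c("G1", "G1", "G2", "G2", "G3"),
                    transcript_id = NA_character_,
                    region_class = "intronic",
                    p_value = c(0.01, 0.02, 0.001, 0.5, 0.2),
                    editing_log2fc = c(1, -1, 0.5, 0.4, 0.1),
                    direction = c("up", "down", "up", "up", "up"),
                    dedit = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  class(rec) <- c("dedit_records", "data.frame")
  gs <- gene_level_summary(rec)
  ## G3 has no DEdit site -> absent
  expect_setequal(gs$gene, c("G1", "G2"))
  g1 <- gs[gs$gene == "G1", ]
  expect_equal(g1$mean_log2fc, 0)               # {1, -1} average
  expect_false(g1$direction_consistent)         # heterogeneity flagged
  expect_equal(gs$gene[1], "G2")                # sorted by min p
  volcano <- attr(gs, "volcano")
  expect_setequal(volcano$gene, c("G1", "G2", "G3"))
})

test_that("per-sample overall editing averages observed sites", {
  freq <- rbind(c(0.2, NA), c(0.4, 0.1))
  colnames(freq) <- c("s1", "s2")
  ov <- overall_editing(sm_from_freq(freq))
  expect_equal(unname(ov), c(0.3, 0.1))
})
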