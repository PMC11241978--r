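## Targeted (amplicon) validation: cDNA-vs-gDNA editing-site calling, group
## comparison at validated sites with the shared KS-gated test, and
## 2^-ddCt relative expression with editing correlation. A site is a
## validated RNA-editing site (is_res) in a sample when its cDNA alternate
## fraction reaches the 10% cutoff while its gDNA mate is
## reference-homozygous (alternate fraction <= gdna_max_alt at adequate
## depth) — the paired-DNA analogue of the dbSNP exclusion.

pileup_alt_fraction <- function(pileup) {
  counts <- as.matrix(pileup[, c("nA", "nC", "nG", "nT")])
  colnames(counts) <- BASES
  depth <- rowSums(counts)
  ai <- match(pileup$alt %||% NA, BASES)
  alt_n <- if (!is.null(pileup$alt)) counts[cbind(seq_len(nrow(counts)), ai)]
  else depth - counts[cbind(seq_len(nrow(counts)), match(pileup$ref, BASES))]
  data.frame(contig = pileup$contig, pos = pileup$pos, sample = pileup$sample,
             depth = depth, alt_n = alt_n,
             alt_fraction = ifelse(depth > 0, alt_n / depth, NA_real_),
             stringsAsFactors = FALSE)
}

#' Call validated editing sites from paired cDNA/gDNA pileups
#'
#' Pileups are expected to be built from uniquely mapped reads above
#' `mapq_min` with duplicate/vendor-failed reads excluded (see
#' [pileup_from_sam()]); the `n_excluded` column is ignored here. The
#' alternate allele is taken per site as the highest-count non-reference
#' cDNA allele pooled over samples when an `alt` column is absent.
#'
#' @param cdna,gdna pileup data.frames over the same sites and samples
#'   (with an `alt` column naming the alternate allele, as emitted by the
#'   amplicon simulator; otherwise derived from pooled cDNA counts).
#' @param min_freq cDNA alternate-fraction cutoff (default 0.10).
#' @param gdna_max_alt maximum gDNA alternate fraction for
#'   reference-homozygosity (default 0.01).
#' @param min_gdna_depth minimum gDNA depth for a usable genotype call
#'   (default 50).
#' @param mapq_min documented mapping-quality floor of the input pileups.
#' @return data.frame of class `validation_calls`, one row per site x
#'   sample: cdna_fraction, cdna_depth, gdna_fraction, gdna_depth, is_res.
#'   Samples lacking a gDNA mate are skipped with a warning.
#' @export
call_validated_sites <- function(cdna, gdna, min_freq = 0.10,
                                 gdna_max_alt = 0.01, min_gdna_depth = 50,
                                 mapq_min = 20) {
  cf <- pileup_alt_fraction(add_pooled_alt(cdna))
  gf <- pileup_alt_fraction(add_pooled_alt(gdna, from = cdna))
  key <- function(d) paste(d$contig, d$pos, d$sample)
  m <- match(key(cf), key(gf))
  if (anyNA(m)) {
    warnf("call_validated_sites: %d cDNA rows lack a gDNA mate; skipped",
          sum(is.na(m)))
    cf <- cf[!is.na(m), ]
    m <- m[!is.na(m)]
  }
  out <- data.frame(contig = cf$contig, pos = cf$pos, sample = cf$sample,
                    cdna_fraction = cf$alt_fraction, cdna_depth = cf$depth,
                    gdna_fraction = gf$alt_fraction[m], gdna_depth = gf$depth[m],
                    stringsAsFactors = FALSE)
  out$is_res <- !is.na(out$cdna_fraction) & out$cdna_fraction >= min_freq &
    out$gdna_depth >= min_gdna_depth &
    !is.na(out$gdna_fraction) & out$gdna_fraction <= gdna_max_alt
  class(out) <- c("validation_calls", "data.frame")
  out
}

add_pooled_alt <- function(pileup, from = NULL) {
  if (!is.null(pileup$alt)) return(pileup)
  src <- from %||% pileup
  counts <- as.matrix(src[, c("nA", "nC", "nG", "nT")])
  pooled <- rowsum(counts, site_key(src$contig, src$pos))
  ref_by_site <- src$ref[!duplicated(site_key(src$contig, src$pos))]
  names(ref_by_site) <- site_key(src$contig, src$pos)[
    !duplicated(site_key(src$contig, src$pos))]
  pooled[cbind(seq_len(nrow(pooled)),
               match(ref_by_site[rownames(pooled)], BASES))] <- -1
  alt_by_site <- BASES[max.col(pooled, ties.method = "first")]
  names(alt_by_site) <- rownames(pooled)
  pileup$alt <- alt_by_site[site_key(pileup$contig, pileup$pos)]
  pileup
}

#' Group comparison at validated sites
#'
#' The KS-gated t / Mann-Whitney machinery applied per site to per-sample
#' cDNA alternate fractions. A site is a validated alteration iff it is a
#' validated editing site (is_res) in at least one sample AND the group
#' p-value is below `alpha`; is_res in >= 1 sample alone marks a verified
#' editing site.
#'
#' @param calls `validation_calls`.
#' @param groups named sample -> group vector (>= 2 samples per group;
#'   the amplicon design uses 3).
#' @param case,control group labels.
#' @param alpha significance level (default 0.05).
#' @param force force a test choice as in [ks_gated_test()].
#' @return data.frame per site: test_used, p_value, mean fractions,
#'   verified_res, validated_alteration.
#' @export
compare_validation_groups <- function(calls, groups, case = "case",
                                      control = "control", alpha = 0.05,
                                      force = NULL) {
  gsz <- table(groups)
  if (any(gsz < 2)) stopf("compare_validation_groups: group sizes < 2")
  by_site <- split(seq_len(nrow(calls)), site_key(calls$contig, calls$pos))
  rows <- lapply(by_site, function(idx) {
    d <- calls[idx, ]
    g <- groups[d$sample]
    x <- d$cdna_fraction[g == case]
    y <- d$cdna_fraction[g == control]
    tt <- ks_gated_test(x, y, force = force)
    data.frame(contig = d$contig[1], pos = d$pos[1],
               test_used = tt$test_used, p_value = tt$p_value,
               mean_fraction_case = mean(x, na.rm = TRUE),
               mean_fraction_control = mean(y, na.rm = TRUE),
               verified_res = any(d$is_res),
               validated_alteration = any(d$is_res) &&
                 !is.na(tt$p_value) && tt$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' dCt = Ct_target - Ct_reference per sample (technical replicates
#' averaged); ddCt = dCt - mean(dCt) over the calibrator group; fold =
#' 2^-ddCt, so the calibrator group has geometric-mean fold 1.
#'
#' @param ct Ct table: sample, gene, Ct (replicate optional), plus a group
#'   column or a separate `groups` vector.
#' @param target target gene label.
#' @param reference reference (normalizer) gene label, e.g. GAPDH.
#' @param calibrator calibrator group label.
#' @param groups optional named sample -> group vector (overrides a group
#'   column).
#' @return data.frame per sample: group, ct_target, ct_reference, dct,
#'   ddct, fold. Samples missing the reference gene are skipped with a
#'   warning.
#' @export
ddct <- function(ct, target, reference = "GAPDH", calibrator = "control",
                 groups = NULL) {
  if (is.null(groups)) {
    if (is.null(ct$group)) stopf("ddct: no group column and no groups vector")
    groups <- stats::setNames(ct$group, ct$sample)[!duplicated(ct$sample)]
  }
  mean_ct <- function(g) {
    sub <- ct[ct$gene == g, ]
    if (!nrow(sub)) stopf("ddct: gene %s absent from Ct table", g)
    vapply(split(sub$Ct, sub$sample), mean, 1)
  }
  ct_t <- mean_ct(target)
  ct_r <- mean_ct(reference)
  samples <- names(ct_t)
  miss <- setdiff(samples, names(ct_r))
  if (length(miss)) {
    warnf("ddct: %d samples missing reference Ct; skipped", length(miss))
    samples <- setdiff(samples, miss)
  }
  if (any(!is.finite(c(ct_t[samples], ct_r[samples]))))
    stopf("ddct: non-finite Ct values")
  dct <- ct_t[samples] - ct_r[samples]
  grp <- groups[samples]
  cal <- dct[grp == calibrator]
  if (!length(cal)) stopf("ddct: calibrator group '%s' empty", calibrator)
  ddct_v <- dct - mean(cal)
  out <- data.frame(sample = samples, group = unname(grp),
                    ct_target = unname(ct_t[samples]),
                    ct_reference = unname(ct_r[samples]),
                    dct = unname(dct), ddct = unname(ddct_v),
                    fold = unname(2^(-ddct_v)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Correlation between relative expression and editing at validated sites
#'
#' Pearson r and R^2, per group and pooled, between per-sample 2^-ddCt fold
#' and per-sample mean editing over the validated sites; a small-n caveat
#' flag is set for n < 5.
#'
#' @param fold named per-sample fold changes (see [ddct()]).
#' @param editing named per-sample mean editing over validated sites.
#' @param groups named sample -> group vector.
#' @return data.frame per scope ("pooled" and each group): r, r2, p_value,
#'   n, small_n, flagged.
#' @export
validation_correlation <- function(fold, editing, groups) {
  samp <- intersect(names(fold), names(editing))
  scopes <- c(list(pooled = samp),
              split(samp, groups[samp]))
  do.call(rbind, lapply(names(scopes), function(sc) {
    s <- scopes[[sc]]
    pr <- pearson_significance(fold[s], editing[s])
    data.frame(scope = sc, r = pr$r, r2 = pr$r^2, p_value = pr$p_value,
               n = pr$n, small_n = pr$small_n, flagged = pr$flagged,
               stringsAsFactors = FALSE)
  }))
}
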