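## Expression integration: median-of-ratios normalization (the standard
## count-normalization used by differential-expression tools, implemented
## directly), a log2FC >= 0.5 differential-expression call with the same
## KS-gated test machinery as the editing arm, and the three Pearson
## correlation analyses (ADAR-homolog expression vs overall editing,
## gene-level and per-site editing vs expression) under the r > 0.5 and
## p < 0.05 significance rule.

#' Median-of-ratios size factors
#'
#' factor_j = median over all-positive genes of count_gj / geometric mean of
#' gene g, rescaled so the factors have geometric mean 1.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return numeric vector of per-sample size factors (> 0).
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) stopf("size_factors: negative counts")
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stopf("size_factors: no gene with positive counts in all samples; consider a pseudocount")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- exp(apply(lg - geo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Normalize a counts matrix by its size factors
#' @param counts genes x samples counts.
#' @param sf size factors (default computed by [size_factors()]).
#' @return normalized matrix (counts divided column-wise by factors).
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2, sf, "/")
}

#' Differential expression by log2 fold-change cutoff
#'
#' log2FC = log2((mean_case + 1) / (mean_control + 1)) on normalized counts;
#' the per-gene test is the same KS-gated t / Mann-Whitney used for editing;
#' a gene is differentially expressed iff |log2FC| >= `lfc_cutoff`.
#'
#' @param norm normalized counts matrix (genes x samples).
#' @param groups named sample -> group vector.
#' @param case,control group labels.
#' @param lfc_cutoff log2FC cutoff (default 0.5).
#' @return data.frame gene, mean_case, mean_control, log2fc, test_used,
#'   p_value, de (flag).
#' @export
diff_expression <- function(norm, groups, case = "case", control = "control",
                            lfc_cutoff = 0.5) {
  cc <- intersect(colnames(norm), names(groups)[groups == case])
  kc <- intersect(colnames(norm), names(groups)[groups == control])
  if (length(cc) < 3 || length(kc) < 3)
    stopf("diff_expression: need >= 3 samples per group")
  rows <- lapply(seq_len(nrow(norm)), function(i) {
    x <- norm[i, cc]; y <- norm[i, kc]
    if (all(c(x, y) == 0))
      return(data.frame(mean_case = 0, mean_control = 0, log2fc = 0,
                        test_used = NA_character_, p_value = 1))
    tt <- ks_gated_test(x, y)
    data.frame(mean_case = mean(x), mean_control = mean(y),
               log2fc = log2((mean(x) + 1) / (mean(y) + 1)),
               test_used = tt$test_used, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- cbind(data.frame(gene = rownames(norm), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out$de <- abs(out$log2fc) >= lfc_cutoff
  rownames(out) <- NULL
  out
}

#' ADAR-homolog expression vs overall editing correlation
#'
#' Pearson correlation, per designated gene, between its normalized
#' expression and the per-sample overall mean editing frequency, pooled
#' across groups. By default expression enters as log2(normalized + 1) —
#' the scale on which count models are linear and Pearson is appropriate
#' for values spanning decades; set `log2_counts = FALSE` for the raw
#' normalized scale.
#'
#' @param norm normalized counts matrix.
#' @param mean_editing named per-sample overall editing (see
#'   [overall_editing()]).
#' @param genes genes to test (default rows named like ADAR homologs).
#' @param r_cutoff,p_cutoff significance rule thresholds.
#' @param log2_counts correlate log2(normalized + 1) expression (default
#'   TRUE).
#' @return data.frame gene, r, p_value, n, significant, flagged.
#' @export
adar_editing_correlation <- function(norm, mean_editing,
                                     genes = grep("^ADAR", rownames(norm),
                                                  value = TRUE),
                                     r_cutoff = 0.5, p_cutoff = 0.05,
                                     log2_counts = TRUE) {
  samp <- intersect(colnames(norm), names(mean_editing))
  if (length(samp) < 3) stopf("adar_editing_correlation: < 3 shared samples")
  do.call(rbind, lapply(genes, function(g) {
    x <- norm[g, samp]
    if (log2_counts) x <- log2(x + 1)
    pr <- pearson_significance(x, mean_editing[samp],
                               r_cutoff, p_cutoff)
    data.frame(gene = g, r = pr$r, p_value = pr$p_value, n = pr$n,
               significant = pr$significant, flagged = pr$flagged,
               stringsAsFactors = FALSE)
  }))
}

#' Editing-expression correlation for a gene and its DEdit sites
#'
#' Gene-level: Pearson r across samples between the gene's normalized
#' expression and its per-sample mean frequency over the gene's DEdit
#' sites. Per-site: the same against each site's own frequencies (samples
#' missing the site are dropped pairwise).
#'
#' @param gene gene name (must be a row of `norm`).
#' @param sm `site_matrix` over retained sites.
#' @param dedit `dedit_records` (used to pick the gene's DEdit sites).
#' @param norm normalized counts matrix.
#' @param r_cutoff,p_cutoff significance rule thresholds.
#' @param log2_counts correlate log2(normalized + 1) expression (default
#'   TRUE, see [adar_editing_correlation()]).
#' @return list with `gene_level` (one-row data.frame) and `per_site`
#'   (one row per DEdit site).
#' @export
editing_expression_correlation <- function(gene, sm, dedit, norm,
                                           r_cutoff = 0.5, p_cutoff = 0.05,
                                           log2_counts = TRUE) {
  de <- dedit[dedit$dedit & !is.na(dedit$gene_name) & dedit$gene_name == gene, ]
  if (!nrow(de)) stopf("editing_expression_correlation: no DEdit sites for %s", gene)
  keys <- site_key(de$contig, de$pos)
  samp <- intersect(colnames(sm$freq), colnames(norm))
  fr <- sm$freq[keys, samp, drop = FALSE]
  expr <- norm[gene, samp]
  if (log2_counts) expr <- log2(expr + 1)
  mean_fr <- colMeans(fr, na.rm = TRUE)
  gl <- pearson_significance(mean_fr, expr, r_cutoff, p_cutoff)
  gene_level <- data.frame(gene = gene, r = gl$r, p_value = gl$p_value,
                           n = gl$n, significant = gl$significant,
                           flagged = gl$flagged, stringsAsFactors = FALSE)
  per_site <- do.call(rbind, lapply(seq_along(keys), function(i) {
    pr <- pearson_significance(fr[i, ], expr, r_cutoff, p_cutoff)
    data.frame(site = keys[i], gene = gene, r = pr$r, p_value = pr$p_value,
               n = pr$n, significant = pr$significant, flagged = pr$flagged,
               stringsAsFactors = FALSE)
  }))
  list(gene_level = gene_level, per_site = per_site)
}

#' Cross-gene log2FC-vs-log2FC correlation (secondary report)
#'
#' Correlates, across genes, the expression log2FC with the editing log2FC
#' of the gene's sites — the one-value-per-gene reading of the
#' editing-expression integration.
#'
#' @param de_table output of [diff_expression()].
#' @param gene_summary output of [gene_level_summary()].
#' @return list as from [pearson_significance()], plus the merged table.
#' @export
log2fc_correlation <- function(de_table, gene_summary) {
  merged <- merge(de_table[c("gene", "log2fc")],
                  gene_summary[c("gene", "mean_log2fc")], by = "gene")
  pr <- pearson_significance(merged$log2fc, merged$mean_log2fc)
  pr$table <- merged
  pr
}
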