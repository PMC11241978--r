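## Group editomes and differential editing. A site enters a phenotype
## group's editome when observed (called and filter-passing) in at least
## half of the group's samples; global profiles are compared with Wilcoxon's
## signed-rank test paired over shared sites, and per-site differences with
## the KS-gated t / Mann-Whitney machinery. Mean frequencies are taken over
## observed samples only — absence reflects non-detection, not zero editing
## (the absent-as-zero alternative is available by flag).

group_cols <- function(sm, groups, g) {
  samp <- names(groups)[groups == g]
  intersect(colnames(sm$freq), samp)
}

#' Build per-group editomes under the presence rule
#'
#' @param sm a `site_matrix`.
#' @param groups named character vector: sample -> group label.
#' @param presence_threshold minimum fraction of the group's samples in
#'   which a site must be observed (default 0.5).
#' @param absent_as_zero treat missing entries as zero frequency instead of
#'   excluding them from means (default FALSE).
#' @return named list of `group_editome` objects, one per group: `group`,
#'   `sites` (with per-site `mean_freq` and `presence`), `freq` (site x
#'   group-sample matrix), `n_events`, `region_distribution` (if region
#'   classes are available).
#' @export
build_group_editome <- function(sm, groups, presence_threshold = 0.5,
                                absent_as_zero = FALSE) {
  out <- list()
  for (g in unique(groups)) {
    cols <- group_cols(sm, groups, g)
    if (length(cols) < 2) stopf("build_group_editome: group '%s' has < 2 samples", g)
    sub <- sm$freq[, cols, drop = FALSE]
    presence <- rowMeans(!is.na(sub))
    keep <- presence >= presence_threshold
    freq <- sub[keep, , drop = FALSE]
    if (absent_as_zero) freq[is.na(freq)] <- 0
    sites <- sm$sites[keep, , drop = FALSE]
    sites$mean_freq <- rowMeans(freq, na.rm = TRUE)
    sites$presence <- presence[keep]
    rownames(sites) <- NULL
    ed <- structure(list(group = g, sites = sites, freq = freq,
                         n_events = sum(keep),
                         region_distribution =
                           if (!is.null(sites$region_class))
                             genomic_distribution_df(sites) else NULL),
                    class = "group_editome")
    out[[g]] <- ed
  }
  out
}

#' @export
print.group_editome <- function(x, ...) {
  cat(sprintf("editome '%s': %d sites over %d samples, median site mean %.3f\n",
              x$group, x$n_events, ncol(x$freq),
              stats::median(x$sites$mean_freq)))
  invisible(x)
}

genomic_distribution_df <- function(sites) {
  tab <- table(factor(sites$region_class, levels = REGION_CLASSES))
  pct <- 100 * as.numeric(tab) / max(1, nrow(sites))
  data.frame(region_class = REGION_CLASSES, percent = pct,
             stringsAsFactors = FALSE)
}

#' Genomic distribution of an editome (percent per region class)
#'
#' @param editome a `group_editome`, or a site data.frame with a
#'   region_class column.
#' @param other optional second editome; when given, a per-class percent
#'   difference column (`editome` minus `other`) is appended.
#' @return data.frame region_class / percent (plus percent_other, diff).
#' @export
genomic_distribution <- function(editome, other = NULL) {
  sites <- if (inherits(editome, "group_editome")) editome$sites else editome
  d <- genomic_distribution_df(sites)
  if (!is.null(other)) {
    s2 <- if (inherits(other, "group_editome")) other$sites else other
    d2 <- genomic_distribution_df(s2)
    d$percent_other <- d2$percent
    d$diff <- d$percent - d2$percent
  }
  d
}

#' Global editome comparison (Wilcoxon signed-rank over shared sites)
#'
#' Per-site mean frequencies are paired by site identity over the sites
#' present in both group editomes; zero differences are dropped (the
#' signed-rank convention), the null is exact for up to 25 non-zero pairs
#' and a continuity-corrected normal approximation above that.
#'
#' @param editome_a,editome_b `group_editome` objects.
#' @return list with `statistic` (V), `p_value`, `n_shared`, `n_nonzero`,
#'   `median_a`, `median_b`, `n_events_a`, `n_events_b`, `degenerate`
#'   (TRUE when all paired differences are zero, p = 1).
#' @export
compare_global <- function(editome_a, editome_b) {
  ka <- site_key(editome_a$sites$contig, editome_a$sites$pos)
  kb <- site_key(editome_b$sites$contig, editome_b$sites$pos)
  shared <- intersect(ka, kb)
  if (!length(shared)) stopf("compare_global: no shared sites between editomes")
  if (length(shared) < 6)
    warnf("compare_global: only %d shared sites; exact test has little power",
          length(shared))
  a <- editome_a$sites$mean_freq[match(shared, ka)]
  b <- editome_b$sites$mean_freq[match(shared, kb)]
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0) {
    return(list(statistic = 0, p_value = 1, n_shared = length(shared),
                n_nonzero = 0L, median_a = stats::median(a),
                median_b = stats::median(b), n_events_a = editome_a$n_events,
                n_events_b = editome_b$n_events, degenerate = TRUE))
  }
  exact <- nz <= 25 && !anyDuplicated(abs(d[d != 0]))
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_shared = length(shared), n_nonzero = nz,
       median_a = stats::median(a), median_b = stats::median(b),
       n_events_a = editome_a$n_events, n_events_b = editome_b$n_events,
       degenerate = FALSE)
}

#' Per-site differential editing
#'
#' For every site observed in at least `min_obs` samples per group: the
#' KS-gated test (t or Mann-Whitney) on per-sample frequencies, the editing
#' log2 fold change log2(mean_case / mean_control) over observed samples,
#' and the DEdit flag at raw p < `alpha` (no multiplicity adjustment, per
#' the raw-p definition; a Benjamini-Hochberg column is emitted alongside).
#'
#' @param sm a `site_matrix` (ideally built from annotated sites so gene and
#'   region columns propagate).
#' @param groups named sample -> group vector.
#' @param case,control group labels (default "case" / "control").
#' @param alpha DEdit significance level (default 0.05).
#' @param min_obs minimum observed samples per group (default 3); sites
#'   below it are skipped and counted in the `skipped` attribute.
#' @param force force "t" or "mann_whitney" for every site (default NULL:
#'   KS-gated).
#' @return data.frame of class `dedit_records` with one row per tested site;
#'   attribute `skipped` holds the number of under-observed sites.
#' @export
differential_editing <- function(sm, groups, case = "case", control = "control",
                                 alpha = 0.05, min_obs = 3, force = NULL) {
  cc <- group_cols(sm, groups, case)
  kc <- group_cols(sm, groups, control)
  xs <- sm$freq[, cc, drop = FALSE]
  ys <- sm$freq[, kc, drop = FALSE]
  n_case <- rowSums(!is.na(xs))
  n_ctl <- rowSums(!is.na(ys))
  testable <- which(n_case >= min_obs & n_ctl >= min_obs)
  rows <- lapply(testable, function(i) {
    x <- xs[i, ][!is.na(xs[i, ])]
    y <- ys[i, ][!is.na(ys[i, ])]
    tt <- ks_gated_test(x, y, force = force)
    mc <- mean(x); mk <- mean(y)
    l2fc <- log2(mc / mk)
    data.frame(test_used = tt$test_used, p_value = tt$p_value,
               mean_freq_case = mc, mean_freq_control = mk,
               editing_log2fc = l2fc,
               direction = ifelse(l2fc > 0, "up", ifelse(l2fc < 0, "down", "none")),
               n_case = length(x), n_control = length(y),
               stringsAsFactors = FALSE)
  })
  res <- cbind(sm$sites[testable, , drop = FALSE], do.call(rbind, rows))
  rownames(res) <- NULL
  res$dedit <- res$p_value < alpha
  res$p_bh <- stats::p.adjust(res$p_value, "BH")
  attr(res, "skipped") <- nrow(sm$freq) - length(testable)
  class(res) <- c("dedit_records", "data.frame")
  res
}

#' @method summary dedit_records
#' @export
summary.dedit_records <- function(object, ...) {
  cat(sprintf("differential editing: %d sites tested (%d skipped), %d DEdit (p < 0.05)\n",
              nrow(object), attr(object, "skipped") %||% 0, sum(object$dedit)))
  cat(sprintf("  direction among DEdit: %d up, %d down\n",
              sum(object$dedit & object$direction == "up"),
              sum(object$dedit & object$direction == "down")))
  invisible(object)
}

intron_index_of <- function(pos, tx_exons, strand) {
  ## index of the intron (in transcript order) containing pos, else NA
  ex <- tx_exons[order(tx_exons$start), ]
  if (nrow(ex) < 2) return(NA_integer_)
  for (k in seq_len(nrow(ex) - 1)) {
    if (pos > ex$end[k] && pos < ex$start[k + 1]) {
      return(if (strand == "+") k else nrow(ex) - k)
    }
  }
  NA_integer_
}

#' Gene-level summary of differential editing
#'
#' One row per gene carrying at least one DEdit site: number of DEdit sites,
#' mean editing log2FC over them (direction heterogeneity flagged), minimum
#' p, Alu context, and per-intron site counts (intron index in transcript
#' order, strand-aware). A volcano table over all tested genes is attached
#' as the `volcano` attribute.
#'
#' @param dedit `dedit_records`.
#' @param gene_models gene-model data.frame (for intron indexing; optional).
#' @param alpha DEdit threshold used for inclusion (default 0.05).
#' @return data.frame of class `gene_dedit_summary`, sorted by min p.
#' @export
gene_level_summary <- function(dedit, gene_models = NULL, alpha = 0.05) {
  if (is.null(dedit$gene_name))
    stopf("gene_level_summary: records carry no gene assignment")
  tested <- dedit[!is.na(dedit$gene_name), , drop = FALSE]
  volcano <- do.call(rbind, lapply(split(tested, tested$gene_name), function(d)
    data.frame(gene = d$gene_name[1], mean_log2fc = mean(d$editing_log2fc),
               min_p = min(d$p_value), n_sites = nrow(d),
               minus_log10_p = -log10(min(d$p_value)),
               stringsAsFactors = FALSE)))
  rownames(volcano) <- NULL
  de <- tested[tested$p_value < alpha, , drop = FALSE]
  if (!nrow(de)) {
    out <- volcano[0, ]
    attr(out, "volcano") <- volcano
    class(out) <- c("gene_dedit_summary", "data.frame")
    return(out)
  }
  per_gene <- lapply(split(de, de$gene_name), function(d) {
    intron_counts <- NULL
    if (!is.null(gene_models) && !is.null(d$transcript_id)) {
      idx <- vapply(seq_len(nrow(d)), function(i) {
        tx <- d$transcript_id[i]
        if (is.na(tx) || d$region_class[i] != "intronic") return(NA_integer_)
        ex <- gene_models[gene_models$feature == "exon" &
                            gene_models$transcript_id %in% tx, ]
        if (!nrow(ex)) return(NA_integer_)
        intron_index_of(d$pos[i], ex, ex$strand[1])
      }, 1L)
      obs <- idx[!is.na(idx)]
      if (length(obs))
        intron_counts <- paste(sprintf("intron%d:%d", sort(unique(obs)),
                                       as.integer(table(obs))), collapse = ",")
    }
    data.frame(gene = d$gene_name[1],
               n_dedit_sites = nrow(d),
               mean_log2fc = mean(d$editing_log2fc),
               min_p = min(d$p_value),
               direction_consistent = length(unique(d$direction)) == 1,
               n_alu = if (!is.null(d$repeat_class)) sum(d$repeat_class == "Alu")
               else NA_integer_,
               intron_sites = intron_counts %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  out <- out[order(out$min_p), ]
  rownames(out) <- NULL
  attr(out, "volcano") <- volcano
  class(out) <- c("gene_dedit_summary", "data.frame")
  out
}

#' Per-sample overall editing level
#'
#' Mean editing frequency over the sites observed in each sample — the
#' per-sample summary used for editing-expression correlation.
#'
#' @param sm a `site_matrix`.
#' @return named numeric vector (one value per sample).
#' @export
overall_editing <- function(sm) {
  colMeans(sm$freq, na.rm = TRUE)
}
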