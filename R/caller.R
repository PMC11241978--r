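## Candidate RNA:DNA-difference calling from pileup tables.
## Thresholds follow the editome pipeline's base-level criteria: coverage
## >= 10, editing frequency >= 10%, per-base quality >= 25 (alleles whose
## mean base quality falls below the cutoff are discarded before counting),
## with a configurable minimum of supporting alternate reads (default 2).

#' Optional per-sample QC pre-filter
#'
#' Drops samples with a low fraction of uniquely mapped reads or a high
#' fraction of duplicated reads before calling.
#'
#' @param qc data.frame with columns sample, unique_map_frac, dup_frac.
#' @param min_unique_map minimum uniquely-mapped fraction (default 0.6).
#' @param max_dup maximum duplicate fraction (default 0.6).
#' @return character vector of retained sample ids.
#' @export
qc_filter_samples <- function(qc, min_unique_map = 0.6, max_dup = 0.6) {
  keep <- qc$unique_map_frac >= min_unique_map & qc$dup_frac <= max_dup
  qc$sample[keep]
}

#' Call candidate editing sites from a pileup table
#'
#' Per pileup row: excluded (duplicate/vendor-failed) reads are ignored;
#' allele classes whose mean base quality is below `min_quality` are
#' discarded; the alternate allele is the highest-count retained non-reference
#' allele (ties broken lexicographically A<C<G<T and recorded); a candidate is
#' emitted iff retained depth >= `min_coverage`, alternate reads >=
#' `min_alt_reads` and frequency >= `min_frequency`. The frequency
#' denominator is the full retained depth (all quality-passing bases).
#'
#' @param pileup pileup data.frame (see [read_pileup()]).
#' @param min_coverage minimum retained base coverage (default 10).
#' @param min_frequency minimum editing frequency (default 0.10).
#' @param min_quality minimum mean per-base quality for an allele class to be
#'   retained (default 25).
#' @param min_alt_reads minimum alternate-read support (default 2; set to 1
#'   for the permissive variant).
#' @param reference optional `Biostrings::DNAStringSet`; when supplied, each
#'   row's `ref` is checked against it and a mismatch is an error.
#' @return data.frame of class `candidate_sites` with columns contig, pos,
#'   ref, alt, rdd_type, adar_class, depth_retained, alt_count,
#'   editing_frequency, mean_alt_quality, tie_broken, sample.
#' @export
call_sites <- function(pileup, min_coverage = 10, min_frequency = 0.10,
                       min_quality = 25, min_alt_reads = 2, reference = NULL) {
  counts <- as.matrix(pileup[, c("nA", "nC", "nG", "nT")])
  if (any(counts < 0)) stopf("call_sites: negative base counts")
  quals <- as.matrix(pileup[, c("qA", "qC", "qG", "qT")])
  colnames(counts) <- colnames(quals) <- BASES
  if (!is.null(reference)) {
    refbase <- as.character(Biostrings::subseq(
      rep(reference[pileup$contig], 1), start = pileup$pos, width = 1))
    bad <- which(refbase != pileup$ref)
    if (length(bad))
      stopf("call_sites: ref mismatch vs FASTA at %s:%d (pileup %s, FASTA %s)",
            pileup$contig[bad[1]], pileup$pos[bad[1]],
            pileup$ref[bad[1]], refbase[bad[1]])
  }

  ## discard allele classes below the quality cutoff
  low_q <- !is.na(quals) & quals < min_quality
  counts[low_q | is.na(quals)] <- 0L
  depth_retained <- rowSums(counts)

  ref_idx <- match(pileup$ref, BASES)
  nonref <- counts
  nonref[cbind(seq_len(nrow(nonref)), ref_idx)] <- -1L
  alt_idx <- max.col(nonref, ties.method = "first")  # lexicographic tie-break
  alt_count <- nonref[cbind(seq_len(nrow(nonref)), alt_idx)]
  alt_count[alt_count < 0L] <- 0L
  tie_broken <- rowSums(nonref == alt_count & alt_count > 0L) > 1L

  freq <- ifelse(depth_retained > 0, alt_count / depth_retained, 0)
  keep <- depth_retained >= min_coverage & alt_count >= min_alt_reads &
    freq >= min_frequency
  alt <- BASES[alt_idx]
  rdd <- paste0(pileup$ref, ">", alt)
  out <- data.frame(contig = pileup$contig[keep], pos = pileup$pos[keep],
                    ref = pileup$ref[keep], alt = alt[keep],
                    rdd_type = rdd[keep],
                    depth_retained = depth_retained[keep],
                    alt_count = alt_count[keep],
                    editing_frequency = freq[keep],
                    mean_alt_quality = quals[cbind(which(keep), alt_idx[keep])],
                    tie_broken = tie_broken[keep],
                    sample = pileup$sample[keep],
                    stringsAsFactors = FALSE)
  out$adar_class <- adar_class(out$rdd_type)
  rownames(out) <- NULL
  class(out) <- c("candidate_sites", "data.frame")
  out
}

#' RNA:DNA difference spectrum
#'
#' Proportion of candidates in each of the 12 ordered mismatch types, plus
#' the ADAR-signature (A>G + T>C) and APOBEC-signature (C>T + G>A) fractions.
#'
#' @param sites a `candidate_sites` data.frame.
#' @return list with `spectrum` (named 12-vector summing to 1),
#'   `adar_fraction`, `apobec_fraction`, `n`, and `empty` flag.
#' @export
rdd_spectrum <- function(sites) {
  if (!nrow(sites)) {
    spec <- stats::setNames(rep(NA_real_, length(RDD_TYPES)), RDD_TYPES)
    return(list(spectrum = spec, adar_fraction = NA_real_,
                apobec_fraction = NA_real_, n = 0L, empty = TRUE))
  }
  tab <- table(factor(sites$rdd_type, levels = RDD_TYPES))
  spec <- as.numeric(tab) / nrow(sites)
  names(spec) <- RDD_TYPES
  list(spectrum = spec,
       adar_fraction = sum(spec[c("A>G", "T>C")]),
       apobec_fraction = sum(spec[c("C>T", "G>A")]),
       n = nrow(sites), empty = FALSE)
}

#' Build the site-by-sample frequency matrix
#'
#' The union of called sites over samples; a site absent from a sample is
#' missing (NA), not zero. Retained depth is carried alongside.
#'
#' @param candidates `candidate_sites` rows pooled over samples.
#' @param samples optional sample ordering (default: order of appearance).
#' @return object of class `site_matrix`: list with `freq` and `depth`
#'   matrices (sites x samples) and a `sites` data.frame (contig, pos, ref,
#'   alt, rdd_type).
#' @export
build_site_matrix <- function(candidates, samples = NULL) {
  key <- site_key(candidates$contig, candidates$pos)
  if (anyDuplicated(paste(key, candidates$sample)))
    stopf("build_site_matrix: duplicate (site, sample) rows")
  samples <- samples %||% unique(candidates$sample)
  usites <- !duplicated(key)
  site_cols <- intersect(c("contig", "pos", "ref", "alt", "rdd_type",
                           "strand_rdd", "region_class", "gene_id", "gene_name",
                           "transcript_id", "repeat_class", "in_known_editing"),
                         names(candidates))
  sites <- candidates[usites, site_cols]
  sites <- sites[order(sites$contig, sites$pos), ]
  rownames(sites) <- NULL
  skey <- site_key(sites$contig, sites$pos)
  freq <- depth <- matrix(NA_real_, nrow(sites), length(samples),
                          dimnames = list(skey, samples))
  i <- match(key, skey)
  j <- match(candidates$sample, samples)
  freq[cbind(i, j)] <- candidates$editing_frequency
  depth[cbind(i, j)] <- candidates$depth_retained
  structure(list(freq = freq, depth = depth, sites = sites),
            class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("site matrix: %d sites x %d samples (%.1f%% observed)\n",
              nrow(x$freq), ncol(x$freq), 100 * mean(!is.na(x$freq))))
  invisible(x)
}

#' Write / read a site matrix as TSV (long format, missingness preserved)
#' @param sm a `site_matrix`.
#' @param path file path.
#' @export
write_site_matrix <- function(sm, path) {
  obs <- which(!is.na(sm$freq), arr.ind = TRUE)
  long <- data.frame(contig = sm$sites$contig[obs[, 1]],
                     pos = sm$sites$pos[obs[, 1]],
                     ref = sm$sites$ref[obs[, 1]], alt = sm$sites$alt[obs[, 1]],
                     rdd_type = sm$sites$rdd_type[obs[, 1]],
                     sample = colnames(sm$freq)[obs[, 2]],
                     editing_frequency = sm$freq[obs],
                     depth_retained = sm$depth[obs], stringsAsFactors = FALSE)
  long <- long[order(long$contig, long$pos, long$sample), ]
  write_tsv(long, path)
}

#' @rdname write_site_matrix
#' @param samples optional sample ordering.
#' @export
read_site_matrix <- function(path, samples = NULL) {
  long <- read_tsv(path)
  cand <- data.frame(contig = long$contig, pos = long$pos, ref = long$ref,
                     alt = long$alt, rdd_type = long$rdd_type,
                     editing_frequency = long$editing_frequency,
                     depth_retained = long$depth_retained,
                     sample = long$sample, stringsAsFactors = FALSE)
  build_site_matrix(cand, samples = samples)
}
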