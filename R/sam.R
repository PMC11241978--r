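## Optional SAM/BAM front-end. The pileup table is the package's canonical
## sequencing interface; this reader produces one from an alignment file via
## Rsamtools, excluding duplicate and vendor-failed reads and applying
## mapping- and base-quality floors at read level. Because Rsamtools
## aggregates base calls, per-allele mean qualities are not recoverable
## here: observed alleles are reported at the base-quality floor, which is
## the exact information the Q >= 25 allele filter needs (bases below the
## floor never reach the counts).

#' Build a pileup table from a SAM/BAM file
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param reference `Biostrings::DNAStringSet` supplying reference bases.
#' @param sample sample id to stamp on the rows.
#' @param mapq_min minimum mapping quality (reads at or below are dropped;
#'   default 0 for the RNA-seq stage, use 20 for amplicon validation).
#' @param min_base_quality base-quality floor applied at read level.
#' @param max_depth maximum pileup depth.
#' @return pileup data.frame (see [read_pileup()]); `n_excluded` counts are
#'   not recoverable from the aggregated pileup and are reported as 0 (the
#'   excluded reads never enter the counts).
#' @export
pileup_from_sam <- function(path, reference, sample, mapq_min = 0,
                            min_base_quality = 0, max_depth = 100000L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stopf("pileup_from_sam requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai"))) Rsamtools::indexBam(bam)
  }
  flag <- Rsamtools::scanBamFlag(isDuplicate = FALSE,
                                 isNotPassingQualityControls = FALSE,
                                 isUnmappedQuery = FALSE)
  sbp <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq_min)
  pp <- Rsamtools::PileupParam(max_depth = max_depth,
                               min_base_quality = as.integer(min_base_quality),
                               min_mapq = as.integer(mapq_min),
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  if (!nrow(pu)) {
    out <- data.frame(contig = character(), pos = integer(), ref = character(),
                      sample = character(), nA = integer(), nC = integer(),
                      nG = integer(), nT = integer(), qA = double(),
                      qC = double(), qG = double(), qT = double(),
                      n_excluded = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  pu <- pu[pu$nucleotide %in% BASES, ]
  key <- paste(pu$seqnames, pu$pos)
  wide <- matrix(0L, length(unique(key)), 4,
                 dimnames = list(unique(key), BASES))
  wide[cbind(match(key, rownames(wide)), match(as.character(pu$nucleotide), BASES))] <-
    pu$count
  first <- !duplicated(key)
  contig <- as.character(pu$seqnames[first])
  pos <- pu$pos[first]
  refbase <- as.character(Biostrings::subseq(reference[contig], start = pos,
                                             width = 1))
  quals <- matrix(NA_real_, nrow(wide), 4, dimnames = dimnames(wide))
  quals[wide > 0] <- max(min_base_quality, 0)
  out <- data.frame(contig = contig, pos = pos, ref = refbase, sample = sample,
                    nA = wide[, "A"], nC = wide[, "C"], nG = wide[, "G"],
                    nT = wide[, "T"], qA = quals[, "A"], qC = quals[, "C"],
                    qG = quals[, "G"], qT = quals[, "T"], n_excluded = 0L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), ]
  rownames(out) <- NULL
  out
}
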