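## Readers/writers for the miniature interchange formats used throughout:
## pileup TSV, GTF-subset gene models, BED (0-based half-open on disk),
## VCF-lite SNP tables, known-editing TSV, GMT gene sets, Ct tables.
## FASTA goes through Biostrings.

PILEUP_COLS <- c("contig", "pos", "ref", "sample",
                 "nA", "nC", "nG", "nT", "qA", "qC", "qG", "qT", "n_excluded")

#' Read / write a pileup table
#'
#' A pileup table holds per-contig, per-position, per-sample base counts
#' (`nA`..`nT`), per-allele mean base qualities (`qA`..`qT`, NA where the
#' allele was not observed), and a count of reads excluded as duplicates or
#' vendor-failed (`n_excluded`). Positions are 1-based.
#'
#' @param path file path.
#' @return `read_pileup` returns a data.frame with columns
#'   contig, pos, ref, sample, nA, nC, nG, nT, qA, qC, qG, qT, n_excluded.
#' @export
read_pileup <- function(path) {
  df <- read_tsv(path)
  missing <- setdiff(PILEUP_COLS, names(df))
  if (length(missing))
    stopf("pileup %s lacks columns: %s", path, paste(missing, collapse = ", "))
  df[PILEUP_COLS]
}

#' @rdname read_pileup
#' @param pileup pileup data.frame.
#' @export
write_pileup <- function(pileup, path) write_tsv(pileup[PILEUP_COLS], path)

#' Read a GTF-subset gene model file
#'
#' Recognised features: gene, transcript, exon, CDS, five_prime_utr,
#' three_prime_utr. Attributes parsed: gene_id, transcript_id, gene_name,
#' biotype. Coordinates 1-based inclusive.
#'
#' @param path GTF file.
#' @return data.frame with columns contig, source, feature, start, end,
#'   strand, gene_id, transcript_id, gene_name, biotype.
#' @export
read_gene_models <- function(path) {
  raw <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("contig", "source", "feature", "start",
                                         "end", "score", "strand", "frame", "attr"))
  att <- function(key) {
    m <- regmatches(raw$attr, regexec(paste0(key, ' "([^"]*)"'), raw$attr))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  gm <- data.frame(contig = raw$contig, source = raw$source, feature = raw$feature,
                   start = raw$start, end = raw$end, strand = raw$strand,
                   gene_id = att("gene_id"), transcript_id = att("transcript_id"),
                   gene_name = att("gene_name"), biotype = att("biotype"),
                   stringsAsFactors = FALSE)
  validate_gene_models(gm)
  gm
}

validate_gene_models <- function(gm) {
  ex <- gm[gm$feature == "exon", ]
  tx <- gm[gm$feature == "transcript", ]
  if (nrow(ex) && nrow(tx)) {
    span <- split(tx[c("start", "end")], tx$transcript_id)
    for (i in seq_len(nrow(ex))) {
      s <- span[[ex$transcript_id[i]]]
      if (!is.null(s) && (ex$start[i] < s$start || ex$end[i] > s$end))
        stopf("malformed gene model: exon [%d,%d] outside transcript %s",
              ex$start[i], ex$end[i], ex$transcript_id[i])
    }
  }
  invisible(gm)
}

#' @rdname read_gene_models
#' @param gm gene-model data.frame.
#' @export
write_gene_models <- function(gm, path) {
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; biotype "%s";',
                      gm$gene_id, ifelse(is.na(gm$transcript_id), "", gm$transcript_id),
                      gm$gene_name, gm$biotype)
  out <- data.frame(gm$contig, gm$source, gm$feature, gm$start, gm$end,
                    ".", gm$strand, ".", attr_str)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an interval track (BED)
#'
#' On-disk BED is 0-based half-open; in memory intervals are 1-based
#' inclusive (the GenomicRanges convention). Column 4 is a name, column 5
#' (where present) a class label, e.g. the repeat class.
#'
#' @param path BED file.
#' @return data.frame with contig, start, end (1-based inclusive), name, class.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(contig = raw[[1]], start = raw[[2]] + 1L, end = raw[[3]],
             name = if (ncol(raw) >= 4) raw[[4]] else NA_character_,
             class = if (ncol(raw) >= 5) raw[[5]] else NA_character_,
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param bed interval data.frame (1-based inclusive).
#' @export
write_bed <- function(bed, path) {
  out <- data.frame(bed$contig, bed$start - 1L, bed$end,
                    bed$name %||% ".", bed$class %||% ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a VCF-lite SNP table (CHROM POS ID REF ALT)
#' @param path file path.
#' @return data.frame contig, pos, id, ref, alt.
#' @export
read_vcf_lite <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  data.frame(contig = raw[[1]], pos = raw[[2]], id = raw[[3]],
             ref = raw[[4]], alt = raw[[5]], stringsAsFactors = FALSE)
}

#' @rdname read_vcf_lite
#' @param snps SNP data.frame.
#' @export
write_vcf_lite <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2-lite", "#CHROM\tPOS\tID\tREF\tALT"), con)
  utils::write.table(snps[c("contig", "pos", "id", "ref", "alt")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write a known-editing-site table (contig, pos, ref, alt)
#' @param path file path.
#' @export
read_known_sites <- function(path) read_tsv(path)

#' @rdname read_known_sites
#' @param known data.frame with contig, pos, ref, alt.
#' @export
write_known_sites <- function(known, path)
  write_tsv(known[c("contig", "pos", "ref", "alt")], path)

#' Read a GMT gene-set collection
#'
#' One term per line: term id, description, then member gene symbols,
#' tab-separated. Duplicate members within a term are dropped.
#'
#' @param path GMT file.
#' @return named list of character vectors; names are term ids, the
#'   "description" attribute holds term names.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2)
  if (any(!lengths(sets))) stopf("GMT contains empty terms")
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% names(sets)
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read a qPCR Ct table (sample, gene, Ct, replicate optional)
#' @param path TSV file.
#' @export
read_ct_table <- function(path) read_tsv(path)
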