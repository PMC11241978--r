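#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

## The 12 ordered RNA:DNA difference (RDD) types, ref>alt.
RDD_TYPES <- as.vector(outer(BASES, BASES, function(r, a) paste0(r, ">", a)))
RDD_TYPES <- RDD_TYPES[substr(RDD_TYPES, 1, 1) != substr(RDD_TYPES, 3, 3)]

REGION_CLASSES <- c("exonic", "3'UTR", "5'UTR", "ncRNA", "NMD/processed_transcript",
                    "intronic", "upstream", "downstream", "other")

REPEAT_CLASSES <- c("Alu", "Simple_repeat", "Low_complexity", "Other_repeat", "none")

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(1, pmax(0, x))

#' Deaminase class of an RDD type
#'
#' A>G and T>C mismatches carry the ADAR signature (A-to-I editing read as
#' guanosine); C>T and G>A carry the APOBEC signature; everything else is
#' "other".
#'
#' @param rdd_type character vector of "R>A" mismatch types.
#' @return character vector in \code{c("ADAR","APOBEC","other")}.
#' @export
adar_class <- function(rdd_type) {
  out <- rep("other", length(rdd_type))
  out[rdd_type %in% c("A>G", "T>C")] <- "ADAR"
  out[rdd_type %in% c("C>T", "G>A")] <- "APOBEC"
  out
}

## Deterministic TSV writer: fixed column order, no quoting, "." for NA.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    colClasses = colClasses, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

site_key <- function(contig, pos) paste0(contig, ":", pos)
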