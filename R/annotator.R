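## Site annotation: genomic region class (with a fixed precedence order),
## repeat class (Alu precedence), dbSNP / known-editing / pseudogene flags,
## homopolymer proximity, flank mappability (seed-and-extend, ungapped),
## recoding consequences, and the ordered exclusion cascade with a
## conservation-checked ledger.

sites_gr <- function(sites) {
  GenomicRanges::GRanges(sites$contig, IRanges::IRanges(sites$pos, sites$pos))
}

bed_gr <- function(bed) {
  if (is.null(bed) || !nrow(bed)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(bed$contig, IRanges::IRanges(bed$start, bed$end))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify sites by genomic region
#'
#' Deterministic class via the precedence
#' exonic > 3'UTR > 5'UTR > ncRNA > NMD/processed_transcript > intronic >
#' upstream > downstream > other. "exonic" means within a CDS; upstream and
#' downstream are within `flank_bp` of a gene 5' / 3' end, strand-aware.
#' The gene/transcript of the first matching feature is assigned.
#'
#' @param sites data.frame with contig, pos.
#' @param gene_models gene-model data.frame (see [read_gene_models()]).
#' @param flank_bp up/downstream window (default 1000).
#' @return `sites` with region_class, gene_id, transcript_id, gene_name and
#'   gene_strand columns appended.
#' @export
classify_region <- function(sites, gene_models, flank_bp = 1000) {
  validate_gene_models(gene_models)
  gm <- gene_models[order(gene_models$contig, gene_models$start), ]
  n <- nrow(sites)
  region <- rep(NA_character_, n)
  gene_id <- tx_id <- gene_name <- gstrand <- rep(NA_character_, n)
  gr <- sites_gr(sites)

  nc_bio <- c("ncRNA", "lincRNA", "lncRNA", "miRNA", "snoRNA")
  nmd_bio <- c("processed_transcript", "NMD", "nonsense_mediated_decay")
  genes <- gm[gm$feature == "gene", ]
  up <- genes; dn <- genes
  up$start <- ifelse(genes$strand == "+", pmax(1, genes$start - flank_bp), genes$end + 1)
  up$end <- ifelse(genes$strand == "+", genes$start - 1, genes$end + flank_bp)
  dn$start <- ifelse(genes$strand == "+", genes$end + 1, pmax(1, genes$start - flank_bp))
  dn$end <- ifelse(genes$strand == "+", genes$end + flank_bp, genes$start - 1)

  cats <- list(
    exonic = gm[gm$feature == "CDS", ],
    `3'UTR` = gm[gm$feature == "three_prime_utr", ],
    `5'UTR` = gm[gm$feature == "five_prime_utr", ],
    ncRNA = gm[gm$feature == "exon" & gm$biotype %in% nc_bio, ],
    `NMD/processed_transcript` = gm[gm$feature == "exon" & gm$biotype %in% nmd_bio, ],
    intronic = genes,
    upstream = up,
    downstream = dn)
  for (cl in names(cats)) {
    feat <- cats[[cl]]
    feat <- feat[feat$end >= feat$start, , drop = FALSE]  # clamp-empty flanks
    if (!nrow(feat)) next
    fgr <- GenomicRanges::GRanges(feat$contig, IRanges::IRanges(feat$start, feat$end))
    hit <- GenomicRanges::findOverlaps(gr, fgr, select = "first")
    take <- is.na(region) & !is.na(hit)
    region[take] <- cl
    gene_id[take] <- feat$gene_id[hit[take]]
    tx_id[take] <- feat$transcript_id[hit[take]]
    gene_name[take] <- feat$gene_name[hit[take]]
    gstrand[take] <- feat$strand[hit[take]]
  }
  region[is.na(region)] <- "other"
  sites$region_class <- region
  sites$gene_id <- gene_id
  sites$transcript_id <- tx_id
  sites$gene_name <- gene_name
  sites$gene_strand <- gstrand
  ## strand-resolved RDD: a genomic T>C inside a minus-strand gene is an
  ## A>G event on the transcript
  if (!is.null(sites$rdd_type)) {
    flip <- !is.na(gstrand) & gstrand == "-"
    ref <- substr(sites$rdd_type, 1, 1)
    alt <- substr(sites$rdd_type, 3, 3)
    sites$strand_rdd <- ifelse(flip,
                               paste0(COMPLEMENT[ref], ">", COMPLEMENT[alt]),
                               sites$rdd_type)
  }
  sites
}

#' Annotate SNP, known-editing, pseudogene and repeat status
#'
#' SNP and known-editing membership by exact position; pseudogene and repeat
#' by interval overlap, with Alu taking precedence over any nested repeat
#' class.
#'
#' @param sites site data.frame (contig, pos).
#' @param snps VCF-lite data.frame (or NULL).
#' @param known known-editing data.frame (or NULL).
#' @param pseudogenes,repeats interval data.frames (1-based; or NULL).
#' @return `sites` with in_dbsnp, in_known_editing, in_pseudogene and
#'   repeat_class columns appended.
#' @export
annotate_flags <- function(sites, snps = NULL, known = NULL,
                           pseudogenes = NULL, repeats = NULL) {
  key <- site_key(sites$contig, sites$pos)
  for (nm in c("snps", "known", "pseudogenes", "repeats"))
    if (is.null(get(nm))) warnf("annotate_flags: %s track absent; flags set FALSE", nm)
  sites$in_dbsnp <- if (!is.null(snps) && nrow(snps))
    key %in% site_key(snps$contig, snps$pos) else FALSE
  sites$in_known_editing <- if (!is.null(known) && nrow(known))
    key %in% site_key(known$contig, known$pos) else FALSE
  gr <- sites_gr(sites)
  sites$in_pseudogene <- if (!is.null(pseudogenes) && nrow(pseudogenes))
    !is.na(GenomicRanges::findOverlaps(gr, bed_gr(pseudogenes), select = "first"))
  else FALSE
  rep_class <- rep("none", nrow(sites))
  if (!is.null(repeats) && nrow(repeats)) {
    alu <- repeats[repeats$class == "Alu", , drop = FALSE]
    oth <- repeats[repeats$class != "Alu", , drop = FALSE]
    hit <- GenomicRanges::findOverlaps(gr, bed_gr(oth), select = "first")
    rep_class[!is.na(hit)] <- oth$class[hit[!is.na(hit)]]
    hit_alu <- GenomicRanges::findOverlaps(gr, bed_gr(alu), select = "first")
    rep_class[!is.na(hit_alu)] <- "Alu"  # Alu precedence over nested classes
  }
  sites$repeat_class <- rep_class
  sites
}

#' Flag sites within or near a homopolymer run
#'
#' TRUE iff a run of at least `min_run` identical bases lies within
#' `near_window` bases of the site (distance 0 when the site is inside the
#' run).
#'
#' @param sites site data.frame.
#' @param reference `Biostrings::DNAStringSet`.
#' @param min_run minimum run length (default 5).
#' @param near_window maximum distance in bases (default 2).
#' @return logical vector.
#' @export
annotate_homopolymer <- function(sites, reference, min_run = 5, near_window = 2) {
  w <- near_window + min_run
  lens <- stats::setNames(Biostrings::width(reference), names(reference))
  vapply(seq_len(nrow(sites)), function(i) {
    pos <- sites$pos[i]; contig <- sites$contig[i]
    L <- lens[[contig]]
    if (is.na(L) || pos < 1 || pos > L)
      stopf("annotate_homopolymer: position %s:%d outside contig", contig, pos)
    lo <- max(1, pos - w); hi <- min(L, pos + w)
    chars <- strsplit(as.character(Biostrings::subseq(reference[[contig]], lo, hi)),
                      "")[[1]]
    r <- rle(chars)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    run <- which(r$lengths >= min_run)
    if (!length(run)) return(FALSE)
    gs <- lo + starts[run] - 1; ge <- lo + ends[run] - 1
    dist <- pmax(0, pmax(gs - pos, pos - ge))
    any(dist <= near_window)
  }, TRUE)
}

#' Flank mappability by exact-seed, ungapped extension
#'
#' Counts the genomic placements of the site's flanking window (site +/-
#' `flank` bases, truncated at contig ends) with sequence identity above
#' `min_identity`. Placements are found by exact matches of the
#' `seed_length`-mer centred on the site and extended without gaps; the self
#' placement is included, so the count is >= 1. Forward strand only.
#'
#' @param sites site data.frame.
#' @param reference `Biostrings::DNAStringSet`.
#' @param flank flank length each side (default 100).
#' @param min_identity identity threshold (default 0.90, exclusive).
#' @param seed_length exact-seed length (default 20).
#' @return integer vector of placement counts.
#' @export
flank_multiplicity <- function(sites, reference, flank = 100,
                               min_identity = 0.90, seed_length = 20) {
  vapply(seq_len(nrow(sites)), function(i) {
    contig <- sites$contig[i]; pos <- sites$pos[i]
    subject <- reference[[contig]]
    L <- length(subject)
    ws <- max(1, pos - flank); we <- min(L, pos + flank)
    win <- strsplit(as.character(Biostrings::subseq(subject, ws, we)), "")[[1]]
    ss <- max(ws, min(pos - seed_length %/% 2, we - seed_length + 1))
    seed <- Biostrings::subseq(subject, ss, ss + seed_length - 1)
    count <- 0L
    for (ctg in names(reference)) {
      m <- Biostrings::matchPattern(seed, reference[[ctg]])
      starts <- IRanges::start(m)
      for (st in starts) {
        cand_ws <- st - (ss - ws)
        span_lo <- max(1, cand_ws)
        span_hi <- min(length(reference[[ctg]]), cand_ws + length(win) - 1)
        if (span_hi < span_lo) next
        cand <- strsplit(as.character(
          Biostrings::subseq(reference[[ctg]], span_lo, span_hi)), "")[[1]]
        wi <- (span_lo - cand_ws + 1):(span_hi - cand_ws + 1)
        ident <- mean(cand == win[wi])
        if (ident > min_identity) count <- count + 1L
      }
    }
    count
  }, 1L)
}

#' Recoding consequence of an editing site within a CDS
#'
#' The codon is resolved in coding orientation (a genomic T>C in a
#' minus-strand CDS is read as transcript A>G), translated with the standard
#' genetic code; synonymous changes have aa_before == aa_after. Transcripts
#' whose CDS length is not a multiple of 3 are skipped with a warning.
#'
#' @param sites annotated sites (needs region_class, transcript_id, alt).
#' @param gene_models gene-model data.frame.
#' @param reference `Biostrings::DNAStringSet`.
#' @return data.frame with codon_before, codon_after, aa_before, aa_after,
#'   codon_pos (1-3), synonymous; NA rows for non-CDS sites.
#' @export
annotate_recoding <- function(sites, gene_models, reference) {
  out <- data.frame(codon_before = NA_character_, codon_after = NA_character_,
                    aa_before = NA_character_, aa_after = NA_character_,
                    codon_pos = NA_integer_, synonymous = NA,
                    stringsAsFactors = FALSE)[rep(1, nrow(sites)), ]
  rownames(out) <- NULL
  gc_tab <- Biostrings::GENETIC_CODE
  cds_all <- gene_models[gene_models$feature == "CDS", ]
  idx <- which(sites$region_class == "exonic" & !is.na(sites$transcript_id))
  for (i in idx) {
    tx <- sites$transcript_id[i]
    cds <- cds_all[cds_all$transcript_id == tx, ]
    if (!nrow(cds)) next
    cds <- cds[order(cds$start), ]
    minus <- cds$strand[1] == "-"
    if (sum(cds$end - cds$start + 1) %% 3 != 0) {
      warnf("annotate_recoding: CDS of %s not a multiple of 3; skipped", tx)
      next
    }
    pieces <- lapply(seq_len(nrow(cds)), function(k)
      as.character(Biostrings::subseq(reference[[cds$contig[k]]],
                                      cds$start[k], cds$end[k])))
    cds_seq <- paste(pieces, collapse = "")
    ## genomic offsets of each CDS base, 5'->3' in transcript orientation
    gpos <- unlist(lapply(seq_len(nrow(cds)), function(k) cds$start[k]:cds$end[k]))
    if (minus) {
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
      gpos <- rev(gpos)
    }
    cpos <- match(sites$pos[i], gpos)
    if (is.na(cpos)) next
    chars <- strsplit(cds_seq, "")[[1]]
    alt_tx <- if (minus) COMPLEMENT[[sites$alt[i]]] else sites$alt[i]
    ci <- (cpos - 1) %/% 3
    codon <- chars[(ci * 3 + 1):(ci * 3 + 3)]
    codon_after <- codon
    codon_after[(cpos - 1) %% 3 + 1] <- alt_tx
    cb <- paste(codon, collapse = ""); ca <- paste(codon_after, collapse = "")
    out$codon_before[i] <- cb; out$codon_after[i] <- ca
    out$aa_before[i] <- gc_tab[[cb]]; out$aa_after[i] <- gc_tab[[ca]]
    out$codon_pos[i] <- (cpos - 1) %% 3 + 1
    out$synonymous[i] <- gc_tab[[cb]] == gc_tab[[ca]]
  }
  out
}

#' Annotate candidate sites against all tracks
#'
#' Convenience driver: region classification, track flags, homopolymer and
#' flank-mappability annotation (computed once per unique site), and
#' recoding consequences.
#'
#' @param candidates `candidate_sites` data.frame.
#' @param gene_models gene-model data.frame.
#' @param reference `Biostrings::DNAStringSet`.
#' @param snps,known,pseudogenes,repeats annotation tracks (may be NULL).
#' @param flank,min_identity,seed_length see [flank_multiplicity()].
#' @param min_run,near_window see [annotate_homopolymer()].
#' @param recoding compute recoding consequences (default TRUE).
#' @return annotated-site data.frame (class `annotated_sites`).
#' @export
annotate_sites <- function(candidates, gene_models, reference,
                           snps = NULL, known = NULL, pseudogenes = NULL,
                           repeats = NULL, flank = 100, min_identity = 0.90,
                           seed_length = 20, min_run = 5, near_window = 2,
                           recoding = TRUE) {
  ann <- classify_region(candidates, gene_models)
  ann <- annotate_flags(ann, snps = snps, known = known,
                        pseudogenes = pseudogenes, repeats = repeats)
  ## per-unique-site sequence annotations, joined back to per-sample rows
  key <- site_key(ann$contig, ann$pos)
  uniq <- !duplicated(key)
  usites <- ann[uniq, c("contig", "pos")]
  hp <- annotate_homopolymer(usites, reference, min_run = min_run,
                             near_window = near_window)
  fm <- flank_multiplicity(usites, reference, flank = flank,
                           min_identity = min_identity, seed_length = seed_length)
  m <- match(key, key[uniq])
  ann$homopolymer_flag <- hp[m]
  ann$flank_multiplicity <- fm[m]
  if (recoding) {
    rec_u <- annotate_recoding(ann[uniq, ], gene_models, reference)
    ann <- cbind(ann, rec_u[m, , drop = FALSE])
    rownames(ann) <- NULL
  }
  class(ann) <- c("annotated_sites", "data.frame")
  ann
}

FILTER_NAMES <- c("pseudogene", "dbsnp_not_known", "nonalu_repeat",
                  "homopolymer", "flank_multimap")

#' Apply the exclusion cascade
#'
#' Ordered filters: (1) pseudogene overlap; (2) dbSNP membership without a
#' known-editing-catalog record (catalog membership rescues the site);
#' (3) simple-repeat / low-complexity location outside Alu (Alu exempts).
#' Homopolymer proximity and flank multi-mapping are annotations by default
#' and become filters 4-5 only on request. Each removed site is attributed
#' to its first failing filter; the ledger conserves counts exactly.
#'
#' @param annotated `annotated_sites` data.frame.
#' @param use_homopolymer also filter homopolymer-adjacent sites (default
#'   FALSE).
#' @param use_multiplicity also filter sites whose flank maps more than
#'   `max_multiplicity` times (default FALSE).
#' @param max_multiplicity threshold for the optional mappability filter.
#' @return list with `retained` (annotated sites passing all filters) and
#'   `ledger` (class `filter_ledger`).
#' @export
apply_filters <- function(annotated, use_homopolymer = FALSE,
                          use_multiplicity = FALSE, max_multiplicity = 1) {
  fails <- list(
    pseudogene = annotated$in_pseudogene,
    dbsnp_not_known = annotated$in_dbsnp & !annotated$in_known_editing,
    nonalu_repeat = annotated$repeat_class %in% c("Simple_repeat", "Low_complexity"))
  if (use_homopolymer) fails$homopolymer <- annotated$homopolymer_flag
  if (use_multiplicity)
    fails$flank_multimap <- annotated$flank_multiplicity > max_multiplicity
  first_fail <- rep(NA_character_, nrow(annotated))
  for (f in rev(names(fails))) first_fail[fails[[f]]] <- f
  removed <- vapply(names(fails), function(f)
    sum(first_fail == f, na.rm = TRUE), 1L)
  retained <- annotated[is.na(first_fail), , drop = FALSE]
  rownames(retained) <- NULL
  ledger <- structure(list(filters = names(fails), removed = removed,
                           retained = nrow(retained), input = nrow(annotated),
                           first_fail = first_fail),
                      class = "filter_ledger")
  stopifnot(ledger$input == ledger$retained + sum(ledger$removed))
  list(retained = retained, ledger = ledger)
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat(sprintf("filter ledger: %d candidates -> %d retained\n", x$input, x$retained))
  for (i in seq_along(x$filters))
    cat(sprintf("  %-18s removed %d\n", x$filters[i], x$removed[i]))
  invisible(x)
}

#' @method as.data.frame filter_ledger
#' @export
as.data.frame.filter_ledger <- function(x, ...) {
  data.frame(filter = c(x$filters, "retained"),
             count = c(unname(x$removed), x$retained),
             stringsAsFactors = FALSE)
}

#' QC: overlap with the known-editing catalog and Alu enrichment
#'
#' @param sites retained annotated sites.
#' @param known known-editing data.frame.
#' @return list with `known_overlap` (pooled fraction of unique sites in the
#'   catalog), `known_overlap_by_sample`, `alu_fraction`, and `n_sites`.
#' @export
qc_overlap_known <- function(sites, known) {
  key <- site_key(sites$contig, sites$pos)
  kk <- if (!is.null(known) && nrow(known)) site_key(known$contig, known$pos)
  else character()
  uniq <- !duplicated(key)
  by_sample <- if (!is.null(sites$sample))
    vapply(split(key %in% kk, sites$sample), mean, 1) else NULL
  list(known_overlap = if (any(uniq)) mean(key[uniq] %in% kk) else NA_real_,
       known_overlap_by_sample = by_sample,
       alu_fraction = if (!is.null(sites$repeat_class) && any(uniq))
         mean(sites$repeat_class[uniq] == "Alu") else NA_real_,
       n_sites = sum(uniq))
}
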