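test_that("region classification follows the stated precedence", {
  gm <- tiny_gene_models()
  sites <- data.frame(contig = "chrT",
                      pos = c(180,   # intron of gX only
                              260,   # 3'UTR of tX and intron of gY
                              140,   # CDS -> exonic
                              110,   # 5'UTR
                              350,   # intron of gY only
                              800,   # past the genes, within gZ's 5' window
                              1900)) # beyond any 1 kb window
  cls <- classify_region(sites, gm)
  expect_equal(cls$region_class[1:5],
               c("intronic", "3'UTR", "exonic", "5'UTR", "intronic"))
  ## 800 is 100 bp past gZ (minus strand) -> upstream of gZ? gZ spans 601-700 on
  ## minus strand, so its 5' end is 700: positions 701-1700 are upstream.
  expect_equal(cls$region_class[6], "upstream")
  expect_equal(cls$region_class[7], "other")
})

test_that("up/downstream are strand-aware 1 kb windows", {
  row <- function(feature, start, end, strand)
    data.frame(contig = "chrT", source = "t", feature = feature, start = start,
               end = end, strand = strand, gene_id = "g1", transcript_id = NA,
               gene_name = "G1", biotype = "protein_coding",
               stringsAsFactors = FALSE)
  gm <- rbind(row("gene", 2000, 3000, "+"), row("transcript", 2000, 3000, "+"))
  cls <- classify_region(data.frame(contig = "chrT", pos = c(3500, 1500)), gm)
  expect_equal(cls$region_class, c("downstream", "upstream"))
  gm_m <- rbind(row("gene", 2000, 3000, "-"), row("transcript", 2000, 3000, "-"))
  cls <- classify_region(data.frame(contig = "chrT", pos = c(3500, 1500)), gm_m)
  expect_equal(cls$region_class, c("upstream", "downstream"))
})

test_that("strand-resolved RDD flips genomic T>C in minus-strand genes to A>G", {
  gm <- tiny_gene_models()
  sites <- data.frame(contig = "chrT", pos = c(140, 620),
                      rdd_type = c("A>G", "T>C"))
  cls <- classify_region(sites, gm)
  expect_equal(cls$strand_rdd, c("A>G", "A>G"))
})

test_that("track flags: dbSNP, known-editing rescue, pseudogene, Alu precedence", {
  sites <- data.frame(contig = "chr1", pos = c(10, 20, 30, 40))
  snps <- data.frame(contig = "chr1", pos = c(10, 20), id = c("rs1", "rs2"),
                     ref = "A", alt = "G")
  known <- data.frame(contig = "chr1", pos = 20, ref = "A", alt = "G")
  repeats <- data.frame(contig = "chr1", start = c(25, 28), end = c(45, 35),
                        name = c("sr", "alu"), class = c("Simple_repeat", "Alu"))
  pg <- data.frame(contig = "chr1", start = 39, end = 60, name = "psi",
                   class = "pseudogene")
  ann <- annotate_flags(sites, snps = snps, known = known,
                        pseudogenes = pg, repeats = repeats)
  expect_equal(ann$in_dbsnp, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ann$in_known_editing, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(ann$in_pseudogene, c(FALSE, FALSE, FALSE, TRUE))
  ## nested Alu takes precedence over the surrounding simple repeat
  expect_equal(ann$repeat_class, c("none", "none", "Alu", "Simple_repeat"))
  ## absent tracks warn (one warning per track) and set flags false
  w <- capture_warnings(a2 <- annotate_flags(sites))
  expect_length(w, 4)
  expect_true(all(grepl("absent", w)))
  expect_false(any(a2$in_dbsnp))
})

test_that("homopolymer proximity uses the run-length and distance thresholds", {
  ref <- Biostrings::DNAStringSet(c(
    chrH = paste0("ACGTACGTAC", "AAAAA", "CGTACGTACT",   # run at 11-15
                  "GGGG",                                 # run of 4 at 26-29
                  "ACGTACGTACGTACGTACGT")))
  site <- function(p) data.frame(contig = "chrH", pos = p)
  expect_true(annotate_homopolymer(site(16), ref))   # immediately 3' of AAAAA
  expect_true(annotate_homopolymer(site(13), ref))   # inside the run
  expect_true(annotate_homopolymer(site(17), ref))   # distance 2
  expect_false(annotate_homopolymer(site(18), ref))  # distance 3
  expect_false(annotate_homopolymer(site(40), ref))  # plain context
  expect_false(annotate_homopolymer(site(31), ref))  # run of 4 < min_run
  expect_true(annotate_homopolymer(site(31), ref, min_run = 4))
  expect_error(annotate_homopolymer(site(1000), ref), "outside")
})

test_that("flank multiplicity: unique, duplicated, and diverged-copy genomes", {
  set.seed(9)
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, 3000, replace = TRUE)
  segment <- chars[1001:1300]              # 300 bp around the site at 1150
  unique_ref <- Biostrings::DNAStringSet(c(chrF = paste(chars, collapse = "")))
  s <- data.frame(contig = "chrF", pos = 1150)
  expect_equal(flank_multiplicity(s, unique_ref), 1L)

  ## exact duplicate -> 2, confirmed by the sliding-identity oracle
  dup <- c(chars, segment, sample(bases, 100, replace = TRUE))
  dup_ref <- Biostrings::DNAStringSet(c(chrF = paste(dup, collapse = "")))
  expect_equal(flank_multiplicity(s, dup_ref), 2L)
  win <- dup[(1150 - 100):(1150 + 100)]
  expect_equal(sliding_identity_oracle(win, dup), 2L)

  ## 15% mismatches in the copy push identity below 0.90 -> only self remains
  seg_bad <- segment
  mut <- seq(1, 300, by = 7)               # ~43/300 = 14.3% positions mutated
  seg_bad[mut] <- vapply(seg_bad[mut], function(b) setdiff(bases, b)[1], "")
  div <- c(chars, seg_bad, sample(bases, 100, replace = TRUE))
  div_ref <- Biostrings::DNAStringSet(c(chrF = paste(div, collapse = "")))
  expect_equal(flank_multiplicity(s, div_ref), 1L)
  expect_equal(sliding_identity_oracle(div[(1150 - 100):(1150 + 100)], div), 1L)
})

test_that("recoding resolves codons in coding orientation", {
  ## tX CDS: 131-160 + 201-230 (plus strand). Put CAG at codon 2 (134-136):
  chars <- rep("T", 800)
  chars[131:160] <- strsplit("ATGCAGGCAAAAAAAAAAAAAAAAAAAAAA", "")[[1]]
  chars[201:230] <- rep("A", 30)
  ## gZ CDS 601-660, minus strand; genomic 601-660 reverse-complemented is
  ## the coding sequence. Put genomic CTG at 655-657 -> transcript CAG codon 2.
  chars[601:660] <- rep("T", 60)
  chars[658:660] <- c("C", "A", "T")   # transcript codon1 ATG
  chars[655:657] <- c("C", "T", "G")   # transcript codon2 CAG (revcomp)
  ref <- Biostrings::DNAStringSet(c(chrT = paste(chars, collapse = "")))
  gm <- tiny_gene_models()

  ## A>G at codon position 2 of CAG: Q -> R (the classic recoding signature)
  sites <- data.frame(contig = "chrT", pos = 135, alt = "G",
                      region_class = "exonic", transcript_id = "tX")
  rec <- annotate_recoding(sites, gm, ref)
  expect_equal(rec$codon_before, "CAG")
  expect_equal(rec$codon_after, "CGG")
  expect_equal(rec$aa_before, "Q")
  expect_equal(rec$aa_after, "R")
  expect_false(rec$synonymous)

  ## A>G at codon position 3 of GCA -> GCG, synonymous Ala
  sites <- data.frame(contig = "chrT", pos = 139, alt = "G",
                      region_class = "exonic", transcript_id = "tX")
  rec <- annotate_recoding(sites, gm, ref)
  expect_equal(rec$codon_before, "GCA")
  expect_equal(rec$codon_after, "GCG")
  expect_true(rec$synonymous)
  expect_equal(rec$aa_before, rec$aa_after)

  ## genomic T>C in the minus-strand CDS reads as transcript A>G
  sites <- data.frame(contig = "chrT", pos = 656, alt = "C",
                      region_class = "exonic", transcript_id = "tZ")
  rec <- annotate_recoding(sites, gm, ref)
  expect_equal(rec$codon_before, "CAG")
  expect_equal(rec$codon_after, "CGG")
  expect_equal(rec$aa_after, "R")
})

test_that("recoding skips transcripts whose CDS is not a codon multiple", {
  gm <- tiny_gene_models()
  gm$end[gm$feature == "CDS" & gm$transcript_id == "tX" & gm$start == 201] <- 229
  ref <- Biostrings::DNAStringSet(c(chrT = paste(rep("A", 800), collapse = "")))
  sites <- data.frame(contig = "chrT", pos = 135, alt = "G",
                      region_class = "exonic", transcript_id = "tX")
  expect_warning(rec <- annotate_recoding(sites, gm, ref), "multiple of 3")
  expect_true(is.na(rec$codon_before))
})

test_that("filter cascade: ordering, Alu exemption, rescue, conservation", {
  ann <- data.frame(
    contig = "chr1", pos = 1:6,
    in_pseudogene =     c(TRUE,  FALSE, FALSE, FALSE, FALSE, TRUE),
    in_dbsnp =          c(TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE),
    in_known_editing =  c(FALSE, FALSE, TRUE,  FALSE, FALSE, FALSE),
    repeat_class = c("none", "none", "none", "Simple_repeat", "Alu", "Low_complexity"),
    stringsAsFactors = FALSE)
  fl <- apply_filters(ann)
  ## site 1: pseudogene AND snp -> attributed to the first filter
  expect_equal(fl$ledger$first_fail[1], "pseudogene")
  expect_equal(fl$ledger$first_fail[2], "dbsnp_not_known")
  ## site 3: snp but in the known catalog -> rescued
  expect_true(3 %in% fl$retained$pos)
  ## site 4: non-Alu simple repeat removed; site 5: Alu exempts
  expect_equal(fl$ledger$first_fail[4], "nonalu_repeat")
  expect_true(5 %in% fl$retained$pos)
  expect_equal(fl$ledger$first_fail[6], "pseudogene")
  ## conservation and one-filter attribution
  expect_equal(fl$ledger$input, fl$ledger$retained + sum(fl$ledger$removed))
  expect_equal(sum(!is.na(fl$ledger$first_fail)), sum(fl$ledger$removed))
  ## idempotence: filtering the retained set removes nothing
  fl2 <- apply_filters(fl$retained)
  expect_equal(fl2$ledger$retained, nrow(fl$retained))
  expect_equal(sum(fl2$ledger$removed), 0L)
})

test_that("optional homopolymer/mappability filters engage only on request", {
  ann <- data.frame(contig = "chr1", pos = 1:2, in_pseudogene = FALSE,
                    in_dbsnp = FALSE, in_known_editing = FALSE,
                    repeat_class = "none", homopolymer_flag = c(TRUE, FALSE),
                    flank_multiplicity = c(1L, 3L))
  expect_equal(apply_filters(ann)$ledger$retained, 2L)
  expect_equal(apply_filters(ann, use_homopolymer = TRUE)$ledger$retained, 1L)
  fl <- apply_filters(ann, use_homopolymer = TRUE, use_multiplicity = TRUE)
  expect_equal(fl$ledger$retained, 0L)
})

test_that("known-site overlap and Alu-enrichment QC", {
  sites <- data.frame(contig = "chr1", pos = c(1, 2, 3, 4),
                      repeat_class = c("Alu", "Alu", "none", "Alu"),
                      sample = "s1")
  known_all <- data.frame(contig = "chr1", pos = 1:4)
  expect_equal(qc_overlap_known(sites, known_all)$known_overlap, 1.0)
  expect_equal(qc_overlap_known(sites, known_all[0, ])$known_overlap, 0.0)
  qc <- qc_overlap_known(sites, data.frame(contig = "chr1", pos = 1:2))
  expect_equal(qc$known_overlap, 0.5)
  expect_equal(qc$alu_fraction, 0.75)
})

test_that("malformed gene models (exon outside transcript) fail at load", {
  gm <- tiny_gene_models()
  gm$end[gm$feature == "exon" & gm$start == 101 & gm$transcript_id == "tX"] <- 400
  path <- withr::local_tempfile(fileext = ".gtf")
  f <- gm
  expect_error(
    {write_gene_models(f, path); read_gene_models(path)},
    "outside transcript")
})
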