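## End-to-end orchestration: one config drives simulate/load -> call ->
## annotate+filter -> editome -> differential -> integrate -> enrich, with
## a structured (timestamp-free, hence byte-reproducible) log, the filter
## ledger, and a QC JSON. Subcommands of the `rededit` script map onto the
## exported stage functions; `editome_cli()` is the dispatcher.

#' Build a run configuration
#'
#' Every pipeline threshold is surfaced as a named key with the editome
#' pipeline's value as default. Round-trips through YAML unchanged.
#'
#' @param mode "synthetic" (generate inputs from `synthetic`) or "files"
#'   (read the paths in `inputs`).
#' @param out_dir output directory for the result bundle.
#' @param seed integer seed for every stochastic stage.
#' @param synthetic named overrides passed to [synthetic_config()].
#' @param inputs named file paths (mode "files"): pileup, genome_fa,
#'   genes_gtf, repeats_bed, pseudogenes_bed, snps_vcf, known_tsv,
#'   counts_tsv, gmt, groups_tsv (sample, group columns).
#' @param min_coverage,min_frequency,min_quality,min_alt_reads caller
#'   thresholds.
#' @param presence_threshold group-editome presence rule.
#' @param alpha significance level for differential editing/expression.
#' @param lfc_cutoff differential-expression log2FC cutoff.
#' @param r_cutoff,p_cutoff correlation significance rule.
#' @param case,control group labels.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), out_dir = tempfile("run"),
                       seed = 1L, synthetic = list(), inputs = list(),
                       min_coverage = 10, min_frequency = 0.10,
                       min_quality = 25, min_alt_reads = 2,
                       presence_threshold = 0.5, alpha = 0.05,
                       lfc_cutoff = 0.5, r_cutoff = 0.5, p_cutoff = 0.05,
                       case = "case", control = "control") {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
              synthetic = synthetic, inputs = inputs,
              min_coverage = min_coverage, min_frequency = min_frequency,
              min_quality = min_quality, min_alt_reads = min_alt_reads,
              presence_threshold = presence_threshold, alpha = alpha,
              lfc_cutoff = lfc_cutoff, r_cutoff = r_cutoff,
              p_cutoff = p_cutoff, case = case, control = control,
              schema = "rededit-run/1")
  if (mode == "files") {
    missing <- setdiff(c("pileup", "genome_fa", "genes_gtf"), names(inputs))
    if (length(missing))
      stopf("run_config: files mode needs inputs: %s", paste(missing, collapse = ", "))
    for (p in unlist(inputs)) if (!file.exists(p)) stopf("run_config: missing file %s", p)
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$synthetic <- y$synthetic %||% list()
  y$inputs <- y$inputs %||% list()
  do.call(run_config, y[setdiff(names(y), "schema")])
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full editome pipeline
#'
#' Stages run in fixed order (simulate/load, call, annotate+filter,
#' editome, differential, integrate, enrich); each stage logs its
#' input/output row counts; a stage failure aborts with the ledger emitted
#' up to that point. When the counts matrix is unavailable the integration
#' and enrichment stages are skipped with explicit log lines.
#'
#' @param config a [run_config()] (or path to its YAML).
#' @return invisibly, the result bundle: list with genome/pileups (synthetic
#'   mode), candidates, annotated, retained, ledger, qc, editomes, global,
#'   region_distribution, dedit, gene_summary, expression results,
#'   enrichment, log, and the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  logline <- function(stage, fmt, ...) {
    log <<- c(log, sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  bundle <- list(out_dir = out_dir)

  ## ---- stage: inputs -----------------------------------------------------
  if (config$mode == "synthetic") {
    scfg <- do.call(synthetic_config, c(config$synthetic,
                                        list(seed = config$seed)))
    genome <- make_genome(scfg, dir = file.path(out_dir, "inputs"))
    sim <- simulate_pileups(genome, scfg)
    counts <- simulate_expression(genome, sim$mean_editing, scfg)
    pileup <- sim$pileup
    groups <- stats::setNames(sim$samples$group, sim$samples$sample)
    reference <- genome$sequence
    gm <- genome$genes; repeats <- genome$repeats; snps <- genome$snps
    known <- genome$known; pseudogenes <- genome$pseudogenes
    bundle$genome <- genome; bundle$pileups <- sim
    write_pileup(pileup, file.path(out_dir, "pileup.tsv"))
    utils::write.table(counts, file.path(out_dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    logline("simulate", "genome %d bp, %d true sites, %d samples, %d pileup rows",
            scfg$genome_length, nrow(genome$truth$true_sites),
            length(groups), nrow(pileup))
  } else {
    inp <- config$inputs
    pileup <- read_pileup(inp$pileup)
    reference <- Biostrings::readDNAStringSet(inp$genome_fa)
    names(reference) <- sub("\\s.*", "", names(reference))
    gm <- read_gene_models(inp$genes_gtf)
    repeats <- if (!is.null(inp$repeats_bed)) read_bed(inp$repeats_bed)
    snps <- if (!is.null(inp$snps_vcf)) read_vcf_lite(inp$snps_vcf)
    known <- if (!is.null(inp$known_tsv)) read_known_sites(inp$known_tsv)
    pseudogenes <- if (!is.null(inp$pseudogenes_bed)) read_bed(inp$pseudogenes_bed)
    counts <- if (!is.null(inp$counts_tsv))
      as.matrix(utils::read.table(inp$counts_tsv, sep = "\t", header = TRUE,
                                  row.names = 1, check.names = FALSE))
    else NULL
    gtab <- utils::read.table(inp$groups_tsv, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    groups <- stats::setNames(gtab$group, gtab$sample)
    logline("load", "%d pileup rows, %d samples", nrow(pileup), length(groups))
  }

  ## ---- stage: call -------------------------------------------------------
  cand <- call_sites(pileup, min_coverage = config$min_coverage,
                     min_frequency = config$min_frequency,
                     min_quality = config$min_quality,
                     min_alt_reads = config$min_alt_reads,
                     reference = reference)
  logline("call", "%d pileup rows -> %d candidate calls", nrow(pileup), nrow(cand))
  bundle$candidates <- cand

  ## ---- stage: annotate + filter ------------------------------------------
  ann <- annotate_sites(cand, gm, reference, snps = snps, known = known,
                        pseudogenes = pseudogenes, repeats = repeats)
  fl <- apply_filters(ann)
  bundle$annotated <- ann; bundle$retained <- fl$retained; bundle$ledger <- fl$ledger
  write_tsv(fl$retained, file.path(out_dir, "retained_sites.tsv"))
  write_tsv(as.data.frame(fl$ledger), file.path(out_dir, "filter_ledger.tsv"))
  spec <- rdd_spectrum(fl$retained)
  qc <- qc_overlap_known(fl$retained, known)
  bundle$qc <- list(rdd_spectrum = as.list(spec$spectrum),
                    adar_fraction = spec$adar_fraction,
                    alu_fraction = qc$alu_fraction,
                    known_overlap = qc$known_overlap,
                    n_candidates = nrow(cand), n_retained = nrow(fl$retained))
  jsonlite::write_json(bundle$qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  logline("filter", "%d candidates -> %d retained (%s)", nrow(ann),
          nrow(fl$retained),
          paste(sprintf("%s:%d", fl$ledger$filters, fl$ledger$removed),
                collapse = " "))

  ## ---- stage: editome ----------------------------------------------------
  sm <- build_site_matrix(fl$retained, samples = names(groups))
  eds <- build_group_editome(sm, groups,
                             presence_threshold = config$presence_threshold)
  ctl <- eds[[config$control]]; cse <- eds[[config$case]]
  glob <- compare_global(cse, ctl)
  reg <- genomic_distribution(cse, ctl)
  logline("editome", "%d/%d sites in %s/%s editomes; global Wilcoxon p=%.3g",
          cse$n_events, ctl$n_events, config$case, config$control, glob$p_value)
  dedit <- differential_editing(sm, groups, case = config$case,
                                control = config$control, alpha = config$alpha)
  gsum <- gene_level_summary(dedit, gm, alpha = config$alpha)
  logline("differential", "%d sites tested, %d DEdit in %d genes",
          nrow(dedit), sum(dedit$dedit), nrow(gsum))
  bundle$editomes <- eds; bundle$global <- glob
  bundle$region_distribution <- reg
  bundle$dedit <- dedit; bundle$gene_summary <- gsum
  write_site_matrix(sm, file.path(out_dir, "site_matrix.tsv"))
  for (g in names(eds))
    write_tsv(eds[[g]]$sites, file.path(out_dir, sprintf("editome_%s.tsv", g)))
  write_tsv(dedit, file.path(out_dir, "dedit_sites.tsv"))
  write_tsv(gsum, file.path(out_dir, "dedit_genes.tsv"))
  write_tsv(attr(gsum, "volcano"), file.path(out_dir, "volcano.tsv"))
  jsonlite::write_json(
    list(global = glob,
         region_distribution = reg,
         n_events = lapply(eds, function(e) e$n_events)),
    file.path(out_dir, "editome_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = 10)

  ## ---- stage: integrate --------------------------------------------------
  if (!is.null(counts)) {
    sf <- size_factors(counts)
    norm <- normalize_counts(counts, sf)
    de <- diff_expression(norm, groups, case = config$case,
                          control = config$control,
                          lfc_cutoff = config$lfc_cutoff)
    med <- overall_editing(sm)
    adar_genes <- grep("^ADAR", rownames(norm), value = TRUE)
    adar_cor <- if (length(adar_genes))
      adar_editing_correlation(norm, med, genes = adar_genes,
                               r_cutoff = config$r_cutoff,
                               p_cutoff = config$p_cutoff)
    else NULL
    bundle$size_factors <- sf; bundle$diff_expression <- de
    bundle$adar_correlation <- adar_cor
    bundle$overall_editing <- med
    write_tsv(de, file.path(out_dir, "diff_expression.tsv"))
    if (!is.null(adar_cor))
      write_tsv(adar_cor, file.path(out_dir, "adar_editing_correlation.tsv"))
    logline("integrate", "%d genes, %d DE; ADAR-like genes tested: %d",
            nrow(de), sum(de$de), length(adar_genes))
  } else {
    logline("integrate", "skipped: no counts matrix")
  }

  ## ---- stage: enrich -----------------------------------------------------
  dedit_genes <- unique(gsum$gene)
  background <- unique(fl$retained$gene_name[!is.na(fl$retained$gene_name)])
  gmt <- if (config$mode == "files" && !is.null(config$inputs$gmt))
    read_gmt(config$inputs$gmt)
  else if (config$mode == "synthetic" && length(dedit_genes) >= 2)
    make_gene_sets(background, dedit_genes, seed = config$seed)
  else NULL
  if (!is.null(gmt) && length(dedit_genes)) {
    enr <- enrich(dedit_genes, background, gmt)
    bundle$enrichment <- enr
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    logline("enrich", "%d terms tested, top: %s (FDR %.3g)",
            nrow(enr), if (nrow(enr)) enr$term[1] else "none",
            if (nrow(enr)) enr$fdr[1] else NA)
  } else {
    logline("enrich", "skipped: no gene sets or no DEdit genes")
  }

  bundle$log <- log
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(bundle)
}

#' Command-line dispatcher
#'
#' Backs the `rededit` script (inst/scripts). Subcommands: simulate, call,
#' annotate, editome, integrate, enrich, validate, run; `--version` prints
#' the package version. Returns the exit status (0 on success) invisibly.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
editome_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args) || args[1] %in% c("--help", "-h")) {
      cat("usage: rededit <simulate|call|annotate|editome|integrate|enrich|validate|run> [--key value ...]\n")
      return(invisible(0L))
    }
    if (args[1] == "--version") {
      cat(sprintf("rededit %s\n", as.character(utils::packageVersion("rededit"))))
      return(invisible(0L))
    }
    cmd <- args[1]
    opt <- cli_parse(args[-1])
    switch(cmd,
           simulate = cli_simulate(opt),
           call = cli_call(opt),
           annotate = cli_annotate(opt),
           editome = cli_editome(opt),
           integrate = cli_integrate(opt),
           enrich = cli_enrich(opt),
           validate = cli_validate(opt),
           run = { run_pipeline(read_run_config(cli_req(opt, "config"))); 0L },
           stopf("unknown subcommand '%s'", cmd))
    0L
  }, error = function(e) {
    message("rededit: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_parse <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stopf("unexpected argument '%s'", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opt[[key]] <- TRUE; i <- i + 1
    } else {
      opt[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  opt
}

cli_req <- function(opt, key) {
  if (is.null(opt[[key]])) stopf("missing required option --%s", key)
  opt[[key]]
}

cli_groups <- function(path) {
  g <- read_tsv(path)
  stats::setNames(g$group, g$sample)
}

cli_simulate <- function(opt) {
  cfg <- synthetic_config(seed = as.integer(opt$seed %||% 1))
  out <- cli_req(opt, "out")
  genome <- make_genome(cfg, dir = out)
  sim <- simulate_pileups(genome, cfg)
  write_pileup(sim$pileup, file.path(out, "pileup.tsv"))
  write_pileup(sim$gdna, file.path(out, "gdna_pileup.tsv"))
  write_tsv(sim$samples, file.path(out, "samples.tsv"))
  counts <- simulate_expression(genome, sim$mean_editing, cfg)
  utils::write.table(counts, file.path(out, "counts.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  0L
}

cli_call <- function(opt) {
  pileup <- read_pileup(cli_req(opt, "pileup"))
  ref <- if (!is.null(opt$fasta)) Biostrings::readDNAStringSet(opt$fasta)
  cand <- call_sites(pileup,
                     min_coverage = as.numeric(opt$`min-coverage` %||% 10),
                     min_frequency = as.numeric(opt$`min-frequency` %||% 0.10),
                     min_quality = as.numeric(opt$`min-quality` %||% 25),
                     min_alt_reads = as.numeric(opt$`min-alt-reads` %||% 2),
                     reference = ref)
  write_tsv(cand, cli_req(opt, "out"))
  0L
}

cli_annotate <- function(opt) {
  cand <- read_tsv(cli_req(opt, "candidates"))
  ref <- Biostrings::readDNAStringSet(cli_req(opt, "fasta"))
  names(ref) <- sub("\\s.*", "", names(ref))
  gm <- read_gene_models(cli_req(opt, "gtf"))
  ann <- annotate_sites(cand, gm, ref,
                        snps = if (!is.null(opt$snps)) read_vcf_lite(opt$snps),
                        known = if (!is.null(opt$known)) read_known_sites(opt$known),
                        pseudogenes = if (!is.null(opt$pseudogenes)) read_bed(opt$pseudogenes),
                        repeats = if (!is.null(opt$repeats)) read_bed(opt$repeats))
  fl <- apply_filters(ann)
  out <- cli_req(opt, "out")
  write_tsv(fl$retained, paste0(out, "_retained.tsv"))
  write_tsv(as.data.frame(fl$ledger), paste0(out, "_ledger.tsv"))
  0L
}

cli_editome <- function(opt) {
  sm <- read_site_matrix(cli_req(opt, "matrix"))
  groups <- cli_groups(cli_req(opt, "groups"))
  eds <- build_group_editome(sm, groups)
  out <- cli_req(opt, "out")
  for (g in names(eds))
    write_tsv(eds[[g]]$sites, sprintf("%s_editome_%s.tsv", out, g))
  dedit <- differential_editing(sm, groups,
                                case = opt$case %||% "case",
                                control = opt$control %||% "control")
  write_tsv(dedit, paste0(out, "_dedit.tsv"))
  0L
}

cli_integrate <- function(opt) {
  counts <- as.matrix(utils::read.table(cli_req(opt, "counts"), sep = "\t",
                                        header = TRUE, row.names = 1,
                                        check.names = FALSE))
  groups <- cli_groups(cli_req(opt, "groups"))
  norm <- normalize_counts(counts)
  de <- diff_expression(norm, groups, case = opt$case %||% "case",
                        control = opt$control %||% "control")
  write_tsv(de, cli_req(opt, "out"))
  0L
}

cli_enrich <- function(opt) {
  sets <- read_gmt(cli_req(opt, "gmt"))
  query <- readLines(cli_req(opt, "query"))
  background <- readLines(cli_req(opt, "background"))
  write_tsv(enrich(query, background, sets), cli_req(opt, "out"))
  0L
}

cli_validate <- function(opt) {
  cdna <- read_pileup(cli_req(opt, "cdna"))
  gdna <- read_pileup(cli_req(opt, "gdna"))
  calls <- call_validated_sites(cdna, gdna)
  out <- cli_req(opt, "out")
  write_tsv(calls, paste0(out, "_calls.tsv"))
  if (!is.null(opt$groups)) {
    groups <- cli_groups(opt$groups)
    write_tsv(compare_validation_groups(calls, groups,
                                        case = opt$case %||% "case",
                                        control = opt$control %||% "control"),
              paste0(out, "_group_comparison.tsv"))
  }
  0L
}
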