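# End-to-end orchestration: synthesis -> quantitation -> contrasts ->
# S/N + FDR -> COG tabulation -> motif scan -> fermentation metrics, with a
# JSON config, per-stage logging, and a checksummed run manifest.

#' Default pipeline configuration
#'
#' Defaults mirror the study design: four substrate conditions with the
#' cellobiose analog as reference, two biological replicates, Znet threshold
#' 1.65 (secondary 1.96), S/N cutoff 2.8, 100 Monte-Carlo replicates.
#'
#' @param outdir Run directory for outputs.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A config list (class `pipeline_config`).
#' @export
default_pipeline_config <- function(outdir = "znet_run", seed = 1L) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    conditions = c("cellobiose", "xylose", "alpha_cellulose", "xylan"),
    reference = "cellobiose",
    replicates = c("A", "B"),
    n_genes = 200L,
    frac_de = 0.1,
    effect_magnitude = 2,
    noise_sd = 0.25,
    protein_detect_frac = 0.6,
    simulate_reads = TRUE,
    read_length = 100L,
    mean_depth = 30,
    gene_length_range = c(300L, 900L),
    min_counts = 2L,
    min_peptides = 2L,
    peptide_log_e_max = -1.5,
    znet_threshold = 1.65,
    secondary_threshold = 1.96,
    snr_cutoff = 2.8,
    mc_replicates = 100L,
    merge_rule = "mean",
    scale_mode = "multiply",
    exclude_classes = "S",
    exclude_hypotheticals = TRUE,
    consensus = "TGWAANCGNTNWCA",
    n_planted_motifs = 5L,
    max_mismatches = 0L,
    upstream_window = 200L,
    fermentation = list(
      stoichiometry = c(ethanol = 2, CO2 = 2),
      mu = 0.15,
      timepoints = seq(0, 48, by = 2),
      substrate_mM = 10,
      substrate_carbons = 6
    )
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unspecified fields fall back to [default_pipeline_config()] values. A seed
#' is mandatory whenever any stochastic stage is enabled.
#'
#' @param path JSON file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(user$seed)) stop("pipeline config must set a seed")
  cfg <- default_pipeline_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$fermentation$stoichiometry <- unlist(cfg$fermentation$stoichiometry)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(log, stage, t0, ...) {
  msg <- paste0(...)
  message(sprintf("[%s] %s (%.2fs)", stage, msg,
                  as.numeric(Sys.time()) - t0))
  c(log, stats::setNames(list(msg), stage))
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order against a synthetic experiment,
#' writes every output as text under `config$outdir`, and returns (and
#' writes) a manifest listing each output with its MD5 checksum, the seed,
#' and the package version. Rerunning with an identical config and seed
#' reproduces identical checksums.
#'
#' @param config A `pipeline_config` list or path to a JSON config.
#' @return The manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  log <- list()
  outfile <- function(name) file.path(cfg$outdir, name)

  design <- experiment_design(cfg$conditions, reference = cfg$reference,
                              replicates = cfg$replicates)

  # --- synthesis ---------------------------------------------------------
  gen <- generate_annotated_genome(
    n_genes = cfg$n_genes, gene_length_range = cfg$gene_length_range,
    motif_plan = list(consensus = cfg$consensus,
                      n_planted = cfg$n_planted_motifs),
    seed = cfg$seed
  )
  Biostrings::writeXStringSet(gen$genome, outfile("genome.fa"))
  write_annotations(gen$annotations, outfile("annotations.tsv"))
  write_annotations(gen$annotations, outfile("annotations.gff3"), "gff3")
  omics <- simulate_omics(
    design, n_genes = nrow(gen$annotations), frac_de = cfg$frac_de,
    effect_magnitude = cfg$effect_magnitude, noise_sd = cfg$noise_sd,
    protein_detect_frac = cfg$protein_detect_frac, seed = cfg$seed + 1L
  )
  # align truth loci with genome loci (both are g%04d over n_genes)
  utils::write.table(omics$truth, outfile("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log <- stage_log(log, "synth", t0, "generated ", cfg$n_genes,
                   " genes, planted ", gen$motif_plan$n_planted, " motifs")

  # --- quantitation ------------------------------------------------------
  if (isTRUE(cfg$simulate_reads)) {
    seqs <- gene_sequences(gen$genome, gen$annotations)
    cols <- sample_columns(design)
    counts <- matrix(0L, length(seqs), length(cols),
                     dimnames = list(names(seqs), cols))
    rel <- 2^(omics$rna - mean(omics$rna))
    for (j in seq_along(cols)) {
      lam <- cfg$mean_depth * rel[, cols[j]] / mean(rel[, cols[j]])
      reads <- simulate_reads(gen$genome, gen$annotations,
                              stats::setNames(lam, rownames(omics$rna)),
                              read_length = cfg$read_length,
                              seed = cfg$seed + 10L + j)
      counts[, j] <- as.integer(count_exact_readmers(reads, seqs))
    }
    rna <- build_rna_matrix(counts, design, min_counts = cfg$min_counts)
    utils::write.table(
      data.frame(locus_id = rownames(counts), counts, check.names = FALSE),
      outfile("alignment_counts.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    log <- stage_log(log, "count", t0, sum(counts), " exact alignments; ",
                     nrow(attr(rna, "filter_log")), " cells filtered")
  } else {
    rna <- omics$rna
    log <- stage_log(log, "count", t0, "read simulation disabled; ",
                     "using simulated log2 matrix directly")
  }
  write_expression_table(rna, outfile("rna_expression.tsv"))
  utils::write.table(omics$evidence, outfile("peptide_evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  protein <- build_protein_matrix(omics$evidence, design,
                                  min_peptides = cfg$min_peptides,
                                  peptide_log_e_max = cfg$peptide_log_e_max)
  write_expression_table(protein, outfile("protein_expression.tsv"))
  log <- stage_log(log, "quantify", t0, nrow(protein), " proteins retained (",
                   nrow(attr(protein, "filter_log")), " filter events)")

  # --- contrasts + S/N + FDR --------------------------------------------
  results <- list(rna = list(), protein = list())
  fdr_tables <- list()
  for (cond in design$contrasts$condition) {
    r <- run_contrast(rna, design, cond, threshold = cfg$znet_threshold,
                      merge_rule = cfg$merge_rule)
    aug <- add_snr_fdr(r, cutoffs = c(1, 2, cfg$snr_cutoff),
                       mc_replicates = cfg$mc_replicates,
                       seed = cfg$seed + 100L + match(cond, cfg$conditions),
                       scale_mode = cfg$scale_mode)
    results$rna[[cond]] <- aug$result
    ft <- aug$fdr_table
    ft$contrast <- r$contrast[1]
    fdr_tables[[cond]] <- ft
    if (nrow(protein) >= 3L) {
      results$protein[[cond]] <-
        run_contrast(protein, design, cond, threshold = cfg$znet_threshold)
    }
  }
  rna_res <- do.call(rbind, results$rna)
  prot_res <- if (length(results$protein)) do.call(rbind, results$protein) else NULL
  all_res <- rbind(rna_res,
                   if (!is.null(prot_res)) {
                     prot_res$snr <- NA_real_; prot_res$fdr <- NA_real_
                     prot_res
                   })
  write_contrast_table(all_res, outfile("contrasts.tsv"))
  utils::write.table(do.call(rbind, fdr_tables), outfile("fdr_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- stage_log(log, "contrast", t0, nrow(all_res), " contrast rows (",
                   sum(all_res$regulation != "ns"), " regulated at |Znet| >= ",
                   cfg$znet_threshold, ")")

  # --- COG tabulation ----------------------------------------------------
  tab_in <- list(rna = rna_res)
  if (!is.null(prot_res)) tab_in$protein <- prot_res
  cog_tab <- classify_and_tabulate(
    tab_in, gen$annotations, threshold = cfg$znet_threshold,
    exclude_classes = cfg$exclude_classes,
    exclude_hypotheticals = cfg$exclude_hypotheticals)
  write_cog_table(cog_tab, outfile("cog_table.tsv"))
  log <- stage_log(log, "tabulate", t0, nrow(cog_tab$counts),
                   " COG class/condition/omic rows")

  # --- motif scan --------------------------------------------------------
  hits <- scan_consensus(gen$genome, cfg$consensus,
                         max_mismatches = cfg$max_mismatches)
  hits <- associate_hits(hits, gen$annotations,
                         upstream_window = cfg$upstream_window)
  write_motif_hits(hits, outfile("motif_hits.tsv"),
                   bed_path = outfile("motif_hits.bed"))
  log <- stage_log(log, "scan", t0, nrow(hits), " consensus hits (",
                   gen$motif_plan$n_planted, " planted)")

  # --- fermentation ------------------------------------------------------
  fs <- cfg$fermentation
  series <- simulate_fermentation(fs$stoichiometry, mu = fs$mu,
                                  timepoints = fs$timepoints,
                                  substrate_mM = fs$substrate_mM,
                                  substrate_carbons = fs$substrate_carbons,
                                  seed = cfg$seed + 200L)
  utils::write.csv(series, outfile("fermentation.csv"), row.names = FALSE)
  bal <- fermentation_balance(series,
                              window = c(0, min(10, max(fs$timepoints))))
  log <- stage_log(log, "ferment", t0, sprintf(
    "doubling %.3g h, C recovery %.3g, O:R %.3g",
    bal$doubling_time, bal$carbon_recovery, bal$or_ratio))

  # --- manifest ----------------------------------------------------------
  cfg_plain <- unclass(cfg)
  # named vectors must serialize as JSON objects, not bare arrays
  cfg_plain$fermentation$stoichiometry <-
    as.list(cfg_plain$fermentation$stoichiometry)
  jsonlite::write_json(cfg_plain, outfile("config_effective.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(setdiff(list.files(cfg$outdir), "manifest.json"))
  manifest <- list(
    package = "znetdiff",
    version = as.character(utils::packageVersion("znetdiff")),
    seed = cfg$seed,
    stages = log,
    fermentation_metrics = bal[c("doubling_time", "carbon_recovery", "or_ratio")],
    outputs = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(cfg$outdir, f))))
  )
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
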