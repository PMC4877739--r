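# Seeded generators that emulate the study design end-to-end: an annotated
# single-contig genome with optionally planted consensus motifs, exact-substring
# 100-mer read sets, a dual-omic expression experiment (2 replicates x 4
# substrate conditions) with recorded ground truth, and a stoichiometrically
# closed fermentation time series.

#' Generate an annotated synthetic genome
#'
#' Lays out `n_genes` non-overlapping genes with random strands on a single
#' contig, separated by random intergenic spacers, and (optionally) plants
#' exact realizations of a degenerate IUPAC consensus into intergenic
#' sequence, recording their positions and strands.
#'
#' @param n_genes Number of genes (>= 1).
#' @param gene_length_range Two-element bp interval for gene lengths.
#' @param intergenic_length_range Two-element bp interval for spacer lengths.
#' @param cog_alphabet Letters COG classes are drawn from (uniform).
#' @param motif_plan Optional `list(consensus = <IUPAC string>, n_planted = k)`.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return `list(genome = DNAStringSet, annotations = gene_annotation,
#'   motif_plan = list(consensus, n_planted, planted_positions))`.
#' @export
generate_annotated_genome <- function(n_genes,
                                      gene_length_range = c(300L, 900L),
                                      intergenic_length_range = c(150L, 400L),
                                      cog_alphabet = strsplit("CEFGHIJKLMNOPQRSTUV", "")[[1]],
                                      motif_plan = NULL,
                                      seed = 1L) {
  stopifnot(n_genes >= 1, all(gene_length_range > 0),
            all(intergenic_length_range > 0))
  set.seed(seed)
  glen <- sample(gene_length_range[1]:gene_length_range[2], n_genes, replace = TRUE)
  ilen <- sample(intergenic_length_range[1]:intergenic_length_range[2],
                 n_genes + 1L, replace = TRUE)
  starts <- integer(n_genes)
  pos <- 1L
  for (i in seq_len(n_genes)) {
    pos <- pos + ilen[i]
    starts[i] <- pos
    pos <- pos + glen[i]
  }
  total <- pos + ilen[n_genes + 1L] - 1L
  seq_chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)

  plan <- list(consensus = NULL, n_planted = 0L,
               planted_positions = data.frame(contig_id = character(),
                                              position = integer(),
                                              strand = character(),
                                              stringsAsFactors = FALSE))
  if (!is.null(motif_plan) && motif_plan$n_planted > 0L) {
    cons <- toupper(motif_plan$consensus)
    check_iupac(cons)
    L <- nchar(cons)
    # candidate intergenic windows, kept off gene bodies and off each other
    inter_start <- c(1L, starts + glen)
    inter_end <- c(starts - 1L, total)
    slots <- list()
    for (j in seq_along(inter_start)) {
      lo <- inter_start[j]; hi <- inter_end[j] - L + 1L
      if (hi >= lo) slots[[length(slots) + 1L]] <- seq.int(lo, hi)
    }
    k <- motif_plan$n_planted
    chosen <- integer(0)
    cand <- sample(unlist(slots))
    for (p in cand) {
      if (length(chosen) == k) break
      if (!any(abs(chosen - p) < L)) chosen <- c(chosen, p)
    }
    if (length(chosen) < k) {
      stop("cannot fit ", k, " non-overlapping motif sites of length ", L,
           " into intergenic sequence; enlarge the genome")
    }
    chosen <- sort(chosen)
    strands <- sample(c("+", "-"), k, replace = TRUE)
    for (j in seq_len(k)) {
      site <- realize_consensus(cons)
      if (strands[j] == "-") site <- revcomp_string(site)
      seq_chars[chosen[j]:(chosen[j] + L - 1L)] <- strsplit(site, "")[[1]]
    }
    plan <- list(consensus = cons, n_planted = k,
                 planted_positions = data.frame(contig_id = "contig_1",
                                                position = chosen,
                                                strand = strands,
                                                stringsAsFactors = FALSE))
  }

  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "contig_1"
  ann <- gene_annotation(
    locus_id = sprintf("g%04d", seq_len(n_genes)),
    contig_id = "contig_1",
    start = starts, end = starts + glen - 1L,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    description = paste("synthetic gene", seq_len(n_genes)),
    cog_class = sample(cog_alphabet, n_genes, replace = TRUE)
  )
  list(genome = genome, annotations = ann, motif_plan = plan)
}

# draw one concrete sequence matching a degenerate consensus
realize_consensus <- function(consensus) {
  letters <- strsplit(consensus, "")[[1]]
  paste(vapply(letters, function(x) sample(IUPAC_SETS[[x]], 1L), ""),
        collapse = "")
}

revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract gene sequences in gene-strand orientation
#'
#' @param genome Named `DNAStringSet`.
#' @param annotations A `gene_annotation` data.frame.
#' @return Named character vector of gene sequences (reverse-complemented for
#'   minus-strand genes).
#' @export
gene_sequences <- function(genome, annotations) {
  out <- character(nrow(annotations))
  gchar <- as.character(genome)
  for (i in seq_len(nrow(annotations))) {
    s <- substr(gchar[[annotations$contig_id[i]]],
                annotations$start[i], annotations$end[i])
    if (annotations$strand[i] == "-") s <- revcomp_string(s)
    out[i] <- s
  }
  names(out) <- annotations$locus_id
  out
}

#' Simulate exact-substring reads from genes
#'
#' Per-gene read counts are Poisson with the given means; read start
#' positions are uniform within the gene, so every read is an exact substring
#' of its source gene in gene-strand orientation (no sequencing errors, by
#' design: the downstream counter is an exact matcher).
#'
#' @param genome Named `DNAStringSet`.
#' @param annotations A `gene_annotation` data.frame.
#' @param abundances Named numeric vector of expected read counts per locus.
#' @param read_length Read length in bp (default 100).
#' @param seed Integer seed.
#' @return Named character vector of reads (`<locus>_r<i>`).
#' @export
simulate_reads <- function(genome, annotations, abundances,
                           read_length = 100L, seed = 1L) {
  set.seed(seed)
  seqs <- gene_sequences(genome, annotations)
  miss <- setdiff(names(abundances), names(seqs))
  if (length(miss)) stop("abundance for unknown locus: ", paste(miss, collapse = ", "))
  reads <- character(0)
  for (g in names(abundances)) {
    lam <- abundances[[g]]
    if (lam <= 0) next
    glen <- nchar(seqs[[g]])
    if (glen < read_length) {
      stop("gene ", g, " (", glen, " bp) is shorter than the read length ",
           read_length)
    }
    n <- stats::rpois(1L, lam)
    if (n == 0L) next
    starts <- sample.int(glen - read_length + 1L, n, replace = TRUE)
    r <- substring(seqs[[g]], starts, starts + read_length - 1L)
    names(r) <- sprintf("%s_r%d", g, seq_len(n))
    reads <- c(reads, r)
  }
  reads
}

#' Simulate a dual-omic expression experiment with ground truth
#'
#' Gene `g` in condition `c`, replicate `r` receives the log2 value
#' `baseline_g + effect_{g,c} + Normal(0, noise_sd)`. A gene is differential
#' in a non-reference condition with probability `frac_de`, with effect
#' `+/- effect_magnitude` (random sign). A `protein_detect_frac` subset of
#' genes additionally yields peptide evidence whose per-channel summed
#' reporter intensities carry the same log2 signal plus an independent
#' gene-level protein offset (`protein_offset_sd`) and channel noise; the
#' offset tunes the expected between-omic correlation.
#'
#' @param design An `experiment_design` (>= 1 non-reference condition).
#' @param n_genes Number of genes.
#' @param frac_de Fraction of truly differential genes per contrast.
#' @param effect_magnitude Absolute log2 effect size for differential genes.
#' @param noise_sd Intra-replicate log2 noise SD (> 0).
#' @param protein_detect_frac Fraction of genes with peptide evidence.
#' @param peptides_per_protein Two-element integer range of peptides per protein.
#' @param baseline_mean,baseline_sd Log2 baseline distribution (Normal).
#' @param protein_offset_sd SD of the gene-level protein-vs-RNA offset
#'   (log2 units); larger values lower the RNA-protein correlation.
#' @param protein_noise_sd Channel-level protein log2 noise SD.
#' @param seed Integer seed.
#' @return `list(rna = expression_matrix, evidence = peptide evidence
#'   data.frame, truth = SyntheticTruth data.frame, protein_log2 = matrix)`.
#' @export
simulate_omics <- function(design, n_genes, frac_de = 0.1,
                           effect_magnitude = 2, noise_sd = 0.25,
                           protein_detect_frac = 0.6,
                           peptides_per_protein = c(2L, 6L),
                           baseline_mean = 10, baseline_sd = 2,
                           protein_offset_sd = 2.7,
                           protein_noise_sd = 0.35,
                           seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            frac_de >= 0, frac_de <= 1, noise_sd > 0)
  if (nrow(design$contrasts) < 1L) stop("design has no non-reference condition")
  set.seed(seed)
  loci <- sprintf("g%04d", seq_len(n_genes))
  non_ref <- design$contrasts$condition
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)

  # planted truth, per non-reference condition
  effect <- matrix(0, n_genes, length(non_ref),
                   dimnames = list(loci, non_ref))
  for (cond in non_ref) {
    de <- stats::runif(n_genes) < frac_de
    effect[de, cond] <- effect_magnitude * sample(c(-1, 1), sum(de), replace = TRUE)
  }
  truth <- do.call(rbind, lapply(non_ref, function(cond) {
    data.frame(locus_id = loci, condition = cond,
               is_differential = effect[, cond] != 0,
               effect = effect[, cond], baseline = baseline,
               noise_sd = noise_sd, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  cols <- sample_columns(design)
  signal <- matrix(baseline, n_genes, length(cols),
                   dimnames = list(loci, cols))
  for (cond in non_ref) {
    cc <- grep(paste0("^", cond, "\\."), cols)
    signal[, cc] <- signal[, cc] + effect[, cond]
  }
  rna_vals <- signal + stats::rnorm(length(signal), 0, noise_sd)
  rna <- expression_matrix(rna_vals, design, "rna")

  # protein: single replicate set (4-plex channels, one per condition)
  detected <- sort(sample.int(n_genes, round(protein_detect_frac * n_genes)))
  prot_cols <- design$conditions
  prot_signal <- matrix(baseline, n_genes, length(prot_cols),
                        dimnames = list(loci, prot_cols))
  for (cond in non_ref) prot_signal[, cond] <- prot_signal[, cond] + effect[, cond]
  prot_offset <- stats::rnorm(n_genes, 0, protein_offset_sd)
  prot_log2 <- prot_signal + prot_offset +
    stats::rnorm(length(prot_signal), 0, protein_noise_sd)
  prot_log2 <- prot_log2[detected, , drop = FALSE]

  evidence <- vector("list", length(detected))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (j in seq_along(detected)) {
    g <- loci[detected[j]]
    npep <- sample(peptides_per_protein[1]:peptides_per_protein[2], 1L)
    w <- stats::runif(npep, 0.2, 1); w <- w / sum(w)
    totals <- 2^prot_log2[j, ]
    pep <- vapply(seq_len(npep), function(i)
      paste(sample(aa, sample(8:20, 1L), replace = TRUE), collapse = ""), "")
    ev <- data.frame(protein_id = g, peptide = pep,
                     log_e = stats::runif(npep, -8, -2),
                     stringsAsFactors = FALSE)
    for (cond in prot_cols) ev[[paste0("intensity.", cond)]] <- w * totals[[cond]]
    evidence[[j]] <- ev
  }
  evidence <- if (length(evidence)) do.call(rbind, evidence) else NULL

  list(rna = rna, evidence = evidence, truth = truth, protein_log2 = prot_log2)
}

#' Simulate a stoichiometrically closed fermentation time series
#'
#' Biomass grows exponentially at rate `mu` until the substrate is exhausted,
#' then plateaus; substrate consumption is proportional to biomass formed and
#' each product is formed per the molar yields, so the series satisfies the
#' input stoichiometry exactly before any added noise.
#'
#' @param stoichiometry Named numeric vector: mol product per mol substrate
#'   (names must appear in the redox table used downstream).
#' @param mu Specific growth rate per hour (> 0).
#' @param timepoints Hours (non-negative, strictly increasing).
#' @param substrate_mM Initial substrate concentration.
#' @param substrate_carbons Carbon atoms per substrate molecule.
#' @param od0 Initial OD600.
#' @param od_per_mM OD yield per mM substrate consumed.
#' @param noise_sd Relative (multiplicative, log-normal) measurement noise; 0
#'   for a noiseless series.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A data.frame (`time`, `od`, `substrate`, one column per product)
#'   with attributes `substrate_carbons` and `stoichiometry`, class
#'   `fermentation_series`.
#' @export
simulate_fermentation <- function(stoichiometry, mu, timepoints,
                                  substrate_mM = 10, substrate_carbons = 6,
                                  od0 = 0.05, od_per_mM = 0.06,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(mu > 0, all(stoichiometry >= 0), substrate_mM > 0)
  if (any(timepoints < 0)) stop("negative timepoint in fermentation series")
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  x <- od0 * exp(mu * timepoints)
  consumed <- pmin((x - od0) / od_per_mM, substrate_mM)
  od <- od0 + consumed * od_per_mM  # plateaus exactly when substrate runs out
  df <- data.frame(time = timepoints, od = od,
                   substrate = substrate_mM - consumed)
  for (p in names(stoichiometry)) df[[p]] <- stoichiometry[[p]] * consumed
  if (noise_sd > 0) {
    set.seed(seed)
    for (cc in setdiff(names(df), "time")) {
      df[[cc]] <- df[[cc]] * exp(stats::rnorm(nrow(df), 0, noise_sd))
    }
  }
  structure(df, substrate_carbons = substrate_carbons,
            stoichiometry = stoichiometry,
            class = c("fermentation_series", "data.frame"))
}
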