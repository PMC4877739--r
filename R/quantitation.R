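# Quantitation: exact read-length alignment counting against gene sequences,
# the log2-sum expression definitions with their evidence filters, and the
# validation regression.

#' Count exact read-length alignments per gene
#'
#' Emulates an exact k-mer alignment engine: a read counts toward a gene when
#' it occurs verbatim in the gene sequence (gene-strand orientation). With
#' `both_strands`, a read whose reverse complement occurs also counts. In the
#' default `"reads"` mode a read increments every matching gene once,
#' regardless of how many positions it matches within the gene; `"occurrences"`
#' counts every matching position.
#'
#' @param reads Character vector (or `DNAStringSet`) of same-length reads.
#' @param gene_seqs Named character vector of uppercase gene sequences.
#' @param both_strands Also match reverse-complemented reads (default FALSE:
#'   reads are simulated in gene-strand orientation).
#' @param mode `"reads"` (per-read per-gene 0/1) or `"occurrences"`.
#' @return Named integer vector of counts per gene, with attribute
#'   `n_skipped` (reads dropped for non-ACGT characters, warned about).
#' @export
count_exact_readmers <- function(reads, gene_seqs, both_strands = FALSE,
                                 mode = c("reads", "occurrences")) {
  mode <- match.arg(mode)
  if (!is.character(reads)) reads <- as.character(reads)
  counts <- stats::setNames(integer(length(gene_seqs)), names(gene_seqs))
  if (!length(reads)) return(structure(counts, n_skipped = 0L))
  lens <- nchar(reads)
  if (length(unique(lens)) != 1L) {
    stop("mixed read lengths: ", paste(sort(unique(lens)), collapse = ", "))
  }
  L <- lens[1]
  clean <- !grepl("[^ACGT]", reads)
  n_skipped <- sum(!clean)
  if (n_skipped) {
    warning(n_skipped, " read(s) with non-ACGT characters skipped")
    reads <- reads[clean]
  }
  mult <- table(reads)
  ur <- names(mult)
  mult <- as.integer(mult)
  for (g in names(gene_seqs)) {
    seqs <- gene_seqs[[g]]
    if (both_strands) seqs <- c(seqs, revcomp_string(seqs))
    kmers <- unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < L) character(0) else substring(s, 1:(n - L + 1L), L:n)
    }), use.names = FALSE)
    if (mode == "reads") {
      counts[[g]] <- sum(mult[ur %in% kmers])
    } else {
      occ <- tabulate(match(kmers, ur), nbins = length(ur))
      counts[[g]] <- sum(occ * mult)
    }
  }
  structure(counts, n_skipped = n_skipped)
}

#' Assemble alignment counts across samples
#'
#' @param read_sets Named list of read vectors, one per design sample column.
#' @param gene_seqs Named character vector of gene sequences.
#' @param ... Passed to [count_exact_readmers()].
#' @return Integer matrix, loci x samples.
#' @export
alignment_count_matrix <- function(read_sets, gene_seqs, ...) {
  m <- vapply(read_sets, function(r)
    as.integer(count_exact_readmers(r, gene_seqs, ...)),
    integer(length(gene_seqs)))
  rownames(m) <- names(gene_seqs)
  m
}

#' Build the RNA log2 expression matrix from alignment counts
#'
#' The expression value is `log2(alignment count)` per gene per sample; cells
#' with fewer than `min_counts` alignments (default 2, the evidence floor for
#' RNA-seq) become missing and are recorded in the filter log. log2 of zero
#' never arises: filtered cells are `NA`, not 0.
#'
#' @param counts Integer matrix, loci x design sample columns.
#' @param design An `experiment_design`.
#' @param min_counts Minimum alignment count per cell (default 2).
#' @return An `expression_matrix` (omic `"rna"`).
#' @export
build_rna_matrix <- function(counts, design, min_counts = 2L) {
  need <- sample_columns(design)
  miss <- setdiff(need, colnames(counts))
  if (length(miss)) stop("count matrix missing sample(s): ",
                         paste(miss, collapse = ", "))
  counts <- counts[, need, drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("alignment counts must be non-negative integers")
  }
  low <- counts < min_counts
  vals <- log2(ifelse(low, NA, counts))
  log <- if (any(low)) {
    idx <- which(low, arr.ind = TRUE)
    data.frame(locus_id = rownames(counts)[idx[, 1]],
               column = colnames(counts)[idx[, 2]],
               filter = "min_counts", stringsAsFactors = FALSE)
  } else empty_filter_log()
  expression_matrix(vals, design, "rna", filter_log = log)
}

#' Build the protein log2 expression matrix from peptide evidence
#'
#' Proteins are retained when they carry at least `min_peptides` peptides with
#' `log_e` strictly below `peptide_log_e_max` each, and a protein-level
#' expectation — taken as the sum of qualifying peptides' `log_e` — strictly
#' below `protein_log_e_max`. The expression value per reporter channel is
#' the log2 of the sum of qualifying peptides' intensities in that channel.
#' Excluded proteins and zero-intensity channels are logged.
#'
#' @param evidence Peptide evidence data.frame (see [read_peptide_evidence()]).
#' @param design An `experiment_design`; channels map onto its conditions and
#'   the matrix is labeled with the design's first replicate.
#' @param min_peptides Minimum qualifying peptides per protein (default 2).
#' @param peptide_log_e_max Peptide log(e) must be `<` this (default -1.5).
#' @param protein_log_e_max Protein log(e) must be `<` this (default -10).
#' @return An `expression_matrix` (omic `"protein"`).
#' @export
build_protein_matrix <- function(evidence, design, min_peptides = 2L,
                                 peptide_log_e_max = -1.5,
                                 protein_log_e_max = -10) {
  chan_cols <- paste0("intensity.", design$conditions)
  miss <- setdiff(chan_cols, names(evidence))
  if (length(miss)) stop("peptide evidence channel(s) unmapped to design: ",
                         paste(miss, collapse = ", "))
  out_cols <- paste(design$conditions, design$replicates[1], sep = ".")
  qual <- evidence$log_e < peptide_log_e_max  # strict, as printed
  prots <- unique(evidence$protein_id)
  log <- list()
  rows <- list()
  for (p in prots) {
    sel <- evidence$protein_id == p & qual
    nq <- sum(sel)
    if (nq < min_peptides) {
      log[[length(log) + 1L]] <- data.frame(
        locus_id = p, column = "*", filter = "min_peptides",
        stringsAsFactors = FALSE)
      next
    }
    if (sum(evidence$log_e[sel]) >= protein_log_e_max) {
      log[[length(log) + 1L]] <- data.frame(
        locus_id = p, column = "*", filter = "protein_log_e",
        stringsAsFactors = FALSE)
      next
    }
    sums <- colSums(evidence[sel, chan_cols, drop = FALSE])
    vals <- ifelse(sums > 0, log2(sums), NA_real_)
    if (any(sums <= 0)) {
      log[[length(log) + 1L]] <- data.frame(
        locus_id = p, column = out_cols[sums <= 0], filter = "zero_intensity",
        stringsAsFactors = FALSE)
    }
    rows[[p]] <- vals
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(out_cols),
           dimnames = list(character(), out_cols))
  colnames(m) <- out_cols
  filter_log <- if (length(log)) do.call(rbind, log) else empty_filter_log()
  expression_matrix(m, design, "protein", filter_log = filter_log)
}

#' Coefficient of determination of an ordinary least-squares fit
#'
#' Pairs with a missing value on either side are dropped; at least 3 complete
#' pairs and nonzero variance in `x` are required. Used for the replicate
#' vs replicate and RNA vs protein validation regressions.
#'
#' @param x,y Paired numeric vectors (log2 expression values).
#' @return R-squared of the least-squares fit of `y` on `x`.
#' @export
correlation_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs, have ", sum(ok))
  if (stats::var(x[ok]) == 0) stop("zero variance in x")
  fit <- stats::lm(y[ok] ~ x[ok])
  sst <- sum((y[ok] - mean(y[ok]))^2)
  if (sst == 0) return(1)  # y constant and x varies: degenerate perfect fit
  1 - sum(stats::residuals(fit)^2) / sst
}
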