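# Shared fixtures, built in code at test time.

two_cond_design <- function() {
  experiment_design(c("cellobiose", "xylose"), reference = "cellobiose")
}

four_cond_design <- function() {
  experiment_design(c("cellobiose", "xylose", "alpha_cellulose", "xylan"),
                    reference = "cellobiose")
}

# tiny expression matrix with hand-set values for one gene
toy_expr <- function(values = c(6, 6.2, 4, 4.1), extra_genes = 10, seed = 1) {
  design <- two_cond_design()
  set.seed(seed)
  n <- extra_genes + 1
  m <- matrix(rnorm(n * 4, 5, 1), n, 4,
              dimnames = list(sprintf("g%02d", seq_len(n)),
                              sample_columns(design)))
  # columns are cellobiose.A, cellobiose.B, xylose.A, xylose.B
  m["g01", c("xylose.A", "xylose.B", "cellobiose.A", "cellobiose.B")] <- values
  list(expr = expression_matrix(m, design, "rna"), design = design)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force IUPAC window-scan oracle, independent of scan_consensus
oracle_scan <- function(seq_char, consensus, max_mm, both = TRUE) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  s <- strsplit(seq_char, "")[[1]]
  pats <- list(`+` = strsplit(consensus, "")[[1]])
  if (both) pats$`-` <- rev(comp[pats$`+`])
  out <- list()
  L <- length(pats$`+`)
  for (strand in names(pats)) {
    p <- pats[[strand]]
    for (i in seq_len(length(s) - L + 1)) {
      mm <- sum(!mapply(function(b, set) b %in% sets[[set]],
                        s[i:(i + L - 1)], p))
      if (mm <= max_mm) {
        out[[length(out) + 1]] <- data.frame(start = i, strand = strand,
                                             mismatches = mm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

# oracle counts: naive per-read substring search via grepl
oracle_counts <- function(reads, gene_seqs, both_strands = FALSE) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  counts <- setNames(integer(length(gene_seqs)), names(gene_seqs))
  for (r in reads) {
    hit <- vapply(gene_seqs, function(g) grepl(r, g, fixed = TRUE), TRUE)
    if (both_strands) {
      hit <- hit | vapply(gene_seqs, function(g) grepl(rc(r), g, fixed = TRUE),
                          TRUE)
    }
    counts <- counts + hit
  }
  counts
}
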