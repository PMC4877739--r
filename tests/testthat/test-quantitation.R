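test_that("exact read counting handles the basic strand and miss cases", {
  genes <- c(g1 = random_dna(300, seed = 1), g2 = random_dna(300))
  read <- substr(genes[["g1"]], 50, 149)
  expect_equal(as.integer(count_exact_readmers(read, genes)), c(1L, 0L),
               ignore_attr = TRUE)
  none <- strrep("A", 100)  # absent from both random genes
  expect_equal(sum(count_exact_readmers(none, genes)), 0L)

  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(substr(genes[["g2"]], 10, 109), "")[[1]]),
                     collapse = ""))
  expect_equal(as.integer(count_exact_readmers(rc, genes, both_strands = TRUE)),
               c(0L, 1L), ignore_attr = TRUE)
  expect_equal(sum(count_exact_readmers(rc, genes, both_strands = FALSE)), 0L)

  expect_error(count_exact_readmers(c(read, substr(read, 1, 50)), genes),
               "mixed read lengths")
  expect_warning(out <- count_exact_readmers(c(read, chartr("A", "N", read)),
                                             genes),
                 "non-ACGT")
  expect_equal(attr(out, "n_skipped"), 1L)
})

test_that("exact read counting equals the naive substring oracle", {
  set.seed(99)
  for (rep in 1:3) {
    gen <- generate_annotated_genome(n_genes = 10, seed = 100 + rep)
    seqs <- gene_sequences(gen$genome, gen$annotations)
    ab <- setNames(rpois(10, 40) + 1, names(seqs))
    reads <- simulate_reads(gen$genome, gen$annotations, ab,
                            seed = 200 + rep)
    for (both in c(FALSE, TRUE)) {
      mine <- count_exact_readmers(reads, seqs, both_strands = both)
      expect_equal(as.integer(mine),
                   as.integer(oracle_counts(reads, seqs, both_strands = both)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("occurrences mode counts every matching position", {
  g <- c(g1 = paste0(strrep("ACGT", 30), strrep("ACGT", 30)))
  read <- substr(g[["g1"]], 1, 100)
  # periodic sequence: the 100-mer occurs at many positions but the read mode
  # still counts it once
  expect_equal(as.integer(count_exact_readmers(read, g, mode = "reads")), 1L,
               ignore_attr = TRUE)
  occ <- as.integer(count_exact_readmers(read, g, mode = "occurrences"))
  expect_gt(occ, 1L)
})

test_that("RNA matrix applies the log2 and minimum-count filter", {
  design <- two_cond_design()
  counts <- matrix(c(4L, 16L, 1L, 3L,
                     1L, 2L, 2L, 2L,
                     0L, 5L, 8L, 2L), 3, 4, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"),
                                   sample_columns(design)))
  m <- build_rna_matrix(counts, design, min_counts = 2L)
  expect_equal(m["g1", "cellobiose.A"], 2)   # log2(4)
  expect_equal(m["g1", "cellobiose.B"], 4)   # log2(16)
  expect_true(is.na(m["g1", "xylose.A"]))    # count 1 < 2
  expect_true(is.na(m["g3", "cellobiose.A"]))
  log <- attr(m, "filter_log")
  expect_setequal(log$filter, "min_counts")
  expect_true(all(c("g1", "g2", "g3") %in% log$locus_id))
  # monotone: raising a count never lowers the value
  counts2 <- counts; counts2["g1", "cellobiose.A"] <- 8L
  m2 <- build_rna_matrix(counts2, design)
  expect_gt(m2["g1", "cellobiose.A"], m["g1", "cellobiose.A"])
})

test_that("protein matrix enforces the two-peptide log(e) filter", {
  design <- two_cond_design()
  ev <- data.frame(
    protein_id = c("p1", "p1", "p2", "p2", "p3"),
    peptide = c("AAK", "CCK", "DDK", "EEK", "FFK"),
    log_e = c(-6, -7, -3, -1.0, -12),
    intensity.cellobiose = c(10, 6, 5, 5, 9),
    intensity.xylose = c(2, 2, 4, 4, 9),
    stringsAsFactors = FALSE
  )
  m <- build_protein_matrix(ev, design)
  # p1: two qualifying peptides; channel sums 10+6=16 and 2+2=4
  expect_equal(unname(m["p1", ]), c(4, 2))  # log2(16), log2(4)
  # p2: one peptide fails log(e) < -1.5; p3: only one peptide
  expect_false("p2" %in% rownames(m))
  expect_false("p3" %in% rownames(m))
  log <- attr(m, "filter_log")
  expect_setequal(log$locus_id, c("p2", "p3"))
  expect_setequal(log$filter, "min_peptides")
  # boundary is strict: log_e exactly at the cutoff does not qualify
  ev$log_e[4] <- -1.5
  m2 <- build_protein_matrix(ev, design)
  expect_false("p2" %in% rownames(m2))
  # protein-level expectation (sum of qualifying log_e) must pass too
  ev2 <- data.frame(protein_id = "p4", peptide = c("GGK", "HHK"),
                    log_e = c(-2, -2), intensity.cellobiose = c(1, 1),
                    intensity.xylose = c(1, 1))
  m3 <- build_protein_matrix(ev2, design)
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "filter_log")$filter, "protein_log_e")
})

test_that("correlation_r2 matches the closed-form OLS computation", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  # closed form: R^2 = cov(x,y)^2 / (var(x) var(y))
  closed <- stats::cov(x, y)^2 / (stats::var(x) * stats::var(y))
  expect_equal(correlation_r2(x, y), closed, tolerance = 1e-12)
  expect_equal(correlation_r2(x, x), 1.0)
  expect_equal(correlation_r2(x, 2 * x + 1), 1.0)
  expect_error(correlation_r2(c(1, 2), c(1, 2)), "3 complete pairs")
  expect_error(correlation_r2(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  # missing-either pairs are dropped
  expect_equal(correlation_r2(c(x, NA), c(y, 5)), closed, tolerance = 1e-12)
})

test_that("between-omic correlation rises with shared signal and noise -> 0", {
  design <- two_cond_design()
  r2 <- sapply(c(4, 1, 1e-6), function(offset_sd) {
    sim <- simulate_omics(design, 600, frac_de = 0.2, seed = 11,
                          noise_sd = 0.02, protein_detect_frac = 1,
                          protein_offset_sd = offset_sd,
                          protein_noise_sd = max(offset_sd / 10, 1e-7))
    correlation_r2(sim$rna[, "cellobiose.A"],
                   sim$protein_log2[rownames(sim$rna), "cellobiose"])
  })
  expect_true(all(diff(r2) > 0))
  expect_gt(r2[3], 0.99)
})
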