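test_that("raw differences implement the four printed formulas", {
  # A_X=6, B_X=6.2, A_Y=4, B_Y=4.1 (X = xylose, Y = cellobiose reference)
  fix <- toy_expr(values = c(6, 6.2, 4, 4.1))
  raw <- raw_differences(fix$expr, fix$design, "xylose")
  g <- raw[raw$locus_id == "g01", ]
  expect_equal(g$z0_raw, 0.2)  # B_X - A_X
  expect_equal(g$z1_raw, 0.1)  # B_Y - A_Y
  expect_equal(g$z2_raw, 2.0)  # A_X - A_Y
  expect_equal(g$z3_raw, 2.1)  # B_X - B_Y

  # all four equal -> all-zero differences
  flat <- toy_expr(values = c(5, 5, 5, 5))
  raw0 <- raw_differences(flat$expr, flat$design, "xylose")
  expect_equal(unlist(raw0[raw0$locus_id == "g01", -1]), rep(0, 4),
               ignore_attr = TRUE)

  # sign convention: higher on the reference gives negative cross-state scores
  neg <- toy_expr(values = c(4, 4, 6, 6))
  rawn <- raw_differences(neg$expr, neg$design, "xylose")
  expect_equal(rawn[rawn$locus_id == "g01", "z2_raw"], -2)
  expect_equal(rawn[rawn$locus_id == "g01", "z3_raw"], -2)

  # genes with a missing value are dropped and logged
  fix2 <- toy_expr()
  m <- unclass(fix2$expr)
  m["g02", 1] <- NA
  expr2 <- expression_matrix(m, fix2$design, "rna")
  raw2 <- raw_differences(expr2, fix2$design, "xylose")
  expect_false("g02" %in% raw2$locus_id)
  expect_equal(attr(raw2, "dropped"), "g02")

  # single-replicate designs are directed to cross_state_only
  d1 <- experiment_design(c("cellobiose", "xylose"), replicates = "A")
  expect_error(raw_differences(fix$expr, d1, "xylose"), "cross_state_only")
})

test_that("population normalization uses the population-SD convention", {
  z <- normalize_population(c(1, 2, 3))
  expect_equal(z, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)

  set.seed(1)
  x <- rnorm(100)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(normalize_population(x), x, tolerance = 1e-9)  # idempotent
  y <- rnorm(50)
  expect_equal(order(normalize_population(y)), order(y))  # order-preserving
  expect_error(normalize_population(rep(2, 5)), "degenerate")
  expect_error(normalize_population(c(1, NA, 2)), "complete")
})

test_that("merge rule averages and renormalizes; ranks preserved when z2 == z3", {
  set.seed(7)
  z <- normalize_population(rnorm(50))
  znet <- merge_znet(z, z)
  expect_equal(order(znet), order(z))
  expect_equal(znet, z, tolerance = 1e-9)  # already normalized

  # 4-gene toy against the hand oracle
  z2 <- c(-1, 0, 0.5, 0.5)
  z3 <- c(-0.5, -0.5, 0, 1)
  avg <- (z2 + z3) / 2
  hand <- (avg - mean(avg)) / sqrt(mean((avg - mean(avg))^2))
  expect_equal(merge_znet(z2, z3), hand, tolerance = 1e-12)

  # custom merge rules plug in
  expect_equal(merge_znet(z2, z3, rule = function(a, b) pmax(a, b)),
               normalize_population(pmax(z2, z3)))
})

test_that("null Znet quantiles approximate the stated outer-population fractions", {
  set.seed(123)
  n <- 2e4
  z2 <- normalize_population(rnorm(n))
  z3 <- normalize_population(rnorm(n))
  znet <- merge_znet(z2, z3)
  expect_equal(mean(znet), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(znet^2)), 1, tolerance = 1e-9)
  expect_equal(mean(abs(znet) > 1.96), 0.05, tolerance = 0.2)
})

test_that("antisymmetry: swapping condition and reference negates Znet", {
  design <- two_cond_design()
  rev_design <- experiment_design(c("cellobiose", "xylose"),
                                  reference = "xylose")
  sim <- simulate_omics(design, 300, frac_de = 0.2, seed = 8,
                        protein_detect_frac = 0)
  fwd <- run_contrast(sim$rna, design, "xylose")
  bwd <- run_contrast(expression_matrix(unclass(sim$rna), rev_design, "rna"),
                      rev_design, "cellobiose")
  expect_equal(bwd$znet, -fwd$znet, tolerance = 1e-9)
})

test_that("population normalization removes global affine shifts", {
  design <- two_cond_design()
  sim <- simulate_omics(design, 300, frac_de = 0.2, seed = 9,
                        protein_detect_frac = 0)
  base <- run_contrast(sim$rna, design, "xylose")
  shifted <- unclass(sim$rna) + 3.7  # same constant added to every sample
  s <- run_contrast(expression_matrix(shifted, design, "rna"), design,
                    "xylose")
  expect_equal(s$znet, base$znet, tolerance = 1e-9)
  # a constant added to one sample shifts whole difference populations by a
  # constant, which the mean-0/SD-1 normalization removes again
  lop <- unclass(sim$rna); lop[, "xylose.A"] <- lop[, "xylose.A"] + 3.7
  l <- run_contrast(expression_matrix(lop, design, "rna"), design, "xylose")
  expect_equal(l$znet, base$znet, tolerance = 1e-9)
  # a gene-specific (non-affine) perturbation does change Znet
  bump <- unclass(sim$rna)
  bump[1, "xylose.A"] <- bump[1, "xylose.A"] + 3.7
  b <- run_contrast(expression_matrix(bump, design, "rna"), design, "xylose")
  expect_false(isTRUE(all.equal(b$znet, base$znet, tolerance = 1e-3)))
})

test_that("single-replicate cross-state mode normalizes X - Y", {
  design <- two_cond_design()
  set.seed(10)
  m <- matrix(rnorm(20, 8, 1), 5, 4,
              dimnames = list(paste0("g", 1:5), sample_columns(design)))
  expr <- expression_matrix(m, design, "rna")
  cs <- cross_state_only(expr, design, "xylose", replicate = "A")
  d <- m[, "xylose.A"] - m[, "cellobiose.A"]
  expect_equal(cs$znet, unname((d - mean(d)) / sqrt(mean((d - mean(d))^2))),
               tolerance = 1e-12)
  # one strongly shifted gene tops the ranking
  m2 <- m; m2["g3", "xylose.A"] <- m2["g3", "cellobiose.A"] + 10
  cs2 <- cross_state_only(expression_matrix(m2, design, "rna"), design,
                          "xylose")
  expect_equal(cs2$locus_id[which.max(cs2$znet)], "g3")
  # degenerate: all genes identical across states
  m3 <- m; m3[, "xylose.A"] <- m3[, "cellobiose.A"]
  expect_error(cross_state_only(expression_matrix(m3, design, "rna"),
                                design, "xylose"), "degenerate")
  expect_error(cross_state_only(expr, design, "xylose", replicate = "C"),
               "not in design")
})

test_that("COG tabulation counts directions and applies overlap exclusions", {
  starts <- seq(1, 501, 100)
  ann <- gene_annotation(paste0("g", 1:6), "c1",
                         start = starts, end = starts + 89,
                         strand = "+",
                         description = c(rep("kinase", 5), "hypothetical protein"),
                         cog_class = c("G", "G", "G", "S", "E", "E"))
  res <- function(znet) data.frame(
    locus_id = paste0("g", 1:6), condition = "xylose", znet = znet,
    stringsAsFactors = FALSE)
  # 3 genes class G with znet (+2.0, -1.7, +1.0) -> G: up=1, down=1
  rna <- res(c(2.0, -1.7, 1.0, 2.0, 1.65, 2.0))
  prot <- res(c(2.0, -1.0, 0.0, 1.9, 1.64, -2.0))
  tab <- classify_and_tabulate(list(rna = rna, protein = prot), ann)
  gx <- tab$counts[tab$counts$cog_class == "G" & tab$counts$omic == "rna", ]
  expect_equal(gx$up, 1L)
  expect_equal(gx$down, 1L)
  # threshold ties count as regulated (1.65 exactly)
  ex <- tab$counts[tab$counts$cog_class == "E" & tab$counts$omic == "rna", ]
  expect_equal(ex$up, 2L)
  # g4 (class S) is past threshold in both omics but excluded from overlap
  sx <- tab$counts[tab$counts$cog_class == "S", ]
  expect_equal(sum(sx$up), 2L)  # counted per omic
  expect_false("S" %in% tab$overlap$cog_class)
  # g1 overlaps in both omics, same direction
  expect_equal(tab$overlap$up[tab$overlap$cog_class == "G"], 1L)

  # all below threshold -> empty table, no error
  none <- classify_and_tabulate(list(rna = res(rep(0.5, 6))), ann)
  expect_equal(nrow(none$counts), 0L)

  # unannotated loci fall into the reserved class
  rna2 <- rbind(rna, data.frame(locus_id = "gX", condition = "xylose",
                                znet = 3))
  tab2 <- classify_and_tabulate(list(rna = rna2), ann)
  expect_true("-" %in% tab2$counts$cog_class)
})

test_that("parameter recovery at the stated noise and effect size", {
  design <- two_cond_design()
  sim <- simulate_omics(design, 3000, frac_de = 0.1, effect_magnitude = 2,
                        noise_sd = 0.25, protein_detect_frac = 0, seed = 14)
  r <- run_contrast(sim$rna, design, "xylose")
  tr <- sim$truth[match(r$locus_id, sim$truth$locus_id), ]
  de <- tr$is_differential
  flagged <- abs(r$znet) >= 1.65
  expect_gte(mean(flagged[de]), 0.95)
  expect_true(all(sign(r$znet[de & flagged]) == sign(tr$effect[de & flagged])))
})
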