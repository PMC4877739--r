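# Signal-to-noise statistics and the Monte-Carlo FDR. The system S/N is the
# ratio of the mean cross-state to mean intra-replicate population SDs; the
# gene S/N is the ratio of the cross-state to intra-replicate 2-vector
# magnitudes of the normalized scores, scaled by the system S/N. Because the
# per-population normalization scales cancel against the system factor, the
# gene S/N equals the raw-scale magnitude ratio; for a null gene (all four
# raw differences i.i.d. normal) its square is F(2,2)-distributed, so
# P(S/N > c) = 1/(1+c^2).

#' Fit the system signal-to-noise model
#'
#' @param raw_diffs Data frame with columns `z0_raw`..`z3_raw` (from
#'   [raw_differences()]), >= 2 genes.
#' @return An `snr_model`: `system_snr`, `intra_noise_sd`, `cross_sd`,
#'   `n_genes`, plus the four population means/SDs used for normalization.
#' @export
system_snr <- function(raw_diffs) {
  need <- c("z0_raw", "z1_raw", "z2_raw", "z3_raw")
  stopifnot(all(need %in% names(raw_diffs)))
  if (nrow(raw_diffs) < 2L) stop("need at least 2 genes")
  sds <- vapply(need, function(cc) pop_sd(raw_diffs[[cc]]), 0)
  means <- vapply(need, function(cc) mean(raw_diffs[[cc]]), 0)
  intra <- mean(sds[c("z0_raw", "z1_raw")])
  cross <- mean(sds[c("z2_raw", "z3_raw")])
  if (intra == 0) stop("zero intra-replicate standard deviation")
  structure(
    list(system_snr = cross / intra, intra_noise_sd = intra, cross_sd = cross,
         n_genes = nrow(raw_diffs), pop_mean = means, pop_sd = sds),
    class = "snr_model"
  )
}

#' @export
print.snr_model <- function(x, ...) {
  cat(sprintf("<snr_model> system S/N = %.4g (cross SD %.4g / intra SD %.4g), %d genes\n",
              x$system_snr, x$cross_sd, x$intra_noise_sd, x$n_genes))
  invisible(x)
}

#' Per-gene signal-to-noise ratio
#'
#' `snr = sqrt(z2^2 + z3^2) / sqrt(z0^2 + z1^2) * system_snr` on the
#' normalized component scores. A zero intra-replicate magnitude yields
#' `+Inf`, which ranks above every finite value. `scale_mode = "divide"`
#' implements the alternative reading of "scaled by".
#'
#' @param z Data frame or matrix with columns `z0`..`z3` (normalized scores).
#' @param model An `snr_model` fitted on the same contrast.
#' @param scale_mode `"multiply"` (default) or `"divide"`.
#' @return Numeric vector of per-gene S/N values.
#' @export
gene_snr <- function(z, model, scale_mode = c("multiply", "divide")) {
  scale_mode <- match.arg(scale_mode)
  stopifnot(inherits(model, "snr_model"))
  cross <- sqrt(z[["z2"]]^2 + z[["z3"]]^2)
  intra <- sqrt(z[["z0"]]^2 + z[["z1"]]^2)
  ratio <- ifelse(intra == 0, Inf, cross / intra)
  if (scale_mode == "multiply") ratio * model$system_snr
  else ratio / model$system_snr
}

# the observed pipeline's snr computation, reused verbatim for the null draws:
# raw differences -> normalization with the model's population stats -> snr
snr_from_raw <- function(raw, model, scale_mode = "multiply") {
  z <- list(
    z0 = (raw[, 1] - model$pop_mean[["z0_raw"]]) / model$pop_sd[["z0_raw"]],
    z1 = (raw[, 2] - model$pop_mean[["z1_raw"]]) / model$pop_sd[["z1_raw"]],
    z2 = (raw[, 3] - model$pop_mean[["z2_raw"]]) / model$pop_sd[["z2_raw"]],
    z3 = (raw[, 4] - model$pop_mean[["z3_raw"]]) / model$pop_sd[["z3_raw"]]
  )
  gene_snr(z, model, scale_mode)
}

#' Monte-Carlo false discovery rate over S/N cutoffs
#'
#' Each Monte-Carlo replicate synthesizes `n_genes` null genes whose four raw
#' differences are i.i.d. `Normal(0, intra_noise_sd)` and pushes them through
#' the identical normalization (the observed populations' means/SDs held in
#' the model) and S/N computation with the observed system S/N. The estimate
#' at cutoff `c` is `min(1, mean null exceedance / observed exceedance)`
#' (conservative plug-in, pi0 fixed at 1). Per-gene FDRs are the estimate at
#' each gene's own S/N, monotonized to be non-increasing in S/N (q-value
#' style). Fixed seed + fixed inputs give an identical table.
#'
#' @param observed_snr Per-gene observed S/N values.
#' @param model An `snr_model`.
#' @param cutoffs Positive S/N cutoffs (default `c(1, 2, 2.8)`).
#' @param mc_replicates Number of Monte-Carlo replicates (default 100).
#' @param seed Integer seed.
#' @param scale_mode Passed through to the S/N computation.
#' @return `list(cutoff_table, gene_fdr)`; `cutoff_table` has columns
#'   `cutoff`, `n_observed`, `mean_null`, `fdr`, `mc_se` (`fdr` is `NA` when
#'   no observed gene exceeds the cutoff); `gene_fdr` aligns with
#'   `observed_snr`.
#' @export
monte_carlo_fdr <- function(observed_snr, model, cutoffs = c(1, 2, 2.8),
                            mc_replicates = 100L, seed = 1L,
                            scale_mode = "multiply") {
  stopifnot(inherits(model, "snr_model"), all(cutoffs > 0), mc_replicates >= 1)
  n <- length(observed_snr)
  set.seed(seed)
  null_snr <- matrix(NA_real_, n, mc_replicates)
  for (b in seq_len(mc_replicates)) {
    raw <- matrix(stats::rnorm(4L * n, 0, model$intra_noise_sd), n, 4L)
    null_snr[, b] <- snr_from_raw(raw, model, scale_mode)
  }
  pooled <- sort(as.vector(null_snr))
  B <- length(pooled)

  exceed_null <- function(cut, strict = TRUE) {
    # counts per replicate, for the SE; strict '>' matches "S/N > 2.8"
    apply(null_snr, 2, function(v) sum(if (strict) v > cut else v >= cut))
  }
  tab <- data.frame(cutoff = cutoffs, n_observed = NA_integer_,
                    mean_null = NA_real_, fdr = NA_real_, mc_se = NA_real_)
  for (i in seq_along(cutoffs)) {
    cnt <- exceed_null(cutoffs[i])
    obs <- sum(observed_snr > cutoffs[i])
    tab$n_observed[i] <- obs
    tab$mean_null[i] <- mean(cnt)
    if (obs > 0) {
      tab$fdr[i] <- min(1, mean(cnt) / obs)
      tab$mc_se[i] <- stats::sd(cnt / obs) / sqrt(mc_replicates)
    }
  }

  # per-gene estimate at its own snr (>= : the gene counts itself as called)
  obs_ge <- n + 1L - rank(observed_snr, ties.method = "min")
  null_gt <- (B - findInterval(observed_snr, pooled)) / mc_replicates
  raw_fdr <- pmin(1, null_gt / obs_ge)
  # monotonize (q-value style): running min over genes with snr at or below
  # this gene's, so the estimate never increases with snr
  o <- order(observed_snr)
  gene_fdr <- numeric(n)
  gene_fdr[o] <- cummin(raw_fdr[o])

  list(cutoff_table = tab, gene_fdr = gene_fdr)
}

#' Attach S/N and FDR columns to a two-replicate contrast result
#'
#' @param result A contrast result data.frame from [run_contrast()] computed
#'   with two replicates.
#' @param cutoffs,mc_replicates,seed,scale_mode Passed to [monte_carlo_fdr()].
#' @return `list(result, model, fdr_table)` where `result` carries `snr` and
#'   `fdr` columns.
#' @export
add_snr_fdr <- function(result, cutoffs = c(1, 2, 2.8), mc_replicates = 100L,
                        seed = 1L, scale_mode = "multiply") {
  if (anyNA(result$z0)) {
    stop("S/N needs the intra-replicate scores; single-replicate contrasts ",
         "have no noise measurement")
  }
  model <- system_snr(result[, c("z0_raw", "z1_raw", "z2_raw", "z3_raw")])
  snr <- gene_snr(result, model, scale_mode)
  fdr <- monte_carlo_fdr(snr, model, cutoffs = cutoffs,
                         mc_replicates = mc_replicates, seed = seed,
                         scale_mode = scale_mode)
  result$snr <- snr
  result$fdr <- fdr$gene_fdr
  list(result = result, model = model, fdr_table = fdr$cutoff_table)
}
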