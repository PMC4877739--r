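# The difference/normalization/merging framework. Per contrast (condition X
# vs reference Y, replicates A and B), each gene yields four raw log2
# differences: intra-replicate Z0 = B_X - A_X and Z1 = B_Y - A_Y, and
# cross-state Z2 = A_X - A_Y and Z3 = B_X - B_Y. Each difference population is
# normalized to mean 0 / SD 1, the two cross-state score vectors are merged
# (averaged, then renormalized) into the net score Znet (Rnet for RNA, Pnet
# for protein). A negative Znet means higher expression on the reference.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Raw per-gene difference scores for one contrast
#'
#' Genes missing any of the four required values are dropped from the
#' contrast (no imputation) and listed in the `dropped` attribute.
#'
#' @param expr An `expression_matrix` with two replicates.
#' @param design An `experiment_design`.
#' @param condition The non-reference condition (X); the design's reference
#'   is Y.
#' @return Data frame `locus_id`, `z0_raw`, `z1_raw`, `z2_raw`, `z3_raw`
#'   with attribute `dropped` (locus ids).
#' @export
raw_differences <- function(expr, design, condition) {
  if (length(design$replicates) < 2L) {
    stop("intra-replicate scores need two replicates; ",
         "use cross_state_only() for a single replicate set")
  }
  if (!condition %in% design$contrasts$condition) {
    stop("`", condition, "` is not a non-reference condition of the design")
  }
  A <- design$replicates[1]; B <- design$replicates[2]
  need <- c(paste(condition, c(A, B), sep = "."),
            paste(design$reference, c(A, B), sep = "."))
  miss <- setdiff(need, colnames(expr))
  if (length(miss)) stop("expression matrix missing column(s): ",
                         paste(miss, collapse = ", "))
  ax <- expr[, need[1]]; bx <- expr[, need[2]]
  ay <- expr[, need[3]]; by <- expr[, need[4]]
  ok <- is.finite(ax) & is.finite(bx) & is.finite(ay) & is.finite(by)
  out <- data.frame(
    locus_id = rownames(expr)[ok],
    z0_raw = (bx - ax)[ok],   # intra-replicate, condition X
    z1_raw = (by - ay)[ok],   # intra-replicate, reference Y
    z2_raw = (ax - ay)[ok],   # cross-state, replicate A
    z3_raw = (bx - by)[ok],   # cross-state, replicate B
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dropped") <- rownames(expr)[!ok]
  out
}

#' Normalize a difference population to mean 0, SD 1
#'
#' Population-SD convention (divide by n). The map is affine and
#' order-preserving; a population with no spread is an error.
#'
#' @param values Numeric vector (>= 2 finite values).
#' @return Normalized scores.
#' @export
normalize_population <- function(values) {
  if (sum(is.finite(values)) < 2L) {
    stop("need at least 2 finite values to normalize")
  }
  if (anyNA(values)) stop("normalize_population expects a complete population")
  s <- pop_sd(values)
  if (s == 0) stop("degenerate population: zero spread")
  (values - mean(values)) / s
}

#' Merge two normalized cross-state score vectors into Znet
#'
#' The default rule averages the two normalized cross-state scores and
#' renormalizes the result, the minimal rule producing a single normalized,
#' approximately Gaussian net score. A custom `rule` function
#' (`function(z2, z3) -> numeric`) may be plugged in; its output is always
#' renormalized.
#'
#' @param z2,z3 Normalized cross-state scores over the same gene set.
#' @param rule `"mean"` or a function of two vectors.
#' @return Znet: merged scores with population mean 0, SD 1.
#' @export
merge_znet <- function(z2, z3, rule = "mean") {
  stopifnot(length(z2) == length(z3))
  merged <- if (is.function(rule)) rule(z2, z3) else
    switch(rule, mean = (z2 + z3) / 2,
           stop("unknown merge rule: ", rule))
  normalize_population(merged)
}

#' Net score from cross-state differences of a single replicate set
#'
#' Proteomic mode: when only one replicate run is analyzed, the net score is
#' the normalized per-gene cross-state difference X - Y of the designated
#' replicate.
#'
#' @param expr An `expression_matrix`.
#' @param design An `experiment_design`.
#' @param condition The non-reference condition (X).
#' @param replicate Replicate label to use (default: the design's first).
#' @return Data frame `locus_id`, `znet` with attribute `dropped`.
#' @export
cross_state_only <- function(expr, design, condition,
                             replicate = design$replicates[1]) {
  if (!replicate %in% design$replicates) {
    stop("replicate '", replicate, "' not in design")
  }
  need <- paste(c(condition, design$reference), replicate, sep = ".")
  miss <- setdiff(need, colnames(expr))
  if (length(miss)) stop("expression matrix missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- expr[, need[1]] - expr[, need[2]]
  ok <- is.finite(d)
  out <- data.frame(locus_id = rownames(expr)[ok],
                    znet = normalize_population(d[ok]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- rownames(expr)[!ok]
  out
}

classify_regulation <- function(znet, threshold) {
  # >= / <= : ties at the threshold count as regulated
  ifelse(znet >= threshold, "up", ifelse(znet <= -threshold, "down", "ns"))
}

#' Run one contrast end to end
#'
#' Computes the raw differences, normalizes the four populations, merges the
#' cross-state scores into Znet, and classifies regulation at the threshold
#' (|Znet| >= 1.65 marks the outermost ~10% of a Gaussian population). For a
#' protein matrix (or `single_replicate = TRUE`) the single-replicate-set
#' cross-state mode is used and the four component scores are absent.
#'
#' @param expr An `expression_matrix`.
#' @param design An `experiment_design`.
#' @param condition The non-reference condition.
#' @param threshold Regulation threshold in SD units (default 1.65).
#' @param merge_rule Passed to [merge_znet()].
#' @param single_replicate Force single-replicate cross-state mode.
#' @return A contrast result data.frame: `locus_id`, `contrast`, `omic`,
#'   `condition`, raw and normalized scores, `znet`, `regulation`.
#' @export
run_contrast <- function(expr, design, condition, threshold = 1.65,
                         merge_rule = "mean", single_replicate = NULL) {
  omic <- attr(expr, "omic")
  if (is.null(single_replicate)) {
    single_replicate <- identical(omic, "protein") ||
      length(design$replicates) < 2L
  }
  label <- contrast_label(design, condition,
                          if (identical(omic, "protein")) "protein" else "rna")
  if (single_replicate) {
    cs <- cross_state_only(expr, design, condition)
    res <- data.frame(
      locus_id = cs$locus_id, contrast = label, omic = omic,
      condition = condition,
      z0_raw = NA_real_, z1_raw = NA_real_, z2_raw = NA_real_,
      z3_raw = NA_real_, z0 = NA_real_, z1 = NA_real_, z2 = NA_real_,
      z3 = NA_real_, znet = cs$znet,
      regulation = classify_regulation(cs$znet, threshold),
      stringsAsFactors = FALSE
    )
    attr(res, "dropped") <- attr(cs, "dropped")
    return(res)
  }
  raw <- raw_differences(expr, design, condition)
  z0 <- normalize_population(raw$z0_raw)
  z1 <- normalize_population(raw$z1_raw)
  z2 <- normalize_population(raw$z2_raw)
  z3 <- normalize_population(raw$z3_raw)
  znet <- merge_znet(z2, z3, rule = merge_rule)
  res <- data.frame(
    locus_id = raw$locus_id, contrast = label, omic = omic,
    condition = condition,
    z0_raw = raw$z0_raw, z1_raw = raw$z1_raw, z2_raw = raw$z2_raw,
    z3_raw = raw$z3_raw,
    z0 = z0, z1 = z1, z2 = z2, z3 = z3, znet = znet,
    regulation = classify_regulation(znet, threshold),
    stringsAsFactors = FALSE
  )
  attr(res, "dropped") <- attr(raw, "dropped")
  res
}

#' Tabulate up/down regulated genes by COG class
#'
#' Counts, per COG letter x condition x omic, the genes past the Znet
#' threshold in each direction, plus the gene/protein overlap (same locus,
#' same direction, past threshold in both omics). Exclusions — COG class S
#' ("function unknown") and genes whose product is hypothetical — apply to
#' the overlap counts only, mirroring how dual-omic agreement is curated.
#' Loci without an annotation or COG letter are counted under the reserved
#' class `"-"`.
#'
#' @param results Named list of contrast result data.frames, e.g.
#'   `list(rna = ..., protein = ...)`; each may hold several contrasts.
#' @param annotations A `gene_annotation` data.frame.
#' @param threshold Regulation threshold (default 1.65).
#' @param exclude_classes COG classes excluded from overlap (default `"S"`).
#' @param exclude_hypotheticals Exclude hypothetical products from overlap.
#' @return `list(counts, overlap)` of long-format data.frames, class
#'   `cog_table`.
#' @export
classify_and_tabulate <- function(results, annotations, threshold = 1.65,
                                  exclude_classes = "S",
                                  exclude_hypotheticals = TRUE) {
  stopifnot(is.list(results), !is.null(names(results)))
  cogs <- stats::setNames(annotations$cog_class, annotations$locus_id)
  hyp <- stats::setNames(annotations$is_hypothetical, annotations$locus_id)
  lookup_cog <- function(locus) {
    x <- cogs[locus]
    x[is.na(x)] <- "-"
    unname(x)
  }
  calls <- list()
  for (omic in names(results)) {
    df <- results[[omic]]
    dir <- classify_regulation(df$znet, threshold)
    keep <- dir != "ns"
    if (!any(keep)) next
    calls[[omic]] <- data.frame(
      locus_id = df$locus_id[keep], condition = df$condition[keep],
      omic = omic, direction = dir[keep],
      cog_class = lookup_cog(df$locus_id[keep]),
      stringsAsFactors = FALSE
    )
  }
  all_calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(locus_id = character(), condition = character(),
               omic = character(), direction = character(),
               cog_class = character(), stringsAsFactors = FALSE)
  counts <- if (nrow(all_calls)) {
    agg <- stats::aggregate(list(n = rep(1L, nrow(all_calls))),
                            all_calls[, c("cog_class", "condition", "omic",
                                          "direction")], sum)
    stats::reshape(agg, idvar = c("cog_class", "condition", "omic"),
                   timevar = "direction", direction = "wide")
  } else NULL
  counts <- tidy_updown(counts)

  # overlap: same gene, same direction, past threshold in both omics
  overlap <- NULL
  if (all(c("rna", "protein") %in% names(calls))) {
    m <- merge(calls$rna, calls$protein,
               by = c("locus_id", "condition", "direction"))
    if (nrow(m)) {
      excl <- m$cog_class.x %in% exclude_classes
      if (exclude_hypotheticals) {
        h <- hyp[m$locus_id]
        excl <- excl | (!is.na(h) & h)
      }
      m <- m[!excl, , drop = FALSE]
    }
    if (nrow(m)) {
      agg <- stats::aggregate(list(n = rep(1L, nrow(m))),
                              data.frame(cog_class = m$cog_class.x,
                                         condition = m$condition,
                                         direction = m$direction,
                                         stringsAsFactors = FALSE), sum)
      overlap <- stats::reshape(agg, idvar = c("cog_class", "condition"),
                                timevar = "direction", direction = "wide")
    }
  }
  overlap <- tidy_updown(overlap, with_omic = FALSE)
  structure(list(counts = counts, overlap = overlap, threshold = threshold),
            class = "cog_table")
}

tidy_updown <- function(df, with_omic = TRUE) {
  id_cols <- if (with_omic) c("cog_class", "condition", "omic") else
    c("cog_class", "condition")
  if (is.null(df)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(id_cols)), id_cols))
    out$up <- integer(0); out$down <- integer(0)
    return(out)
  }
  names(df) <- sub("^n\\.", "", names(df))
  for (cc in c("up", "down")) {
    if (!cc %in% names(df)) df[[cc]] <- 0L
    df[[cc]][is.na(df[[cc]])] <- 0L
  }
  out <- df[, c(id_cols, "up", "down")]
  out <- out[do.call(order, out[id_cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cog_table <- function(x, ...) {
  cat("COG regulation table (|Znet| >=", x$threshold, ")\n")
  print(x$counts)
  if (nrow(x$overlap)) {
    cat("gene/protein overlap (exclusions applied):\n")
    print(x$overlap)
  }
  invisible(x)
}

#' Write a COG table in wide (publication) shape
#'
#' Rows are COG letters; columns are `<condition>.<omic>.<direction>` counts
#' plus `<condition>.overlap.<direction>`.
#'
#' @param tab A `cog_table`.
#' @param path Output TSV path.
#' @export
write_cog_table <- function(tab, path) {
  long <- tab$counts
  ov <- tab$overlap
  if (nrow(ov)) {
    ov$omic <- "overlap"
    long <- rbind(long[, c("cog_class", "condition", "omic", "up", "down")],
                  ov[, c("cog_class", "condition", "omic", "up", "down")])
  }
  if (!nrow(long)) {
    writeLines("cog_class", path)
    return(invisible(path))
  }
  long$key_up <- paste(long$condition, long$omic, "up", sep = ".")
  long$key_down <- paste(long$condition, long$omic, "down", sep = ".")
  keys <- unique(c(rbind(long$key_up, long$key_down)))
  classes <- sort(unique(long$cog_class))
  m <- matrix(0L, length(classes), length(keys),
              dimnames = list(classes, keys))
  for (i in seq_len(nrow(long))) {
    m[long$cog_class[i], long$key_up[i]] <- long$up[i]
    m[long$cog_class[i], long$key_down[i]] <- long$down[i]
  }
  out <- data.frame(cog_class = classes, m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
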