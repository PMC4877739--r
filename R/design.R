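#' Describe a two-replicate multi-substrate experiment
#'
#' An experiment design names the growth conditions (substrates), designates
#' one of them as the reference that every contrast is measured against, and
#' lists the biological replicate labels. Contrast labels follow the
#' `R0/R1/...` (RNA) and `P0/P1/...` (protein) convention: the i-th
#' non-reference condition, in the order given, gets index `i - 1`.
#'
#' @param conditions Character vector of condition labels (>= 2, unique).
#' @param reference The reference condition; must be one of `conditions`.
#'   Defaults to the first.
#' @param replicates Character vector of one or two replicate labels.
#'   Two replicates are required for intra-replicate difference scores.
#' @return An object of class `experiment_design`.
#' @examples
#' design <- experiment_design(
#'   c("cellobiose", "xylose", "alpha_cellulose", "xylan"),
#'   reference = "cellobiose"
#' )
#' design$contrasts
#' @export
experiment_design <- function(conditions,
                              reference = conditions[[1L]],
                              replicates = c("A", "B")) {
  if (!is.character(conditions) || length(conditions) < 2L) {
    stop("`conditions` must be a character vector with at least 2 entries ",
         "(one reference plus >= 1 contrast condition)")
  }
  if (anyDuplicated(conditions)) {
    stop("duplicate condition labels: ",
         paste(unique(conditions[duplicated(conditions)]), collapse = ", "))
  }
  if (length(reference) != 1L || !reference %in% conditions) {
    stop("`reference` must name exactly one of `conditions`")
  }
  if (!is.character(replicates) || !length(replicates) %in% 1:2 ||
      anyDuplicated(replicates)) {
    stop("`replicates` must be 1 or 2 distinct labels")
  }
  non_ref <- setdiff(conditions, reference)
  contrasts <- data.frame(
    condition = non_ref,
    rna = paste0("R", seq_along(non_ref) - 1L),
    protein = paste0("P", seq_along(non_ref) - 1L),
    stringsAsFactors = FALSE
  )
  structure(
    list(conditions = conditions, reference = reference,
         replicates = replicates, contrasts = contrasts),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", length(x$conditions), "conditions,",
      length(x$replicates), "replicate(s)\n")
  cat("  reference:", x$reference, "\n")
  cat("  contrasts:\n")
  for (i in seq_len(nrow(x$contrasts))) {
    cat(sprintf("    %s/%s: %s - %s\n", x$contrasts$rna[i],
                x$contrasts$protein[i], x$contrasts$condition[i], x$reference))
  }
  invisible(x)
}

#' Sample column labels implied by a design
#'
#' Columns are named `<condition>.<replicate>` in condition-major order.
#'
#' @param design An `experiment_design`.
#' @return Character vector of column labels.
#' @export
sample_columns <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  as.vector(t(outer(design$conditions, design$replicates, paste, sep = ".")))
}

#' Look up the contrast label for a condition
#'
#' @param design An `experiment_design`.
#' @param condition A non-reference condition label.
#' @param omic `"rna"` or `"protein"`.
#' @return The contrast label, e.g. `"R0"`.
#' @export
contrast_label <- function(design, condition, omic = c("rna", "protein")) {
  omic <- match.arg(omic)
  i <- match(condition, design$contrasts$condition)
  if (is.na(i)) stop("`", condition, "` is not a non-reference condition")
  design$contrasts[[omic]][i]
}
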