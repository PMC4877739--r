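# Expression matrices and the tabular I/O around them. Values are log2
# expression; a filtered cell is NA (never zero), and every filtering event is
# recorded in the matrix's filter log.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, rows = loci, columns = `<condition>.<replicate>`
#'   sample labels consistent with `design` (protein matrices use the design's
#'   first replicate label for the single 4-plex run).
#' @param design An `experiment_design`.
#' @param omic `"rna"` or `"protein"`.
#' @param filter_log Data frame of filtering events
#'   (`locus_id`, `column`, `filter`).
#' @return The matrix with class `expression_matrix` and attributes
#'   `omic`, `design`, `filter_log`.
#' @export
expression_matrix <- function(values, design, omic = c("rna", "protein"),
                              filter_log = empty_filter_log()) {
  omic <- match.arg(omic)
  stopifnot(is.matrix(values), inherits(design, "experiment_design"))
  if (nrow(values) > 0L && is.null(rownames(values))) {
    stop("expression matrix needs locus_id rownames")
  }
  allowed <- sample_columns(design)
  bad <- setdiff(colnames(values), allowed)
  if (length(bad)) {
    stop("column(s) not in design: ", paste(bad, collapse = ", "))
  }
  structure(values, class = c("expression_matrix", class(values)),
            omic = omic, design = design, filter_log = filter_log)
}

empty_filter_log <- function() {
  data.frame(locus_id = character(), column = character(),
             filter = character(), stringsAsFactors = FALSE)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> omic=%s  %d loci x %d samples  (%d filter events)\n",
              attr(x, "omic"), nrow(x), ncol(x), nrow(attr(x, "filter_log"))))
  invisible(x)
}

#' Read a log2 expression table
#'
#' Expects a TSV whose first column is `locus_id` and whose remaining header
#' names are `<condition>.<replicate>` sample labels. Every sample column
#' implied by the design must be present; missing cells may be `"."` or empty
#' and are kept as `NA`.
#'
#' @param path File path.
#' @param design An `experiment_design`.
#' @param omic `"rna"` or `"protein"`.
#' @param columns Optional subset of design columns to require (defaults to
#'   all for RNA, first replicate only for protein).
#' @return An `expression_matrix`.
#' @export
read_expression_table <- function(path, design, omic = c("rna", "protein"),
                                  columns = NULL) {
  omic <- match.arg(omic)
  if (is.null(columns)) {
    columns <- if (omic == "rna") sample_columns(design) else
      paste(design$conditions, design$replicates[1], sep = ".")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ".", ""))
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols)) {
    stop("expression table missing design column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  vals <- as.matrix(df[, columns, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1]])
  expression_matrix(vals, design, omic)
}

#' Write a log2 expression table
#'
#' @param expr An `expression_matrix` (or plain matrix with rownames).
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(locus_id = rownames(expr), unclass(expr)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read peptide evidence
#'
#' A TSV with columns `protein_id`, `peptide`, `log_e` (base-10 log of the
#' peptide expectation value; more negative is more confident) and one
#' `intensity.<condition>` reporter-channel column per design condition.
#'
#' @param path File path.
#' @param design An `experiment_design`; channel columns are checked against
#'   its conditions.
#' @return A data.frame of peptide evidence.
#' @export
read_peptide_evidence <- function(path, design) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ".", ""))
  need <- c("protein_id", "peptide", "log_e",
            paste0("intensity.", design$conditions))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("peptide evidence missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(df$log_e))) stop("non-finite log_e in peptide evidence")
  df
}

.contrast_num_cols <- c("z0_raw", "z1_raw", "z2_raw", "z3_raw",
                        "z0", "z1", "z2", "z3", "znet", "snr", "fdr")

#' Write a contrast result table
#'
#' One row per gene per contrast with the raw and normalized difference
#' scores, the merged net score, the regulation call, and (when computed) the
#' gene signal-to-noise ratio and its estimated FDR. Numeric fields are
#' serialized with enough digits to round-trip beyond 6 decimals.
#'
#' @param results A contrast result data.frame (see [run_contrast()]).
#' @param path Output path.
#' @export
write_contrast_table <- function(results, path) {
  cols <- c("locus_id", "contrast", "omic", "condition", .contrast_num_cols,
            "regulation")
  out <- results[, intersect(cols, names(results)), drop = FALSE]
  for (cc in intersect(.contrast_num_cols, names(out))) {
    x <- out[[cc]]
    out[[cc]] <- ifelse(is.na(x), NA, sprintf("%.10g", x))
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write contrast table to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a contrast result table written by [write_contrast_table()]
#'
#' @param path File path.
#' @return A contrast result data.frame.
#' @export
read_contrast_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "."))
  for (cc in intersect(.contrast_num_cols, names(df))) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  df
}
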