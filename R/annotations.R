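# Gene annotations: locus, contig coordinates (1-based inclusive, GFF
# convention), strand, product description, optional single-letter COG class.

#' Construct a gene annotation table
#'
#' @param locus_id,contig_id,start,end,strand,description,cog_class,is_hypothetical
#'   Parallel vectors, one entry per gene. `start`/`end` are 1-based inclusive;
#'   `strand` is `"+"` or `"-"`; `cog_class` a single uppercase letter or `NA`;
#'   `is_hypothetical` defaults to a case-insensitive "hypothetical" match in
#'   the description.
#' @return A `data.frame` with class `gene_annotation`.
#' @export
gene_annotation <- function(locus_id, contig_id, start, end, strand,
                            description = "", cog_class = NA_character_,
                            is_hypothetical = NULL) {
  n <- length(locus_id)
  ann <- data.frame(
    locus_id = as.character(locus_id),
    contig_id = rep_len(as.character(contig_id), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    description = rep_len(as.character(description), n),
    cog_class = rep_len(as.character(cog_class), n),
    stringsAsFactors = FALSE
  )
  ann$is_hypothetical <- if (is.null(is_hypothetical)) {
    grepl("hypothetical", ann$description, ignore.case = TRUE)
  } else rep_len(as.logical(is_hypothetical), n)
  validate_annotations(ann)
}

validate_annotations <- function(ann, lines = NULL) {
  bad <- which(is.na(ann$start) | is.na(ann$end) | ann$end < ann$start)
  if (length(bad)) {
    where <- if (is.null(lines)) paste("record", bad[1]) else paste("line", lines[bad[1]])
    stop("annotation with end < start (or unparsable coordinates) at ", where,
         " (locus ", ann$locus_id[bad[1]], ")")
  }
  if (anyDuplicated(ann$locus_id)) {
    stop("duplicate locus_id: ",
         paste(unique(ann$locus_id[duplicated(ann$locus_id)]), collapse = ", "))
  }
  bad <- which(!ann$strand %in% c("+", "-"))
  if (length(bad)) {
    where <- if (is.null(lines)) paste("record", bad[1]) else paste("line", lines[bad[1]])
    stop("invalid strand '", ann$strand[bad[1]], "' at ", where)
  }
  multi <- !is.na(ann$cog_class) & nchar(ann$cog_class) > 1L
  if (any(multi)) {
    warning(sum(multi), " multi-letter COG assignment(s) reduced to first letter")
    ann$cog_class[multi] <- substr(ann$cog_class[multi], 1L, 1L)
  }
  ann$cog_class[!is.na(ann$cog_class) & ann$cog_class == ""] <- NA_character_
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read gene annotations from GFF3 or TSV
#'
#' The TSV dialect has a header with columns `locus_id`, `contig_id`, `start`,
#' `end`, `strand`, `description` and optionally `COG` and `hypothetical`.
#' GFF3 features of type `gene` (or all features when no `gene` type is
#' present) are used; the locus is taken from the `locus_tag` attribute, then
#' `ID`; the COG letter from a `cog_class` attribute; the description from
#' `product`, then `description`. Missing values are `"."` or empty.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @param genome Optional named `DNAStringSet`; when supplied, coordinates are
#'   checked against contig lengths.
#' @return A `gene_annotation` data.frame.
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "tsv"),
                             genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  ann <- if (format == "gff3") read_annotations_gff3(path) else read_annotations_tsv(path)
  if (!is.null(genome)) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    miss <- setdiff(ann$contig_id, names(lens))
    if (length(miss)) stop("contig(s) absent from genome: ", paste(miss, collapse = ", "))
    out <- ann$end > lens[ann$contig_id] | ann$start < 1L
    if (any(out)) stop("coordinates outside contig for locus ",
                       ann$locus_id[which(out)[1]])
  }
  ann
}

read_annotations_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty annotation TSV: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("locus_id", "contig_id", "start", "end", "strand")
  if (!all(need %in% header)) {
    stop("annotation TSV header missing column(s): ",
         paste(setdiff(need, header), collapse = ", "))
  }
  body <- lines[-1]
  if (!length(body)) {
    return(gene_annotation(character(), character(), integer(), integer(), character()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    i <- which(nf != length(header))[1]
    stop("malformed annotation TSV line ", i + 1L, ": expected ",
         length(header), " fields, found ", nf[i])
  }
  m <- do.call(rbind, parts)
  colnames(m) <- header
  val <- function(col, default = NA_character_) {
    if (col %in% header) {
      x <- m[, col]
      x[x == "." | x == ""] <- NA_character_
      x
    } else rep(default, nrow(m))
  }
  start <- suppressWarnings(as.integer(val("start")))
  end <- suppressWarnings(as.integer(val("end")))
  desc <- val("description")
  desc[is.na(desc)] <- ""
  hyp_col <- val("hypothetical")
  hyp <- if (all(is.na(hyp_col))) NULL else toupper(hyp_col) %in% c("TRUE", "T", "1", "YES")
  ann <- data.frame(
    locus_id = val("locus_id"), contig_id = val("contig_id"),
    start = start, end = end, strand = val("strand"),
    description = desc, cog_class = val("COG"),
    stringsAsFactors = FALSE
  )
  ann$is_hypothetical <- if (is.null(hyp)) {
    grepl("hypothetical", ann$description, ignore.case = TRUE)
  } else hyp
  validate_annotations(ann, lines = seq_len(nrow(ann)) + 1L)
}

read_annotations_gff3 <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  if ("type" %in% names(gr) && any(gr$type == "gene")) gr <- gr[gr$type == "gene", ]
  pick <- function(keys) {
    out <- rep(NA_character_, nrow(gr))
    for (k in keys) {
      if (k %in% names(gr)) {
        v <- as.character(gr[[k]])
        take <- is.na(out) & !is.na(v)
        out[take] <- v[take]
      }
    }
    out
  }
  locus <- pick(c("locus_tag", "ID", "Name"))
  if (anyNA(locus)) stop("GFF3 feature without locus_tag/ID attribute")
  desc <- pick(c("product", "description"))
  desc[is.na(desc)] <- ""
  strand <- as.character(gr$strand)
  if (any(strand == "*")) stop("GFF3 gene feature with unspecified strand")
  ann <- data.frame(
    locus_id = locus,
    contig_id = as.character(gr$seqnames),
    start = gr$start, end = gr$end,
    strand = strand, description = desc,
    cog_class = pick("cog_class"),
    stringsAsFactors = FALSE
  )
  ann$is_hypothetical <- grepl("hypothetical", ann$description, ignore.case = TRUE)
  validate_annotations(ann)
}

#' Write gene annotations
#'
#' The GFF3 writer emits one `gene` feature per annotation with `ID`,
#' `locus_tag`, `product` and `cog_class` attributes, so that reading the file
#' back reproduces coordinates and strands exactly.
#'
#' @param ann A `gene_annotation` data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"gff3"`.
#' @export
write_annotations <- function(ann, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- ann[, c("locus_id", "contig_id", "start", "end", "strand",
                   "description", "cog_class")]
    names(out)[7] <- "COG"
    out$hypothetical <- ann$is_hypothetical
    out$COG[is.na(out$COG)] <- "."
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    attrs <- sprintf("ID=%s;locus_tag=%s", ann$locus_id, ann$locus_id)
    has_desc <- nzchar(ann$description)
    attrs[has_desc] <- paste0(attrs[has_desc], ";product=", ann$description[has_desc])
    has_cog <- !is.na(ann$cog_class)
    attrs[has_cog] <- paste0(attrs[has_cog], ";cog_class=", ann$cog_class[has_cog])
    rows <- sprintf("%s\tznetdiff\tgene\t%d\t%d\t.\t%s\t.\t%s",
                    ann$contig_id, ann$start, ann$end, ann$strand, attrs)
    writeLines(c("##gff-version 3", rows), path)
  }
  invisible(path)
}
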