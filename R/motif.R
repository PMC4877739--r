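# Degenerate IUPAC consensus scanning, as used for catabolite-responsive
# element (cre) searches: slide the consensus over both strands, count
# mismatches per window, and classify hits by their relation to annotated
# genes (overlapping a gene body / adjacent upstream / unassociated).

#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

check_iupac <- function(consensus) {
  letters <- strsplit(consensus, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC character '", bad[1], "' in consensus")
  }
  if (length(letters) < 4L) stop("consensus must be at least 4 bases long")
  invisible(letters)
}

revcomp_iupac <- function(consensus) {
  paste(rev(IUPAC_COMPLEMENT[strsplit(consensus, "")[[1]]]), collapse = "")
}

# per-window mismatch counts of `pattern` (IUPAC) against character vector `s`
window_mismatches <- function(s, pattern) {
  letters <- strsplit(pattern, "")[[1]]
  L <- length(letters)
  nw <- length(s) - L + 1L
  if (nw < 1L) return(integer(0))
  mm <- integer(nw)
  for (j in seq_len(L)) {
    ok <- s[j:(j + nw - 1L)] %in% IUPAC_SETS[[letters[j]]]
    mm <- mm + !ok
  }
  mm
}

#' Scan a genome for a degenerate IUPAC consensus
#'
#' Every window of consensus length whose mismatch count (on either searched
#' strand) is at most `max_mismatches` yields a hit. `N` in the consensus
#' matches any base and never counts as a mismatch. Positions are 1-based
#' forward-strand coordinates of the window's leftmost base; the matched
#' sequence is the forward-strand slice. A window matching on both strands
#' (palindromic consensus) is reported once, on the `+` strand, with
#' `palindromic = TRUE` and the smaller of the two mismatch counts.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param consensus IUPAC string (ACGTRYSWKMBDHVN, length >= 4).
#' @param max_mismatches Allowed mismatches per window (default 0).
#' @param strands `"both"` (default) or `"forward"`.
#' @return A `motif_hits` data.frame: `contig_id`, `start`, `strand`,
#'   `matched_sequence`, `mismatches`, `palindromic`, `association`,
#'   `associated_locus`.
#' @export
scan_consensus <- function(genome, consensus, max_mismatches = 0L,
                           strands = c("both", "forward")) {
  strands <- match.arg(strands)
  consensus <- toupper(consensus)
  check_iupac(consensus)
  L <- nchar(consensus)
  gchar <- if (is.character(genome)) genome else
    stats::setNames(as.character(genome), names(genome))
  if (is.null(names(gchar))) stop("genome sequences must be named")
  rc <- revcomp_iupac(consensus)
  hits <- list()
  for (contig in names(gchar)) {
    s <- strsplit(toupper(gchar[[contig]]), "")[[1]]
    mm_fwd <- window_mismatches(s, consensus)
    # a minus-strand site reads as the reverse complement of the consensus on
    # the forward strand, at the same leftmost coordinate
    mm_rev <- if (strands == "both") window_mismatches(s, rc) else
      rep.int(.Machine$integer.max, length(mm_fwd))
    pos <- which(mm_fwd <= max_mismatches | mm_rev <= max_mismatches)
    if (!length(pos)) next
    fwd_ok <- mm_fwd[pos] <= max_mismatches
    rev_ok <- mm_rev[pos] <= max_mismatches
    hits[[contig]] <- data.frame(
      contig_id = contig,
      start = pos,
      strand = ifelse(fwd_ok, "+", "-"),
      matched_sequence = substring(gchar[[contig]], pos, pos + L - 1L),
      mismatches = ifelse(fwd_ok & rev_ok, pmin(mm_fwd[pos], mm_rev[pos]),
                          ifelse(fwd_ok, mm_fwd[pos], mm_rev[pos])),
      palindromic = fwd_ok & rev_ok,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(contig_id = character(), start = integer(), strand = character(),
               matched_sequence = character(), mismatches = integer(),
               palindromic = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$association <- rep(NA_character_, nrow(out))
  out$associated_locus <- rep(NA_character_, nrow(out))
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Classify motif hits by their relation to genes
#'
#' A hit is `overlapping` when any of its bases lies within a gene body
#' (1-based inclusive coordinates), else `adjacent` when it lies within
#' `upstream_window` bp 5' of a gene start on that gene's strand (regulatory
#' element semantics; set `downstream = TRUE` to accept either side), else
#' `unassociated`. Among qualifying genes the nearest wins (overlap distance
#' 0, ties broken by gene start).
#'
#' @param hits A `motif_hits` data.frame from [scan_consensus()].
#' @param annotations A `gene_annotation` data.frame sharing contig ids.
#' @param upstream_window Adjacency window in bp (default 200).
#' @param downstream Also accept hits within the window 3' of a gene end.
#' @return The hits with `association` and `associated_locus` filled.
#' @export
associate_hits <- function(hits, annotations, upstream_window = 200L,
                           downstream = FALSE) {
  if (!nrow(hits)) return(hits)
  L <- nchar(hits$matched_sequence[1])
  for (i in seq_len(nrow(hits))) {
    h_start <- hits$start[i]
    h_end <- h_start + L - 1L
    ann <- annotations[annotations$contig_id == hits$contig_id[i], , drop = FALSE]
    if (!nrow(ann)) next
    ov <- ann$start <= h_end & ann$end >= h_start
    if (any(ov)) {
      cand <- ann[ov, ]
      hits$association[i] <- "overlapping"
      hits$associated_locus[i] <- cand$locus_id[order(cand$start)][1]
      next
    }
    # strand-aware upstream windows
    up_lo <- ifelse(ann$strand == "+", ann$start - upstream_window, ann$end + 1L)
    up_hi <- ifelse(ann$strand == "+", ann$start - 1L, ann$end + upstream_window)
    adj <- up_lo <= h_end & up_hi >= h_start
    if (downstream) {
      dn_lo <- ifelse(ann$strand == "+", ann$end + 1L, ann$start - upstream_window)
      dn_hi <- ifelse(ann$strand == "+", ann$end + upstream_window, ann$start - 1L)
      adj <- adj | (dn_lo <= h_end & dn_hi >= h_start)
    }
    if (any(adj)) {
      cand <- ann[adj, ]
      gap <- pmax(cand$start - h_end, h_start - cand$end)
      o <- order(gap, cand$start)
      hits$association[i] <- "adjacent"
      hits$associated_locus[i] <- cand$locus_id[o[1]]
    } else {
      hits$association[i] <- "unassociated"
    }
  }
  hits
}

#' Write motif hits as TSV (and optionally BED)
#'
#' The BED writer converts to 0-based half-open coordinates at the boundary.
#'
#' @param hits A `motif_hits` data.frame.
#' @param path Output TSV path.
#' @param bed_path Optional BED output path.
#' @export
write_motif_hits <- function(hits, path, bed_path = NULL) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  if (!is.null(bed_path) && nrow(hits)) {
    L <- nchar(hits$matched_sequence[1])
    bed <- data.frame(hits$contig_id, hits$start - 1L, hits$start + L - 1L,
                      ifelse(is.na(hits$associated_locus), ".",
                             hits$associated_locus),
                      hits$mismatches, hits$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
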