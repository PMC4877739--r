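test_that("exact planted sites are found on both strands", {
  set.seed(61)
  left <- random_dna(100)
  right <- random_dna(100)
  gnm <- c(contig_1 = paste0(left, "TGTAAA", right))
  hits <- scan_consensus(gnm, "TGTAAA")
  plus <- hits[hits$strand == "+" | hits$palindromic, ]
  expect_true(101 %in% plus$start)
  expect_equal(hits$matched_sequence[hits$start == 101], "TGTAAA")
  expect_equal(hits$mismatches[hits$start == 101], 0L)

  # reverse complement plants as a minus-strand hit at the same left edge
  gnm2 <- c(contig_1 = paste0(left, "TTTACA", right))
  hits2 <- scan_consensus(gnm2, "TGTAAA")
  expect_true(any(hits2$start == 101 & hits2$strand == "-"))
  fwd_only <- scan_consensus(gnm2, "TGTAAA", strands = "forward")
  expect_false(any(fwd_only$start == 101))
})

test_that("degenerate scanning equals the brute-force window oracle", {
  seqs <- list(a = random_dna(4000, seed = 62), b = random_dna(4000, seed = 63))
  consensi <- c("TGWNANCGNTNWCA", "TGWAANCGNTNWCA", "RRYYNNSSWW",
                "ACGTN", "TGTGANCGNTNACA")
  for (cons in consensi) {
    for (mm in 0:2) {
      gnm <- c(c1 = seqs$a)
      mine <- scan_consensus(gnm, cons, max_mismatches = mm)
      oracle <- oracle_scan(seqs$a, cons, mm, both = TRUE)
      # expand palindromic single rows back to both strands for comparison
      expanded <- mine[rep(seq_len(nrow(mine)), 1 + mine$palindromic), ]
      if (any(mine$palindromic)) {
        dup <- duplicated(paste(expanded$start, expanded$strand))
        expanded$strand[dup] <- "-"
      }
      key <- function(df) sort(paste(df$start, df$strand))
      expect_equal(key(expanded), key(oracle), label = paste(cons, mm))
      # mismatch counts agree per +-strand window
      mo <- merge(mine[mine$strand == "+" & !mine$palindromic, ],
                  oracle[oracle$strand == "+", ], by = "start")
      expect_true(all(mo$mismatches.x == mo$mismatches.y))
    }
  }
})

test_that("strand closure: both-strand scan equals forward scans of S and revcomp(S)", {
  s <- random_dna(3000, seed = 64)
  cons <- "TGWAANCGNT"
  L <- nchar(cons)
  both <- scan_consensus(c(c1 = s), cons, max_mismatches = 1)
  fwd <- scan_consensus(c(c1 = s), cons, max_mismatches = 1,
                        strands = "forward")
  rc_s <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rc_hits <- scan_consensus(c(c1 = rc_s), cons, max_mismatches = 1,
                            strands = "forward")
  mapped <- sort(nchar(s) - (rc_hits$start + L - 1) + 1)  # back to fwd coords
  minus <- both[both$strand == "-" | both$palindromic, "start"]
  expect_equal(sort(minus), mapped)
  expect_setequal(both[both$strand == "+" | both$palindromic, "start"],
                  fwd$start)
})

test_that("palindromic windows are reported once with the flag set", {
  gnm <- c(c1 = paste0(random_dna(50, seed = 65), "ACGCGT",
                       random_dna(50)))
  hits <- scan_consensus(gnm, "ACGCGT")  # palindrome
  pal <- hits[hits$start == 51, ]
  expect_equal(nrow(pal), 1L)
  expect_equal(pal$strand, "+")
  expect_true(pal$palindromic)
})

test_that("invalid IUPAC characters are named in the error", {
  expect_error(scan_consensus(c(c1 = "ACGT"), "ACXG"), "'X'")
  expect_error(scan_consensus(c(c1 = "ACGT"), "ACG"), "at least 4")
})

test_that("hits classify as overlapping, adjacent (strand-aware) or unassociated", {
  ann <- gene_annotation(c("gPlus", "gMinus"), "c1",
                         start = c(1000, 3000), end = c(1500, 3500),
                         strand = c("+", "-"))
  hit_at <- function(start) {
    data.frame(contig_id = "c1", start = start, strand = "+",
               matched_sequence = "ACGTACGT", mismatches = 0L,
               palindromic = FALSE, association = NA_character_,
               associated_locus = NA_character_, stringsAsFactors = FALSE)
  }
  # inside gene body
  h <- associate_hits(hit_at(1200), ann)
  expect_equal(h$association, "overlapping")
  expect_equal(h$associated_locus, "gPlus")
  # ends 100 bp upstream of the + gene start (window 200)
  h2 <- associate_hits(hit_at(893), ann)  # hit spans 893..900, gap 100
  expect_equal(h2$association, "adjacent")
  expect_equal(h2$associated_locus, "gPlus")
  # upstream of a - strand gene means to its right
  h3 <- associate_hits(hit_at(3550), ann)
  expect_equal(h3$association, "adjacent")
  expect_equal(h3$associated_locus, "gMinus")
  # 3' side of the + gene is not adjacent unless downstream = TRUE
  h4 <- associate_hits(hit_at(1550), ann)
  expect_equal(h4$association, "unassociated")
  h5 <- associate_hits(hit_at(1550), ann, downstream = TRUE)
  expect_equal(h5$association, "adjacent")
  # far from every gene
  h6 <- associate_hits(hit_at(9000), ann)
  expect_equal(h6$association, "unassociated")
  expect_true(is.na(h6$associated_locus))
})

test_that("planted motif recall is 100% at zero mismatches", {
  plan <- list(consensus = "TGWAANCGNTNWCA", n_planted = 8L)
  gen <- generate_annotated_genome(n_genes = 15, motif_plan = plan, seed = 66)
  hits <- scan_consensus(gen$genome, plan$consensus, max_mismatches = 0)
  planted <- gen$motif_plan$planted_positions
  found <- merge(planted, hits, by.x = "position", by.y = "start")
  expect_equal(nrow(found), plan$n_planted)
  # planted strand is recovered (palindromic windows count as either)
  ok <- found$strand.x == found$strand.y | found$palindromic
  expect_true(all(ok))
})
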