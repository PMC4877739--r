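Package: znetdiff
Title: Dual-Omic Differential Expression via Merged Z-Score Contrasts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for dual-omic (RNA-seq and iTRAQ proteomic)
    differential expression analysis in bacteria grown on contrasting carbon
    sources. Expression is quantified as log2 sums of exact 100-mer read
    alignments per gene (RNA) and of peptide reporter-ion intensities per
    protein (iTRAQ). Per-contrast intra-replicate and cross-state log2
    difference populations are normalized to Z-scores and merged into a single
    net score (Rnet/Pnet) per gene; a signal-to-noise statistic with a
    Monte-Carlo false discovery rate calibrates calls. Includes COG-category
    up/down tabulation, a degenerate IUPAC consensus genome scanner for
    catabolite-responsive elements, fermentation balance metrics (doubling
    time, carbon recovery, oxidation:reduction ratio), and seeded synthetic
    data generators with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
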