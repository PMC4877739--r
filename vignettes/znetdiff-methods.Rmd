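---
title: "Methods: merged Z-score contrasts for dual-omic differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: merged Z-score contrasts for dual-omic differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A bacterium grown on several carbon sources (here the study design is a
cellobiose reference against xylose, α-cellulose, and xylan, two biological
replicates each) is profiled on two levels at once: transcripts by RNA-seq
and proteins by 4-plex iTRAQ mass spectrometry. The analysis question is the
same on both levels — which genes respond to the substrate switch — but the
measurements are sparse, differently scaled, and replicated differently
(two full replicates for RNA; one usable 4-plex run for protein). znetdiff
implements a deliberately simple, population-based differential framework
suited to that situation, together with the quantitation rules, a
signal-to-noise (S/N) statistic with a Monte-Carlo FDR, COG-category
tabulation, a degenerate-consensus genome scanner, fermentation balance
metrics, and seeded synthetic-data generators so the whole pipeline is
testable without any external data.

# Expression values and filters

RNA expression of a gene in a sample is `log2(number of exact read-length
alignments to the gene)`; protein expression per reporter channel is
`log2(sum of member-peptide reporter-ion intensities)`. Two evidence floors
are applied before any analysis:

* an RNA cell needs at least 2 alignment counts (`min_counts = 2`);
* a protein needs at least 2 peptides with expectation `log(e) < -1.5`
  each (`min_peptides = 2`, `peptide_log_e_max = -1.5`), and a protein-level
  expectation below `-10`.

All inequalities are strict, as printed. Filtered cells are missing (`NA`),
never zero, so `log2(0)` cannot arise. The protein-level expectation is not
carried in the peptide table; we take it as the sum of the qualifying
peptides' `log(e)` values, the convention of X!Tandem-style engines. Every
filtering event is recorded in the matrix's `filter_log`.

The exact alignment counter treats a read as aligned to a gene when it
occurs verbatim in the gene sequence (optionally on either strand). A read
matching several genes increments each once; multiple occurrences within
one gene also count once by default, because per-gene presence is the most
conservative resolution of multi-mapping and is exactly checkable against a
substring-search oracle. An `occurrences` mode counts every matching
position instead.

# The Z0–Z3 / Znet framework

For a contrast of condition X against reference Y with replicates A and B,
each gene contributes four raw log2 differences:

* intra-replicate: `Z0 = B_X − A_X`, `Z1 = B_Y − A_Y` (pure noise), and
* cross-state: `Z2 = A_X − A_Y`, `Z3 = B_X − B_Y` (signal plus noise).

Each of the four difference populations is normalized to mean 0 and SD 1
(population-SD convention, dividing by *n*; at these population sizes the
difference from *n−1* is negligible, but one convention has to be fixed for
exact tests). The two normalized cross-state vectors are merged into the
net score `Znet` (called Rnet for RNA, Pnet for protein): the package
averages them and renormalizes. The merging algorithm behind the original
framework is cited but not printed; the average is the minimal rule that
yields a single normalized, approximately Gaussian score, and the merge is
exposed as a pluggable function for users who want a different rule. A
negative Znet always means higher expression on the reference.

Under the null the resulting population is standard Gaussian, which gives
the printed calibration: about 33% of genes beyond |Znet| = 1, 10% beyond
1.65, and 5% beyond 1.96. The default regulation threshold is 1.65 with
ties counted as regulated (`>=`), matching the enumeration convention of
the published table rather than the strict `>` of the running text.

When only one replicate run is usable (the proteomic situation), only the
cross-state difference of the designated replicate exists; `Pnet` is then
the normalized `X − Y` population and no S/N is available, because the
intra-replicate slots are the framework's only noise measurement.

Genes missing any required value are dropped from that contrast, not
imputed, and listed in the result's `dropped` attribute.

A consequence worth knowing: because every difference population is
affinely renormalized, adding a constant to *any single sample* (not just
to all samples) leaves Znet unchanged — per-sample normalization offsets
cannot masquerade as differential expression, but genuine global shifts
are equally invisible.

# Signal-to-noise and the Monte-Carlo FDR

The system S/N is `mean(SD(Z2), SD(Z3)) / mean(SD(Z0), SD(Z1))` over the
raw populations — a single dataset-quality number. The per-gene S/N is the
ratio of the cross-state to intra-replicate 2-vector magnitudes of the
normalized scores, scaled by the system S/N. "Scaled by" is implemented as
multiplication (a `divide` mode implements the other reading): with
multiplication the per-population normalization factors cancel and the
gene S/N equals the raw-scale magnitude ratio, which is the interpretable
quantity.

For a null gene, all four raw differences are i.i.d. normal, so the squared
gene S/N is the ratio of two independent chi-squared(2) variables — an
F(2,2) variable — giving the closed form `P(S/N > c) = 1/(1+c²)` used as
an independent oracle in the tests.

The FDR at a cutoff `c` is estimated by Monte Carlo: each replicate draws
`n` null genes with all four raw differences `Normal(0, intra_noise_sd)`
(the intra-replicate SD estimated from the data — the framework's only
stated noise measurement), pushes them through the *identical* computation,
and the estimate is `min(1, mean null exceedance / observed exceedance)`.
Two deliberate choices:

* **Null normalization uses the observed populations' means and SDs**
  (stored in the fitted model), not a re-fit on the null draws. This makes
  the null S/N distribution exactly match that of a truly-null gene
  embedded in the observed dataset; re-fitting would inflate the null S/N
  by a factor of the system S/N and destroy calibration.
* **π0 is fixed at 1** (conservative plug-in; the estimand is "expected
  null exceedance over observed exceedance", with no attempt to estimate
  the fraction of true nulls). Consequently the estimate upper-bounds the
  realized false-discovery proportion by roughly a factor 1/π0; the
  acceptance suite asserts both the calibration against the π0 = 1
  estimand (via the closed-form null law) and conservativity against the
  ground-truth FDP.

Per-gene FDRs are the estimate at each gene's own S/N, monotonized
(q-value style, running minimum over genes with lower S/N) so the value
never increases with S/N. Infinite S/N (a zero intra-replicate magnitude)
sorts above all finite values and is counted in exceedances, giving a
deterministic total order. The published "S/N > 2.8 corresponds to
FDR ≤ 10%" is a property of the original dataset; it is reproduced here as
defaults (cutoff 2.8 in configs), not asserted, since the correspondence is
data-dependent.

# COG tabulation

Regulated genes (|Znet| past threshold) are counted per COG letter,
condition, omic, and direction. The gene∩protein overlap counts genes past
threshold in the same direction in both omics, excluding COG class S
("function unknown") and genes annotated as hypothetical — the exclusions
apply to the overlap only, mirroring how the dual-omic agreement was
curated in the source analysis. Multi-letter COG assignments reduce to the
first letter with a warning (the tabulation uses single letters; how the
original counted multi-letter genes is unstated). Loci without annotation
or COG letter fall into a reserved class `"-"`.

# Consensus scanning

Catabolite-responsive elements are sought by sliding a degenerate IUPAC
consensus over both strands; a window is a hit when its mismatch count on
either strand is within the budget (`max_mismatches`, default 0). `N`
matches anything and never counts as a mismatch. The consensus string is a
required input rather than a constant: the source analysis cites the
*B. subtilis* consensus without printing it, and its similarity criterion
is unstated, so published site counts are not reproducible and not
asserted. Minus-strand hits are reported at the forward-strand coordinate
of the window's left edge; palindromic double-hits are deduplicated to a
single `+` row with a flag so counts are stable. Association is
strand-aware and upstream-only by default (a hit within 200 bp 5′ of a
gene start is `adjacent`; any overlap with a gene body is `overlapping`),
with `downstream` and window overrides, because "adjacent to or
overlapping" is otherwise undefined.

# Fermentation metrics

Growth rate is the least-squares slope of `ln(biomass)` versus time over a
user-stated exponential window (phase identification is manual, as in the
source); doubling time is `ln 2 / μ`. Carbon recovery is product carbon
over substrate carbon consumed, with no biomass carbon term (published
recoveries below 1 likewise exclude cells). The O/R ratio balances
oxidized against reduced product equivalents using the classical
convention carried in an editable table: CO2 +2, formate +1, H2 −1,
ethanol −2, acetate and lactate 0. A stoichiometrically closed synthetic
fermentation gives carbon recovery and O/R of exactly 1 before noise — the
package's exactness check.

# What the generators emulate (and what they do not)

`simulate_omics` draws log2 baselines `Normal(10, 2)` — wide enough to
mimic the observed dynamic ranges — adds signed planted effects
(`frac_de`, `effect_magnitude`) per non-reference condition, and
i.i.d. `Normal(0, noise_sd)` measurement noise per cell. Protein channels
share the gene-level signal plus an independent gene offset
(`protein_offset_sd`, default 2.7) chosen so the expected between-omic R²
lands near the reported 0.3–0.37; the offset is a tuning knob for the
correlation check, not an inference about biology. Reads are exact
substrings with Poisson counts and uniform starts, and no sequencing
errors, because the counter is an exact matcher by design. Defaults for
the study design (2 replicates × 4 conditions, cellobiose-analog
reference) are fixed in `default_pipeline_config()`.

A green test on this synthetic world establishes that the *computations*
are correct and calibrated under the model's assumptions (Gaussian log2
noise, gene-wise independence, no batch structure, no count overdispersion
beyond Poisson). It does not establish distributional claims about real
RNA-seq/iTRAQ data, and dataset-level published numbers (per-category
counts, site counts, generation times, recoveries) are inputs-dependent
and out of scope.

# Numerical choices and degenerate inputs

* Population SD (divide by `n`) everywhere; normalization of a zero-spread
  population is an error ("degenerate population"), not a NaN.
* Threshold comparisons are `>=`/`<=` for regulation, strict `>` for S/N
  cutoffs and `<` for log(e) filters, following the printed inequalities.
* Genes with any missing required value are dropped per contrast.
* Contrast tables serialize numerics at 10 significant digits, enough to
  round-trip past 6 decimals.
* Seeds are mandatory for every stochastic stage; the pipeline derives
  per-stage seeds from the master seed by small fixed offsets (all well
  below 2³¹).
* Configs are JSON (the environment provides no YAML parser); named
  stoichiometries are serialized as JSON objects to survive round-trips.

# Known limitations

* No moderated-variance or count-model testing (edgeR/DESeq2-style) — that
  would be a different method from the one reproduced here.
* The proteomic mode has no S/N or FDR (no intra-replicate measurement).
* The scanner has no PWM scoring or enrichment statistics.
* π0 is not estimated; FDR estimates are conservative when many genes are
  truly differential.
* Multi-letter COG membership is reduced to the first letter rather than
  fractional or multiple counting.
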