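# Growth and fermentation balance metrics: exponential-phase specific growth
# rate / doubling time, carbon recovery, and the classical oxidation:reduction
# product balance.

#' Default redox table for fermentation end-products
#'
#' O/R values follow the classical fermentation-balance convention (relative
#' to carbohydrate): CO2 +2, formate +1, H2 -1, ethanol -2, acetate and
#' lactate 0; carbon atoms per mole alongside. Editable / replaceable via a
#' TSV with columns `compound`, `carbons`, `or_value`.
#'
#' @return Data frame `compound`, `carbons`, `or_value`.
#' @export
default_redox_table <- function() {
  data.frame(
    compound = c("H2", "CO2", "formate", "acetate", "ethanol", "lactate"),
    carbons  = c(0L,   1L,    1L,        2L,        2L,        3L),
    or_value = c(-1,   2,     1,         0,         -2,        0),
    stringsAsFactors = FALSE
  )
}

#' Read a redox table TSV
#' @param path TSV with columns `compound`, `carbons`, `or_value`.
#' @return Data frame in [default_redox_table()] shape.
#' @export
read_redox_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound", "carbons", "or_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("redox table missing column(s): ",
                         paste(miss, collapse = ", "))
  df[, need]
}

#' Read a fermentation time series CSV
#'
#' Columns: `time`, a biomass proxy (`od` or `protein`), `substrate`, and one
#' column per measured end-product.
#'
#' @param path CSV path.
#' @param substrate_carbons Carbon atoms per substrate molecule.
#' @return A `fermentation_series` data.frame.
#' @export
read_fermentation_csv <- function(path, substrate_carbons = 6L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("fermentation CSV needs a `time` column")
  if (is.unsorted(df$time, strictly = TRUE)) {
    stop("fermentation time must be strictly increasing")
  }
  structure(df, substrate_carbons = substrate_carbons,
            class = c("fermentation_series", "data.frame"))
}

#' Exponential-phase specific growth rate and doubling time
#'
#' Least-squares slope of `ln(biomass)` against time over the stated window
#' (exponential-phase identification is manual, via `window`). Doubling time
#' is `ln(2) / mu` hours per generation; the result is invariant to scaling
#' the biomass proxy.
#'
#' @param series A `fermentation_series` (needs `time` and `od` or `protein`).
#' @param window Two-element time interval (hours); default: whole series.
#' @param biomass_col Column to use as biomass proxy (default `"od"`).
#' @return `list(mu, doubling_time)` (per hour; hours per generation).
#' @export
doubling_time <- function(series, window = range(series$time),
                          biomass_col = "od") {
  if (!biomass_col %in% names(series)) {
    stop("no biomass column `", biomass_col, "` in series")
  }
  sel <- series$time >= window[1] & series$time <= window[2]
  t <- series$time[sel]
  x <- series[[biomass_col]][sel]
  if (length(t) < 3L) stop("need at least 3 points in the window")
  if (any(x <= 0)) stop("non-positive biomass in window")
  mu <- unname(stats::coef(stats::lm(log(x) ~ t))[2])
  if (mu <= 0) stop("no exponential growth in window (mu <= 0)")
  list(mu = mu, doubling_time = log(2) / mu)
}

match_redox <- function(products, table) {
  miss <- setdiff(names(products), table$compound)
  if (length(miss)) stop("product(s) absent from redox table: ",
                         paste(miss, collapse = ", "))
  table[match(names(products), table$compound), ]
}

#' Carbon recovery of a fermentation
#'
#' Carbon in measured end-products divided by carbon in substrate consumed;
#' H2 contributes no carbon, cell carbon is excluded. Values near 1 indicate
#' the major products were accounted for.
#'
#' @param substrate_consumed_mM Substrate consumed (mM, > 0).
#' @param substrate_carbons Carbon atoms per substrate molecule.
#' @param products Named numeric vector of end-product deltas (mM).
#' @param table Redox table (default [default_redox_table()]).
#' @return Carbon recovery as a fraction.
#' @export
carbon_recovery <- function(substrate_consumed_mM, substrate_carbons,
                            products, table = default_redox_table()) {
  if (substrate_consumed_mM <= 0) stop("zero substrate consumption")
  if (!length(products)) return(0)
  tab <- match_redox(products, table)
  sum(products * tab$carbons) / (substrate_consumed_mM * substrate_carbons)
}

#' Oxidation:reduction ratio of fermentation end-products
#'
#' Sum of oxidized-product equivalents (mM x O/R value over products with
#' positive O/R) divided by the absolute sum over reduced products (negative
#' O/R). A balanced, fully accounted fermentation gives 1.
#'
#' @param products Named numeric vector of end-product deltas (mM).
#' @param table Redox table (default [default_redox_table()]).
#' @return O/R ratio.
#' @export
or_ratio <- function(products, table = default_redox_table()) {
  tab <- match_redox(products, table)
  eq <- products * tab$or_value
  red <- abs(sum(eq[tab$or_value < 0]))
  if (red == 0) stop("O/R undefined: no reduced products")
  sum(eq[tab$or_value > 0]) / red
}

#' Growth and balance metrics for a whole series
#'
#' Convenience wrapper: substrate consumed and product deltas are taken
#' between the first and last timepoints; growth over the given window.
#'
#' @param series A `fermentation_series`.
#' @param window Exponential-phase window for [doubling_time()].
#' @param table Redox table.
#' @return `list(mu, doubling_time, carbon_recovery, or_ratio)`.
#' @export
fermentation_balance <- function(series, window = range(series$time),
                                 table = default_redox_table()) {
  prods <- intersect(names(series), table$compound)
  n <- nrow(series)
  deltas <- vapply(prods, function(p) series[[p]][n] - series[[p]][1], 0)
  consumed <- series$substrate[1] - series$substrate[n]
  growth <- doubling_time(series, window)
  list(mu = growth$mu, doubling_time = growth$doubling_time,
       carbon_recovery = carbon_recovery(
         consumed, attr(series, "substrate_carbons"), deltas, table),
       or_ratio = or_ratio(deltas, table))
}
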