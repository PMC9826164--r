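#' Unit-conversion constants for offset crediting
#'
#' Credits and registry stocks are issued in tons of CO2; remote-sensing
#' products track aboveground biomass. Three constants connect them: the
#' molar mass ratio C/CO2 (12.01/44.01), the mean aboveground-live (AGL)
#' share of total reported carbon stocks (0.806, overridable), and the
#' carbon content of dry biomass (0.47 ton C per ton biomass).
#'
#' @param agl_fraction AGL carbon / total carbon.
#' @param carbon_per_biomass ton C per ton dry biomass.
#' @return a named list of class `conversion_constants`.
#' @export
conversion_constants <- function(agl_fraction = 0.806,
                                 carbon_per_biomass = 0.47) {
  cc <- list(c_per_co2 = 12.01 / 44.01,
             agl_fraction = agl_fraction,
             carbon_per_biomass = carbon_per_biomass)
  for (k in names(cc))
    if (cc[[k]] <= 0 || cc[[k]] >= 1)
      stop(sprintf("conversion constant `%s` must be in (0, 1)", k))
  structure(cc, class = "conversion_constants")
}

check_nonneg <- function(x, what) {
  if (any(x < 0, na.rm = TRUE)) stop(sprintf("negative %s not allowed", what))
  x
}

#' Unit conversions
#'
#' Linear scalings between tons CO2, total carbon, AGL carbon, and biomass.
#' All reject negative input.
#'
#' @param x quantity to convert (vectorized).
#' @param constants a [conversion_constants()] object.
#' @return converted quantity.
#' @export
co2_to_c <- function(x, constants = conversion_constants()) {
  check_nonneg(x, "ton CO2") * constants$c_per_co2
}

#' @rdname co2_to_c
#' @export
c_to_co2 <- function(x, constants = conversion_constants()) {
  check_nonneg(x, "ton C") / constants$c_per_co2
}

#' @rdname co2_to_c
#' @export
total_to_agl <- function(x, constants = conversion_constants()) {
  check_nonneg(x, "ton C (total)") * constants$agl_fraction
}

#' @rdname co2_to_c
#' @export
agl_to_total <- function(x, constants = conversion_constants()) {
  check_nonneg(x, "ton C (AGL)") / constants$agl_fraction
}

#' @rdname co2_to_c
#' @export
biomass_to_c <- function(x, constants = conversion_constants()) {
  check_nonneg(x, "ton biomass") * constants$carbon_per_biomass
}

#' Project record
#'
#' One offset project's polygon plus its crediting document: start year,
#' baseline stock, reported stocks by year (AGL or total carbon, per
#' `reported_is_total`), and credits issued by year.
#'
#' @param id project identifier.
#' @param polygon a `polygon_shape` (may be `NULL` for purely tabular use).
#' @param start_year project initiation year.
#' @param area project area, ha.
#' @param owner_class `"large-timber"` or `"other"`.
#' @param baseline_stock baseline carbon stock, ton C/ha (AGL convention).
#' @param reported_stocks named numeric, year -> ton C/ha.
#' @param reported_is_total `TRUE` when `reported_stocks` are total carbon
#'   (converted to AGL by the 0.806 convention where needed).
#' @param credits_issued named numeric, year -> credits (tCO2e).
#' @param region_label `"coastal"` or `"interior"`.
#' @export
project_record <- function(id, polygon = NULL, start_year, area,
                           owner_class = "other", baseline_stock = NA_real_,
                           reported_stocks = numeric(0),
                           reported_is_total = FALSE,
                           credits_issued = numeric(0),
                           region_label = "coastal") {
  if (area <= 0) stop("project `area` must be positive")
  structure(list(id = id, polygon = polygon,
                 start_year = as.integer(start_year), area = area,
                 owner_class = owner_class, baseline_stock = baseline_stock,
                 reported_stocks = reported_stocks,
                 reported_is_total = reported_is_total,
                 credits_issued = credits_issued,
                 region_label = region_label),
            class = "project_record")
}

#' @export
print.project_record <- function(x, ...) {
  cat(sprintf("<project_record> %s: start %d, %.1f ha, %s, %s region\n",
              x$id, x$start_year, x$area, x$owner_class, x$region_label))
  invisible(x)
}

#' Summarize a project's crediting schedule
#'
#' Splits issued credits into the initial issuance (mostly above-baseline
#' stocking) and the mean annual incremental issuance thereafter, and derives
#' the initial-to-annual ratio, which equals the break-even time in years for
#' cumulative incremental credits to match the initial payout.
#'
#' @param record a `project_record` with nonempty `credits_issued`, or a
#'   named numeric of issuances.
#' @return a list of class `credit_summary` with `initial_credits`,
#'   `mean_annual_incremental_credits`, `initial_to_annual_ratio`,
#'   `break_even_years`, and a `degenerate` flag when the incremental stream
#'   is undefined (single issuance) or non-positive.
#' @export
credit_summary <- function(record) {
  issuances <- if (inherits(record, "project_record")) record$credits_issued
               else record
  if (length(issuances) == 0L) stop("credits_issued is empty")
  yrs <- as.integer(names(issuances))
  ord <- order(yrs)
  yrs <- yrs[ord]; issuances <- as.numeric(issuances[ord])
  initial <- issuances[1L]
  if (length(issuances) == 1L) {
    return(structure(list(initial_credits = initial,
                          mean_annual_incremental_credits = NA_real_,
                          initial_to_annual_ratio = NA_real_,
                          break_even_years = NA_real_,
                          degenerate = TRUE),
                     class = "credit_summary"))
  }
  # later issuances spread over the years they cover
  annual <- sum(issuances[-1L]) / (yrs[length(yrs)] - yrs[1L])
  ratio <- if (annual > 0) initial / annual else NA_real_
  structure(list(initial_credits = initial,
                 mean_annual_incremental_credits = annual,
                 initial_to_annual_ratio = if (annual > 0) ratio else
                   if (initial == 0) 0 else NA_real_,
                 break_even_years = ratio,
                 degenerate = annual <= 0),
            class = "credit_summary")
}

#' @export
print.credit_summary <- function(x, ...) {
  cat(sprintf(paste0("<credit_summary> initial %.0f, incremental %.1f/yr,",
                     " ratio %.1f, break-even %.1f yr%s\n"),
              x$initial_credits, x$mean_annual_incremental_credits,
              x$initial_to_annual_ratio, x$break_even_years,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Project-reported carbon accumulation rate
#'
#' OLS slope of the reported AGL stock against year. Total-carbon stocks are
#' converted to AGL by the `agl_fraction` convention first.
#'
#' @param record a `project_record` with at least two reported stocks.
#' @param constants a [conversion_constants()] object.
#' @return rate in ton C/ha/yr (AGL).
#' @export
reported_rate <- function(record, constants = conversion_constants()) {
  stocks <- record$reported_stocks
  if (length(stocks) < 2L)
    stop("at least two reported stocks are required for a rate")
  yrs <- as.integer(names(stocks))
  vals <- as.numeric(stocks)
  if (record$reported_is_total) vals <- total_to_agl(vals, constants)
  unname(stats::cov(yrs, vals) / stats::var(yrs))
}

#' Portfolio-average reported rate
#'
#' Area-weighted mean of per-project rates; the standard error is the
#' unweighted SE of per-project rates across the sample (weights affect the
#' mean only).
#'
#' @param records list of `project_record`.
#' @param weights project weights; defaults to project areas.
#' @param constants a [conversion_constants()] object.
#' @return list with `rate`, `se`, `n`, and per-project `rates`.
#' @export
portfolio_rate <- function(records, weights = NULL,
                           constants = conversion_constants()) {
  if (length(records) < 2L) stop("a portfolio rate needs >= 2 projects")
  rates <- vapply(records, reported_rate, numeric(1), constants = constants)
  if (is.null(weights))
    weights <- vapply(records, `[[`, numeric(1), "area")
  list(rate = sum(rates * weights) / sum(weights),
       se = stats::sd(rates) / sqrt(length(rates)),
       n = length(rates), rates = rates)
}
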