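# Closed-form simple regression; returns slope, intercept, rss, n, sxx.
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, rss = rss, n = n, sxx = sxx)
}

#' Linear trend of an annual time series
#'
#' OLS of value on year, plus the period mean, its standard error across
#' years, and the trend expressed as percent of the period-mean stock per
#' year (optionally of the fitted initial-year stock instead).
#'
#' @param ts a time-series data frame (`year`, `value`); `NA` years are
#'   dropped.
#' @param period optional `c(first, last)` year window.
#' @param percent_denominator `"period_mean"` (default) or `"initial"`
#'   (fitted value in the first year of the period).
#' @return a list of class `trend_result`: `slope` (units/yr), `slope_se`,
#'   `slope_p` (two-sided, slope = 0), `intercept`, `percent_rate` (%/yr),
#'   `mean_value`, `mean_se`, `period`, `n_years`.
#' @export
trend <- function(ts, period = NULL,
                  percent_denominator = c("period_mean", "initial")) {
  percent_denominator <- match.arg(percent_denominator)
  keep <- !is.na(ts$value)
  if (!is.null(period))
    keep <- keep & ts$year >= period[1L] & ts$year <= period[2L]
  x <- ts$year[keep]; y <- ts$value[keep]
  if (length(x) < 3L) stop("a trend needs at least 3 years of data")
  fit <- ols_line(x, y)
  df <- fit$n - 2L
  slope_se <- sqrt(fit$rss / df / fit$sxx)
  tstat <- if (slope_se > 0) fit$slope / slope_se else
    if (fit$slope == 0) 0 else Inf * sign(fit$slope)
  denom <- switch(percent_denominator,
                  period_mean = mean(y),
                  initial = fit$intercept + fit$slope * min(x))
  structure(list(
    slope = fit$slope, slope_se = slope_se,
    slope_p = 2 * stats::pt(-abs(tstat), df),
    intercept = fit$intercept,
    percent_rate = if (denom != 0) 100 * fit$slope / denom else NA_real_,
    mean_value = mean(y), mean_se = stats::sd(y) / sqrt(fit$n),
    period = range(x), n_years = fit$n), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(paste0("<trend> %.3f +/- %.3f units/yr (%.2f %%/yr), mean ",
                     "%.1f +/- %.1f, %d years %d-%d\n"),
              x$slope, x$slope_se, x$percent_rate, x$mean_value, x$mean_se,
              x$n_years, x$period[1L], x$period[2L]))
  invisible(x)
}

#' Paired t-test across years
#'
#' Classic paired t on per-year differences over the years common to both
#' series, with the relative difference expressed as percent of the control
#' (second) series mean. Zero-variance differences are reported as
#' degenerate rather than given a p-value of zero.
#'
#' @param ts_a,ts_b time-series data frames (`year`, `value`); `ts_b` is the
#'   reference (control) series.
#' @return a list of class `paired_result`: `mean_difference`,
#'   `relative_difference` (% of control mean), `t`, `p`, `n_pairs`,
#'   `degenerate`.
#' @export
paired_across_years <- function(ts_a, ts_b) {
  m <- merge(ts_a[!is.na(ts_a$value), c("year", "value")],
             ts_b[!is.na(ts_b$value), c("year", "value")], by = "year")
  if (nrow(m) < 2L) stop("no (or too few) overlapping years")
  d <- m$value.x - m$value.y
  n <- length(d)
  sd_d <- stats::sd(d)
  mean_b <- mean(m$value.y)
  degenerate <- sd_d == 0
  if (degenerate) {
    t <- if (all(d == 0)) 0 else Inf * sign(mean(d))
    p <- if (all(d == 0)) 1 else NA_real_
  } else {
    t <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1L)
  }
  structure(list(mean_difference = mean(d),
                 relative_difference =
                   if (mean_b != 0) 100 * mean(d) / mean_b else NA_real_,
                 t = t, p = p, n_pairs = n, degenerate = degenerate),
            class = "paired_result")
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("<paired t> diff %.4g (%.1f%% of control), t = %.2f, p = %.3g, n = %d%s\n",
              x$mean_difference, x$relative_difference, x$t, x$p, x$n_pairs,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Chow structural-break test on a carbon trend
#'
#' Tests whether the linear trend differs before and after a breakpoint:
#' F = [(RSS_pooled - RSS1 - RSS2)/k] / [(RSS1 + RSS2)/(n1 + n2 - 2k)] with
#' k = 2 (intercept and slope), against F(k, n1 + n2 - 2k). Years <=
#' `breakpoint_year` form the first segment.
#'
#' @param ts time-series data frame (`year`, `value`).
#' @param breakpoint_year last year of the first segment.
#' @return a list of class `chow_result`: `F`, `p`, `df`, `slope_before`,
#'   `slope_after`, `slope_change`, `breakpoint_year`, `n`.
#' @export
chow <- function(ts, breakpoint_year) {
  ok <- !is.na(ts$value)
  x <- ts$year[ok]; y <- ts$value[ok]
  i1 <- x <= breakpoint_year
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 < 3L || n2 < 3L)
    stop("chow test needs at least 3 years on each side of the breakpoint")
  f1 <- ols_line(x[i1], y[i1])
  f2 <- ols_line(x[!i1], y[!i1])
  fp <- ols_line(x, y)
  k <- 2L
  df2 <- n1 + n2 - 2L * k
  rss_seg <- f1$rss + f2$rss
  if (rss_seg <= 0) {
    Fstat <- Inf
    p <- if (fp$rss - rss_seg > 0) 0 else 1
    if (fp$rss - rss_seg <= 0) Fstat <- 0  # three exactly collinear fits
  } else {
    Fstat <- ((fp$rss - rss_seg) / k) / (rss_seg / df2)
    Fstat <- max(Fstat, 0)
    p <- stats::pf(Fstat, k, df2, lower.tail = FALSE)
  }
  structure(list(F = Fstat, p = p, df = c(k, df2),
                 slope_before = f1$slope, slope_after = f2$slope,
                 slope_change = f2$slope - f1$slope,
                 breakpoint_year = breakpoint_year, n = n1 + n2),
            class = "chow_result")
}

#' @export
print.chow_result <- function(x, ...) {
  cat(sprintf(paste0("<chow> F(%d, %d) = %.3g, p = %.3g; slope %.3g -> %.3g",
                     " at %d\n"),
              x$df[1L], x$df[2L], x$F, x$p, x$slope_before, x$slope_after,
              x$breakpoint_year))
  invisible(x)
}

#' Equal-window before/after comparison for one project
#'
#' Builds equal time windows around a project's start year: the window
#' length is the number of post-start years available from each data source
#' (capped by that source's data end and by the pre-start record), the
#' before-window is the same number of years ending at the start year.
#' Carbon is compared by a Chow test at the start year restricted to the two
#' windows; harvest by a paired t-test pairing years by their offset from
#' the start (`start + i` vs `start - w + i`).
#'
#' @param start_year project initiation year.
#' @param carbon_ts,harvest_ts time-series data frames (either may be
#'   `NULL`).
#' @param carbon_end,harvest_end last usable year per source (defaults to
#'   the series' last year).
#' @param min_carbon_points,min_harvest_points minimum post-start years per
#'   source; a source with fewer is excluded with a reason.
#' @return a list of class `before_after_result`: per source the window
#'   length, the test result (or `NULL` with an exclusion reason), and for
#'   carbon the slope change.
#' @export
before_after <- function(start_year, carbon_ts = NULL, harvest_ts = NULL,
                         carbon_end = NULL, harvest_end = NULL,
                         min_carbon_points = 3L, min_harvest_points = 7L) {
  out <- list(start_year = start_year, carbon = NULL, harvest = NULL,
              carbon_window = NA_integer_, harvest_window = NA_integer_,
              reasons = character(0))
  window_for <- function(ts, data_end) {
    last <- min(max(ts$year), data_end %||% max(ts$year))
    post <- last - start_year
    pre <- start_year - min(ts$year) + 1L
    as.integer(min(post, pre))
  }
  if (!is.null(carbon_ts)) {
    w <- window_for(carbon_ts, carbon_end)
    out$carbon_window <- w
    if (w < min_carbon_points) {
      out$reasons <- c(out$reasons, sprintf(
        "carbon: only %d post-start year(s), need %d", w, min_carbon_points))
    } else {
      win <- carbon_ts[carbon_ts$year > start_year - w &
                         carbon_ts$year <= start_year + w, ]
      out$carbon <- chow(win, breakpoint_year = start_year)
    }
  }
  if (!is.null(harvest_ts)) {
    w <- window_for(harvest_ts, harvest_end)
    out$harvest_window <- w
    if (w < min_harvest_points) {
      out$reasons <- c(out$reasons, sprintf(
        "harvest: only %d post-start year(s), need %d", w,
        min_harvest_points))
    } else {
      before <- harvest_ts$value[match((start_year - w + 1L):start_year,
                                       harvest_ts$year)]
      after <- harvest_ts$value[match((start_year + 1L):(start_year + w),
                                      harvest_ts$year)]
      offs <- seq_len(w)
      out$harvest <- paired_across_years(
        data.frame(year = offs, value = after),
        data.frame(year = offs, value = before))
    }
  }
  class(out) <- "before_after_result"
  out
}

#' Species-composition contrast between projects and controls
#'
#' The fraction of a species is its share of total AGL carbon within a mask
#' (carbon-weighted, in percent). Per project, the fraction inside the
#' project mask is paired with the fraction in its control mask; the pooled
#' fractions are area-weighted means and a paired t-test runs across
#' projects.
#'
#' @param species_fractions named list of per-species fraction matrices.
#' @param total_layer matrix of total carbon density for the species year.
#' @param project_masks,control_masks lists of `region_mask`s, in project
#'   order.
#' @param species species name to contrast.
#' @param areas optional project areas for pooled weighting.
#' @return list of class `species_comparison`: pooled `project_fraction` and
#'   `control_fraction` (%), per-project table, paired `t`, `p`, `n`.
#' @export
species_contrast <- function(species_fractions, total_layer, project_masks,
                             control_masks, species, areas = NULL) {
  if (!species %in% names(species_fractions))
    stop(sprintf("species '%s' not present in the layer set", species))
  frac <- species_fractions[[species]]
  mask_fraction <- function(mask) {
    sel <- mask$mask & !is.na(total_layer) & !is.na(frac)
    tot <- sum(total_layer[sel])
    if (tot <= 0) return(NA_real_)
    100 * sum(frac[sel] * total_layer[sel]) / tot
  }
  pf <- vapply(project_masks, mask_fraction, numeric(1))
  cf <- vapply(control_masks, mask_fraction, numeric(1))
  drop <- is.na(pf) | is.na(cf)
  if (any(drop))
    warning(sprintf("%d project(s) dropped (zero total carbon in a mask)",
                    sum(drop)))
  pf <- pf[!drop]; cf <- cf[!drop]
  if (is.null(areas)) areas <- rep(1, length(pf)) else areas <- areas[!drop]
  if (length(pf) == 0L) stop("no projects with valid species fractions")
  tt <- if (length(pf) >= 2L)
    paired_across_years(data.frame(year = seq_along(pf), value = pf),
                        data.frame(year = seq_along(cf), value = cf))
  else list(t = NA_real_, p = NA_real_)
  structure(list(species = species,
                 project_fraction = sum(pf * areas) / sum(areas),
                 control_fraction = sum(cf * areas) / sum(areas),
                 per_project = data.frame(project_fraction = pf,
                                          control_fraction = cf),
                 t = tt$t, p = tt$p, n = length(pf)),
            class = "species_comparison")
}

#' Area-weighted portfolio aggregation of project time series
#'
#' Per-year area-weighted mean across projects over their common years,
#' plus cross-project summary statistics (unweighted SE of per-project
#' means across the sample).
#'
#' @param series_list list of time-series data frames.
#' @param weights project weights (areas).
#' @return list with `series` (a time-series data frame) and `summary`
#'   (`per_project_means`, `mean`, `se`, `n_projects`).
#' @export
portfolio_aggregate <- function(series_list, weights = NULL) {
  if (length(series_list) == 0L) stop("empty project list")
  if (is.null(weights)) weights <- rep(1, length(series_list))
  yrs <- Reduce(intersect, lapply(series_list, function(s)
    s$year[!is.na(s$value)]))
  if (length(yrs) == 0L) stop("projects share no years of data")
  all_years <- sort(unique(unlist(lapply(series_list, `[[`, "year"))))
  if (length(yrs) < length(all_years))
    warning("disjoint year coverage; restricted to common years")
  yrs <- sort(yrs)
  vals <- vapply(yrs, function(y) {
    v <- vapply(series_list, function(s) s$value[match(y, s$year)],
                numeric(1))
    sum(v * weights) / sum(weights)
  }, numeric(1))
  per_project <- vapply(series_list, function(s)
    mean(s$value[s$year %in% yrs]), numeric(1))
  list(series = new_time_series(yrs, vals, NA_integer_,
                                variable = "portfolio_mean",
                                units = attr(series_list[[1L]], "units") %||%
                                  "", label = "portfolio"),
       summary = list(per_project_means = per_project,
                      mean = sum(per_project * weights) / sum(weights),
                      se = if (length(per_project) > 1L)
                        stats::sd(per_project) / sqrt(length(per_project))
                      else NA_real_,
                      n_projects = length(series_list)))
}
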