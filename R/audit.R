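#' Audit configuration
#'
#' Periods, cohort filters and test parameters for the five-hypothesis
#' additionality audit.
#'
#' @param pre_period pre-program window `c(first, last)` for the historical
#'   contrasts (H1-H3).
#' @param carbon_data_end,harvest_data_end last usable year per data source.
#' @param control_methods which control systems to run.
#' @param start_year_cutoff latest project start admitted to the
#'   before/after cohort (H4-H5).
#' @param alpha significance level.
#' @param buffer_width buffer-control width, m.
#' @param match_resolution covariate-matching resolution, m.
#' @param low_value_species species used for the H3 contrast; defaults to
#'   the scene's configured low-value species.
#' @param include_projects_in_region include project pixels in regional
#'   pools (region-wide curves) instead of excluding them.
#' @param min_carbon_points,min_harvest_points minimum post-start years per
#'   source for the before/after cohort.
#' @param percent_denominator passed to [trend()].
#' @export
audit_config <- function(pre_period = c(1986L, 2012L),
                         carbon_data_end = 2017L,
                         harvest_data_end = 2021L,
                         control_methods = c("buffer", "region", "matched"),
                         start_year_cutoff = 2014L,
                         alpha = 0.05,
                         buffer_width = 2000,
                         match_resolution = 800,
                         low_value_species = NULL,
                         include_projects_in_region = FALSE,
                         min_carbon_points = 3L,
                         min_harvest_points = 7L,
                         percent_denominator = "period_mean") {
  bad <- setdiff(control_methods, c("buffer", "region", "matched"))
  if (length(bad))
    stop(sprintf("unknown control method '%s'", bad[1L]))
  structure(as.list(environment()), class = "audit_config")
}

verdict_from <- function(additional, nonadditional, p, alpha) {
  if (!is.na(p) && p < alpha && isTRUE(additional))
    "consistent-with-additionality"
  else if (!is.na(p) && p < alpha && isTRUE(nonadditional)) "inconsistent"
  else "inconclusive"
}

expand_mask <- function(mask, native_dim) {
  f <- mask$factor
  out <- matrix(FALSE, native_dim[1L], native_dim[2L])
  idx <- which(mask$mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    rows <- ((idx[k, 1L] - 1L) * f + 1L):(idx[k, 1L] * f)
    cols <- ((idx[k, 2L] - 1L) * f + 1L):(idx[k, 2L] * f)
    out[rows, cols] <- TRUE
  }
  region_mask(out, mask$label)
}

# Offset-aligned, area-weighted pooled series for the before/after cohort:
# years are re-indexed as offsets from each project's start so that equal
# windows line up, then averaged across projects.
pooled_offset_series <- function(series_list, starts, weights, w) {
  offs <- (-w + 1L):w
  vals <- vapply(offs, function(o) {
    v <- mapply(function(s, st) s$value[match(st + o, s$year)],
                series_list, starts)
    sum(v * weights) / sum(weights)
  }, numeric(1))
  data.frame(year = offs, value = vals)
}

#' Run the five-hypothesis additionality audit
#'
#' Orchestrates the full audit of a scene: builds the requested control
#' systems, extracts zonal carbon and harvest series for projects and
#' controls, and evaluates, per control method, H1 (pre-project carbon
#' trend), H2 (pre-project harvest contrast), H3 (low-timber-value species
#' contrast), H4 (before/after change in carbon slope, Chow test) and H5
#' (before/after change in harvest, paired t), each mapped to a three-way
#' verdict: `consistent-with-additionality` when the effect lies in the
#' additional direction with p below alpha, `inconsistent` when it lies
#' significantly in the non-additional direction, `inconclusive` otherwise.
#'
#' @param scene a `synthetic_scene` (or an equivalently shaped list built
#'   from real data layers).
#' @param config an [audit_config()].
#' @return an object of class `ifm_audit`.
#' @export
run_audit <- function(scene, config = audit_config()) {
  projects <- scene$projects
  if (length(projects) == 0L) stop("empty project list")
  template <- scene$observed_carbon
  carbon_years <- template$years[template$years <= config$carbon_data_end]
  harvest_years <- scene$harvest$years[
    scene$harvest$years <= config$harvest_data_end]
  carbon <- stack_subset(scene$observed_carbon, carbon_years)
  harvest <- stack_subset(scene$harvest, harvest_years)
  n_proj <- length(projects)
  areas <- vapply(projects, `[[`, numeric(1), "area")
  starts <- vapply(projects, `[[`, integer(1), "start_year")
  if (min(starts) < config$pre_period[2L])
    warning("pre_period extends past the earliest project start year")
  masks <- scene$project_masks %||%
    lapply(projects, function(p)
      rasterize_polygons(p$polygon, template)$mask)
  pmasks <- lapply(seq_len(n_proj), function(i)
    region_mask(masks[[i]], projects[[i]]$id))

  proj_carbon <- lapply(pmasks, function(m) zonal_series(carbon, m))
  proj_harv <- lapply(pmasks, function(m) zonal_fraction(harvest, m))

  low_sp <- config$low_value_species %||% scene$config$low_value_species
  sp_year <- attr(scene$species_fractions, "year") %||% min(carbon_years)
  sp_total <- stack_layer(carbon,
                          if (sp_year %in% carbon$years) sp_year
                          else max(carbon$years))

  results <- list()
  per_project <- list()
  control_sets <- list()
  for (method in config$control_methods) {
    spec <- control_spec(method, buffer_width = config$buffer_width,
                         match_resolution = config$match_resolution,
                         include_projects = config$include_projects_in_region)
    csets <- vector("list", n_proj)
    region_cache <- list()
    for (i in seq_len(n_proj)) {
      reg <- projects[[i]]$region_label
      csets[[i]] <- switch(
        method,
        buffer = buffer_control(projects[[i]], scene$land_class, projects,
                                template, spec),
        region = {
          if (is.null(region_cache[[reg]]))
            region_cache[[reg]] <- region_control(reg, scene$region_map,
                                                  scene$land_class, projects,
                                                  template, spec)
          region_cache[[reg]]
        },
        matched = matched_control(projects[[i]], scene$covariates,
                                  scene$region_map, scene$land_class,
                                  projects, template, spec))
    }
    control_sets[[method]] <- csets
    ctrl_series <- function(cs) {
      if (cs$mask$factor > 1L) {
        f <- cs$mask$factor
        list(carbon = zonal_series(block_aggregate(carbon, f), cs$mask),
             harvest = zonal_series(block_aggregate(harvest, f), cs$mask))
      } else {
        list(carbon = zonal_series(carbon, cs$mask),
             harvest = zonal_fraction(harvest, cs$mask))
      }
    }
    ctrl <- lapply(csets, ctrl_series)

    # pooled project and control series (area-weighted)
    pool_c <- portfolio_aggregate(proj_carbon, areas)$series
    pool_h <- portfolio_aggregate(proj_harv, areas)$series
    pool_cc <- portfolio_aggregate(lapply(ctrl, `[[`, "carbon"),
                                   areas)$series
    pool_ch <- portfolio_aggregate(lapply(ctrl, `[[`, "harvest"),
                                   areas)$series

    # --- H1: pre-project carbon trend (vs zero, controls reported) ---
    tr_p <- trend(pool_c, config$pre_period,
                  percent_denominator = config$percent_denominator)
    tr_c <- trend(pool_cc, config$pre_period,
                  percent_denominator = config$percent_denominator)
    H1 <- list(project_percent_rate = tr_p$percent_rate,
               control_percent_rate = tr_c$percent_rate,
               slope = tr_p$slope, p = tr_p$slope_p, detail = tr_p,
               verdict = verdict_from(tr_p$slope <= 0, tr_p$slope > 0,
                                      tr_p$slope_p, config$alpha))

    # --- H2: pre-project harvest, project vs control ---
    pre <- function(ts) ts[ts$year >= config$pre_period[1L] &
                             ts$year <= config$pre_period[2L], ]
    H2t <- paired_across_years(pre(pool_h), pre(pool_ch))
    H2 <- list(mean_difference = H2t$mean_difference,
               relative_difference = H2t$relative_difference,
               t = H2t$t, p = H2t$p, detail = H2t,
               verdict = verdict_from(H2t$mean_difference < 0,
                                      H2t$mean_difference > 0,
                                      H2t$p, config$alpha))

    # --- H3: low-timber-value species contrast ---
    ctrl_sp_masks <- lapply(csets, function(cs)
      if (cs$mask$factor > 1L) expand_mask(cs$mask, dim(template)[1:2])
      else cs$mask)
    H3s <- species_contrast(scene$species_fractions, sp_total, pmasks,
                            ctrl_sp_masks, low_sp, areas)
    H3 <- list(species = low_sp,
               project_fraction = H3s$project_fraction,
               control_fraction = H3s$control_fraction,
               t = H3s$t, p = H3s$p, detail = H3s,
               verdict = verdict_from(
                 H3s$project_fraction < H3s$control_fraction,
                 H3s$project_fraction > H3s$control_fraction,
                 H3s$p, config$alpha))

    # --- before/after cohort ---
    eligible <- which(starts <= config$start_year_cutoff)
    ba_proj <- ba_ctrl <- vector("list", n_proj)
    excluded <- character(0)
    for (i in eligible) {
      ba_proj[[i]] <- before_after(starts[i], proj_carbon[[i]],
                                   proj_harv[[i]],
                                   carbon_end = config$carbon_data_end,
                                   harvest_end = config$harvest_data_end,
                                   min_carbon_points = config$min_carbon_points,
                                   min_harvest_points = config$min_harvest_points)
      ba_ctrl[[i]] <- before_after(starts[i], ctrl[[i]]$carbon,
                                   ctrl[[i]]$harvest,
                                   carbon_end = config$carbon_data_end,
                                   harvest_end = config$harvest_data_end,
                                   min_carbon_points = config$min_carbon_points,
                                   min_harvest_points = config$min_harvest_points)
      if (length(ba_proj[[i]]$reasons))
        excluded <- c(excluded, sprintf("%s: %s", projects[[i]]$id,
                                        paste(ba_proj[[i]]$reasons,
                                              collapse = "; ")))
    }
    ok_c <- eligible[vapply(eligible, function(i)
      !is.null(ba_proj[[i]]$carbon), logical(1))]
    ok_h <- eligible[vapply(eligible, function(i)
      !is.null(ba_proj[[i]]$harvest), logical(1))]

    # --- H4: before/after carbon slope change (chow), vs controls ---
    if (length(ok_c)) {
      wc <- min(vapply(ok_c, function(i) ba_proj[[i]]$carbon_window,
                       integer(1)))
      pc <- pooled_offset_series(proj_carbon[ok_c], starts[ok_c],
                                 areas[ok_c], wc)
      cc <- pooled_offset_series(lapply(ctrl[ok_c], `[[`, "carbon"),
                                 starts[ok_c], areas[ok_c], wc)
      ch_p <- chow(pc, breakpoint_year = 0)
      ch_c <- chow(cc, breakpoint_year = 0)
      H4 <- list(slope_change = ch_p$slope_change,
                 control_slope_change = ch_c$slope_change,
                 F = ch_p$F, p = ch_p$p, window = wc,
                 n_projects = length(ok_c), detail = ch_p,
                 control_detail = ch_c,
                 verdict = verdict_from(
                   ch_p$slope_change > 0 &&
                     ch_p$slope_change > ch_c$slope_change,
                   ch_p$slope_change < 0, ch_p$p, config$alpha))
    } else {
      H4 <- list(verdict = "inconclusive",
                 reason = "no projects with sufficient post-start carbon data")
    }

    # --- H5: before/after harvest change (paired), vs controls ---
    if (length(ok_h)) {
      wh <- min(vapply(ok_h, function(i) ba_proj[[i]]$harvest_window,
                       integer(1)))
      ph <- pooled_offset_series(proj_harv[ok_h], starts[ok_h],
                                 areas[ok_h], wh)
      chh <- pooled_offset_series(lapply(ctrl[ok_h], `[[`, "harvest"),
                                  starts[ok_h], areas[ok_h], wh)
      offs <- seq_len(wh)
      pair_of <- function(s) paired_across_years(
        data.frame(year = offs, value = s$value[match(offs, s$year)]),
        data.frame(year = offs, value = s$value[match(offs - wh, s$year)]))
      t_p <- pair_of(ph)
      t_c <- pair_of(chh)
      H5 <- list(mean_change = t_p$mean_difference,
                 control_mean_change = t_c$mean_difference,
                 t = t_p$t, p = t_p$p, window = wh,
                 n_projects = length(ok_h), detail = t_p,
                 control_detail = t_c,
                 verdict = verdict_from(
                   t_p$mean_difference < 0 &&
                     t_p$mean_difference < t_c$mean_difference,
                   t_p$mean_difference > 0, t_p$p, config$alpha))
    } else {
      H5 <- list(verdict = "inconclusive",
                 reason = "no projects with sufficient post-start harvest data")
    }

    results[[method]] <- list(H1 = H1, H2 = H2, H3 = H3, H4 = H4, H5 = H5,
                              excluded = excluded)

    # --- per-project rows ---
    rows <- lapply(seq_len(n_proj), function(i) {
      trp <- trend(proj_carbon[[i]], config$pre_period,
                   percent_denominator = config$percent_denominator)
      prh <- pre(proj_harv[[i]])
      ba <- ba_proj[[i]]; bc <- ba_ctrl[[i]]
      data.frame(
        id = projects[[i]]$id, method = method,
        region = projects[[i]]$region_label,
        owner_class = projects[[i]]$owner_class,
        start_year = starts[i], area_ha = areas[i],
        pre_percent_rate = trp$percent_rate, pre_slope = trp$slope,
        pre_slope_p = trp$slope_p,
        pre_harvest = mean(prh$value, na.rm = TRUE),
        pre_harvest_control = mean(pre(ctrl[[i]]$harvest)$value,
                                   na.rm = TRUE),
        carbon_window = if (!is.null(ba)) ba$carbon_window else NA_integer_,
        carbon_slope_change = if (!is.null(ba) && !is.null(ba$carbon))
          ba$carbon$slope_change else NA_real_,
        carbon_chow_p = if (!is.null(ba) && !is.null(ba$carbon))
          ba$carbon$p else NA_real_,
        control_slope_change = if (!is.null(bc) && !is.null(bc$carbon))
          bc$carbon$slope_change else NA_real_,
        harvest_window = if (!is.null(ba)) ba$harvest_window else NA_integer_,
        harvest_change = if (!is.null(ba) && !is.null(ba$harvest))
          ba$harvest$mean_difference else NA_real_,
        harvest_p = if (!is.null(ba) && !is.null(ba$harvest))
          ba$harvest$p else NA_real_)
    })
    per_project[[method]] <- do.call(rbind, rows)
  }

  structure(list(config = config, hypotheses = results,
                 per_project = do.call(rbind, per_project),
                 control_sets = control_sets,
                 n_projects = n_proj),
            class = "ifm_audit")
}

#' @export
print.ifm_audit <- function(x, ...) {
  cat(sprintf("<ifm_audit> %d project(s); methods: %s\n", x$n_projects,
              paste(names(x$hypotheses), collapse = ", ")))
  labels <- c(H1 = "H1 pre-project carbon trend",
              H2 = "H2 pre-project harvest",
              H3 = "H3 species composition",
              H4 = "H4 post-project carbon change",
              H5 = "H5 post-project harvest change")
  for (method in names(x$hypotheses)) {
    cat(sprintf("-- %s controls --\n", method))
    hs <- x$hypotheses[[method]]
    for (h in names(labels)) {
      cat(sprintf("  %-32s %s\n", labels[[h]], hs[[h]]$verdict))
    }
  }
  invisible(x)
}

#' @export
summary.ifm_audit <- function(object, ...) {
  for (method in names(object$hypotheses)) {
    hs <- object$hypotheses[[method]]
    cat(sprintf("== %s controls ==\n", method))
    cat(sprintf("H1: project %.2f %%/yr vs control %.2f %%/yr (p = %.3g) -> %s\n",
                hs$H1$project_percent_rate, hs$H1$control_percent_rate,
                hs$H1$p, hs$H1$verdict))
    cat(sprintf("H2: harvest diff %.4g (%.0f%% of control), p = %.3g -> %s\n",
                hs$H2$mean_difference, hs$H2$relative_difference, hs$H2$p,
                hs$H2$verdict))
    cat(sprintf("H3: %s %.1f%% vs %.1f%%, p = %.3g -> %s\n",
                hs$H3$species, hs$H3$project_fraction,
                hs$H3$control_fraction, hs$H3$p, hs$H3$verdict))
    if (!is.null(hs$H4$p))
      cat(sprintf("H4: slope change %+.3g (control %+.3g), p = %.3g -> %s\n",
                  hs$H4$slope_change, hs$H4$control_slope_change, hs$H4$p,
                  hs$H4$verdict))
    else cat(sprintf("H4: %s (%s)\n", hs$H4$verdict, hs$H4$reason))
    if (!is.null(hs$H5$p))
      cat(sprintf("H5: harvest change %+.4g (control %+.4g), p = %.3g -> %s\n",
                  hs$H5$mean_change, hs$H5$control_mean_change, hs$H5$p,
                  hs$H5$verdict))
    else cat(sprintf("H5: %s (%s)\n", hs$H5$verdict, hs$H5$reason))
    if (length(hs$excluded))
      cat("excluded:", paste(hs$excluded, collapse = " | "), "\n")
  }
  invisible(object)
}

#' Group the before/after audit by landowner category
#'
#' Aggregates per-project before/after carbon and harvest changes into
#' owner-class groups (large timber companies versus others by default),
#' with one-sample t significance flags on the per-project changes and the
#' groups' pre-period harvest levels.
#'
#' @param report an `ifm_audit`.
#' @param grouping named character vector mapping owner classes to group
#'   labels; every owner class present must be mapped.
#' @param method which control method's rows to summarize.
#' @return data frame, one row per group.
#' @export
owner_class_summary <- function(report,
                                grouping = c("large-timber" = "large-timber",
                                             "other" = "other"),
                                method = NULL) {
  pp <- report$per_project
  method <- method %||% pp$method[1L]
  pp <- pp[pp$method == method, ]
  unknown <- setdiff(unique(pp$owner_class), names(grouping))
  if (length(unknown))
    stop(sprintf("unknown owner class label '%s'", unknown[1L]))
  pp$group <- unname(grouping[pp$owner_class])
  one_sample_p <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L || stats::sd(x) == 0) return(NA_real_)
    stats::t.test(x)$p.value
  }
  out <- do.call(rbind, lapply(split(pp, pp$group), function(g) {
    data.frame(group = g$group[1L], n_projects = nrow(g),
               pre_harvest = mean(g$pre_harvest, na.rm = TRUE),
               pre_harvest_control = mean(g$pre_harvest_control,
                                          na.rm = TRUE),
               carbon_slope_change = mean(g$carbon_slope_change,
                                          na.rm = TRUE),
               carbon_change_p = one_sample_p(g$carbon_slope_change),
               harvest_change = mean(g$harvest_change, na.rm = TRUE),
               harvest_change_p = one_sample_p(g$harvest_change))
  }))
  rownames(out) <- NULL
  out
}
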