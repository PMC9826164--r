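#' Synthetic landscape configuration
#'
#' Defines a complete fabricated study region: a two-region grid (a wet,
#' productive "coastal" analogue accumulating carbon at about +1%/yr and a
#' drier "interior" analogue with near-zero net change), logistic stand
#' dynamics with patchy harvest and recovery, a saturating measurement model
#' (underestimation above ~210 ton C/ha), species-fraction layers, offset
#' project polygons with crediting documents, and known ground truth.
#'
#' Biomass is simulated in ton biomass/ha and converted to carbon by the
#' 0.47 factor; initial biomass defaults put the coastal analogue near the
#' carbon densities of northern-California project lands (~120 ton C/ha) and
#' the interior analogue near ~50 ton C/ha.
#'
#' @param grid_shape `(rows, cols)` of the native grid.
#' @param cell_size pixel size, m.
#' @param years inclusive simulated year range (span >= 10).
#' @param growth_rate_by_region target net regional carbon growth,
#'   fraction/yr, named `coastal`/`interior`.
#' @param initial_biomass_by_region mean initial biomass, ton biomass/ha.
#' @param initial_noise_sd lognormal sd of pixel initial biomass.
#' @param growth_noise_sd lognormal sd of pixel-year growth noise.
#' @param year_effect_sd lognormal sd of the shared region-year growth shock
#'   (interannual climate variability common to all pixels of a region;
#'   kept small because it integrates into the carbon level).
#' @param obs_noise_sd lognormal sd of the shared region-year observation
#'   shock applied to the observed carbon stack only (year-to-year retrieval
#'   noise common to a region, serially independent; it does not integrate).
#' @param harvest_prob_by_region expected fraction of area harvested per
#'   year.
#' @param harvest_patch_size side length of square harvest patches, pixels.
#' @param harvest_retention fraction of biomass remaining after harvest
#'   (< 1).
#' @param recovery_halflife years for a harvested stand to close half its
#'   deficit (sets the logistic rate used while biomass is below half the
#'   regional initial level).
#' @param carrying_capacity logistic carrying capacity, ton biomass/ha.
#' @param saturation_onset carbon density (ton C/ha) above which the
#'   measurement model compresses increments.
#' @param saturation_slope observed increment per unit true increment above
#'   the onset.
#' @param species_names,background_fractions species layers and their
#'   landscape-mean fractions (must sum to 1).
#' @param low_value_species which species proxies low timber value.
#' @param species_noise_sd sd of the smooth spatial field perturbing the
#'   low-value species fraction.
#' @param n_projects,project_area_range number of project polygons and their
#'   area range, ha.
#' @param project_start_years,project_owner_classes,project_regions per
#'   project start years, owner classes (`large-timber`/`other`) and regions
#'   (recycled to `n_projects`).
#' @param project_placement_bias `"none"`, `"recently_harvested"` (projects
#'   of large-timber owners placed on lands with high pre-start harvest), or
#'   `"low_value_species"` (placed on high low-value-species stands).
#' @param effect_injection `"none"` or any of `c("stop_harvest",
#'   "growth_boost")`: management effects applied inside project polygons
#'   after each project's start year.
#' @param effect_magnitude growth boost, ton C/ha/yr.
#' @param reporting_inflation ratio of document-reported to measured carbon
#'   accumulation.
#' @param baseline_fraction baseline stock as a fraction of the initial
#'   stock.
#' @param frac_reported_total fraction of projects whose documents report
#'   total rather than AGL carbon.
#' @param public_rows,urban_rows number of grid rows assigned to public
#'   ownership (top) and urban/agriculture (bottom).
#' @param rng_seed integer seed; identical config + seed reproduces the
#'   scene bit-for-bit.
#' @return a validated list of class `landscape_config`.
#' @export
landscape_config <- function(grid_shape = c(160L, 160L),
                             cell_size = 30,
                             years = 1986:2021,
                             growth_rate_by_region =
                               c(coastal = 0.0105, interior = 0.001),
                             initial_biomass_by_region =
                               c(coastal = 260, interior = 110),
                             initial_noise_sd = 0.25,
                             growth_noise_sd = 0.01,
                             year_effect_sd = 0.002,
                             obs_noise_sd = 0.01,
                             harvest_prob_by_region =
                               c(coastal = 0.012, interior = 0.018),
                             harvest_patch_size = 3L,
                             harvest_retention = 0.15,
                             recovery_halflife = 25,
                             carrying_capacity = 700,
                             saturation_onset = 210,
                             saturation_slope = 0.5,
                             species_names = c("redwood", "douglas_fir",
                                               "tanoak", "other"),
                             background_fractions = c(0.25, 0.30, 0.20, 0.25),
                             low_value_species = "tanoak",
                             species_noise_sd = 0.06,
                             n_projects = 6L,
                             project_area_range = c(30, 90),
                             project_start_years = c(2012L, 2012L, 2013L,
                                                     2013L, 2014L, 2014L),
                             project_owner_classes = c("other", "other",
                                                       "other", "large-timber",
                                                       "large-timber",
                                                       "large-timber"),
                             project_regions = c("coastal", "coastal",
                                                 "coastal", "coastal",
                                                 "interior", "interior"),
                             project_placement_bias = "none",
                             effect_injection = "none",
                             effect_magnitude = 0.5,
                             reporting_inflation = 1,
                             baseline_fraction = 0.8,
                             frac_reported_total = 0.5,
                             public_rows = 20L,
                             urban_rows = 8L,
                             rng_seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "landscape_config"
  validate_landscape_config(cfg)
  cfg
}

validate_landscape_config <- function(cfg) {
  frac_fields <- c("harvest_retention", "baseline_fraction",
                   "frac_reported_total", "saturation_slope")
  for (f in frac_fields)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("config field `%s` must lie in [0, 1]", f))
  if (any(cfg$harvest_prob_by_region < 0 | cfg$harvest_prob_by_region > 1))
    stop("config field `harvest_prob_by_region` must lie in [0, 1]")
  if (any(cfg$background_fractions < 0 | cfg$background_fractions > 1) ||
      abs(sum(cfg$background_fractions) - 1) > 1e-8)
    stop("config field `background_fractions` must lie in [0, 1] and sum to 1")
  if (cfg$harvest_retention >= 1)
    stop("config field `harvest_retention` must be < 1")
  if (diff(range(cfg$years)) + 1L < 10L)
    stop("config field `years` must span at least 10 years")
  if (cfg$saturation_onset <= 0)
    stop("config field `saturation_onset` must be positive")
  if (!cfg$low_value_species %in% cfg$species_names)
    stop("config field `low_value_species` must be one of `species_names`")
  bad_effect <- setdiff(cfg$effect_injection,
                        c("none", "stop_harvest", "growth_boost"))
  if (length(bad_effect))
    stop(sprintf("config field `effect_injection`: unknown value '%s'",
                 bad_effect[1L]))
  px_area_ha <- (cfg$cell_size / 100)^2
  total_project <- cfg$n_projects * max(cfg$project_area_range)
  landscape <- prod(cfg$grid_shape) * px_area_ha
  if (total_project > 0.25 * landscape)
    stop(paste("config fields `n_projects`/`project_area_range`: total",
               "project area exceeds 25% of the landscape"))
  invisible(cfg)
}

# Deterministic cohort model of the regional mean biomass trajectory under
# expected harvest: the lognormal spread of initial biomass is represented
# by equal-weight quantile cohorts (the logistic is concave, so spatial
# heterogeneity lowers the mean net rate), each cohort grows logistically,
# and a fraction h of each is harvested and pooled into one new cohort per
# year. Used to calibrate the intrinsic logistic rate so that the *net*
# regional percent growth (after logistic drag, heterogeneity and harvest
# losses/recovery) matches the configured target.
cohort_percent_rate <- function(r, B0, K, h, retention, halflife, nyears,
                                init_sd = 0, n_cohorts = 15L) {
  if (init_sd > 0) {
    q <- (seq_len(n_cohorts) - 0.5) / n_cohorts
    cohB <- B0 * exp(stats::qnorm(q, 0, init_sd))
    cohW <- rep(1 / n_cohorts, n_cohorts)
  } else {
    cohB <- B0; cohW <- 1
  }
  r_rec <- log(2) / halflife
  meanB <- numeric(nyears)
  meanB[1L] <- sum(cohB * cohW) / sum(cohW)
  for (y in 2:nyears) {
    reff <- ifelse(cohB < 0.5 * B0, r_rec, r)
    cohB <- cohB * (1 + reff * (1 - cohB / K))
    if (h > 0) {
      harvB <- sum(cohW * h * cohB * retention) / sum(cohW * h)
      newW <- sum(cohW * h)
      cohW <- cohW * (1 - h)
      cohB <- c(cohB, harvB)
      cohW <- c(cohW, newW)
    }
    meanB[y] <- sum(cohB * cohW) / sum(cohW)
  }
  yrs <- seq_len(nyears)
  slope <- stats::cov(yrs, meanB) / stats::var(yrs)
  100 * slope / mean(meanB)
}

.calib_cache <- new.env(parent = emptyenv())

calibrate_growth_rate <- function(cfg, region) {
  target <- 100 * cfg$growth_rate_by_region[[region]]
  B0 <- cfg$initial_biomass_by_region[[region]]
  key <- paste(region, target, B0, cfg$carrying_capacity,
               cfg$harvest_prob_by_region[[region]], cfg$harvest_retention,
               cfg$recovery_halflife, length(cfg$years),
               cfg$initial_noise_sd, sep = "|")
  cached <- .calib_cache[[key]]
  if (!is.null(cached)) return(cached)
  f <- function(r) cohort_percent_rate(r, B0, cfg$carrying_capacity,
                                       cfg$harvest_prob_by_region[[region]],
                                       cfg$harvest_retention,
                                       cfg$recovery_halflife,
                                       length(cfg$years),
                                       init_sd = cfg$initial_noise_sd) - target
  # the net rate is not monotone in r at large r (logistic overshoot), so
  # bracket the lowest sign change on a grid before root-finding
  grid <- c(1e-6, seq(0.005, 0.3, by = 0.005))
  vals <- vapply(grid, f, numeric(1))
  i <- which(vals[-1L] * vals[-length(vals)] <= 0)[1L]
  r <- if (is.na(i)) {
    warning(sprintf(
      "growth-rate target for region '%s' unattainable; using closest rate",
      region))
    grid[which.min(abs(vals))]
  } else stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-9)$root
  .calib_cache[[key]] <- r
  r
}

smooth_field <- function(nr, nc, sd, passes = 3L, window = 9L) {
  # moving-average smoothed Gaussian noise, rescaled back to sd
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- rep(1 / window, window)
  for (p in seq_len(passes)) {
    f <- unclass(stats::filter(f, k, sides = 2, circular = TRUE))
    f <- t(unclass(stats::filter(t(f), k, sides = 2, circular = TRUE)))
  }
  f * (sd / stats::sd(as.vector(f)))
}

#' Saturating measurement model
#'
#' Mimics the high-density bias of Landsat-based biomass products: observed
#' carbon equals true carbon below the onset; above it, each unit of true
#' increment yields only `slope` units of observed increment (piecewise
#' linear, monotone nondecreasing for `slope >= 0`).
#'
#' @param true_stack a `raster_stack` (ton C/ha), matrix, or numeric vector.
#' @param onset carbon density where compression begins, ton C/ha (> 0).
#' @param slope observed-per-true increment above the onset.
#' @return object of the same shape with the model applied.
#' @export
apply_measurement_model <- function(true_stack, onset = 210, slope = 0.5) {
  if (onset <= 0) stop("`onset` must be positive")
  f <- function(x) {
    if (any(x < 0, na.rm = TRUE))
      stop("negative carbon values are not allowed")
    ifelse(x <= onset, x, onset + slope * (x - onset))
  }
  if (inherits(true_stack, "raster_stack")) {
    out <- true_stack
    out$values[] <- f(true_stack$values)
    return(out)
  }
  f(true_stack)
}

# All top-left corners where an h x w block fits entirely inside `ok`,
# found with a summed-area table. Returns a 2-column (row, col) matrix.
valid_positions <- function(ok, h_px, w_px) {
  nr <- nrow(ok); nc <- ncol(ok)
  if (h_px > nr || w_px > nc) return(matrix(integer(0), 0L, 2L))
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(apply(apply(ok + 0L, 2L, cumsum), 1L, cumsum))
  r0 <- seq_len(nr - h_px + 1L)
  c0 <- seq_len(nc - w_px + 1L)
  blk <- S[r0 + h_px, c0 + w_px, drop = FALSE] -
    S[r0, c0 + w_px, drop = FALSE] -
    S[r0 + h_px, c0, drop = FALSE] + S[r0, c0, drop = FALSE]
  which(blk == h_px * w_px, arr.ind = TRUE)
}

#' Generate a synthetic scene
#'
#' Runs the full fabrication pipeline: regions, covariates and land classes;
#' patchy harvest; project placement (optionally biased toward recently
#' harvested or low-timber-value stands); logistic biomass dynamics with
#' calibrated regional growth; effect injection; the saturating measurement
#' model; species-fraction layers; and crediting documents.
#'
#' @param config a [landscape_config()].
#' @return a list of class `synthetic_scene` with elements `true_carbon`,
#'   `observed_carbon`, `harvest` (all `raster_stack`s), `species_fractions`
#'   (named list of fraction matrices for the species year),
#'   `covariates` (temperature degC, precipitation mm/yr, site_class 1-7),
#'   `land_class` (character matrix), `region_map`, `projects` (list of
#'   [project_record()]), and `config`.
#' @export
generate_scene <- function(config) {
  validate_landscape_config(config)
  set.seed(config$rng_seed)
  nr <- config$grid_shape[1L]; nc <- config$grid_shape[2L]
  cell <- config$cell_size
  years <- config$years
  nyears <- length(years)
  px_area_ha <- (cell / 100)^2
  regions <- names(config$growth_rate_by_region)

  # --- regions: west half coastal analogue, east half interior analogue ---
  region_map <- matrix(regions[1L], nr, nc)
  if (length(regions) > 1L)
    region_map[, (nc %/% 2 + 1L):nc] <- regions[2L]

  # --- land class: public band at top, urban/ag strip at bottom ---
  land_class <- matrix("private-forest", nr, nc)
  if (config$public_rows > 0L)
    land_class[seq_len(config$public_rows), ] <- "public"
  if (config$urban_rows > 0L)
    land_class[(nr - config$urban_rows + 1L):nr, ] <- "urban/ag"
  private <- land_class == "private-forest"

  # --- covariates: smooth west-east gradients plus spatial noise ---
  colfrac <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
  rowfrac <- matrix(seq_len(nr) / nr, nr, nc)
  temperature <- 9 + 6 * colfrac + 1.5 * rowfrac + smooth_field(nr, nc, 0.6)
  precipitation <- 2200 - 1600 * colfrac - 150 * rowfrac +
    smooth_field(nr, nc, 80)
  productivity <- (precipitation - min(precipitation)) /
    diff(range(precipitation)) + smooth_field(nr, nc, 0.12)
  site_class <- matrix(pmin(7, pmax(1, round(1 + 6 * productivity))), nr, nc)

  # --- species base field (needed before placement for the species bias) ---
  low_sp <- config$low_value_species
  bg <- stats::setNames(config$background_fractions, config$species_names)
  low_field <- bg[[low_sp]] + smooth_field(nr, nc, config$species_noise_sd)
  low_field <- pmin(0.9, pmax(0.01, low_field))

  # --- harvest stack (pre-effect): Poisson counts of square patches ---
  patch <- config$harvest_patch_size
  harvest <- array(0, dim = c(nr, nc, nyears))
  for (reg in regions) {
    reg_private <- which(region_map == reg & private, arr.ind = TRUE)
    if (nrow(reg_private) == 0L) next
    h <- config$harvest_prob_by_region[[reg]]
    lambda <- h * nrow(reg_private) / patch^2
    for (y in seq_len(nyears)) {
      n_patches <- stats::rpois(1L, lambda)
      if (n_patches == 0L) next
      centers <- reg_private[sample.int(nrow(reg_private), n_patches,
                                        replace = TRUE), , drop = FALSE]
      half <- patch %/% 2L
      for (k in seq_len(n_patches)) {
        rows <- max(1L, centers[k, 1L] - half):
          min(nr, centers[k, 1L] - half + patch - 1L)
        cols <- max(1L, centers[k, 2L] - half):
          min(nc, centers[k, 2L] - half + patch - 1L)
        blk <- harvest[rows, cols, y]
        sel <- region_map[rows, cols] == reg & private[rows, cols]
        blk[sel] <- 1
        harvest[rows, cols, y] <- blk
      }
    }
  }

  # --- project placement ---
  n_proj <- config$n_projects
  starts <- rep_len(config$project_start_years, n_proj)
  owners <- rep_len(config$project_owner_classes, n_proj)
  proj_regions <- rep_len(config$project_regions, n_proj)
  areas_ha <- stats::runif(n_proj, config$project_area_range[1L],
                           config$project_area_range[2L])
  bias <- config$project_placement_bias
  taken <- matrix(FALSE, nr, nc)
  pre_harvest_any <- NULL
  polys <- vector("list", n_proj)
  masks <- vector("list", n_proj)
  for (i in seq_len(n_proj)) {
    n_px_want <- max(9L, round(areas_ha[i] / px_area_ha))
    n_px_min <- max(9L, round(config$project_area_range[1L] / px_area_ha))
    aspect0 <- stats::runif(1, 0.7, 1.4)
    allowed <- private & region_map == proj_regions[i]
    # keep a 2-pixel gap between projects
    taken_exp <- taken
    if (any(taken)) {
      idx <- which(taken, arr.ind = TRUE)
      for (dr in -2:2) for (dc in -2:2) {
        rr <- pmin(nr, pmax(1L, idx[, 1L] + dr))
        cc <- pmin(nc, pmax(1L, idx[, 2L] + dc))
        taken_exp[cbind(rr, cc)] <- TRUE
      }
    }
    biased <- bias != "none" &&
      (bias == "low_value_species" || owners[i] == "large-timber")
    # try the drawn shape first, then alternative aspects, then shrink the
    # area toward the configured minimum before declaring infeasibility
    free <- allowed & !taken_exp
    pos <- NULL
    for (n_px in unique(round(n_px_want * c(1, 0.9, 0.8, 0.7, 0.6)))) {
      if (n_px < n_px_min && n_px != n_px_min) n_px <- n_px_min
      for (aspect in c(aspect0, 1, 0.75, 1.35)) {
        h_px <- max(3L, round(sqrt(n_px * aspect)))
        w_px <- max(3L, round(n_px / h_px))
        pos <- valid_positions(free, h_px, w_px)
        if (nrow(pos) > 0L) break
      }
      if (!is.null(pos) && nrow(pos) > 0L) break
      if (n_px <= n_px_min) break
    }
    if (is.null(pos) || nrow(pos) == 0L)
      stop(sprintf("could not place project %d in region '%s'", i,
                   proj_regions[i]))
    n_cand <- if (biased) min(60L, nrow(pos)) else 1L
    cand_pos <- pos[sample.int(nrow(pos), n_cand), , drop = FALSE]
    score_of <- function(r0, c0) {
      rows <- r0:(r0 + h_px - 1L); cols <- c0:(c0 + w_px - 1L)
      if (!biased) 0 else if (bias == "recently_harvested") {
        pre_idx <- which(years < starts[i] & years >= starts[i] - 15L)
        mean(harvest[rows, cols, pre_idx])
      } else mean(low_field[rows, cols])
    }
    scores <- mapply(score_of, cand_pos[, 1L], cand_pos[, 2L])
    pick <- cand_pos[which.max(scores), ]
    best <- list(rows = pick[1L]:(pick[1L] + h_px - 1L),
                 cols = pick[2L]:(pick[2L] + w_px - 1L))
    taken[best$rows, best$cols] <- TRUE
    m <- matrix(FALSE, nr, nc)
    m[best$rows, best$cols] <- TRUE
    masks[[i]] <- m
    # polygon from the pixel block's outer edges
    x0 <- (min(best$cols) - 1L) * cell; x1 <- max(best$cols) * cell
    y1 <- nr * cell - (min(best$rows) - 1L) * cell
    y0 <- nr * cell - max(best$rows) * cell
    polys[[i]] <- rect_polygon(x0, x1, y0, y1, id = sprintf("PROJ%d", i),
                               properties = list(start_year = starts[i],
                                                 owner_class = owners[i]))
  }
  project_any <- Reduce(`|`, masks)

  # --- effect injection: stop_harvest ---
  effects <- setdiff(config$effect_injection, "none")
  if ("stop_harvest" %in% effects) {
    for (i in seq_len(n_proj)) {
      post <- which(years > starts[i])
      for (y in post) {
        lyr <- harvest[, , y]
        lyr[masks[[i]]] <- 0
        harvest[, , y] <- lyr
      }
    }
  }

  # --- biomass dynamics ---
  K <- config$carrying_capacity
  r_reg <- vapply(regions, function(rg) calibrate_growth_rate(config, rg),
                  numeric(1))
  r_rec <- log(2) / config$recovery_halflife
  B0_reg <- config$initial_biomass_by_region
  B <- matrix(0, nr, nc)
  r_map <- matrix(0, nr, nc)
  B0_map <- matrix(0, nr, nc)
  for (reg in regions) {
    sel <- region_map == reg
    B0_map[sel] <- B0_reg[[reg]]
    r_map[sel] <- r_reg[[reg]]
  }
  B <- B0_map * exp(stats::rnorm(nr * nc, 0, config$initial_noise_sd))
  B[land_class == "urban/ag"] <- NA
  boost_biomass <- config$effect_magnitude /
    conversion_constants()$carbon_per_biomass
  true_carbon <- array(NA_real_, dim = c(nr, nc, nyears))
  reg_idx <- lapply(regions, function(reg) which(region_map == reg))
  names(reg_idx) <- regions
  for (y in seq_len(nyears)) {
    if (y > 1L) {
      reff <- r_map
      low <- which(B < 0.5 * B0_map)
      reff[low] <- r_rec
      shock <- numeric(nr * nc)
      for (reg in regions)
        shock[reg_idx[[reg]]] <- stats::rnorm(1, 0, config$year_effect_sd)
      noise <- stats::rnorm(nr * nc, 0, config$growth_noise_sd)
      B <- B * (1 + reff * (1 - B / K)) * exp(shock + noise)
      if ("growth_boost" %in% effects) {
        for (i in seq_len(n_proj)) if (years[y] > starts[i])
          B[masks[[i]]] <- B[masks[[i]]] + boost_biomass
      }
    }
    harv <- harvest[, , y] == 1
    B[harv & !is.na(B)] <- B[harv & !is.na(B)] * config$harvest_retention
    true_carbon[, , y] <- B * conversion_constants()$carbon_per_biomass
  }

  mk_stack <- function(arr, units) {
    raster_stack(arr, years = years, xmin = 0, ymax = nr * cell, cell = cell,
                 crs = "EPSG:3310", units = units)
  }
  true_stack <- mk_stack(true_carbon, "ton C/ha")
  observed_stack <- apply_measurement_model(true_stack,
                                            config$saturation_onset,
                                            config$saturation_slope)
  if (config$obs_noise_sd > 0) {
    for (y in seq_len(nyears)) {
      lyr <- observed_stack$values[, , y]
      for (reg in regions) {
        sel <- region_map == reg
        lyr[sel] <- lyr[sel] * exp(stats::rnorm(1, 0, config$obs_noise_sd))
      }
      # the saturating sensor never reads above the true value
      tru <- true_carbon[, , y]
      over <- !is.na(tru) & tru > config$saturation_onset
      lyr[over] <- pmin(lyr[over], tru[over])
      observed_stack$values[, , y] <- lyr
    }
  }
  harvest[rep(land_class == "urban/ag", nyears)] <- NA
  harvest_stack <- mk_stack(harvest, "binary")

  # --- species fractions (single species year: earliest project start) ---
  vegetated <- land_class != "urban/ag"
  sp <- list()
  others <- setdiff(config$species_names, low_sp)
  other_bg <- bg[others] / sum(bg[others])
  sp[[low_sp]] <- low_field
  rest <- 1 - low_field
  for (j in seq_along(others)) {
    f <- other_bg[[j]] + smooth_field(nr, nc, config$species_noise_sd / 2)
    sp[[others[j]]] <- pmax(0.01, f)
  }
  other_sum <- Reduce(`+`, sp[others])
  for (j in others) sp[[j]] <- sp[[j]] / other_sum * rest
  for (j in names(sp)) sp[[j]][!vegetated] <- NA
  attr(sp, "year") <- min(starts)

  # --- project records ---
  projects <- vector("list", n_proj)
  for (i in seq_len(n_proj)) {
    projects[[i]] <- project_record(
      id = sprintf("PROJ%d", i), polygon = polys[[i]],
      start_year = starts[i], area = sum(masks[[i]]) * px_area_ha,
      owner_class = owners[i], region_label = proj_regions[i])
  }

  scene <- structure(
    list(true_carbon = true_stack, observed_carbon = observed_stack,
         harvest = harvest_stack, species_fractions = sp,
         covariates = list(temperature = temperature,
                           precipitation = precipitation,
                           site_class = site_class),
         land_class = land_class, region_map = region_map,
         projects = projects, project_masks = masks, config = config),
    class = "synthetic_scene")
  scene$projects <- generate_project_documents(scene,
                                               config$reporting_inflation)
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$true_carbon$values)
  cat(sprintf(paste0("<synthetic_scene> %dx%d pixels, %d years (%d-%d), ",
                     "%d projects\n"),
              d[1L], d[2L], d[3L], min(x$true_carbon$years),
              max(x$true_carbon$years), length(x$projects)))
  invisible(x)
}

#' Fabricate crediting documents for a scene's projects
#'
#' Reported stocks start from the measured (true zonal) AGL stock at project
#' start and accumulate at `inflation` times the measured accumulation, so
#' that the document-reported rate divided by the measured rate equals the
#' inflation factor. The baseline is a configured fraction of the initial
#' stock; the first issuance covers initial-above-baseline stocking and
#' subsequent annual issuances cover reported incremental accumulation (in
#' tCO2e via the molar ratio). Documents flagged `reported_is_total` carry
#' stocks in total-carbon units via the AGL convention.
#'
#' @param scene a `synthetic_scene` with placed projects.
#' @param inflation ratio of reported to measured accumulation.
#' @return list of completed [project_record()]s.
#' @export
generate_project_documents <- function(scene, inflation = 1) {
  cfg <- scene$config
  cc <- conversion_constants()
  d <- dim(scene$true_carbon$values)[1:2]
  n_total <- if (length(scene$projects) > 0)
    ceiling(cfg$frac_reported_total * length(scene$projects)) else 0L
  out <- vector("list", length(scene$projects))
  for (i in seq_along(scene$projects)) {
    rec <- scene$projects[[i]]
    mask <- scene$project_masks[[i]]
    if (!any(mask)) stop(sprintf("project %s lies outside the grid", rec$id))
    idx <- which(mask, arr.ind = TRUE)
    if (max(idx[, 1L]) > d[1L] || max(idx[, 2L]) > d[2L])
      stop(sprintf("project %s lies outside the grid", rec$id))
    ts <- zonal_series(scene$true_carbon, region_mask(mask, rec$id))
    yrs <- ts$year[ts$year >= rec$start_year]
    vals <- ts$value[ts$year >= rec$start_year]
    initial <- vals[1L]
    reported <- initial + inflation * (vals - initial)
    baseline <- cfg$baseline_fraction * initial
    is_total <- i <= n_total
    stocks <- if (is_total) reported / cc$agl_fraction else reported
    credits <- c(c_to_agl_credits(initial - baseline, rec$area, cc),
                 c_to_agl_credits(diff(reported), rec$area, cc))
    out[[i]] <- project_record(
      id = rec$id, polygon = rec$polygon, start_year = rec$start_year,
      area = rec$area, owner_class = rec$owner_class,
      baseline_stock = baseline,
      reported_stocks = stats::setNames(stocks, yrs),
      reported_is_total = is_total,
      credits_issued = stats::setNames(pmax(0, credits), yrs),
      region_label = rec$region_label)
  }
  out
}

# AGL carbon density change (ton C/ha) over a project area -> credits (tCO2e)
c_to_agl_credits <- function(delta_density, area_ha, cc) {
  delta_density * area_ha / cc$c_per_co2
}

#' Write a scene to disk in open formats
#'
#' Rasters as ASCII-grid stacks with JSON sidecars, project polygons as
#' GeoJSON (properties `id`, `start_year`, `owner_class`), documents as CSV,
#' and the configuration as a `key = value` text file.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$true_carbon, dir, "true_carbon")
  write_stack(scene$observed_carbon, dir, "observed_carbon")
  write_stack(scene$harvest, dir, "harvest")
  write_polygons_geojson(lapply(scene$projects, `[[`, "polygon"),
                         file.path(dir, "projects.geojson"))
  write_project_documents(scene$projects, dir)
  cfg <- scene$config
  lines <- vapply(names(unclass(cfg)), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, paste(format(v, scientific = FALSE),
                                collapse = ", "))
  }, character(1))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
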