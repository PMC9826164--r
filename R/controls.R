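#' Control-group specification
#'
#' Parameters for the three spatial control constructions: a surrounding
#' buffer ring, a regional pool of private forestland, or a
#' covariate-matched set of coarse pixels.
#'
#' @param method `"buffer"`, `"region"`, or `"matched"`.
#' @param buffer_width buffer distance from the project boundary, m.
#' @param exclusion_classes land classes excluded from controls.
#' @param region_label regional pool / matching region.
#' @param covariates ordered covariate names used for matching.
#' @param match_resolution target matching resolution, m (block aggregated
#'   from the native grid by the nearest integer factor).
#' @param n_pixels number of matched pixels; `NULL` picks
#'   `round(project_area / coarse_pixel_area)` (area-matched), bounded >= 1.
#' @param include_projects for the region method: include project pixels in
#'   the pool (reproduces region-wide curves) instead of excluding them.
#' @export
control_spec <- function(method = c("buffer", "region", "matched"),
                         buffer_width = 2000,
                         exclusion_classes = c("urban/ag", "public"),
                         region_label = NULL,
                         covariates = c("temperature", "precipitation",
                                        "site_class"),
                         match_resolution = 800,
                         n_pixels = NULL,
                         include_projects = FALSE) {
  method <- match.arg(method)
  if (buffer_width <= 0) stop("`buffer_width` must be positive")
  if (method == "matched" && length(covariates) == 0L)
    stop("matched controls need at least one covariate")
  structure(list(method = method, buffer_width = buffer_width,
                 exclusion_classes = exclusion_classes,
                 region_label = region_label, covariates = covariates,
                 match_resolution = match_resolution, n_pixels = n_pixels,
                 include_projects = include_projects),
            class = "control_spec")
}

new_control_set <- function(project_id, method, mask, n_pixels,
                            mean_covariate_distance = NA_real_) {
  structure(list(project_id = project_id, method = method, mask = mask,
                 n_pixels = n_pixels,
                 mean_covariate_distance = mean_covariate_distance),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("<control_set> %s control for %s: %d pixels%s\n", x$method,
              x$project_id, x$n_pixels,
              if (!is.na(x$mean_covariate_distance))
                sprintf(", mean covariate distance %.3f",
                        x$mean_covariate_distance) else ""))
  invisible(x)
}

project_union_mask <- function(all_projects, template) {
  masks <- lapply(all_projects, function(p)
    rasterize_polygons(p$polygon, template)$mask)
  Reduce(`|`, masks)
}

#' Surrounding-buffer control
#'
#' All pixels within `buffer_width` of the project boundary, outside the
#' project itself, on private forestland (urban/agricultural and public
#' pixels excluded), and outside every other project polygon.
#'
#' @param project a `project_record` with a polygon.
#' @param land_class character matrix of per-pixel land classes.
#' @param all_projects list of all `project_record`s (their interiors are
#'   excluded).
#' @param template a `raster_stack` providing the grid.
#' @param spec a [control_spec()].
#' @return a `control_set`.
#' @export
buffer_control <- function(project, land_class, all_projects, template,
                           spec = control_spec("buffer")) {
  ctr <- pixel_centers(template)
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  coords <- project$polygon$coords
  # restrict distance computation to the expanded bounding box
  w <- spec$buffer_width
  inbox <- px >= min(coords[, 1L]) - w & px <= max(coords[, 1L]) + w &
    py >= min(coords[, 2L]) - w & py <= max(coords[, 2L]) + w
  near <- rep(FALSE, length(px))
  near[inbox] <- dist_to_boundary(px[inbox], py[inbox], coords) <= w
  inside <- point_in_polygon(px, py, coords)
  m <- matrix(near & !inside, nrow(ctr$x), ncol(ctr$x))
  m <- m & !matrix(land_class %in% spec$exclusion_classes, nrow(m), ncol(m))
  others <- Filter(function(p) !identical(p$id, project$id), all_projects)
  if (length(others))
    m <- m & !project_union_mask(others, template)
  if (!any(m))
    stop(sprintf(paste("empty buffer control for %s after exclusions;",
                       "consider a wider buffer"), project$id))
  new_control_set(project$id, "buffer",
                  region_mask(m, sprintf("%s-buffer", project$id)), sum(m))
}

#' Regional-pool control
#'
#' All private-forest pixels carrying the region label, with project pixels
#' excluded unless `spec$include_projects` asks for the region-wide pool.
#'
#' @param region_label region name present in `region_map`.
#' @param region_map character matrix of per-pixel region labels.
#' @inheritParams buffer_control
#' @export
region_control <- function(region_label, region_map, land_class,
                           all_projects, template,
                           spec = control_spec("region")) {
  if (!region_label %in% region_map)
    stop(sprintf("unknown region label '%s'", region_label))
  m <- region_map == region_label &
    !matrix(land_class %in% spec$exclusion_classes,
            nrow(region_map), ncol(region_map)) &
    land_class == "private-forest"
  if (length(all_projects) && !isTRUE(spec$include_projects))
    m <- m & !project_union_mask(all_projects, template)
  if (!any(m))
    stop(sprintf("region control '%s' is empty", region_label))
  new_control_set(region_label, "region",
                  region_mask(m, sprintf("%s-region", region_label)), sum(m))
}

#' Covariate-matched control
#'
#' Regrids the covariates to the matching resolution by block means,
#' standardizes them over the region's candidate pixels (z-scores), and
#' selects the `n` candidate pixels closest to the project's mean covariates
#' in Mahalanobis distance (covariance of the standardized regional
#' covariates). Candidates are private forest of the same region outside
#' all projects; `n` is area-matched unless given. Ties are broken
#' deterministically by pixel index. A singular covariance falls back to
#' its diagonal with a warning.
#'
#' @param project a `project_record`.
#' @param covariate_layers named list of native-resolution covariate
#'   matrices (in `spec$covariates` order or a superset).
#' @param region_map,land_class per-pixel label matrices.
#' @inheritParams buffer_control
#' @return a `control_set` whose mask lives on the aggregated grid (its
#'   `factor` attribute records the aggregation).
#' @export
matched_control <- function(project, covariate_layers, region_map,
                            land_class, all_projects, template,
                            spec = control_spec("matched")) {
  cell <- template$transform$cell
  factor <- max(1L, round(spec$match_resolution / cell))
  agg <- function(m) block_aggregate_matrix(m, factor, min_valid = 0)
  covs <- lapply(spec$covariates, function(k) {
    if (is.null(covariate_layers[[k]]))
      stop(sprintf("covariate '%s' missing", k))
    agg(covariate_layers[[k]])
  })
  region_label <- project$region_label
  reg_frac <- agg((region_map == region_label) + 0)
  priv_frac <- agg((land_class == "private-forest") + 0)
  proj_all <- project_union_mask(all_projects, template)
  projall_frac <- agg(proj_all + 0)
  this_mask <- rasterize_polygons(project$polygon, template)$mask
  this_frac <- agg(this_mask + 0)

  candidates <- reg_frac >= 0.5 & priv_frac >= 0.5 & projall_frac < 0.5
  X <- do.call(cbind, lapply(covs, as.vector))
  colnames(X) <- spec$covariates
  cand_idx <- which(as.vector(candidates) & !apply(is.na(X), 1L, any))
  if (length(cand_idx) < 2L)
    stop(sprintf("too few matching candidates for %s", project$id))

  # project mean covariates over its coarse footprint (50% coverage rule,
  # falling back to the best-covered cell for very small projects)
  fp <- which(as.vector(this_frac >= 0.5))
  if (length(fp) == 0L) fp <- which.max(as.vector(this_frac))
  mu_cand <- colMeans(X[cand_idx, , drop = FALSE])
  sd_cand <- apply(X[cand_idx, , drop = FALSE], 2L, stats::sd)
  if (any(sd_cand == 0)) sd_cand[sd_cand == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu_cand), 2L, sd_cand, `/`)
  proj_mean <- colMeans(Z[fp, , drop = FALSE])
  S <- stats::cov(Z[cand_idx, , drop = FALSE])
  Sinv <- tryCatch({
    if (abs(det(S)) < 1e-12) stop("singular")
    solve(S)
  }, error = function(e) {
    warning("singular covariate covariance; falling back to diagonal")
    diag(1 / pmax(diag(S), 1e-12), nrow(S))
  })
  D <- sweep(Z[cand_idx, , drop = FALSE], 2L, proj_mean)
  d2 <- rowSums((D %*% Sinv) * D)

  px_area_ha <- (cell * factor / 100)^2
  n <- spec$n_pixels %||% max(1L, round(project$area / px_area_ha))
  n <- min(n, length(cand_idx))
  sel_pos <- order(d2, cand_idx)[seq_len(n)]
  sel <- cand_idx[sel_pos]
  m <- matrix(FALSE, nrow(candidates), ncol(candidates))
  m[sel] <- TRUE
  new_control_set(project$id, "matched",
                  region_mask(m, sprintf("%s-matched", project$id),
                              factor = factor),
                  n, mean(sqrt(d2[sel_pos])))
}
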