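#' Annual raster stack
#'
#' The basic gridded container used throughout the package: a year-indexed
#' set of aligned 2-D grids (carbon density, binary harvest, or a covariate)
#' with an affine georeference. Grids are stored row-major with `(row, col)`
#' indexing; the transform maps pixel centers, with `x = xmin + (col - 0.5) *
#' cell` and `y = ymax - (row - 0.5) * cell`. Missing data are `NA`
#' internally; a nodata sentinel is only used on disk.
#'
#' @param values a `rows x cols x years` numeric array, or a list of equal
#'   sized matrices (one per year), or a single matrix (single-year stack).
#' @param years integer vector of years, one per layer, strictly increasing.
#' @param xmin,ymax coordinates of the top-left corner of the grid (map units).
#' @param cell pixel size in map units (meters).
#' @param crs coordinate reference system label (informational; all stacks in
#'   an analysis must share it).
#' @param units one of `"ton C/ha"`, `"ton biomass/ha"`, `"binary"`, or a
#'   covariate-specific label.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(values, years, xmin = 0, ymax = NULL, cell = 30,
                         crs = "EPSG:3310", units = "ton C/ha") {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (is.list(values)) {
    dims <- unique(lapply(values, dim))
    if (length(dims) != 1L)
      stop("all layers of a raster_stack must share one grid shape")
    values <- array(unlist(values, use.names = FALSE),
                    dim = c(dims[[1L]], length(values)))
  }
  if (length(dim(values)) != 3L)
    stop("`values` must be a rows x cols x years array")
  years <- as.integer(years)
  if (length(years) != dim(values)[3L])
    stop("length(years) must equal the number of layers")
  if (length(years) > 1L && any(diff(years) <= 0L))
    stop("years must be strictly increasing")
  if (is.null(ymax)) ymax <- dim(values)[1L] * cell
  dimnames(values) <- list(NULL, NULL, years)
  structure(
    list(values = values, years = years,
         transform = list(xmin = xmin, ymax = ymax, cell = cell),
         crs = crs, units = units),
    class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_stack> %d x %d pixels, %d year(s) (%d-%d)\n",
              d[1L], d[2L], d[3L], min(x$years), max(x$years)))
  cat(sprintf("  cell %g m, origin (%g, %g), crs %s, units %s\n",
              x$transform$cell, x$transform$xmin, x$transform$ymax,
              x$crs, x$units))
  invisible(x)
}

#' @export
dim.raster_stack <- function(x) dim(x$values)

#' Extract one year's grid from a stack
#' @param stack a `raster_stack`.
#' @param year the year to extract.
#' @return a numeric matrix.
#' @export
stack_layer <- function(stack, year) {
  i <- match(as.integer(year), stack$years)
  if (is.na(i)) stop(sprintf("year %s not present in stack", year))
  stack$values[, , i]
}

#' Restrict a stack to a span of years
#' @param stack a `raster_stack`.
#' @param years years to keep (must all be present).
#' @export
stack_subset <- function(stack, years) {
  idx <- match(as.integer(years), stack$years)
  if (anyNA(idx))
    stop(sprintf("years not present in stack: %s",
                 paste(years[is.na(idx)], collapse = ", ")))
  out <- stack
  out$values <- stack$values[, , idx, drop = FALSE]
  out$years <- stack$years[idx]
  dimnames(out$values)[[3L]] <- out$years
  out
}

#' Check that two stacks (or a stack and a mask) share one grid
#' @param a,b raster stacks, or `b` a `region_mask`.
#' @return `TRUE` invisibly, or an error.
#' @export
check_aligned <- function(a, b) {
  da <- dim(a$values)[1:2]
  db <- if (inherits(b, "region_mask")) dim(b$mask) else dim(b$values)[1:2]
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %dx%d vs %dx%d", da[1L], da[2L],
                 db[1L], db[2L]))
  if (inherits(b, "raster_stack")) {
    ta <- a$transform; tb <- b$transform
    if (!isTRUE(all.equal(unlist(ta), unlist(tb))) ||
        !identical(a$crs, b$crs))
      stop("grid mismatch: transforms or CRS differ")
  }
  invisible(TRUE)
}

#' Pixel-center coordinates of a grid
#'
#' @param stack a `raster_stack` (only its shape and transform are used).
#' @return a list with matrices `x` and `y` of pixel-center coordinates.
#' @export
pixel_centers <- function(stack) {
  d <- dim(stack$values)
  tr <- stack$transform
  xs <- tr$xmin + (seq_len(d[2L]) - 0.5) * tr$cell
  ys <- tr$ymax - (seq_len(d[1L]) - 0.5) * tr$cell
  list(x = matrix(xs, d[1L], d[2L], byrow = TRUE),
       y = matrix(ys, d[1L], d[2L]))
}

#' Region mask
#'
#' A boolean grid aligned to a stack, labelled with its provenance (a project
#' id, `"buffer"`, a region name, or `"matched-set"`).
#'
#' @param mask logical matrix.
#' @param label provenance label.
#' @param factor block-aggregation factor relative to the native grid (1 for
#'   native-resolution masks; >1 for masks defined on a coarsened grid, e.g.
#'   covariate-matched pixel sets).
#' @export
region_mask <- function(mask, label = "region", factor = 1L) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, label = label, factor = as.integer(factor)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> '%s': %d of %d pixels%s\n", x$label,
              sum(x$mask), length(x$mask),
              if (x$factor > 1L) sprintf(" (aggregation factor %d)", x$factor)
              else ""))
  invisible(x)
}
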