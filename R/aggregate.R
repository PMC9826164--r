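#' Block-mean aggregation of a raster stack
#'
#' Aggregates each layer onto a coarser grid by averaging `factor x factor`
#' blocks of valid fine cells. A coarse cell is nodata when fewer than
#' `min_valid` of its fine cells are valid (the 50% rule by default).
#' Trailing rows/columns that do not fill a whole block are dropped, so a
#' 30 m grid coarsened by factor 27 yields 810 m cells.
#'
#' @param stack a `raster_stack` (or a plain matrix, returned as a matrix).
#' @param factor integer aggregation factor, >= 1.
#' @param min_valid minimum fraction of valid fine cells per coarse cell.
#' @return a coarser `raster_stack` (or matrix).
#' @export
block_aggregate <- function(stack, factor, min_valid = 0.5) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be a positive integer")
  if (is.matrix(stack)) {
    return(block_aggregate_matrix(stack, factor, min_valid))
  }
  d <- dim(stack$values)
  if (factor > min(d[1:2]))
    stop(sprintf("factor %d exceeds grid extent %dx%d", factor, d[1L], d[2L]))
  layers <- lapply(seq_len(d[3L]), function(i)
    block_aggregate_matrix(stack$values[, , i], factor, min_valid))
  tr <- stack$transform
  raster_stack(layers, years = stack$years, xmin = tr$xmin, ymax = tr$ymax,
               cell = tr$cell * factor, crs = stack$crs, units = stack$units)
}

block_aggregate_matrix <- function(m, factor, min_valid = 0.5) {
  if (factor == 1L) return(m)
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  if (nr < 1L || nc < 1L)
    stop(sprintf("factor %d exceeds grid extent %dx%d", factor,
                 nrow(m), ncol(m)))
  m <- m[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  # fold rows then columns; track valid counts for the 50% rule
  valid <- !is.na(m)
  mv <- m; mv[!valid] <- 0
  fold <- function(x, f) {
    # sum consecutive groups of f rows
    dim(x) <- c(f, nrow(x) / f, ncol(x))
    colSums(x)
  }
  s <- fold(mv, factor); n <- fold(valid + 0, factor)
  s <- t(fold(t(s), factor)); n <- t(fold(t(n), factor))
  out <- s / n
  out[n < min_valid * factor * factor] <- NA
  out
}

new_time_series <- function(year, value, n_pixels, variable, units,
                            label = "") {
  ts <- data.frame(year = as.integer(year), value = value,
                   n_pixels = as.integer(n_pixels))
  attr(ts, "variable") <- variable
  attr(ts, "units") <- units
  attr(ts, "label") <- label
  class(ts) <- c("time_series", "data.frame")
  ts
}

#' Zonal time series over a mask
#'
#' Per-year mean of the stack over valid masked pixels. A region-year whose
#' valid-pixel fraction falls below `min_valid` is reported missing (`NA`),
#' never zero. The number of valid pixels is returned alongside each value.
#'
#' @param stack a `raster_stack`.
#' @param mask a `region_mask` aligned with the stack (same aggregation
#'   level).
#' @param min_valid minimum valid fraction for a year to be reported.
#' @return a `time_series` data frame with columns `year`, `value`,
#'   `n_pixels`.
#' @export
zonal_series <- function(stack, mask, min_valid = 0.5) {
  check_aligned(stack, mask)
  idx <- which(mask$mask)
  if (length(idx) == 0L) stop("empty mask")
  d <- dim(stack$values)
  v <- matrix(stack$values, d[1L] * d[2L], d[3L])[idx, , drop = FALSE]
  npix <- colSums(!is.na(v))
  value <- colMeans(v, na.rm = TRUE)
  value[npix < min_valid * length(idx) | npix == 0L] <- NA_real_
  new_time_series(stack$years, value, npix, variable = "zonal_mean",
                  units = stack$units, label = mask$label)
}

#' Zonal harvested-area fraction over a mask
#'
#' For binary (0/1/nodata) stacks: per-year (harvested valid pixels) /
#' (all valid masked pixels).
#'
#' @inheritParams zonal_series
#' @export
zonal_fraction <- function(stack, mask, min_valid = 0.5) {
  check_aligned(stack, mask)
  d <- dim(stack$values)
  sel <- matrix(stack$values, d[1L] * d[2L], d[3L])[which(mask$mask), ,
                                                    drop = FALSE]
  bad <- sel[!is.na(sel)]
  if (length(bad) && !all(bad == 0 | bad == 1))
    stop("zonal_fraction requires a binary (0/1/nodata) stack")
  ts <- zonal_series(stack, mask, min_valid = min_valid)
  attr(ts, "variable") <- "harvest_fraction"
  attr(ts, "units") <- "fraction of area/yr"
  ts
}
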