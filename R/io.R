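#' Read and write annual raster stacks
#'
#' Stacks are stored as one ESRI ASCII Grid (`.asc`) file per year, named
#' `<name>_<year>.asc`, plus a JSON sidecar `<name>.json` recording the year
#' range, CRS, units and nodata sentinel. ASCII grids are a plain-text
#' geospatial raster format with a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' row-major cell values; values round-trip bit-exactly for integer data and
#' within 1e-6 for floats.
#'
#' @param stack a `raster_stack`.
#' @param dir output directory (created if needed).
#' @param name basename for the layer files and sidecar.
#' @param nodata sentinel written for `NA` cells.
#' @return invisibly, the vector of files written.
#' @export
write_stack <- function(stack, dir, name, nodata = -9999) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$values)
  tr <- stack$transform
  header <- c(
    sprintf("ncols %d", d[2L]),
    sprintf("nrows %d", d[1L]),
    sprintf("xllcorner %.10g", tr$xmin),
    sprintf("yllcorner %.10g", tr$ymax - d[1L] * tr$cell),
    sprintf("cellsize %.10g", tr$cell),
    sprintf("NODATA_value %.10g", nodata))
  files <- character(0)
  for (i in seq_along(stack$years)) {
    v <- stack$values[, , i]
    v[is.na(v)] <- nodata
    path <- file.path(dir, sprintf("%s_%d.asc", name, stack$years[i]))
    rows <- apply(v, 1L, function(r) paste(sprintf("%.10g", r),
                                           collapse = " "))
    writeLines(c(header, rows), path)
    files <- c(files, path)
  }
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(name = name, years = stack$years, crs = stack$crs,
         units = stack$units, nodata = nodata),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sidecar))
}

read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
  }
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  list(values = m, header = hdr)
}

#' @rdname write_stack
#' @param years years the stack is declared to cover; a missing file within
#'   this range is an explicit gap error. Defaults to the sidecar's years.
#' @export
read_stack <- function(dir, name, years = NULL) {
  sidecar_path <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(sidecar_path))
    stop(sprintf("missing sidecar %s", sidecar_path))
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(years)) years <- meta$years
  years <- as.integer(years)
  paths <- file.path(dir, sprintf("%s_%d.asc", name, years))
  missing <- !file.exists(paths)
  if (any(missing))
    stop(sprintf("gap in declared year range: missing %s",
                 paste(basename(paths[missing]), collapse = ", ")))
  layers <- lapply(paths, read_asc)
  ref <- layers[[1L]]$header
  for (i in seq_along(layers)[-1L]) {
    h <- layers[[i]]$header
    same <- all(vapply(c("ncols", "nrows", "xllcorner", "yllcorner",
                         "cellsize"),
                       function(k) isTRUE(all.equal(h[[k]], ref[[k]])),
                       logical(1)))
    if (!same)
      stop(sprintf("grid mismatch in %s: transform differs from %s",
                   basename(paths[i]), basename(paths[1L])))
  }
  raster_stack(lapply(layers, `[[`, "values"), years = years,
               xmin = ref$xllcorner,
               ymax = ref$yllcorner + ref$nrows * ref$cellsize,
               cell = ref$cellsize,
               crs = meta$crs %||% "unknown", units = meta$units %||% "")
}

#' Write an extracted time series to CSV
#'
#' Columns: `region_id`, `year`, `variable`, `value`, `n_pixels`.
#' @param ts a time-series data frame from [zonal_series()] and friends.
#' @param path output CSV.
#' @param region_id provenance label for the rows.
#' @export
write_series_csv <- function(ts, path, region_id = attr(ts, "label") %||% "") {
  out <- data.frame(region_id = region_id, year = ts$year,
                    variable = attr(ts, "variable") %||% "",
                    value = ts$value, n_pixels = ts$n_pixels)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write and read project crediting documents as CSV
#'
#' Two files: `<name>_projects.csv` (one row per project: id, start_year,
#' area_ha, owner_class, region_label, baseline_stock, reported_is_total)
#' and `<name>_stocks.csv` (one row per project-year: id, year, stock,
#' stock_basis, credits).
#'
#' @param records list of `project_record`.
#' @param dir output directory.
#' @param name file basename prefix.
#' @export
write_project_documents <- function(records, dir, name = "documents") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proj <- do.call(rbind, lapply(records, function(r)
    data.frame(id = r$id, start_year = r$start_year, area_ha = r$area,
               owner_class = r$owner_class, region_label = r$region_label,
               baseline_stock = r$baseline_stock,
               reported_is_total = r$reported_is_total)))
  rows <- do.call(rbind, lapply(records, function(r) {
    yrs <- sort(unique(c(as.integer(names(r$reported_stocks)),
                         as.integer(names(r$credits_issued)))))
    data.frame(id = r$id, year = yrs,
               stock = unname(r$reported_stocks[as.character(yrs)]),
               stock_basis = if (r$reported_is_total) "total" else "AGL",
               credits = unname(r$credits_issued[as.character(yrs)]))
  }))
  utils::write.csv(proj, file.path(dir, paste0(name, "_projects.csv")),
                   row.names = FALSE)
  utils::write.csv(rows, file.path(dir, paste0(name, "_stocks.csv")),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_project_documents
#' @param polygons optional named list of project polygons to attach.
#' @export
read_project_documents <- function(dir, name = "documents", polygons = NULL) {
  proj <- utils::read.csv(file.path(dir, paste0(name, "_projects.csv")))
  rows <- utils::read.csv(file.path(dir, paste0(name, "_stocks.csv")))
  lapply(seq_len(nrow(proj)), function(i) {
    p <- proj[i, ]
    sub <- rows[rows$id == p$id, ]
    stocks <- stats::setNames(sub$stock, sub$year)
    credits <- stats::setNames(sub$credits, sub$year)
    credits <- credits[!is.na(credits)]
    project_record(
      id = p$id, polygon = polygons[[p$id]],
      start_year = p$start_year, area = p$area_ha,
      owner_class = p$owner_class, baseline_stock = p$baseline_stock,
      reported_stocks = stocks[!is.na(stocks)],
      reported_is_total = as.logical(p$reported_is_total),
      credits_issued = credits, region_label = p$region_label)
  })
}
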