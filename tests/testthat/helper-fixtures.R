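# Shared fixtures, built in code at test time.

# A small deterministic stack: values year*1000 + pixel index.
toy_stack <- function(nr = 6, nc = 6, years = 2000:2004, cell = 30,
                      units = "ton C/ha") {
  layers <- lapply(seq_along(years), function(i)
    matrix(i * 1000 + seq_len(nr * nc), nr, nc))
  raster_stack(layers, years = years, cell = cell, units = units)
}

# A compact scene configuration that keeps test scenes fast.
small_config <- function(...) {
  defaults <- list(grid_shape = c(80L, 80L),
                   n_projects = 3L,
                   project_area_range = c(15, 35),
                   project_start_years = c(2010L, 2011L, 2012L),
                   project_owner_classes = c("other", "large-timber",
                                             "large-timber"),
                   project_regions = c("coastal", "coastal", "interior"),
                   public_rows = 10L, urban_rows = 4L)
  do.call(landscape_config, utils::modifyList(defaults, list(...)))
}

# Distance from a point to the boundary of an axis-aligned rectangle,
# computed independently of the package's segment-distance code.
rect_boundary_dist <- function(px, py, xmin, xmax, ymin, ymax) {
  dx <- pmax(xmin - px, 0, px - xmax)
  dy <- pmax(ymin - py, 0, py - ymax)
  outside <- sqrt(dx^2 + dy^2)
  # for interior points: distance to the nearest edge
  inside <- pmin(px - xmin, xmax - px, py - ymin, ymax - py)
  ifelse(dx == 0 & dy == 0, inside, outside)
}
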