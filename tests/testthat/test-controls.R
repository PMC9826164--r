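# A bare template grid plus uniform land classes for control construction.
control_fixture <- function(nr = 40, nc = 40, cell = 30) {
  template <- raster_stack(matrix(0, nr, nc), years = 2000, cell = cell)
  list(template = template,
       land = matrix("private-forest", nr, nc),
       region = matrix("coastal", nr, nc))
}

proj_at <- function(xmin, xmax, ymin, ymax, id = "P1", region = "coastal") {
  area_ha <- (xmax - xmin) * (ymax - ymin) / 1e4
  project_record(id, polygon = rect_polygon(xmin, xmax, ymin, ymax, id = id),
                 start_year = 2012, area = area_ha, region_label = region)
}

test_that("buffer controls form a ring verified by a distance oracle", {
  fx <- control_fixture()
  p <- proj_at(450, 750, 450, 750)  # 10x10 pixel block in the middle
  spec <- control_spec("buffer", buffer_width = 150)
  cs <- buffer_control(p, fx$land, list(p), fx$template, spec)

  ctr <- pixel_centers(fx$template)
  d_oracle <- rect_boundary_dist(as.vector(ctr$x), as.vector(ctr$y),
                                 450, 750, 450, 750)
  inside <- as.vector(ctr$x) > 450 & as.vector(ctr$x) < 750 &
    as.vector(ctr$y) > 450 & as.vector(ctr$y) < 750
  expected <- matrix(!inside & d_oracle <= 150, 40, 40)
  expect_identical(cs$mask$mask, expected)
  expect_equal(cs$n_pixels, sum(expected))

  # mask area grows with buffer width
  widths <- c(60, 150, 300, 600)
  sizes <- sapply(widths, function(w)
    buffer_control(p, fx$land, list(p), fx$template,
                   control_spec("buffer", buffer_width = w))$n_pixels)
  expect_true(all(diff(sizes) > 0))
})

test_that("buffer controls honor exclusions and adjacency", {
  fx <- control_fixture()
  p <- proj_at(450, 750, 450, 750)
  # fully surrounded by public land: empty control is an error
  pub <- fx$land; pub[] <- "public"
  expect_error(buffer_control(p, pub, list(p), fx$template,
                              control_spec("buffer", buffer_width = 150)),
               "wider buffer")

  # adjacent second project is excluded from the first project's buffer
  p2 <- proj_at(780, 930, 450, 750, id = "P2")
  spec <- control_spec("buffer", buffer_width = 150)
  solo <- buffer_control(p, fx$land, list(p), fx$template, spec)
  both <- buffer_control(p, fx$land, list(p, p2), fx$template, spec)
  m2 <- rasterize_polygons(p2$polygon, fx$template)$mask
  # counting oracle: pixels lost are exactly the buffer pixels inside P2
  expect_equal(solo$n_pixels - both$n_pixels, sum(solo$mask$mask & m2))
  expect_false(any(both$mask$mask & m2))
})

test_that("region controls pool private forest with exclusion flags", {
  fx <- control_fixture()
  fx$land[1:5, ] <- "public"
  p <- proj_at(450, 750, 450, 750)
  pmask <- rasterize_polygons(p$polygon, fx$template)$mask

  cs <- region_control("coastal", fx$region, fx$land, list(p), fx$template)
  expect_false(any(cs$mask$mask & pmask))
  expect_false(any(cs$mask$mask[1:5, ]))
  expect_equal(cs$n_pixels, sum(fx$land == "private-forest") - sum(pmask))

  incl <- region_control("coastal", fx$region, fx$land, list(p),
                         fx$template,
                         control_spec("region", include_projects = TRUE))
  expect_true(all(incl$mask$mask[pmask]))  # control superset of project
  expect_error(region_control("alpine", fx$region, fx$land, list(p),
                              fx$template), "unknown region")
})

test_that("matched controls equal a brute-force Mahalanobis oracle", {
  set.seed(5)
  nr <- 10; nc <- 10
  fx <- control_fixture(nr, nc)
  covs <- list(temperature = matrix(rnorm(100, 12, 2), nr, nc),
               precipitation = matrix(rnorm(100, 1500, 300), nr, nc),
               site_class = matrix(sample(1:7, 100, TRUE), nr, nc))
  p <- proj_at(60, 120, 60, 120)  # 2x2 block
  spec <- control_spec("matched", match_resolution = 30, n_pixels = 3)
  cs <- matched_control(p, covs, fx$region, fx$land, list(p), fx$template,
                        spec)
  expect_equal(cs$n_pixels, 3L)

  # brute-force oracle: standardize over candidates, full covariance
  pmask <- rasterize_polygons(p$polygon, fx$template)$mask
  X <- cbind(as.vector(covs$temperature), as.vector(covs$precipitation),
             as.vector(covs$site_class))
  cand <- which(!as.vector(pmask))
  Z <- scale(X, colMeans(X[cand, ]), apply(X[cand, ], 2, sd))
  mu <- colMeans(Z[which(as.vector(pmask)), , drop = FALSE])
  Sm <- solve(cov(Z[cand, ]))
  d2 <- apply(Z[cand, ], 1, function(z) t(z - mu) %*% Sm %*% (z - mu))
  oracle <- sort(cand[order(d2, cand)][1:3])
  expect_identical(which(cs$mask$mask), oracle)

  # control and project never share pixels
  expect_false(any(cs$mask$mask & pmask))
})

test_that("matching is invariant to affine covariate rescaling", {
  set.seed(6)
  nr <- 12; nc <- 12
  fx <- control_fixture(nr, nc)
  covs <- list(temperature = matrix(rnorm(144, 12, 2), nr, nc),
               precipitation = matrix(rnorm(144, 1500, 300), nr, nc),
               site_class = matrix(runif(144, 1, 7), nr, nc))
  p <- proj_at(90, 180, 90, 180)
  spec <- control_spec("matched", match_resolution = 30, n_pixels = 10)
  base <- matched_control(p, covs, fx$region, fx$land, list(p),
                          fx$template, spec)
  rescaled <- covs
  rescaled$temperature <- 1.8 * covs$temperature + 32   # degF
  rescaled$precipitation <- covs$precipitation / 25.4   # inches
  again <- matched_control(p, rescaled, fx$region, fx$land, list(p),
                           fx$template, spec)
  expect_identical(which(base$mask$mask), which(again$mask$mask))
})

test_that("a planted covariate twin is recovered by matching", {
  nr <- 20; nc <- 20
  fx <- control_fixture(nr, nc)
  # project block and a disjoint twin share identical covariates
  tw <- matrix(FALSE, nr, nc); tw[3:6, 14:17] <- TRUE
  pm <- matrix(FALSE, nr, nc); pm[13:16, 3:6] <- TRUE
  set.seed(3)
  base <- matrix(rnorm(nr * nc, 10, 2), nr, nc)
  base[tw | pm] <- 25
  covs <- list(temperature = base,
               precipitation = 2 * base + 100,
               site_class = matrix(rep(1:7, length.out = nr * nc), nr, nc))
  p <- proj_at(60, 180, 120, 240)  # covers pm rows 12-15, cols 3-6
  pmask <- rasterize_polygons(p$polygon, fx$template)$mask
  expect_identical(pmask, pm)
  spec <- control_spec("matched", match_resolution = 30,
                       n_pixels = sum(tw))
  # temperature and precipitation are exactly collinear here, so the
  # documented diagonal fallback engages
  expect_warning(
    cs <- matched_control(p, covs, fx$region, fx$land, list(p), fx$template,
                          spec),
    "singular")
  recovered <- sum(cs$mask$mask & tw) / sum(tw)
  expect_gte(recovered, 0.9)
})

test_that("matched candidate with covariates equal to the project mean is selected", {
  nr <- 8; nc <- 8
  fx <- control_fixture(nr, nc)
  set.seed(8)
  covs <- list(temperature = matrix(rnorm(64, 15, 3), nr, nc),
               precipitation = matrix(rnorm(64, 1000, 100), nr, nc),
               site_class = matrix(runif(64, 1, 7), nr, nc))
  p <- proj_at(30, 90, 30, 90)
  pmask <- rasterize_polygons(p$polygon, fx$template)$mask
  for (k in names(covs)) covs[[k]][1, 8] <- mean(covs[[k]][pmask])
  cs <- matched_control(p, covs, fx$region, fx$land, list(p), fx$template,
                        control_spec("matched", match_resolution = 30,
                                     n_pixels = 1))
  expect_true(cs$mask$mask[1, 8])
  expect_equal(cs$mean_covariate_distance, 0, tolerance = 1e-9)
})
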