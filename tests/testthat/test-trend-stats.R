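ts_of <- function(years, values) data.frame(year = years, value = values)

test_that("trend recovers exact lines and percent rates", {
  tr <- trend(ts_of(2000:2009, 5 + 2 * (0:9)))
  expect_equal(tr$slope, 2)
  expect_equal(tr$slope_se, 0)

  flat <- trend(ts_of(2000:2009, rep(42, 10)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$percent_rate, 0)

  # slope 1.30 on a period-mean stock of 123.0 sits in the 1.0-1.1 %/yr band
  yrs <- 1986:2012
  tr2 <- trend(ts_of(yrs, 123 + 1.3 * (yrs - mean(yrs))))
  expect_equal(tr2$slope, 1.3)
  expect_equal(tr2$mean_value, 123)
  expect_equal(tr2$percent_rate, 100 * 1.3 / 123)
  expect_gt(tr2$percent_rate, 1.0)
  expect_lt(tr2$percent_rate, 1.1)

  # adding a constant shifts the intercept only
  tr3 <- trend(ts_of(2000:2009, 5 + 2 * (0:9) + 100))
  expect_equal(tr3$slope, tr$slope)
  expect_equal(tr3$intercept, tr$intercept + 100)

  expect_error(trend(ts_of(2000:2001, c(1, 2))), "3 years")
})

test_that("paired t across years matches the textbook formula", {
  a <- ts_of(2001:2005, c(3.2, 4.1, 2.8, 5.0, 4.4))
  b <- ts_of(2001:2005, c(2.5, 3.0, 3.1, 3.9, 3.2))
  res <- paired_across_years(a, b)
  d <- a$value - b$value
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4))
  expect_equal(res$n_pairs, 5L)
  expect_equal(res$relative_difference, 100 * mean(d) / mean(b$value))

  # antisymmetry
  rev <- paired_across_years(b, a)
  expect_equal(rev$mean_difference, -res$mean_difference)

  # identical series: t = 0, p = 1, flagged
  same <- paired_across_years(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  # constant offset: zero-variance differences flagged degenerate
  off <- paired_across_years(ts_of(2001:2005, a$value + 2), a)
  expect_true(off$degenerate)
  expect_true(is.infinite(off$t))

  expect_error(paired_across_years(ts_of(2001:2002, 1:2),
                                   ts_of(2005:2006, 1:2)), "overlap")
})

test_that("chow F equals the direct three-regression computation", {
  # one global line: no break
  line <- ts_of(2000:2011, 10 + 0.5 * (0:11))
  cw <- chow(line, 2005)
  expect_equal(cw$F, 0)
  expect_equal(cw$p, 1)

  # two noiseless segments with different slopes: p ~ 0
  kink <- ts_of(2000:2011, c(10 + 0.5 * (0:5), 13 + 3 * (1:6)))
  cwk <- chow(kink, 2005)
  expect_true(is.infinite(cwk$F))
  expect_equal(cwk$p, 0)
  expect_equal(cwk$slope_before, 0.5)
  expect_equal(cwk$slope_after, 3)

  # 12-point noisy series against an lm()-based RSS oracle
  set.seed(99)
  y <- 20 + 0.8 * (0:11) + rnorm(12)
  ts <- ts_of(2000:2011, y)
  cw2 <- chow(ts, 2005)
  rss <- function(sub) sum(resid(lm(value ~ year, data = sub))^2)
  r1 <- rss(ts[1:6, ]); r2 <- rss(ts[7:12, ]); rp <- rss(ts)
  F_oracle <- ((rp - r1 - r2) / 2) / ((r1 + r2) / (12 - 4))
  expect_equal(cw2$F, F_oracle, tolerance = 1e-10)
  expect_equal(cw2$p, pf(F_oracle, 2, 8, lower.tail = FALSE))

  # invariant to adding a constant (but not a global linear trend)
  ts_sh <- ts_of(2000:2011, y + 57)
  expect_equal(chow(ts_sh, 2005)$F, cw2$F, tolerance = 1e-9)

  expect_error(chow(line, 2001), "3 years on each side")
})

test_that("before/after windows follow the equal-period rule", {
  yrs_c <- 1986:2017
  yrs_h <- 1986:2021
  carbon <- ts_of(yrs_c, 100 + 1.2 * seq_along(yrs_c) +
                    rnorm(length(yrs_c), 0, 0.1))
  harvest <- ts_of(yrs_h, rep(c(0.01, 0.02), length.out = length(yrs_h)))

  ba <- before_after(2014, carbon, harvest,
                     carbon_end = 2017, harvest_end = 2021)
  expect_equal(ba$carbon_window, 3L)   # 2015-2017 vs 2012-2014
  expect_equal(ba$harvest_window, 7L)  # 2015-2021 vs 2008-2014
  expect_equal(ba$carbon$n, 6L)
  expect_equal(ba$carbon$breakpoint_year, 2014)
  expect_equal(ba$harvest$n_pairs, 7L)

  # too little post-start data excludes the source with a reason
  late <- before_after(2016, carbon, harvest, carbon_end = 2017,
                       harvest_end = 2021)
  expect_null(late$carbon)
  expect_match(late$reasons, "carbon", all = FALSE)
  expect_equal(late$harvest_window, 5L)
  expect_null(late$harvest)
})

test_that("species contrasts recover constructed compositions", {
  nr <- 20; nc <- 20
  total <- matrix(100, nr, nc)
  pmask <- matrix(FALSE, nr, nc); pmask[6:10, 6:10] <- TRUE
  cmask <- matrix(FALSE, nr, nc); cmask[12:16, 12:16] <- TRUE

  # single-species landscape: both fractions 100%
  mono <- list(redwood = matrix(1, nr, nc))
  sc1 <- species_contrast(mono, total, list(region_mask(pmask)),
                          list(region_mask(cmask)), "redwood")
  expect_equal(sc1$project_fraction, 100)
  expect_equal(sc1$control_fraction, 100)

  # planted 35% patch vs 20% background: contrast ~ +15 points
  tan <- matrix(0.20, nr, nc); tan[pmask] <- 0.35
  duo <- list(tanoak = tan, other = 1 - tan)
  sc2 <- species_contrast(duo, total, list(region_mask(pmask)),
                          list(region_mask(cmask)), "tanoak")
  expect_equal(sc2$project_fraction - sc2$control_fraction, 15)

  # built to emulate 30.3% in projects vs 25.4% in surroundings
  tan2 <- matrix(0.254, nr, nc); tan2[pmask] <- 0.303
  sc3 <- species_contrast(list(tanoak = tan2, other = 1 - tan2), total,
                          list(region_mask(pmask)),
                          list(region_mask(cmask)), "tanoak")
  expect_lt(abs(sc3$project_fraction - 30.3), 0.5)
  expect_lt(abs(sc3$control_fraction - 25.4), 0.5)

  expect_error(species_contrast(mono, total, list(region_mask(pmask)),
                                list(region_mask(cmask)), "ghost"),
               "not present")
})

test_that("portfolio aggregation is an area-weighted mean per year", {
  s1 <- ts_of(2000:2004, rep(1, 5))
  s3 <- ts_of(2000:2004, rep(3, 5))
  # one project: identity
  expect_equal(portfolio_aggregate(list(s1))$series$value, s1$value)
  # equal areas: plain mean
  expect_equal(portfolio_aggregate(list(s1, s3), c(1, 1))$series$value,
               rep(2, 5))
  # areas {1,2}, values {3,6} -> 5
  expect_equal(portfolio_aggregate(list(ts_of(2000, 3), ts_of(2000, 6)),
                                   c(1, 2))$series$value, 5)
  expect_warning(
    portfolio_aggregate(list(ts_of(2000:2004, 1:5), ts_of(2002:2006, 1:5))),
    "common years")
})
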