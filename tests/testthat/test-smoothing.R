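test_that("constant response yields a flat fit whose band covers the value", {
  days <- round(seq(60, 430, length.out = 20))
  dat <- expand.grid(tree_id = paste0("t", 1:3), season_day = days,
                     KEEP.OUT.ATTRS = FALSE)
  dat$count <- 5.0
  cv <- fit_phase_curve(dat, smooth_config())
  expect_lt(max(abs(cv$mean - 5)), 1e-6)
  expect_true(all(cv$lower <= 5 + 1e-6 & cv$upper >= 5 - 1e-6))
})

test_that("smoother recovers a known seasonal bump within 0.5 cells RMSE", {
  f <- function(t) 6 * exp(-((t - 85) / 30)^2)
  days <- round(seq(60, 430, length.out = 38))
  dat <- make_curve_data(f, n_trees = 5, days = days, sd = 0.5, seed = 42)
  cv <- fit_phase_curve(dat, smooth_config())
  rmse <- sqrt(mean((cv$mean - f(cv$grid))^2))
  expect_lt(rmse, 0.5)
})

test_that("too few distinct dates raises an informative error", {
  dat <- data.frame(tree_id = "t1", season_day = c(60, 70, 80),
                    count = c(1, 2, 3))
  expect_error(fit_phase_curve(dat, smooth_config(basis_dim = 10)),
               "insufficient data.*10")
})

test_that("the fit is invariant under permutation of input rows", {
  f <- function(t) 3 + 2 * sin(t / 40)
  days <- round(seq(60, 430, length.out = 25))
  dat <- make_curve_data(f, n_trees = 3, days = days, sd = 0.3, seed = 9)
  cv1 <- fit_phase_curve(dat, smooth_config())
  set.seed(1)
  cv2 <- fit_phase_curve(dat[sample(nrow(dat)), ], smooth_config())
  expect_equal(cv1$mean, cv2$mean, tolerance = 1e-10)
  expect_equal(cv1$se, cv2$se, tolerance = 1e-10)
})

test_that("an infinite penalty drives the spline to its linear limit", {
  # the cubic-regression-spline penalty annihilates straight lines, so the
  # forced-smoothness limit is the least-squares line; on a balanced design
  # its average equals the overall group mean
  f <- function(t) 4 * exp(-((t - 150) / 50)^2)
  days <- round(seq(60, 430, length.out = 30))
  dat <- make_curve_data(f, n_trees = 3, days = days, sd = 0.2, seed = 3)
  cv <- fit_phase_curve(dat, smooth_config(sp = 1e12),
                        grid = days)
  curvature <- diff(diff(cv$mean)) / mean(diff(days))^2
  # raw-data curvature is ~3e-3 at this grid spacing; the forced fit is
  # flatter by orders of magnitude and indistinguishable from the OLS line
  expect_lt(max(abs(curvature)), 1e-4)
  ols <- stats::lm(count ~ season_day, data = dat)
  expect_equal(cv$mean,
               unname(stats::predict(ols,
                 data.frame(season_day = cv$grid))),
               tolerance = 1e-3)
  expect_equal(mean(cv$mean), mean(dat$count), tolerance = 1e-6)
})

test_that("band overlap comparison finds exactly the disjoint windows", {
  grid <- 60:200
  a <- make_band(grid, mean = rep(5, length(grid)),
                 lower = rep(4, length(grid)), upper = rep(6, length(grid)),
                 group = "a")
  b_overlap <- make_band(grid, rep(6, length(grid)), rep(5, length(grid)),
                         rep(7, length(grid)), group = "b")
  expect_equal(nrow(compare_groups(a, b_overlap)), 0)

  w <- compare_groups(a, make_band(grid, rep(1.5, length(grid)),
                                   rep(1, length(grid)),
                                   rep(2, length(grid)), group = "b"))
  expect_equal(nrow(w), 1)
  expect_equal(w$start_day, 60)
  expect_equal(w$end_day, 200)
})

test_that("window endpoints are refined to the exact band-gap crossing", {
  grid <- 60:200
  # gap between b.lower and a.upper is a tent: zero at 100 and 150,
  # positive strictly inside
  tent <- pmax(0.1 * pmin(grid - 100, 150 - grid), -0.5)
  a <- make_band(grid, rep(1.5, length(grid)), rep(1, length(grid)),
                 rep(2, length(grid)), group = "a")
  b <- make_band(grid, 2 + tent + 1, 2 + tent, 2 + tent + 2, group = "b")
  w <- compare_groups(a, b)
  expect_equal(nrow(w), 1)
  expect_equal(w$start_day, 100, tolerance = 1e-9)
  expect_equal(w$end_day, 150, tolerance = 1e-9)

  # oracle: fine pointwise scan of the interpolated gap
  tt <- seq(60, 200, by = 0.01)
  gap <- stats::approx(grid, 2 + tent - 2, xout = tt)$y   # b.lower - a.upper
  scan_window <- range(tt[gap > 0])
  expect_lt(abs(w$start_day - scan_window[1]), 1)   # within one grid step
  expect_lt(abs(w$end_day - scan_window[2]), 1)

  # symmetry in the arguments
  w2 <- compare_groups(b, a)
  expect_equal(w$start_day, w2$start_day)
  expect_equal(w$end_day, w2$end_day)

  short <- make_band(60:199, rep(1, 140), rep(0.5, 140), rep(1.5, 140))
  expect_error(compare_groups(a, short), "identical grid")
})
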