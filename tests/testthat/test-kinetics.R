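test_that("cumulative entry curves add later phases onto earlier ones", {
  grid <- c(60, 70, 80)
  curves <- list(
    enlarging = make_band(grid, c(2, 1, 0), c(1, 0, -1), c(3, 2, 1)),
    thickening = make_band(grid, c(0, 1, 1), c(-1, 0, 0), c(1, 2, 2)),
    mature = make_band(grid, c(0, 0, 1), c(-1, -1, 0), c(1, 1, 2)))
  cums <- cumulative_entry_curves(curves)
  expect_equal(cums$C_E, c(2, 2, 2))
  expect_equal(cums$C_L, c(0, 1, 2))
  expect_equal(cums$C_M, c(0, 0, 1))
  # reconstruction identity where no monotonization occurred
  expect_equal(conservation_diagnostic(cums), 0)
})

test_that("monotonization is a running maximum after clipping", {
  grid <- c(60, 70, 80, 90)
  curves <- list(
    enlarging = make_band(grid, rep(0, 4), rep(-1, 4), rep(1, 4)),
    thickening = make_band(grid, rep(0, 4), rep(-1, 4), rep(1, 4)),
    mature = make_band(grid, c(0, 1.2, 1.0, 1.5), c(0, 1, 0.8, 1.3),
                       c(0, 1.4, 1.2, 1.7)))
  cums <- cumulative_entry_curves(curves)
  expect_equal(cums$C_M, c(0, 1.2, 1.2, 1.5))
  # negative fitted counts are clipped before summing
  neg <- list(
    enlarging = make_band(grid, c(-0.5, 2, 1, 0.5), rep(-1, 4), rep(3, 4)),
    thickening = make_band(grid, rep(0, 4), rep(-1, 4), rep(1, 4)),
    mature = make_band(grid, rep(0, 4), rep(-1, 4), rep(1, 4)))
  expect_equal(cumulative_entry_curves(neg)$C_E, c(0, 2, 2, 2))
})

test_that("entrance dates interpolate crossings and flag unformed cells", {
  cum <- list(grid = c(60, 70), value = c(0, 2))
  expect_equal(entrance_date(cum, 1), 65)
  expect_equal(entrance_date(cum, 2), 70)
  expect_true(is.na(entrance_date(list(grid = c(60, 70), value = c(0, 2.4)),
                                  3)))
  # already above level at grid start -> first grid time
  expect_equal(entrance_date(list(grid = c(60, 70), value = c(3, 4)), 2), 60)
})

test_that("entrance dates agree with a brute-force crossing scan", {
  set.seed(21)
  for (rep in 1:10) {
    grid <- seq(60, 160, by = 5)
    value <- cumsum(runif(length(grid), 0, 1.5))
    cum <- list(grid = grid, value = value)
    n <- floor(max(value))
    dates <- entrance_date(cum, seq_len(n))
    tt <- seq(60, 160, by = 0.01)
    vv <- stats::approx(grid, value, xout = tt)$y
    brute <- vapply(seq_len(n), function(i) tt[which(vv >= i)[1]],
                    numeric(1))
    expect_lt(max(abs(dates - brute)), 0.011)
    # monotone in cell index
    expect_true(all(diff(dates) >= -1e-12))
  }
})

test_that("residence durations and rates follow from entrance dates", {
  grid <- 60:100
  # C_E crosses 1 at 65, C_L at 75, C_M at 90
  cums <- make_cums(grid,
                    E = pmin(pmax((grid - 60) / 5, 0), 2) -
                        pmin(pmax((grid - 70) / 5, 0), 2),
                    L = pmin(pmax((grid - 70) / 5, 0), 2) -
                        pmin(pmax((grid - 85) / 5, 0), 2),
                    M = pmin(pmax((grid - 85) / 5, 0), 2))
  kin <- cell_kinetics(cums)
  expect_equal(kin$t_enl[1], 65)     # C_E = (t - 60)/5 reaches 1 at day 65
  expect_equal(kin$d_E, kin$t_thick - kin$t_enl)
  expect_equal(kin$d_T, kin$t_mature - kin$t_thick)
  expect_true(all(kin$t_enl <= kin$t_thick + 1e-9))
  expect_true(all(kin$t_thick <= kin$t_mature + 1e-9, na.rm = TRUE))
})

test_that("enlargement and wall-deposition rates divide size by duration", {
  # forced arithmetic at the magnitudes typical of a Mediterranean pine ring
  grid <- seq(60, 300, by = 1)
  E <- ifelse(grid >= 65 & grid < 85, 1, 0)
  L <- ifelse(grid >= 85 & grid < 205, 1, 0)
  M <- ifelse(grid >= 205, 1, 0)
  cums <- make_cums(grid, E, L, M)
  anatomy <- data.frame(rel_pos = 0.5, lumen_diameter = 40,
                        wall_thickness = 6)
  kin <- cell_kinetics(cums, anatomy = anatomy)
  expect_equal(kin$d_E[1], 20)
  expect_equal(kin$d_T[1], 120)
  expect_equal(kin$r_enl[1], 40 / 20)      # 2 um/day
  expect_equal(kin$r_wall[1], 6 / 120)     # 0.05 um/day
  expect_equal(kin$r_enl[1] * kin$d_E[1], 40, tolerance = 1e-12)
})

test_that("rate curves are derivatives of the cumulative curves", {
  grid <- seq(60, 160, by = 1)
  cums <- make_cums(grid, E = 0.3 * (grid - 60), L = 0 * grid, M = 0 * grid)
  cambial <- make_band(grid, rep(5, length(grid)), rep(4, length(grid)),
                       rep(6, length(grid)), phase = "cambial")
  rates <- production_rate_curves(cums, cambial)
  rE <- rates$rate[rates$kind == "rE"]
  expect_equal(rE, rep(0.3, length(grid)), tolerance = 1e-9)
  # constant pool adds nothing to the division rate
  rC <- rates$rate[rates$kind == "rC"]
  expect_equal(rC, rE, tolerance = 1e-9)

  flat <- make_cums(grid, E = rep(2, length(grid)), L = 0 * grid,
                    M = 0 * grid)
  rates_flat <- production_rate_curves(flat, cambial)
  expect_true(all(rates_flat$rate == 0))

  tiny <- make_cums(c(60, 70), E = c(0, 1), L = c(0, 0), M = c(0, 0))
  expect_error(production_rate_curves(tiny, rc_method = "entry"),
               "at least 3")
})

test_that("a growing cambial pool raises the division rate above rE", {
  grid <- seq(60, 160, by = 1)
  cums <- make_cums(grid, E = 0.2 * (grid - 60), L = 0 * grid, M = 0 * grid)
  pool <- 5 + 3 * exp(-((grid - 110) / 20)^2)
  cambial <- make_band(grid, pool, pool - 1, pool + 1, phase = "cambial")
  rates <- production_rate_curves(cums, cambial)
  rC <- rates$rate[rates$kind == "rC"]
  rE <- rates$rate[rates$kind == "rE"]
  expect_true(any(rC > rE + 0.01))
  expect_true(all(rC >= 0))
})

test_that("fit-free inversion flags entries that predate observation", {
  df <- make_counts(days = c(100, 110, 120), E = 0, L = 0, M = 0)
  df$n_enlarging <- c(2, 3, 3)
  rec <- recover_entrance_dates(df)
  enl <- rec[rec$phase == "enlarging", ]
  expect_equal(nrow(enl), 3)
  expect_true(all(enl$censored[1:2]))
  expect_equal(enl$t_est[3], 105)       # first seen at 110, midpoint of gap
})
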