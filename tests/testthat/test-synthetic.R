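test_that("cohorts replay bit-identically from the same seed", {
  cfg <- small_sim(seed = 5)
  a <- simulate_cohort(cfg, "a", 2)
  b <- simulate_cohort(cfg, "a", 2)
  expect_identical(a$cells, b$cells)

  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$tracheids, s2$tracheids)

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_counts(s1$counts, f1)
  write_counts(s2$counts, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("deterministic placement hits the configured cohort exactly", {
  groups <- list(group_params("g", total_cells = 41,
                              peaks = data.frame(day = 85, sd = 25,
                                                 weight = 1)))
  cfg <- simulation_config(groups, n_trees = 1, seed = 3)
  co <- simulate_cohort(cfg, "g", 1)
  expect_equal(nrow(co$cells), 41)
  # inverse-CDF placement: the median cell sits at the peak day
  expect_equal(stats::median(co$cells$t_enl), 85, tolerance = 1e-6)
  # timelines ordered, durations positive
  expect_true(all(diff(co$cells$t_enl) > 0))
  expect_true(all(co$cells$d_E > 0 & co$cells$d_T > 0))
})

test_that("observation assigns each cell to its current phase", {
  groups <- list(group_params("g", total_cells = 1,
                              peaks = data.frame(day = 100, sd = 1,
                                                 weight = 1),
                              d_E = c(10, 10), d_T = c(30, 30)))
  cfg <- simulation_config(groups, n_trees = 1, seed = 2)
  co <- simulate_cohort(cfg, "g", 1)
  t_enl <- co$cells$t_enl
  obs <- observe_counts(co, c(t_enl - 5, t_enl + 5, t_enl + 15, t_enl + 50),
                        n_files = 2, noise = list(type = "none"))
  phase_at <- function(day) {
    r <- obs[obs$season_day == day & obs$radial_file == 1, ]
    c(r$n_enlarging, r$n_thickening, r$n_mature)
  }
  expect_equal(phase_at(t_enl - 5), c(0, 0, 0))    # before entry
  expect_equal(phase_at(t_enl + 5), c(1, 0, 0))    # enlarging
  expect_equal(phase_at(t_enl + 15), c(0, 1, 0))   # wall thickening
  expect_equal(phase_at(t_enl + 50), c(0, 0, 1))   # mature
  # noiseless files are identical
  expect_equal(obs$n_enlarging[obs$radial_file == 1],
               obs$n_enlarging[obs$radial_file == 2])
})

test_that("counts conserve the cohort total", {
  cfg <- small_sim(seed = 9)
  co <- simulate_cohort(cfg, "a", 1)
  obs <- observe_counts(co, seq(60, 300, by = 5), 1, list(type = "none"))
  tot <- obs$n_enlarging + obs$n_thickening + obs$n_mature
  n <- nrow(co$cells)
  expect_true(all(tot <= n))
  expect_equal(tot[obs$season_day >= max(co$cells$t_mature)][1], n)
})

test_that("thinning noise keeps counts integer and below truth", {
  cfg <- small_sim(seed = 13)
  co <- simulate_cohort(cfg, "a", 1)
  set.seed(99)
  noisy <- observe_counts(co, seq(60, 300, by = 10), 3,
                          list(type = "thinning", p = 0.8))
  exact <- observe_counts(co, seq(60, 300, by = 10), 1,
                          list(type = "none"))
  for (col in c("n_enlarging", "n_thickening", "n_mature")) {
    expect_true(all(noisy[[col]] == round(noisy[[col]])))
    truth_by_day <- exact[[col]][match(noisy$season_day, exact$season_day)]
    expect_true(all(noisy[[col]] <= truth_by_day))
  }
  expect_error(simulation_config(cfg$groups,
                                 noise = list(type = "thinning", p = 0)),
               "detection probability")
})

test_that("the default drought-experiment scenario is internally coherent", {
  cfg <- default_paper_scenario(seed = 1)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(length(cfg$groups), 3)
  expect_equal(cfg$n_trees, 5)
  expect_equal(range(cfg$sampling_days), c(60, 430))
  expect_equal(cfg$groups$control$total_cells -
                 cfg$groups$exclusion$total_cells, 15)
  expect_equal(nrow(cfg$groups$exclusion$peaks), 1)
  expect_equal(nrow(cfg$groups$control$peaks), 2)
  # latewood walls: drought-capped 6 um vs 8 um elsewhere
  expect_equal(cfg$groups$exclusion$CWT[2], 6)
  expect_equal(cfg$groups$control$CWT[2], 8)
  expect_error(group_params("x", 10,
                            peaks = data.frame(day = 85, sd = 10,
                                               weight = 0.7)),
               "sum to 1")
})
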