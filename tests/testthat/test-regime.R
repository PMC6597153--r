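test_that("two-means detection flags a bimodal cloud and not a unimodal one", {
  withr::with_seed(17, {
    P <- rep(seq(525, 1475, by = 50), times = 8)
    n <- length(P)
    run <- rep(1:8, each = n / 8)
    # below 1000 mm odd runs land on the low branch, even runs on the high
    branch <- ifelse(run %% 2 == 0, 0.6, 0.1)
    bimodal <- tibble::tibble(
      rainfall = P, run = run, S = 0, F = 0,
      T = ifelse(P < 1000, branch, 0.6) + rnorm(n, sd = 0.02)
    )
    unimodal <- bimodal
    unimodal$T <- 0.35 + rnorm(n, sd = 0.03)
  })
  hit <- detect_bistability(bimodal, min_points = 8)
  expect_gt(nrow(hit), 0)
  expect_lte(min(hit$P_low), 600)
  expect_gte(max(hit$P_high), 950)
  miss <- detect_bistability(unimodal, min_points = 8)
  expect_equal(nrow(miss), 0)
  one_run <- bimodal[bimodal$run == 1, ]
  expect_error(detect_bistability(one_run), "at least 2 runs")
})

test_that("ensemble runs are reproducible and share the forcing grid", {
  g <- small_grid()
  sc <- ensemble_scatter("forest", z = Inf, n_runs = 2, seeds = c(4, 9),
                         grid = g, t_end = 200)
  expect_tibble(sc, c("rainfall", "run", "seed", "S", "T", "F"))
  expect_equal(nrow(sc), 2 * g$n)
  expect_true(all(sc$F >= 0 & sc$F <= 1))
  # a one-run ensemble reproduces a direct simulate call bit for bit
  one <- ensemble_scatter("forest", z = Inf, n_runs = 1, seeds = 4,
                          grid = g, t_end = 200)
  ic <- random_initial_condition(g, "forest", seed = 4)
  direct <- simulate_model(ic, forcing_linear(), variant = "forest",
                           grid = g, times = c(0, 200))
  # the scatter projects integrator undershoot onto [0, 1]
  expect_identical(one$F, pmin(pmax(unname(final_profile(direct)$F), 0), 1))
})

test_that("cycle statistics recover known periods and classifications", {
  reg <- synthetic_cycle_series(period = 120, t_end = 2000, seed = 1)
  cs <- cycle_statistics(reg, value_col = "value")
  expect_equal(cs$classification, "regular_cycle")
  expect_equal(cs$mean_period, 120, tolerance = 1 / 120)
  expect_equal(cs$amplitude, 0.4, tolerance = 0.01)

  irr <- synthetic_cycle_series(period = 120, t_end = 4000,
                                period_jitter = 0.25, seed = 2)
  ci <- cycle_statistics(irr, value_col = "value")
  expect_equal(ci$classification, "irregular_cycle")
  expect_gt(ci$period_cv, 0.1)

  flat <- tibble::tibble(time = 0:500, value = 0.4)
  cf <- cycle_statistics(flat, value_col = "value")
  expect_equal(cf$classification, "steady")
  expect_equal(cf$n_peaks, 0)
  expect_tibble(glance(cs), c("classification", "period_cv"))
})

test_that("peak detection honours the prominence filter", {
  t <- seq(0, 100, by = 0.1)
  v <- 0.3 + 0.2 * sin(2 * pi * t / 20) + 0.01 * sin(2 * pi * t / 1.3)
  peaks_strict <- treefronts:::find_prominent_peaks(v, 0.1)
  expect_equal(length(peaks_strict), 5)
  peaks_loose <- treefronts:::find_prominent_peaks(v, 0.005)
  expect_gt(length(peaks_loose), 20)
})

test_that("space-time export preserves snapshots and writes CSV", {
  g <- small_grid()
  ss <- forest_steady_states(2000)
  u_plus <- max(ss$root[ss$stability == "stable"])
  sim <- simulate_model(rep(u_plus, g$n), forcing_homogeneous(2000),
                        variant = "forest", grid = g, t_end = 100,
                        n_out = 5)
  st <- spacetime_export(sim, "F")
  expect_equal(dim(st$values), c(5L, g$n))
  # a steady run has time-invariant columns
  expect_lt(max(abs(sweep(st$values, 2, st$values[1, ]))), 1e-6)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_spacetime_csv(st, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(nrow(back), 5)
  expect_equal(ncol(back), g$n + 1)
  # single-snapshot export stays a one-row matrix
  sim1 <- simulate_model(rep(u_plus, g$n), forcing_homogeneous(2000),
                         variant = "forest", grid = g, times = c(0, 1))
  expect_error(spacetime_export(sim1, "T"), "not stored")
})
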