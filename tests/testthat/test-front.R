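test_that("an exact logistic profile is recovered to high precision", {
  prof <- synthetic_logistic_profile(A = 0.8, k = 0.05, P_f = 1400)
  for (loss in c("soft_l1", "ls")) {
    fit <- fit_logistic_front(prof, loss = loss)
    expect_equal(fit$A, 0.8, tolerance = 1e-6)
    expect_equal(fit$k, 0.05, tolerance = 1e-6)
    expect_equal(fit$P_f, 1400, tolerance = 1e-6)
    expect_equal(fit$R2, 1, tolerance = 1e-10)
  }
  td <- tidy(fit_logistic_front(prof))
  expect_tibble(td, c("term", "estimate"))
  expect_equal(td$term, c("A", "k", "P_f"))
})

test_that("gradient extraction agrees with the fit on a clean sigmoid", {
  prof <- synthetic_logistic_profile(P = seq(0, 3000, by = 5), A = 0.8,
                                     k = 0.05, P_f = 1400)
  grad <- front_from_gradient(prof)
  expect_lt(abs(grad$P_f - 1400), 5)   # within one grid spacing
  expect_equal(grad$method, "gradient")
  expect_true(is.na(grad$R2))
})

test_that("ties on a linear ramp resolve to the lowest rainfall", {
  # slopes are exactly representable so every centered difference ties
  prof <- tibble::tibble(P = seq(0, 3000, by = 100), F = (0:30) / 32)
  grad <- front_from_gradient(prof)
  expect_equal(grad$P_f, 100)   # first interior node
})

test_that("flat and undersized profiles are rejected", {
  flat <- tibble::tibble(P = seq(0, 3000, by = 10), F = 0.31)
  expect_error(fit_logistic_front(flat), "no front")
  expect_error(front_from_gradient(tibble::tibble(P = 1:2, F = c(0, 1))),
               "at least 3")
  expect_error(fit_logistic_front(tibble::tibble(P = 1:4, F = c(0, 1, 0, 1))),
               "at least 5")
})

test_that("front rainfall is recovered within 5 mm under cover noise", {
  errs <- vapply(1:100, function(seed) {
    prof <- synthetic_logistic_profile(P = seq(0, 3000, by = 10), A = 0.8,
                                       k = 0.05, P_f = 1400,
                                       noise_sd = 0.02, seed = seed)
    fit_logistic_front(prof)$P_f - 1400
  }, numeric(1))
  expect_lt(max(abs(errs)), 5)
})

test_that("wave-speed estimation needs a homogeneous run and a front inside", {
  g <- build_grid(0, 200, 2)
  ic <- random_initial_condition(g, "forest", seed = 1)
  het <- simulate_model(ic, forcing_linear(), variant = "forest", grid = g,
                        t_end = 10, n_out = 3)
  expect_error(estimate_wave_speed(het), "homogeneous")

  # a front that leaves the domain is reported, not silently extrapolated
  ss <- forest_steady_states(2000)
  u_plus <- max(ss$root[ss$stability == "stable"])
  u0 <- ifelse(g$x < 180, 0, u_plus)   # forest sliver near the right edge
  sim <- simulate_model(u0, forcing_homogeneous(1250), variant = "forest",
                        grid = g, t_end = 2000, n_out = 21)
  expect_error(estimate_wave_speed(sim), "left the domain")
})

test_that("a retreating and an advancing front have opposite speed signs", {
  g <- build_grid(0, 400, 1)
  ss <- forest_steady_states(2000)
  u_plus <- max(ss$root[ss$stability == "stable"])
  u0 <- ifelse(g$x < 200, 0, u_plus)
  sim_wet <- simulate_model(u0, forcing_homogeneous(1700),
                            variant = "forest", grid = g, t_end = 300,
                            n_out = 31)
  sim_dry <- simulate_model(u0, forcing_homogeneous(1300),
                            variant = "forest", grid = g, t_end = 300,
                            n_out = 31)
  expect_lt(estimate_wave_speed(sim_wet)$speed, 0)   # forest invades
  expect_gt(estimate_wave_speed(sim_dry)$speed, 0)   # forest retreats
})
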