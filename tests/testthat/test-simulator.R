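test_that("the grid reproduces the study discretization", {
  g <- build_grid()
  expect_equal(g$n, 4479L)           # round(3000 / 0.67) + 1
  expect_equal(g$dx, 0.67)
  # linear forcing assigns rainfall equal to the coordinate
  expect_equal(rainfall_at(forcing_linear(), g), g$x)
  # minimal two-node grid is valid
  expect_equal(build_grid(0, 10, 10)$n, 2L)
  expect_error(build_grid(0, 100, 0), "dx")
  expect_error(build_grid(100, 0, 1), "x1")
})

test_that("mirror-boundary Laplacian is exact on known fields", {
  expect_equal(laplacian_noflux(rep(0.4, 20), 0.5), rep(0, 20))
  # linear field: zero in the interior, mirror values at the ends
  u <- seq(0, 1, length.out = 5)
  lap <- laplacian_noflux(u, 2)
  expect_equal(lap[2:4], rep(0, 3))
  expect_equal(lap[1], 2 * (u[2] - u[1]) / 4)
  expect_equal(lap[5], 2 * (u[4] - u[5]) / 4)
  # flux conservation: the trapezoid-weighted sum telescopes to zero
  withr::with_seed(3, u <- runif(50))
  w <- c(0.5, rep(1, 48), 0.5)
  expect_lt(abs(sum(w * laplacian_noflux(u, 0.25)) * 0.25^2), 1e-12)
})

test_that("random initial conditions are seeded, simplex-valued draws", {
  g <- small_grid()
  ic1 <- random_initial_condition(g, "forest-savanna", seed = 11)
  ic2 <- random_initial_condition(g, "forest-savanna", seed = 11)
  expect_identical(ic1, ic2)
  expect_true(all(ic1$S >= 0 & ic1$S <= 1))
  expect_true(all(ic1$S + ic1$T + ic1$F <= 1 + 1e-12))
  ic3 <- random_initial_condition(g, "forest-savanna", seed = 12)
  expect_gt(mean(ic1$F != ic3$F), 0.99)
  # forest variant has a single field
  expect_named(random_initial_condition(g, "forest", seed = 1), c("x", "F"))
})

test_that("an equilibrium initial state stays stationary", {
  g <- small_grid()
  ss <- forest_steady_states(2000)
  u_plus <- max(ss$root[ss$stability == "stable"])
  sim <- simulate_model(rep(u_plus, g$n), forcing_homogeneous(2000),
                        variant = "forest", grid = g, t_end = 200,
                        n_out = 5)
  expect_lt(max(abs(sim$fields$F - u_plus)), 1e-6)
  expect_lt(sim$final_residual, 1e-8)
})

test_that("pure diffusion conserves mass to near machine precision", {
  g <- small_grid()
  ic <- random_initial_condition(g, "forest", seed = 5)
  sim <- simulate_model(ic, forcing_homogeneous(1e6), inert_params(),
                        "forest", g, t_end = 500, n_out = 6,
                        rtol = 1e-10, atol = 1e-12)
  w <- c(0.5, rep(1, g$n - 2), 0.5)   # the invariant of the mirror stencil
  masses <- sim$fields$F %*% w
  expect_lt(max(abs(masses - masses[1])), 1e-8)
})

test_that("the full model preserves the simplex from random starts", {
  g <- build_grid(0, 3000, 5)
  for (seed in 1:3) {
    ic <- random_initial_condition(g, "forest-savanna", seed = seed)
    sim <- simulate_model(ic, forcing_linear(), fs_params(),
                          "forest-savanna", g, times = c(0, 2500, 5000))
    for (f in c("S", "T", "F")) {
      expect_gte(min(sim$fields[[f]]), -1e-6)
      expect_lte(max(sim$fields[[f]]), 1 + 1e-6)
    }
    total <- sim$fields$S + sim$fields$T + sim$fields$F
    expect_lte(max(total), 1 + 1e-6)
  }
})

test_that("homogeneous forcing preserves mirror symmetry of the solution", {
  g <- build_grid(0, 200, 2)   # odd node count
  half <- withr::with_seed(9, runif(g$n %/% 2))
  u0 <- c(half, 0.5, rev(half))
  sim <- simulate_model(u0, forcing_homogeneous(1800), variant = "forest",
                        grid = g, t_end = 300, n_out = 4)
  final <- sim$fields$F[4, ]
  expect_lt(max(abs(final - rev(final))), 1e-9)
})

test_that("run_to_steady flags convergence honestly", {
  g <- small_grid()
  # an equilibrium start converges immediately under any tolerance
  ss <- forest_steady_states(2000)
  u_plus <- max(ss$root[ss$stability == "stable"])
  quick <- run_to_steady(rep(u_plus, g$n), forcing_homogeneous(2000),
                         variant = "forest", grid = g, tol_steady = Inf)
  expect_true(quick$converged)
  expect_equal(length(quick$times), 1L)
  # the cycling regime never settles
  ic <- random_initial_condition(g, "forest-savanna", seed = 2)
  cyc <- run_to_steady(ic, forcing_homogeneous(1500),
                       high_savanna_params(), "forest-savanna", g,
                       tol_steady = 1e-8, t_max = 1500, window = 500,
                       rtol = 1e-6, atol = 1e-9)
  expect_false(cyc$converged)
  expect_gt(cyc$final_residual, 1e-8)
})

test_that("halving dx moves the pinned front by less than one cell", {
  # window around the Maxwell point with a step initial condition
  fit_at <- function(dx) {
    g <- front_window_grid(dx)
    ss <- forest_steady_states(1500)
    u_plus <- max(ss$root[ss$stability == "stable"])
    u0 <- ifelse(g$x < 1411.57, 0, u_plus)
    sim <- run_to_steady(u0, forcing_linear(), variant = "forest", grid = g,
                         t_max = 6000, window = 2000)
    front_from_gradient(final_profile(sim))$P_f
  }
  pf_coarse <- fit_at(0.67)
  pf_fine <- fit_at(0.335)
  expect_lt(abs(pf_coarse - pf_fine), 0.67)
})

test_that("state validation catches malformed inputs", {
  g <- small_grid()
  expect_error(simulate_model(rep(0.5, g$n - 1), forcing_linear(),
                              variant = "forest", grid = g),
               "does not match")
  bad <- random_initial_condition(g, "forest", seed = 1)
  bad$F[3] <- NA
  expect_error(simulate_model(bad, forcing_linear(), variant = "forest",
                              grid = g), "finite")
  ic <- random_initial_condition(g, "forest", seed = 1)
  expect_error(simulate_model(ic, forcing_linear(),
                              variant = "forest-savanna", grid = g),
               "lacks field")
})

test_that("nonspatial runs report all three species with absences at zero", {
  ts <- simulate_nonspatial(c(S = 0.2, T = 0.1), P = 1000,
                            variant = "savanna-only", t_end = 50,
                            n_out = 11)
  expect_tibble(ts, c("time", "S", "T", "F"))
  expect_true(all(ts$F == 0))
  expect_true(all(ts$S >= 0 & ts$S <= 1))
})
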