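p <- fs_params()
nd <- nondimensionalize(p)

test_that("forest steady states bracket the bistable structure", {
  # dry: only grassland
  dry <- forest_steady_states(800)
  expect_equal(dry$root, 0)
  expect_equal(dry$stability, "stable")
  # bistable: grassland, saddle, forest — stability alternates
  wet <- forest_steady_states(2000)
  expect_equal(nrow(wet), 3)
  expect_equal(wet$stability, c("stable", "unstable", "stable"))
  expect_true(all(diff(wet$root) > 0))
  # the forest root satisfies its defining equation
  u_plus <- max(wet$root)
  g <- nd_alpha(2000, Inf, nd) - nd_beta(2000, nd) * u_plus -
    treefronts:::nd_f(u_plus, 2000, nd)
  expect_lt(abs(g), 1e-10)
})

test_that("the bistable rainfall range is a single verified interval", {
  rng <- bistable_range(p)
  expect_equal(nrow(rng), 1)
  expect_lt(rng$P_low, rng$P_high)
  # interior points are bistable, exterior points are not
  inside <- forest_steady_states((rng$P_low + rng$P_high) / 2)
  expect_equal(sum(inside$stability == "stable"), 2)
  below <- forest_steady_states(rng$P_low - 20)
  expect_equal(sum(below$stability == "stable" & below$root > 0), 0)
  # at full human impact the range shifts/narrows
  rng0 <- bistable_range(p, z = 0)
  expect_false(isTRUE(all.equal(rng0$P_low, rng$P_low, tolerance = 1e-3)))
  expect_gt(rng0$P_low, rng$P_low)
})

test_that("delta_V matches a quadrature oracle and signals monostability", {
  for (P in c(1300, 1700, 2500)) {
    roots <- treefronts:::nontrivial_roots(P, Inf, nd)
    u_plus <- max(roots)
    oracle <- -stats::integrate(function(u) nondim_reaction(u, P, Inf, nd),
                                0, u_plus, rel.tol = 1e-12)$value
    expect_equal(delta_V(P, Inf, nd), oracle, tolerance = 1e-9)
  }
  expect_error(delta_V(800, Inf, nd), "no front")
})

test_that("the Maxwell point is the zero of delta_V inside the bistable range", {
  mp <- maxwell_point(Inf, p)
  expect_lt(abs(mp$deltaV_at_root), 1e-8)
  rng <- bistable_range(p)
  expect_gt(mp$P_MP, rng$P_low)
  expect_lt(mp$P_MP, rng$P_high)
  # forest invades above, retreats below
  expect_lt(delta_V(mp$P_MP + 50, Inf, nd), 0)
  expect_gt(delta_V(mp$P_MP - 50, Inf, nd), 0)
})

test_that("the Maxwell point decreases with distance from cultivation", {
  zs <- c(0, 500, 1000, 2000, 5000)
  curve <- maxwell_curve(zs, p)
  expect_true(all(diff(curve$P_MP) < 0))
  # large-z asymptote equals the no-impact value
  far <- maxwell_point(5e4, p)$P_MP
  expect_equal(far, maxwell_point(Inf, p)$P_MP, tolerance = 1e-6)
})

test_that("full-model equilibria satisfy the reaction to tight tolerance", {
  eq <- full_model_steady_states(1500, params = fs_params())
  expect_gt(nrow(eq), 0)
  for (i in seq_len(nrow(eq))) {
    r <- reaction_terms(eq$S[i], eq$T[i], eq$F[i], 1500, Inf, fs_params())
    expect_lt(max(abs(unlist(r))), 1e-8)
  }
  # no rainfall: only the extinction state, and it is stable
  eq0 <- full_model_steady_states(0, params = fs_params())
  expect_equal(nrow(eq0), 1)
  expect_true(eq0$stable)
  expect_equal(c(eq0$S, eq0$T, eq0$F), c(0, 0, 0))
})

test_that("the high-savanna regime at 1500 mm cycles instead of settling", {
  eq <- full_model_steady_states(1500, params = high_savanna_params(),
                                 probe_cycle = TRUE)
  expect_equal(sum(eq$stable), 0)
  cyc <- attr(eq, "cycle")
  expect_true(cyc$detected)
  expect_gt(cyc$amplitude, 0.1)
})

test_that("savanna subsystem interval endpoints bracket a stability change", {
  pars <- high_savanna_params()
  rng <- savanna_subsystem_range(pars, P_grid = seq(300, 900, by = 50))
  expect_gt(nrow(rng), 0)
  n_stable <- function(P) {
    sum(full_model_steady_states(P, params = pars,
                                 variant = "savanna-only")$stable)
  }
  expect_gte(n_stable((rng$P_low[1] + rng$P_high[1]) / 2), 2)
  expect_lt(n_stable(rng$P_high[nrow(rng)] + 25), 2)
})
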