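p <- fs_params()

test_that("growth rate saturates, clamps at zero and crosses where expected", {
  # asymptote: the ceiling r_Y
  expect_equal(growth_rate(1e6, "F", p), p$r_F)
  expect_equal(growth_rate(1e6, "S", p), p$r_S)
  # clamp: exp(a_RF) > 1 forces zero at P = 0
  expect_equal(growth_rate(0, "F", p), 0)
  # zero crossing of 1 - exp(-kP + a) at P = a/k
  P0 <- p$a_RF / p$k_RF
  expect_equal(growth_rate(P0, "F", p), 0)
  expect_gt(growth_rate(P0 + 1, "F", p), 0)
  # monotone nondecreasing on a dense grid
  g <- growth_rate(seq(0, 4000, by = 5), "F", p)
  expect_true(all(diff(g) >= 0))
  expect_error(growth_rate(2000, "T", p))
  expect_error(growth_rate(-5, "F", p), ">= 0")
})

test_that("mortality decays to the baseline and is nonincreasing", {
  expect_equal(mortality_rate(1e6, "F", p), p$m_Fo)
  expect_equal(mortality_rate(0, "F", p), p$m_Fo + exp(-2.15))
  # savanna mortality with the default zero offset: m_So + exp(-k_MS P)
  expect_equal(mortality_rate(500, "S", p), p$m_So + exp(-0.008 * 500))
  # adults share the sapling parameters
  expect_equal(mortality_rate(731, "T", p), mortality_rate(731, "S", p))
  m <- mortality_rate(seq(0, 4000, by = 5), "F", p)
  expect_true(all(diff(m) <= 0))
})

test_that("fire threshold is clamped-linear and vanishes at high rainfall", {
  expect_equal(fire_threshold(0, p), p$Y_c0)
  expect_equal(fire_threshold(1000, p), 0.56 - 1.43e-4 * 1000)
  P_zero <- -p$Y_c0 / p$k_c
  expect_equal(fire_threshold(P_zero, p), 0)
  expect_equal(fire_threshold(P_zero + 500, p), 0)
  yc <- fire_threshold(seq(0, 4500, by = 5), p)
  expect_true(all(diff(yc) <= 0))
})

test_that("burnt fraction is a capped, decreasing Hill function of woody cover", {
  # open grassland burns at the cap 1/tau
  expect_equal(burnt_fraction(0, 0, 1000, p), 1 / p$tau)
  # half-saturation exactly at the fire-spread threshold
  yc <- fire_threshold(1000, p)
  expect_equal(burnt_fraction(yc / 2, yc / 2, 1000, p), 1 / (2 * p$tau))
  # closed forest at P = 0: direct evaluation of the Hill form
  expect_equal(burnt_fraction(0, 1, 0, p),
               (1 / 2.7) * 0.56^4 / (0.56^4 + 1))
  # strictly decreasing in woody cover while the threshold is positive
  w <- seq(0, 1, length.out = 200)
  phi <- burnt_fraction(w / 2, w / 2, 1500, p)
  expect_true(all(diff(phi) < 0))
  # degenerate threshold: no fire for any positive cover
  expect_equal(burnt_fraction(0.3, 0.2, 4000, p), 0)
  expect_equal(burnt_fraction(0, 0, 4000, p), 1 / p$tau)
  expect_error(burnt_fraction(-0.1, 0.2, 1000, p))
})

test_that("deforestation decays exponentially with distance", {
  expect_equal(deforestation_rate(0, p), p$c_def)
  expect_equal(deforestation_rate(Inf, p), 0)
  half <- log(2) / p$k_C
  expect_equal(deforestation_rate(half, p), p$c_def / 2)
})

test_that("reaction terms match an independent hand evaluation", {
  # extinction is an equilibrium
  d0 <- reaction_terms(0, 0, 0, P = 1700, z = 300, p)
  expect_equal(unlist(d0), c(dS = 0, dT = 0, dF = 0))

  # term-by-term oracle at a generic interior state
  S <- 0.12; T <- 0.28; F <- 0.31; P <- 1350; z <- 800
  phi <- (1 / p$tau) * fire_threshold(P, p)^4 /
    (fire_threshold(P, p)^4 + (T + F)^4)
  R_S <- max(0, p$r_S * (1 - exp(-p$k_RS * P + p$a_RS)))
  R_F <- max(0, p$r_F * (1 - exp(-p$k_RF * P + p$a_RF)))
  M_S <- p$m_So + exp(-p$k_MS * P + p$a_MS)
  M_F <- p$m_Fo + exp(-p$k_MF * P + p$a_MF)
  C <- p$c_def * exp(-p$k_C * z)
  expected <- c(
    dS = R_S * (1 - S - T - F) * T - p$Q0 * (1 - p$h * phi) * S - M_S * S -
      R_F * S * F,
    dT = p$Q0 * (1 - p$h * phi) * S - M_S * T - R_F * T * F,
    dF = R_F * (1 - F) * F - p$b * phi * F - M_F * F - C * F
  )
  got <- reaction_terms(S, T, F, P, z, p)
  expect_equal(unlist(got), expected)
  expect_error(reaction_terms(1.2, 0, 0, 1000, Inf, p), "\\[0, 1\\]")
})

test_that("the S = T = 0 reduction equals the forest model exactly", {
  u <- seq(0, 1, length.out = 41)
  for (P in c(900, 1500, 2600)) {
    full <- reaction_terms(rep(0, 41), rep(0, 41), u, P = P, z = 1000, p)$dF
    forest <- vapply(u, function(ui) {
      treefronts:::nonspatial_rhs(ui, P, 1000, p, "forest")
    }, numeric(1))
    expect_equal(full, forest, tolerance = 1e-14)
  }
})
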