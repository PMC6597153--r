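# shared fixtures: small grids and parameter regimes used across tests

small_grid <- function(x1 = 300, dx = 2) build_grid(0, x1, dx)

# subdomain around the no-impact Maxwell point, used for cheap front tests
front_window_grid <- function(dx = 0.67) build_grid(1200, 1600, dx)

high_savanna_params <- function() fs_params(r_S = 0.13, Q0 = 0.2, tau = 1)

# parameters that switch every reaction term off (at very high rainfall the
# residual mortality exp(-k P) vanishes numerically), leaving pure diffusion
inert_params <- function() {
  fs_params(r_S = 0, r_F = 0, m_So = 0, m_Fo = 0, Q0 = 0, c_def = 0, b = 0)
}

expect_tibble <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
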