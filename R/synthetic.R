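#' Synthetic logistic front profile
#'
#' Generates an exact (optionally noisy) sigmoid cover-versus-rainfall
#' profile with known parameters, used to validate the front-extraction
#' routines: `F(P) = A / (1 + exp(-k (P - P_f))) + noise`.
#'
#' @param P rainfall values, mm/y.
#' @param A upper asymptote (cover fraction).
#' @param k front steepness, 1/mm.
#' @param P_f front rainfall, mm/y.
#' @param noise_sd standard deviation of additive Gaussian noise (0 = exact).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @return a tibble with columns `P`, `F`, carrying the true parameters as
#'   attribute `"truth"`.
#' @export
synthetic_logistic_profile <- function(P = seq(0, 3000, by = 5), A = 0.8,
                                       k = 0.05, P_f = 1400, noise_sd = 0,
                                       seed = NULL) {
  f <- A / (1 + exp(-k * (P - P_f)))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required for noisy profiles",
                            call. = FALSE)
    f <- f + withr::with_seed(seed, stats::rnorm(length(P), sd = noise_sd))
  }
  out <- tibble::tibble(P = P, F = f)
  attr(out, "truth") <- list(A = A, k = k, P_f = P_f, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Synthetic oscillatory time series
#'
#' Piecewise-sinusoidal cover series with one peak per cycle and known
#' cycle lengths, for validating peak detection and the regular/irregular
#' classification. With `period_jitter = 0` every cycle has exactly the
#' nominal period (a regular cycle); positive jitter draws each cycle length
#' from `period * (1 + jitter * N(0,1))` (an irregular cycle).
#'
#' @param t_end record length, years.
#' @param dt sampling step, years.
#' @param period nominal cycle length, years.
#' @param amplitude peak-to-trough amplitude (cover).
#' @param baseline trough level (cover).
#' @param period_jitter relative jitter of individual cycle lengths.
#' @param seed integer seed (used when `period_jitter > 0`).
#' @return a tibble with columns `time`, `value`, with the generating
#'   parameters in attribute `"truth"`.
#' @export
synthetic_cycle_series <- function(t_end = 3000, dt = 1, period = 120,
                                   amplitude = 0.4, baseline = 0.2,
                                   period_jitter = 0, seed = 1) {
  n_cycles <- ceiling(t_end / period) + 3
  lengths <- if (period_jitter > 0) {
    withr::with_seed(seed, {
      pmax(period * (1 + period_jitter * stats::rnorm(n_cycles)),
           0.2 * period)
    })
  } else {
    rep(period, n_cycles)
  }
  bounds <- c(0, cumsum(lengths))
  t <- seq(0, t_end, by = dt)
  cyc <- findInterval(t, bounds, rightmost.closed = TRUE)
  s <- (t - bounds[cyc]) / lengths[cyc]          # phase within cycle in [0,1)
  v <- baseline + amplitude * (1 - cos(2 * pi * s)) / 2
  out <- tibble::tibble(time = t, value = v)
  attr(out, "truth") <- list(period = period, amplitude = amplitude,
                             baseline = baseline,
                             period_jitter = period_jitter, seed = seed,
                             cycle_bounds = bounds)
  out
}

#' Write synthetic test fixtures
#'
#' Writes reproducible CSV fixtures (exact and noisy logistic profiles,
#' regular and irregular cycle series) plus a JSON manifest of the true
#' generating parameters.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling all noisy components.
#' @return invisibly, a character vector of the files written.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    logistic_exact = synthetic_logistic_profile(A = 0.8, k = 0.05,
                                                P_f = 1400),
    logistic_noisy = synthetic_logistic_profile(A = 0.8, k = 0.05,
                                                P_f = 1400, noise_sd = 0.02,
                                                seed = seed),
    cycle_regular = synthetic_cycle_series(period = 120, seed = seed),
    cycle_irregular = synthetic_cycle_series(period = 120,
                                             period_jitter = 0.25,
                                             seed = seed)
  )
  files <- character(0)
  manifest <- list(seed = seed)
  for (nm in names(specs)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(specs[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
    truth <- attr(specs[[nm]], "truth")
    truth$cycle_bounds <- NULL
    manifest[[nm]] <- truth
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mf))
}
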