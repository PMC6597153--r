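#' Rainfall response of the growth rate
#'
#' Cover expansion rate `R_Y(P) = max[0, r_Y (1 - exp(-k_RY P + a_RY))]` for
#' savanna saplings (`"S"`) or forest trees (`"F"`). Saturating in rainfall:
#' zero below the rainfall where the exponential balances the offset
#' (`P = a_RY / k_RY`), approaching the ceiling `r_Y` in wet climates.
#'
#' @param P mean annual rainfall, mm/y (vectorized, must be >= 0).
#' @param species `"S"` or `"F"`. Savanna adults have no growth term of their
#'   own (they recruit from saplings), so `"T"` is not accepted here.
#' @param params an [fs_params()] object.
#' @return growth rate(s), 1/y.
#' @examples
#' growth_rate(2000, "F", fs_params())
#' @export
growth_rate <- function(P, species = c("S", "F"), params = fs_params()) {
  species <- match.arg(species)
  check_rainfall(P)
  r <- switch(species, S = params$r_S, F = params$r_F)
  k <- switch(species, S = params$k_RS, F = params$k_RF)
  a <- switch(species, S = params$a_RS, F = params$a_RF)
  pmax(0, r * (1 - exp(-k * P + a)))
}

#' Rainfall response of the drought mortality rate
#'
#' Cover reduction rate `M_Y(P) = m_Yo + exp(-k_MY P + a_MY)`, decreasing in
#' rainfall towards the baseline `m_Yo`. Savanna adults (`"T"`) share the
#' sapling parameters (`m_To = m_So`, `k_MT = k_MS`, `a_MT = a_MS`).
#'
#' @inheritParams growth_rate
#' @param species `"S"`, `"T"` or `"F"`.
#' @return mortality rate(s), 1/y.
#' @export
mortality_rate <- function(P, species = c("S", "T", "F"),
                           params = fs_params()) {
  species <- match.arg(species)
  check_rainfall(P)
  m0 <- switch(species, S = params$m_So, T = params$m_So, F = params$m_Fo)
  k <- switch(species, S = params$k_MS, T = params$k_MS, F = params$k_MF)
  a <- switch(species, S = params$a_MS, T = params$a_MS, F = params$a_MF)
  m0 + exp(-k * P + a)
}

#' Fire-spread threshold
#'
#' Percolation-style critical woody cover `Y_c(P) = max[0, Y_c0 + k_c P]`
#' below which the grassy fuel layer is connected enough for fire to spread.
#' Clamped-linear and nonincreasing in rainfall; identically zero beyond
#' `P = -Y_c0 / k_c`.
#'
#' @inheritParams growth_rate
#' @return threshold cover fraction(s) in `[0, Y_c0]`.
#' @export
fire_threshold <- function(P, params = fs_params()) {
  check_rainfall(P)
  pmax(0, params$Y_c0 + params$k_c * P)
}

#' Burnt-area fraction
#'
#' Fraction of area burnt per year,
#' `Phi(T, F; P) = (1/tau) Y_c^n / (Y_c^n + (T+F)^n)` with Hill exponent
#' `n = n_fire`. A sigmoid, strictly decreasing function of woody cover
#' `T + F`, capped at `1/tau` in open grassland. In the degenerate case
#' `Y_c(P) = 0` the limit is used: no fire for any positive woody cover, and
#' the open-grassland cap at `T + F = 0`.
#'
#' @param T savanna adult tree cover in `[0, 1]` (vectorized).
#' @param F forest tree cover in `[0, 1]` (vectorized).
#' @inheritParams growth_rate
#' @return burnt fraction(s) per year, in `[0, 1/tau]`.
#' @export
burnt_fraction <- function(T, F, P, params = fs_params()) {
  if (any(T < 0) || any(F < 0)) stop("cover fractions must be >= 0",
                                     call. = FALSE)
  check_rainfall(P)
  n <- params$n_fire
  m <- max(length(T), length(F), length(P))
  w <- rep_len(T, m) + rep_len(F, m)
  ycn <- rep_len(fire_threshold(P, params), m)^n
  out <- numeric(m)
  pos <- ycn > 0
  out[pos] <- ycn[pos] / (ycn[pos] + w[pos]^n)
  out[!pos] <- as.numeric(w[!pos] == 0)
  out / params$tau
}

#' Deforestation rate near human cultivation
#'
#' Forest removal rate `C(z) = c_def exp(-k_C z)` as a function of distance
#' `z` (meters) from cultivated areas. Beyond a few kilometers the impact is
#' negligible; `z = Inf` gives the natural (unimpacted) regime.
#'
#' @param z distance from human cultivation, m (vectorized, >= 0; `Inf`
#'   allowed).
#' @inheritParams growth_rate
#' @return removal rate(s), 1/y.
#' @export
deforestation_rate <- function(z, params = fs_params()) {
  if (any(z < 0)) stop("z must be >= 0", call. = FALSE)
  ifelse(is.infinite(z), 0, params$c_def * exp(-params$k_C * z))
}

#' Reaction terms of the forest-savanna model
#'
#' Evaluates the local (non-diffusive) dynamics of savanna sapling cover `S`,
#' savanna adult cover `T` and forest cover `F`:
#' saplings establish in grass in proportion to adult cover, are recruited
#' into adults at rate `Q0 (1 - h Phi)` (fire suppresses recruitment), and
#' both savanna stages are outcompeted by forest; forest grows logistically,
#' and is removed by fire (`b Phi`), drought mortality and deforestation.
#' With `S = T = 0` the `F` equation reduces exactly to the single-species
#' forest model.
#'
#' @param S,T,F cover fractions in `[0, 1]` (vectorized, same length).
#' @inheritParams growth_rate
#' @param z distance from human cultivation, m.
#' @return a tibble with columns `dS`, `dT`, `dF` (rates, 1/y).
#' @examples
#' reaction_terms(0.1, 0.2, 0.3, P = 1500, z = Inf)
#' @export
reaction_terms <- function(S, T, F, P, z = Inf, params = fs_params()) {
  for (v in list(S, T, F)) {
    if (any(v < 0 | v > 1)) stop("cover fractions must lie in [0, 1]",
                                 call. = FALSE)
  }
  phi <- burnt_fraction(T, F, P, params)
  R_S <- growth_rate(P, "S", params)
  R_F <- growth_rate(P, "F", params)
  M_S <- mortality_rate(P, "S", params)
  M_T <- mortality_rate(P, "T", params)
  M_F <- mortality_rate(P, "F", params)
  C <- deforestation_rate(z, params)
  G <- 1 - S - T - F
  recr <- params$Q0 * (1 - params$h * phi)
  tibble::tibble(
    dS = R_S * G * T - recr * S - M_S * S - R_F * S * F,
    dT = recr * S - M_T * T - R_F * T * F,
    dF = R_F * (1 - F) * F - params$b * phi * F - M_F * F - C * F
  )
}

check_rainfall <- function(P) {
  if (any(P < 0)) stop("rainfall P must be >= 0", call. = FALSE)
  invisible(P)
}
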