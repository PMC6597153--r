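#' Nondimensionalize the forest model
#'
#' Rescaling time by `t -> b t / tau` in the forest model (the
#' forest-savanna system restricted to `S = T = 0`) turns every rate into a
#' dimensionless group and gives the fire term a unit coefficient:
#' \deqn{u_t = \alpha(P, z) u - \beta(P) u^2 - u f(u; P) + \delta_F
#'   \nabla^2 u,}
#' with `alpha = rho r(P) - mu m(P) - gamma c(z) - mu0`, `beta = rho r(P)`,
#' `r(P) = max[0, 1 - exp(-kappa_r P + a)]`, `m(P) = exp(-kappa_m P)`,
#' `c(z) = exp(-k_C z)` and the fire response
#' `f(u; P) = u_c^n / (u_c^n + u^n)` with `u_c(P) = max(0, u_c0 + k_c P)`.
#'
#' The five rate groups are `rho = r_F tau / b`, `mu = exp(a_MF) tau / b`,
#' `mu0 = m_Fo tau / b`, `gamma = c_def tau / b` and
#' `delta_F = D_F tau / b` — the unique scaling under which `f` appears with
#' coefficient 1. The clamp in `r(P)` mirrors the clamp of the dimensional
#' growth response so that the dimensional and nondimensional reactions have
#' identical roots at every `(P, z)`.
#'
#' @param params an [fs_params()] object with `b > 0`, `tau > 0`.
#' @return an object of class `nd_params` with fields `rho`, `mu`, `mu0`,
#'   `gamma`, `deltaF`, `kappa_r`, `kappa_m`, `a`, `u_c0`, `k_c`, plus the
#'   carried-over `k_C` (needed by `c(z)`) and `n_fire`.
#' @seealso [nondim_reaction()], [potential()], [maxwell_point()]
#' @examples
#' nd <- nondimensionalize(fs_params())
#' nd$rho   # ~ 1.174
#' @export
nondimensionalize <- function(params = fs_params()) {
  stopifnot(inherits(params, "fs_params"))
  if (params$b <= 0 || params$tau <= 0) {
    stop("nondimensionalization requires b > 0 and tau > 0", call. = FALSE)
  }
  s <- params$tau / params$b
  structure(list(
    rho = params$r_F * s,
    mu = exp(params$a_MF) * s,
    mu0 = params$m_Fo * s,
    gamma = params$c_def * s,
    deltaF = params$D_F * s,
    kappa_r = params$k_RF,
    kappa_m = params$k_MF,
    a = params$a_RF,
    u_c0 = params$Y_c0,
    k_c = params$k_c,
    k_C = params$k_C,
    n_fire = params$n_fire
  ), class = "nd_params")
}

#' @export
print.nd_params <- function(x, ...) {
  cat("<nd_params> nondimensional forest-model constants\n")
  v <- unlist(unclass(x))
  cat(paste0("  ", format(names(v), width = 7), " = ", format(v)),
      sep = "\n")
  invisible(x)
}

# dimensionless rainfall/impact responses -----------------------------------

nd_r <- function(P, nd) pmax(0, 1 - exp(-nd$kappa_r * P + nd$a))

nd_m <- function(P, nd) exp(-nd$kappa_m * P)

nd_c <- function(z, nd) ifelse(is.infinite(z), 0, exp(-nd$k_C * z))

nd_uc <- function(P, nd) pmax(0, nd$u_c0 + nd$k_c * P)

# fire response f(u; P); the degenerate threshold u_c = 0 is handled as the
# pointwise limit: 0 for u > 0, 1 at u = 0. u and P recycle to a common
# length.
nd_f <- function(u, P, nd) {
  n <- nd$n_fire
  m <- max(length(u), length(P))
  u <- rep_len(u, m)
  ucn <- rep_len(nd_uc(P, nd), m)^n
  out <- numeric(m)
  pos <- ucn > 0
  out[pos] <- ucn[pos] / (ucn[pos] + u[pos]^n)
  out[!pos] <- as.numeric(u[!pos] == 0)
  out
}

# derivative of f with respect to u (zero in the degenerate u_c = 0 case)
nd_f_du <- function(u, P, nd) {
  n <- nd$n_fire
  m <- max(length(u), length(P))
  u <- rep_len(u, m)
  ucn <- rep_len(nd_uc(P, nd), m)^n
  out <- numeric(m)
  pos <- ucn > 0
  out[pos] <- -n * u[pos]^(n - 1) * ucn[pos] / (ucn[pos] + u[pos]^n)^2
  out
}

#' Linear coefficients of the nondimensional forest model
#'
#' `nd_alpha()` is the net low-cover growth factor
#' `alpha(P, z) = rho r(P) - mu m(P) - gamma c(z) - mu0` and `nd_beta()` the
#' self-limitation coefficient `beta(P) = rho r(P)`. The grassland state
#' `u = 0` is linearly stable exactly when `alpha < 1` (since `f(0) = 1`).
#'
#' @param P rainfall, mm/y (vectorized).
#' @param z distance from cultivation, m.
#' @param nd an [nondimensionalize()] object.
#' @return numeric vector.
#' @export
nd_alpha <- function(P, z = Inf, nd = nondimensionalize()) {
  nd$rho * nd_r(P, nd) - nd$mu * nd_m(P, nd) - nd$gamma * nd_c(z, nd) - nd$mu0
}

#' @rdname nd_alpha
#' @export
nd_beta <- function(P, nd = nondimensionalize()) {
  nd$rho * nd_r(P, nd)
}

#' Nondimensional forest-model reaction
#'
#' The local dynamics `alpha(P, z) u - beta(P) u^2 - u f(u; P)` of the
#' rescaled forest model (time unit `tau / b`). Its roots coincide exactly
#' with the equilibria of the dimensional forest model at the same `(P, z)`.
#'
#' @param u forest cover in `[0, 1]` (vectorized).
#' @inheritParams nd_alpha
#' @return reaction rate(s) in dimensionless time.
#' @export
nondim_reaction <- function(u, P, z = Inf, nd = nondimensionalize()) {
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]", call. = FALSE)
  nd_alpha(P, z, nd) * u - nd_beta(P, nd) * u^2 - u * nd_f(u, P, nd)
}

# d/du of the nondimensional reaction (analytic)
nondim_reaction_du <- function(u, P, z = Inf, nd = nondimensionalize()) {
  nd_alpha(P, z, nd) - 2 * nd_beta(P, nd) * u - nd_f(u, P, nd) -
    u * nd_f_du(u, P, nd)
}
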