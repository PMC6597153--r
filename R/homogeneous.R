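#' Steady states of the nonspatial forest model
#'
#' Finds all equilibria of the forest-model reaction at a single `(P, z)`:
#' the grassland state `u = 0` plus every root of
#' `g(u) = alpha - beta u - f(u)` on `(0, 1]`, located by a sign-change scan
#' (2000 points) with bracketed bisection polishing. Stability follows the
#' sign of the reaction derivative at each root; along a scalar reaction the
#' labels alternate.
#'
#' @param P rainfall, mm/y (scalar).
#' @param z distance from human cultivation, m (scalar; `Inf` = no impact).
#' @param params an [fs_params()] object.
#' @param n_scan number of scan points on `u` in `(0, 1]`.
#' @return a tibble with columns `P`, `z`, `root` (ascending) and
#'   `stability` (`"stable"` / `"unstable"`).
#' @examples
#' forest_steady_states(2000)   # grassland, saddle, forest
#' forest_steady_states(800)    # only grassland
#' @export
forest_steady_states <- function(P, z = Inf, params = fs_params(),
                                 n_scan = 2000) {
  nd <- nondimensionalize(params)
  roots <- c(0, nontrivial_roots(P, z, nd, n_scan = n_scan))
  dN <- nondim_reaction_du(roots, P, z, nd)
  tibble::tibble(
    P = P, z = z, root = roots,
    stability = ifelse(dN < 0, "stable", "unstable")
  )
}

# roots of g(u) = alpha - beta*u - f(u) on (0, 1], sorted ascending
nontrivial_roots <- function(P, z, nd, n_scan = 2000) {
  g <- function(u) {
    nd_alpha(P, z, nd) - nd_beta(P, nd) * u - nd_f(u, P, nd)
  }
  us <- seq(1e-9, 1, length.out = n_scan)
  gv <- g(us)
  idx <- which(gv[-1] * gv[-n_scan] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(g, c(us[i], us[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  # exact zeros on scan points (measure-zero but cheap to keep correct)
  roots <- sort(unique(c(roots, us[gv == 0])))
  roots
}

# is the grassland state an attractor at (P, z)?  Linear stability requires
# alpha < 1 (f(0) = 1); once the fire threshold u_c(P) reaches 0 the saddle
# collides with 0 and the grassland basin vanishes, so it is treated as
# unstable from there on.
grassland_stable <- function(P, z, nd) {
  nd_alpha(P, z, nd) < 1 & nd_uc(P, nd) > 0
}

#' Rainfall range of forest-grassland bistability
#'
#' Scans rainfall for coexistence of a stable grassland state (`u = 0`) and
#' a stable high-cover forest state in the nonspatial forest model, then
#' polishes each boundary by bisection. The lower endpoint is the
#' saddle-node where the forest branch appears; the upper endpoint is where
#' the grassland state loses its basin (the saddle collides with zero as the
#' fire-spread threshold reaches 0).
#'
#' @inheritParams forest_steady_states
#' @param P_grid rainfall values (mm/y) spanning the candidate range.
#' @param tol bisection tolerance on the endpoints, mm.
#' @return a tibble with columns `P_low`, `P_high`, one row per bistable
#'   interval (zero rows if the model is nowhere bistable on the grid).
#' @examples
#' bistable_range(fs_params())   # roughly 1150-3900 mm without impact
#' @export
bistable_range <- function(params = fs_params(), z = Inf,
                           P_grid = seq(400, 4400, by = 10), tol = 0.5) {
  nd <- nondimensionalize(params)
  bistable_at <- function(P) {
    if (!grassland_stable(P, z, nd)) return(FALSE)
    r <- nontrivial_roots(P, z, nd, n_scan = 1200)
    any(nondim_reaction_du(r, P, z, nd) < 0)
  }
  flags <- vapply(P_grid, bistable_at, logical(1))
  if (!any(flags)) {
    return(tibble::tibble(P_low = numeric(0), P_high = numeric(0)))
  }
  refine <- function(P_out, P_in) {
    # bisect between a non-bistable and a bistable rainfall
    while (abs(P_in - P_out) > tol) {
      mid <- (P_in + P_out) / 2
      if (bistable_at(mid)) P_in <- mid else P_out <- mid
    }
    (P_in + P_out) / 2
  }
  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- list()
  for (j in which(runs$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    lo <- if (i0 == 1) P_grid[1] else refine(P_grid[i0 - 1], P_grid[i0])
    hi <- if (i1 == length(P_grid)) P_grid[i1] else
      refine(P_grid[i1 + 1], P_grid[i1])
    out[[length(out) + 1]] <- tibble::tibble(P_low = lo, P_high = hi)
  }
  dplyr::bind_rows(out)
}

#' Potential of the homogeneous forest model
#'
#' The nondimensional forest model is a gradient system,
#' `u_t = -dV/du + Laplacian(u)`, with
#' \deqn{V(u) = \beta u^3/3 - \alpha u^2/2 + \frac{u_c^2}{2}
#'   \arctan[(u/u_c)^2],}
#' the arctan term being the closed form of the fire integral
#' `int_0^u s u_c^4 / (u_c^4 + s^4) ds` available for the default Hill
#' exponent `n_fire = 4`. For other exponents that integral is evaluated by
#' adaptive quadrature.
#' `V(0) = 0` by construction, and `dV/du = -[alpha - beta u - f(u)] u`.
#'
#' @param u forest cover in `[0, 1]` (vectorized).
#' @param P rainfall, mm/y (scalar).
#' @param z distance from human cultivation, m (scalar).
#' @param nd an [nondimensionalize()] object.
#' @return potential value(s), dimensionless.
#' @export
potential <- function(u, P, z = Inf, nd = nondimensionalize()) {
  al <- nd_alpha(P, z, nd)
  be <- nd_beta(P, nd)
  uc <- nd_uc(P, nd)
  fire_int <- if (uc == 0) {
    rep(0, length(u))  # f vanishes for u > 0 in the degenerate limit
  } else if (nd$n_fire == 4) {
    (uc^2 / 2) * atan((u / uc)^2)
  } else {
    n <- nd$n_fire
    vapply(u, function(ui) {
      if (ui == 0) return(0)
      stats::integrate(function(s) s * uc^n / (uc^n + s^n), 0, ui,
                       rel.tol = 1e-12, abs.tol = 1e-14)$value
    }, numeric(1))
  }
  be * u^3 / 3 - al * u^2 / 2 + fire_int
}

#' Potential difference between forest and grassland
#'
#' `delta_V(P, z) = V(u_+) - V(u_-)` with `u_- = 0` (grassland) and `u_+`
#' the high-cover forest state. With the front oriented grassland-to-forest
#' (`u(-Inf) = 0`, `u(+Inf) = u_+`, moving frame `xi = x - c t`), the wave
#' speed satisfies `sign(c) = sign(delta_V)`: negative `delta_V` means the
#' forest state has the lower potential and invades.
#'
#' @inheritParams potential
#' @return the potential difference (scalar).
#' @export
delta_V <- function(P, z = Inf, nd = nondimensionalize()) {
  roots <- nontrivial_roots(P, z, nd)
  stable <- roots[nondim_reaction_du(roots, P, z, nd) < 0]
  if (!length(stable)) {
    stop("no front exists: the model is not bistable at P = ", P,
         ", z = ", z, call. = FALSE)
  }
  u_plus <- max(stable)
  potential(u_plus, P, z, nd) - potential(0, P, z, nd)
}

#' Maxwell point of the homogeneous forest model
#'
#' The rainfall at which the forest and grassland states have equal
#' potential, so that a front between them is stationary (`c = 0`). Found as
#' the bracketed root of `P -> delta_V(P, z)` inside the bistable rainfall
#' range (shrunk by 1 mm at each end to avoid the degenerate saddle-node
#' endpoints).
#'
#' @inheritParams forest_steady_states
#' @param tol root tolerance on the rainfall, mm.
#' @return a one-row tibble with columns `z`, `P_MP` (mm/y),
#'   `deltaV_at_root` (residual), `bracket_lo`, `bracket_hi`.
#' @examples
#' maxwell_point()          # no-impact Maxwell point
#' maxwell_point(z = 1000)  # shifted to wetter conditions near cultivation
#' @export
maxwell_point <- function(z = Inf, params = fs_params(), tol = 1e-6) {
  nd <- nondimensionalize(params)
  rng <- bistable_range(params, z = z)
  if (nrow(rng) == 0) {
    stop("no bistable rainfall range at z = ", z,
         "; the Maxwell point is undefined", call. = FALSE)
  }
  # use the widest interval should there be more than one
  rng <- rng[which.max(rng$P_high - rng$P_low), ]
  lo <- rng$P_low + 1
  hi <- rng$P_high - 1
  f_lo <- delta_V(lo, z, nd)
  f_hi <- delta_V(hi, z, nd)
  if (f_lo * f_hi > 0) {
    stop("delta_V does not change sign over the bistable range [",
         round(lo), ", ", round(hi), "] mm at z = ", z, call. = FALSE)
  }
  root <- stats::uniroot(function(P) delta_V(P, z, nd), c(lo, hi),
                         f.lower = f_lo, f.upper = f_hi, tol = tol)
  tibble::tibble(z = z, P_MP = root$root,
                 deltaV_at_root = delta_V(root$root, z, nd),
                 bracket_lo = lo, bracket_hi = hi)
}

#' @rdname maxwell_point
#' @param z_values vector of distances (m) at which to evaluate the Maxwell
#'   point.
#' @return `maxwell_curve()` returns one row per `z`.
#' @export
maxwell_curve <- function(z_values, params = fs_params(), tol = 1e-6) {
  purrr::map_dfr(z_values, function(zz) maxwell_point(zz, params, tol))
}
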