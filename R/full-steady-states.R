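#' Equilibria of the nonspatial forest-savanna model
#'
#' Multi-start damped-Newton search for equilibria of the three-species
#' reaction (diffusion off) at a single `(P, z)`, with local stability from
#' the eigenvalues of the numerically differentiated 3x3 Jacobian.
#' Equilibria are classified as `"stable node"` (all eigenvalues real and
#' negative), `"stable focus"` (negative real parts, complex pair) or
#' `"unstable"`. Optionally, a limit cycle is probed by integrating the ODE
#' from perturbed equilibria (or from the simplex centroid when no
#' equilibrium is stable) and testing for sustained oscillation after a
#' transient.
#'
#' @param P rainfall, mm/y (scalar).
#' @param z distance from human cultivation, m.
#' @param params an [fs_params()] object.
#' @param variant `"forest-savanna"` for the full (S, T, F) system or
#'   `"savanna-only"` for the savanna subsystem with `F = 0` fixed.
#' @param n_starts number of random starting points in the simplex.
#' @param seed integer seed making the starting points reproducible.
#' @param probe_cycle if `TRUE`, run the oscillation probe and attach the
#'   result as attribute `"cycle"` (a list with `detected`, `amplitude`).
#' @return a tibble with columns `S`, `T`, `F`, `max_re_lambda`, `stable`,
#'   `class`; equilibria satisfy `max |reaction| < 1e-10`.
#' @examples
#' full_model_steady_states(1500, params = fs_params(r_S = 0.13, Q0 = 0.2,
#'                                                   tau = 1))
#' @export
full_model_steady_states <- function(P, z = Inf, params = fs_params(),
                                     variant = c("forest-savanna",
                                                 "savanna-only"),
                                     n_starts = 40, seed = 1,
                                     probe_cycle = FALSE) {
  variant <- match.arg(variant)
  k <- if (variant == "forest-savanna") 3L else 2L
  fn <- function(v) nonspatial_rhs(v, P, z, params, variant)

  starts <- withr::with_seed(seed, {
    m <- matrix(stats::runif(n_starts * k), ncol = k)
    m / pmax(1, rowSums(m))   # project into the simplex
  })
  starts <- rbind(rep(0, k), rep(0.8 / k, k), starts)

  sols <- list()
  for (i in seq_len(nrow(starts))) {
    v <- newton_nd(fn, starts[i, ])
    if (is.null(v)) next
    v[abs(v) < 1e-12] <- 0
    if (any(v < -1e-9) || any(v > 1 + 1e-9) || sum(v) > 1 + 1e-6) next
    key <- paste(round(v, 7), collapse = "|")
    if (!key %in% names(sols)) sols[[key]] <- pmin(pmax(v, 0), 1)
  }

  rows <- purrr::map_dfr(sols, function(v) {
    J <- numeric_jacobian(fn, v)
    ev <- eigen(J, only.values = TRUE)$values
    max_re <- max(Re(ev))
    cls <- if (max_re >= 0) "unstable" else if (max(abs(Im(ev))) > 1e-9) {
      "stable focus"
    } else "stable node"
    full <- if (k == 3L) v else c(v, 0)
    tibble::tibble(S = full[1], T = full[2], F = full[3],
                   max_re_lambda = max_re,
                   stable = max_re < 0, class = cls)
  })
  rows <- dplyr::arrange(rows, .data$T, .data$F)

  if (probe_cycle) {
    attr(rows, "cycle") <- probe_limit_cycle(rows, P, z, params, variant,
                                             seed = seed)
  }
  rows
}

# reaction right-hand side for the nonspatial system; `v` need not lie in
# the simplex during Newton iterations, so the raw formulae are used.
nonspatial_rhs <- function(v, P, z, params, variant) {
  if (variant == "forest") {
    F <- v[1]
    yc <- fire_threshold(P, params)
    ycn <- yc^params$n_fire
    phi <- if (yc > 0) ycn / (ycn + max(F, 0)^params$n_fire) / params$tau else
      as.numeric(F <= 0) / params$tau
    R_F <- growth_rate(P, "F", params)
    return(R_F * (1 - F) * F - params$b * phi * F -
             mortality_rate(P, "F", params) * F -
             deforestation_rate(z, params) * F)
  }
  if (variant == "forest-savanna") {
    S <- v[1]; T <- v[2]; F <- v[3]
  } else {
    S <- v[1]; T <- v[2]; F <- 0
  }
  w <- pmax(T, 0) + pmax(F, 0)
  yc <- fire_threshold(P, params)
  ycn <- yc^params$n_fire
  phi <- if (yc > 0) ycn / (ycn + w^params$n_fire) / params$tau else
    as.numeric(w == 0) / params$tau
  R_S <- growth_rate(P, "S", params)
  R_F <- growth_rate(P, "F", params)
  recr <- params$Q0 * (1 - params$h * phi)
  dS <- R_S * (1 - S - T - F) * T - recr * S -
    mortality_rate(P, "S", params) * S - R_F * S * F
  dT <- recr * S - mortality_rate(P, "T", params) * T - R_F * T * F
  if (variant == "forest-savanna") {
    dF <- R_F * (1 - F) * F - params$b * phi * F -
      mortality_rate(P, "F", params) * F - deforestation_rate(z, params) * F
    c(dS, dT, dF)
  } else {
    c(dS, dT)
  }
}

# damped Newton with numeric Jacobian; returns NULL on failure
newton_nd <- function(fn, v0, tol = 1e-12, max_iter = 60) {
  v <- v0
  r <- fn(v)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) return(v)
    J <- numeric_jacobian(fn, v)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      v_new <- v + lam * step
      r_new <- fn(v_new)
      if (all(is.finite(r_new)) &&
          (max(abs(r_new)) < max(abs(r)) || lam < 1e-4)) break
      lam <- lam / 2
    }
    if (lam < 1e-4 && max(abs(r_new)) >= max(abs(r))) return(NULL)
    v <- v_new; r <- r_new
  }
  if (max(abs(r)) < tol) v else NULL
}

numeric_jacobian <- function(fn, v, h = 1e-7) {
  k <- length(v)
  f0 <- fn(v)
  J <- matrix(0, length(f0), k)
  for (j in seq_len(k)) {
    vp <- v; vm <- v
    vp[j] <- vp[j] + h
    vm[j] <- vm[j] - h
    J[, j] <- (fn(vp) - fn(vm)) / (2 * h)
  }
  J
}

# integrate the nonspatial ODE from perturbed equilibria and test for
# sustained oscillation of adult savanna cover after a transient
probe_limit_cycle <- function(eq, P, z, params, variant, seed = 1,
                              t_end = 4000, amp_tol = 0.02) {
  starts <- list()
  if (nrow(eq) > 0) {
    for (i in seq_len(nrow(eq))) {
      v <- c(S = eq$S[i], T = eq$T[i], F = eq$F[i])
      starts[[i]] <- pmin(pmax(v + 0.02, 0), 1)
    }
  }
  starts[[length(starts) + 1]] <- c(S = 0.2, T = 0.2, F = 0.2)
  detected <- FALSE; amp <- 0
  for (s0 in starts) {
    ts <- simulate_nonspatial(s0, P = P, z = z, params = params,
                              variant = if (variant == "savanna-only")
                                "savanna-only" else "forest-savanna",
                              t_end = t_end, n_out = 2001)
    tail_ts <- ts[ts$time > 0.5 * t_end, ]
    a <- max(tail_ts$T) - min(tail_ts$T)
    if (a > amp_tol) { detected <- TRUE; amp <- max(amp, a) }
  }
  list(detected = detected, amplitude = amp)
}

#' Rainfall range of savanna-woodland bistability (savanna subsystem)
#'
#' Scans rainfall for coexistence of two stable equilibria of the savanna
#' subsystem (forest trees absent, `F = 0`): the low-cover savanna state and
#' the high-cover woodland state. Interval endpoints are polished by
#' bisection on the count of stable equilibria.
#'
#' @param params an [fs_params()] object; the regime of interest uses
#'   `fs_params(r_S = 0.13, Q0 = 0.2, tau = 1)`.
#' @param P_grid rainfall scan values, mm/y.
#' @param z distance from human cultivation, m.
#' @param n_starts,seed passed to [full_model_steady_states()].
#' @param tol endpoint bisection tolerance, mm.
#' @return tibble with columns `P_low`, `P_high`, one row per interval.
#' @export
savanna_subsystem_range <- function(params, P_grid = seq(100, 3200, by = 50),
                                    z = Inf, n_starts = 25, seed = 1,
                                    tol = 5) {
  n_stable <- function(P) {
    eq <- full_model_steady_states(P, z, params, variant = "savanna-only",
                                   n_starts = n_starts, seed = seed)
    sum(eq$stable)
  }
  flags <- vapply(P_grid, function(P) n_stable(P) >= 2, logical(1))
  if (!any(flags)) {
    return(tibble::tibble(P_low = numeric(0), P_high = numeric(0)))
  }
  refine <- function(P_out, P_in) {
    while (abs(P_in - P_out) > tol) {
      mid <- (P_in + P_out) / 2
      if (n_stable(mid) >= 2) P_in <- mid else P_out <- mid
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
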