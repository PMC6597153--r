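#' Stationary front of the heterogeneous forest model
#'
#' Solves the boundary-value problem `0 = R(u; P(x), z) + D_F u_xx` on the
#' grid (central differences, mirror no-flux boundaries) by damped Newton
#' iteration, starting from a guess with a single interface — typically a
#' converged [run_to_steady()] profile or a previous front at a nearby `z`.
#' The Jacobian is tridiagonal (reaction derivative on the diagonal plus the
#' discrete Laplacian) and is solved directly.
#'
#' @param u_guess initial profile: numeric vector on the grid, or a data
#'   frame with a forest-cover column `F`.
#' @param forcing an [forcing_linear()] object (the front position is read
#'   in rainfall units via `P(x) = x`).
#' @param params an [fs_params()] object.
#' @param grid an [build_grid()] object.
#' @param tol Newton tolerance on `max |residual|`, 1/y.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `stationary_front`: list with `z`, `u_star`,
#'   `grid`, `forcing`, `params`, `P_f` (gradient-argmax front rainfall),
#'   `newton_residual`, `iterations`.
#' @seealso [continue_branch()], [stability()]
#' @export
solve_stationary_front <- function(u_guess, forcing, params = fs_params(),
                                   grid = build_grid(dx = 2),
                                   tol = 1e-10, max_iter = 30) {
  stopifnot(inherits(forcing, "fs_forcing"), inherits(grid, "fs_grid"))
  u <- if (is.data.frame(u_guess)) u_guess$F else as.numeric(u_guess)
  stopifnot(length(u) == grid$n)
  P <- rainfall_at(forcing, grid)
  z <- forcing$z

  res_fun <- function(u) {
    forest_reaction(u, P, z, params) + params$D_F * laplacian_noflux(u, grid$dx)
  }
  r <- res_fun(u)
  hist <- max(abs(r))
  it <- 0
  while (max(abs(r)) > tol && it < max_iter) {
    it <- it + 1
    J <- front_jacobian_tridiag(u, P, z, params, grid$dx)
    step <- solve_tridiag(J$lower, J$diag, J$upper, -r)
    lam <- 1
    repeat {
      u_new <- u + lam * step
      r_new <- res_fun(u_new)
      if (max(abs(r_new)) < max(abs(r)) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6 && max(abs(r_new)) >= max(abs(r))) {
      stop("Newton iteration stalled; residual history: ",
           paste(format(hist, digits = 3), collapse = " -> "), call. = FALSE)
    }
    u <- u_new; r <- r_new
    hist <- c(hist, max(abs(r)))
  }
  if (max(abs(r)) > tol) {
    stop("Newton did not converge in ", max_iter, " iterations; residuals: ",
         paste(format(hist, digits = 3), collapse = " -> "), call. = FALSE)
  }
  pf <- front_from_gradient(tibble::tibble(P = P, F = u))$P_f
  structure(list(z = z, u_star = u, grid = grid, forcing = forcing,
                 params = params, P_f = pf,
                 newton_residual = max(abs(r)), iterations = it),
            class = "stationary_front")
}

#' @export
print.stationary_front <- function(x, ...) {
  cat("<stationary_front> z =", x$z, "m, P_f =", format(x$P_f),
      "mm/y, residual =", format(x$newton_residual), "(",
      x$iterations, "Newton iterations )\n")
  invisible(x)
}

# dimensional forest-model reaction, vectorized over nodes (u and P recycle
# to a common length)
forest_reaction <- function(u, P, z, params) {
  nf <- params$n_fire
  m <- max(length(u), length(P))
  u <- rep_len(u, m)
  uc <- pmax(u, 0)
  ycn <- rep_len(fire_threshold(P, params), m)^nf
  P <- rep_len(P, m)
  phi <- numeric(m)
  pos <- ycn > 0
  phi[pos] <- ycn[pos] / (ycn[pos] + uc[pos]^nf)
  phi[!pos] <- as.numeric(uc[!pos] == 0)
  phi <- phi / params$tau
  growth_rate(P, "F", params) * (1 - u) * u - params$b * phi * u -
    mortality_rate(P, "F", params) * u - deforestation_rate(z, params) * u
}

# analytic d(reaction)/du
forest_reaction_du <- function(u, P, z, params) {
  nf <- params$n_fire
  m <- max(length(u), length(P))
  u <- rep_len(u, m)
  uc <- pmax(u, 0)
  ycn <- rep_len(fire_threshold(P, params), m)^nf
  P <- rep_len(P, m)
  denom <- ycn + uc^nf
  phi <- numeric(m); dphi <- numeric(m)
  pos <- ycn > 0
  phi[pos] <- ycn[pos] / denom[pos]
  phi[!pos] <- as.numeric(uc[!pos] == 0)
  dphi[pos] <- -nf * uc[pos]^(nf - 1) * ycn[pos] / denom[pos]^2
  phi <- phi / params$tau
  dphi <- dphi / params$tau
  growth_rate(P, "F", params) * (1 - 2 * u) -
    params$b * (phi + u * dphi) -
    mortality_rate(P, "F", params) - deforestation_rate(z, params)
}

# tridiagonal Jacobian of the stationary residual (mirror BC: the
# off-diagonal entries at the boundary rows are doubled)
front_jacobian_tridiag <- function(u, P, z, params, dx) {
  n <- length(u)
  d <- forest_reaction_du(u, P, z, params) - 2 * params$D_F / dx^2
  up <- rep(params$D_F / dx^2, n - 1)
  lo <- rep(params$D_F / dx^2, n - 1)
  up[1] <- 2 * params$D_F / dx^2
  lo[n - 1] <- 2 * params$D_F / dx^2
  list(lower = lo, diag = d, upper = up)
}

# largest (rightmost) eigenvalue of a tridiagonal operator by shifted
# inverse power iteration. The mirror-BC operator is similar to a symmetric
# matrix, so its spectrum is real; the shift is a Gershgorin upper bound,
# which makes the rightmost eigenvalue the one closest to the shift.
tridiag_max_re <- function(J3, tol = 1e-11, max_iter = 500) {
  n <- length(J3$diag)
  gersh <- max(J3$diag + c(abs(J3$upper), 0) + c(0, abs(J3$lower)))
  sigma <- gersh + 0.01
  d <- J3$diag - sigma
  v <- rep(1 / sqrt(n), n)
  lam_old <- Inf
  for (it in seq_len(max_iter)) {
    w <- solve_tridiag(J3$lower, d, J3$upper, v)
    nu <- sum(v * w)
    lam <- sigma + 1 / nu
    v <- w / sqrt(sum(w^2))
    if (abs(lam - lam_old) < tol) return(lam)
    lam_old <- lam
  }
  lam
}

# Thomas algorithm
solve_tridiag <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n - 1); dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    m <- diag[i] - lower[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Discretized linearization about a stationary front
#'
#' The dense `n x n` operator `diag(dR/du(u*, P)) + D_F L / dx^2`, where `L`
#' is the mirror-boundary discrete Laplacian, governing the growth of small
#' perturbations about the front.
#'
#' @param front a `stationary_front`, or a numeric profile (then `forcing`,
#'   `params`, `grid` must be supplied).
#' @param forcing,params,grid used when `front` is a plain profile.
#' @return a dense matrix.
#' @export
jacobian_operator <- function(front, forcing = NULL, params = NULL,
                              grid = NULL) {
  if (inherits(front, "stationary_front")) {
    u <- front$u_star; forcing <- front$forcing
    params <- front$params; grid <- front$grid
  } else {
    u <- as.numeric(front)
    stopifnot(!is.null(forcing), !is.null(params), !is.null(grid))
  }
  n <- length(u)
  P <- rainfall_at(forcing, grid)
  J3 <- front_jacobian_tridiag(u, P, forcing$z, params, grid$dx)
  J <- diag(J3$diag)
  J[cbind(1:(n - 1), 2:n)] <- J3$upper
  J[cbind(2:n, 1:(n - 1))] <- J3$lower
  J
}

#' Linear stability of a stationary front
#'
#' Computes the spectrum of [jacobian_operator()] and reports the largest
#' real part and whether the spectrum is real. Under the mirror-boundary
#' stencil the operator is exactly similar to a symmetric matrix via the
#' trapezoid weight `diag(1/2, 1, ..., 1, 1/2)`, so its eigenvalues are real
#' and the default `method = "symmetric"` computes them with a symmetric
#' eigensolver after that similarity transform. `method = "general"` runs
#' the plain nonsymmetric eigensolver and measures the imaginary parts
#' numerically instead of using the similarity argument.
#'
#' @param front a `stationary_front`.
#' @param method `"symmetric"` (default) or `"general"`.
#' @return a one-row tibble with `z`, `P_f`, `max_re_lambda` (1/y),
#'   `spectrum_real`, `max_im` and `method`.
#' @export
stability <- function(front, method = c("symmetric", "general")) {
  method <- match.arg(method)
  stopifnot(inherits(front, "stationary_front"))
  J <- jacobian_operator(front)
  n <- nrow(J)
  if (method == "symmetric") {
    w <- rep(1, n); w[c(1, n)] <- 0.5
    s <- sqrt(w)
    Jt <- J * (s %o% (1 / s))
    Jsym <- (Jt + t(Jt)) / 2
    asym <- max(abs(Jt - t(Jt)))
    if (asym > 1e-8) {
      stop("operator is not similar-symmetric (asymmetry ", format(asym),
           "); use method = 'general'", call. = FALSE)
    }
    ev <- eigen(Jsym, symmetric = TRUE, only.values = TRUE)$values
    max_im <- 0
    spectrum_real <- TRUE
  } else {
    ev_c <- eigen(J, only.values = TRUE)$values
    max_im <- max(abs(Im(ev_c)))
    spectrum_real <- max_im < 1e-10
    ev <- Re(ev_c)
  }
  tibble::tibble(z = front$z, P_f = front$P_f,
                 max_re_lambda = max(ev), spectrum_real = spectrum_real,
                 max_im = max_im, method = method)
}

#' Continue the stationary-front branch in distance to cultivation
#'
#' Pseudo-arclength continuation of [solve_stationary_front()] solutions in
#' the human-impact distance `z`: secant predictor plus damped-Newton
#' corrector on the extended system (stationary residual plus arclength
#' condition) in `(u, z)`. On the discrete grid the front depins cell by
#' cell as `z` varies, so the branch threads a ladder of micro-folds; the
#' arclength parameterization steps through (or over) these, with the step
#' length halving on corrector failure and growing again after successes.
#' The branch is truncated with a warning if the corrector keeps failing at
#' the minimum step.
#'
#' At every accepted point the front rainfall `P_f` (gradient argmax) and
#' the rightmost eigenvalue of the linearized operator (by shifted inverse
#' iteration on the tridiagonal matrix) are recorded. The depinning ladder
#' makes itself visible here: accepted points on stable segments have
#' `max_re_lambda < 0`, while points on the intervening saddle segments
#' (the barriers between neighbouring pinned positions) have small positive
#' values. Profiles are stored on an evenly thinned subset of at most
#' `stability_max` points; [pinned_front()] returns the dynamically
#' realized (stable) front at a given `z`.
#'
#' @param start a converged `stationary_front` (its `z` is the branch
#'   start).
#' @param z_end target distance, m (continuation proceeds from `start$z`
#'   towards `z_end`).
#' @param ds initial arclength step (dimensionless; `z` enters the
#'   arclength metric scaled by `z_scale`).
#' @param ds_max cap on the adapted step.
#' @param z_scale scale (m) weighting `z` against the profile in the
#'   arclength metric.
#' @param compute_stability if `TRUE`, record `max_re_lambda` at every
#'   accepted point.
#' @param stability_max maximum number of points at which profiles are
#'   retained in the result.
#' @param max_points safety cap on the number of accepted points.
#' @return an object of class `front_branch`: a tibble with one row per
#'   accepted point (`z`, `P_f`, `newton_residual`, `max_re_lambda`,
#'   `spectrum_real`), with the retained profiles in attribute
#'   `"profiles"` (named by row index).
#' @export
continue_branch <- function(start, z_end = 0, ds = 0.25, ds_max = 2,
                            z_scale = 1000, compute_stability = TRUE,
                            stability_max = 15, max_points = 20000) {
  stopifnot(inherits(start, "stationary_front"))
  grid <- start$grid
  params <- start$params
  P <- rainfall_at(start$forcing, grid)
  dir <- sign(z_end - start$z)
  if (dir == 0) stop("z_end equals the starting z", call. = FALSE)

  res_fun <- function(u, z) {
    forest_reaction(u, P, z, params) + params$D_F *
      laplacian_noflux(u, grid$dx)
  }

  # unit tangent (scaled coordinates) from the implicit-function theorem:
  # J du/dz = -dR/dz; oriented to continue in the same direction
  tangent_at <- function(u, z, t_prev = NULL) {
    J3 <- front_jacobian_tridiag(u, P, z, params, grid$dx)
    w <- solve_tridiag(J3$lower, J3$diag, J3$upper,
                       -dresidual_dz(u, z, params))
    tv <- c(w, 1 / z_scale)
    tv <- tv / sqrt(sum(tv^2))
    orient <- if (is.null(t_prev)) {
      sign(tv[length(tv)]) * dir
    } else {
      sign(sum(tv * t_prev))
    }
    if (orient < 0) tv <- -tv
    tv
  }

  # damped-Newton corrector on the bordered system
  # [J, dr_dz; t_u', tz_s/zs] [du; dz] = -[r; g]
  correct <- function(u_pred, z_pred, t_u, tz_s) {
    u <- u_pred; z <- z_pred
    merit <- function(u, z) {
      r <- res_fun(u, z)
      g <- sum(t_u * (u - u_pred)) + tz_s * (z - z_pred) / z_scale
      list(r = r, g = g, m = max(max(abs(r)), abs(g)))
    }
    st <- merit(u, z)
    for (it in 1:40) {
      if (st$m < 1e-10) return(list(u = u, z = z, res = max(abs(st$r))))
      J3 <- front_jacobian_tridiag(u, P, z, params, grid$dx)
      dr_dz <- dresidual_dz(u, z, params)
      a <- solve_tridiag(J3$lower, J3$diag, J3$upper, -st$r)
      bvec <- solve_tridiag(J3$lower, J3$diag, J3$upper, -dr_dz)
      denom <- tz_s / z_scale + sum(t_u * bvec)
      if (abs(denom) < 1e-14 || any(!is.finite(a)) || any(!is.finite(bvec)))
        return(NULL)
      dz <- (-st$g - sum(t_u * a)) / denom
      du <- a + bvec * dz
      lam <- 1
      repeat {
        cand <- merit(u + lam * du, max(z + lam * dz, 0))
        if (cand$m < st$m || lam < 1e-4) break
        lam <- lam / 2
      }
      if (lam < 1e-4 && cand$m >= st$m) return(NULL)
      u <- u + lam * du; z <- max(z + lam * dz, 0)
      st <- cand
    }
    NULL
  }

  u_cur <- start$u_star
  z_cur <- start$z
  rows <- list(tibble::tibble(z = z_cur, P_f = start$P_f,
                              newton_residual = start$newton_residual))
  kept <- list(`1` = u_cur)
  t_prev <- NULL
  step <- ds
  truncated <- FALSE

  while (length(rows) < max_points) {
    m <- length(rows)
    if ((dir > 0 && z_cur >= z_end - 1e-2) ||
        (dir < 0 && z_cur <= z_end + 1e-2)) break
    tv <- tangent_at(u_cur, z_cur, t_prev)
    n <- grid$n
    t_u <- tv[seq_len(n)]; tz_s <- tv[n + 1]  # z-component in scaled units
    accepted <- FALSE
    while (!accepted && step > 1e-4) {
      z_pred <- z_cur + tz_s * step * z_scale
      if ((dir > 0 && z_pred > z_end) || (dir < 0 && z_pred < z_end)) {
        z_pred <- z_end
      }
      z_pred <- max(z_pred, 0)
      u_pred <- u_cur + t_u * step
      sol <- correct(u_pred, z_pred, t_u, tz_s)
      if (!is.null(sol) &&
          !(abs(sol$z - z_cur) < 1e-9 && max(abs(sol$u - u_cur)) < 1e-12)) {
        accepted <- TRUE
        u_cur <- sol$u; z_cur <- sol$z
        t_prev <- tv
        pf <- front_from_gradient(tibble::tibble(P = P, F = sol$u))$P_f
        rows[[m + 1]] <- tibble::tibble(z = sol$z, P_f = pf,
                                        newton_residual = sol$res)
        kept[[as.character(m + 1)]] <- sol$u
        step <- min(step * 1.3, ds_max)
      } else {
        step <- step / 2
      }
    }
    if (!accepted) { truncated <- TRUE; break }
  }
  if (truncated) {
    warning("branch truncated at z = ", z_cur,
            " m after repeated corrector failures", call. = FALSE)
  }

  branch <- dplyr::bind_rows(rows)
  n_pts <- nrow(branch)
  keep_idx <- unique(round(seq(1, n_pts, length.out =
                                 min(stability_max, n_pts))))
  if (compute_stability) {
    branch$max_re_lambda <- vapply(seq_len(n_pts), function(i) {
      u <- kept[[as.character(i)]]
      tridiag_max_re(front_jacobian_tridiag(u, P, branch$z[i], params,
                                            grid$dx))
    }, numeric(1))
    # real by the exact symmetric-similarity of the mirror-BC operator;
    # stability() offers the dense general-eigensolver cross-check
    branch$spectrum_real <- TRUE
  }
  kept <- kept[as.character(keep_idx)]
  attr(branch, "profiles") <- kept
  attr(branch, "grid") <- grid
  attr(branch, "params") <- params
  class(branch) <- c("front_branch", class(branch))
  branch
}

# derivative of the stationary residual with respect to z:
# only the deforestation term depends on z
dresidual_dz <- function(u, z, params) {
  rep(params$c_def * params$k_C * exp(-params$k_C * z), length(u)) * u
}

#' Dynamically realized pinned front at a given distance to cultivation
#'
#' Builds a forest-front profile at distance `z`, lets the PDE dynamics
#' select the attracting pinned state (a time integration from a sigmoid
#' seed centred on the Maxwell point, or from a supplied guess), and
#' polishes the result with [solve_stationary_front()]. Unlike an arbitrary
#' point on a [continue_branch()] ladder, the front returned here is the
#' stable pinned solution an observer of the dynamics would find.
#'
#' @param z distance from human cultivation, m.
#' @param params an [fs_params()] object.
#' @param grid an [build_grid()] object; extends past the study domain so
#'   the front stays interior even at small `z`.
#' @param guess optional starting profile (vector on the grid).
#' @param t_settle years of time integration in the first settling round;
#'   each retry doubles it.
#' @param max_rounds settle-and-polish attempts before the final error
#'   propagates.
#' @return a `stationary_front`.
#' @export
pinned_front <- function(z, params = fs_params(),
                         grid = build_grid(0, 3600, 0.67), guess = NULL,
                         t_settle = 6000, max_rounds = 4) {
  forcing <- forcing_linear(z = z)
  P <- rainfall_at(forcing, grid)
  if (is.null(guess)) {
    mp <- maxwell_point(z, params)$P_MP
    nd <- nondimensionalize(params)
    up <- vapply(P, function(Pi) {
      r <- nontrivial_roots(Pi, z, nd, n_scan = 400)
      if (length(r)) max(r) else 0
    }, numeric(1))
    guess <- up / (1 + exp(-(grid$x - mp) / 2))
  }
  # the Newton basin around a pinned front is narrow along the soft
  # translation mode, so settle dynamically and retry with more settling if
  # the polish stalls
  state <- guess
  for (round in seq_len(max_rounds - 1)) {
    settle <- t_settle * 2^(round - 1)
    sim <- run_to_steady(state, forcing, params, "forest", grid,
                         t_max = settle, window = settle / 3)
    state <- final_profile(sim)$F
    fr <- tryCatch(solve_stationary_front(state, forcing, params, grid),
                   error = function(e) NULL)
    if (!is.null(fr)) return(fr)
  }
  settle <- t_settle * 2^(max_rounds - 1)
  sim <- run_to_steady(state, forcing, params, "forest", grid,
                       t_max = settle, window = settle / 3)
  solve_stationary_front(final_profile(sim)$F, forcing, params, grid)
}
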