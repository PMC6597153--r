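#' Integrate the 1-D model by the method of lines
#'
#' Discretizes space with central differences and no-flux (mirror)
#' boundaries and integrates the resulting ODE system with an adaptive
#' embedded Runge-Kutta 4(5) scheme (Dormand-Prince, via
#' [deSolve::ode()] method `"ode45"`). Savanna saplings and forest trees
#' diffuse; adult savanna trees do not.
#'
#' Reaction terms are evaluated on covers clamped at 0 inside the
#' right-hand side, and stored output is projected onto `[0, 1]` within
#' `neg_tol` of the boundary, since an explicit scheme can undershoot zero
#' by the order of the absolute tolerance.
#'
#' @param state0 initial state: a tibble from [random_initial_condition()]
#'   (column `x` plus field columns), or a plain matrix/vector of field
#'   values on the grid.
#' @param forcing an [forcing_linear()] / [forcing_homogeneous()] object.
#' @param params an [fs_params()] object.
#' @param variant `"forest"`, `"forest-savanna"` or `"savanna-only"`.
#' @param grid an [build_grid()] object (defaults to the study grid).
#' @param t_end final time, years.
#' @param n_out number of equally spaced output snapshots (including t = 0).
#' @param times explicit output times (overrides `t_end`/`n_out`).
#' @param rtol,atol relative and absolute integration tolerances.
#' @param neg_tol negativity projection band for stored output.
#' @return an object of class `fs_sim`: a list with `times`, `fields` (one
#'   `length(times) x n` matrix per field), `grid`, `forcing`, `params`,
#'   `variant`, `seed` (from `state0`, if any), `converged` (NA here; set by
#'   [run_to_steady()]) and `final_residual` (max |du/dt| at the last
#'   snapshot, 1/y).
#' @seealso [run_to_steady()], [final_profile()], [spacetime_export()]
#' @examples
#' g <- build_grid(0, 300, 2)
#' ic <- random_initial_condition(g, "forest", seed = 1)
#' sim <- simulate_model(ic, forcing_homogeneous(2000), variant = "forest",
#'                       grid = g, t_end = 50)
#' @export
simulate_model <- function(state0, forcing, params = fs_params(),
                           variant = c("forest", "forest-savanna",
                                       "savanna-only"),
                           grid = build_grid(), t_end = 1000, n_out = 51,
                           times = NULL, rtol = 1e-6, atol = 1e-9,
                           neg_tol = 1e-6) {
  variant <- match.arg(variant)
  stopifnot(inherits(forcing, "fs_forcing"), inherits(grid, "fs_grid"))
  fields <- variant_fields(variant)
  y0 <- state_to_vector(state0, fields, grid$n)
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)

  rhs <- make_rhs(forcing, params, variant, grid)
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, p) list(rhs(y)),
                      parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol, maxsteps = 1e6)
  if (attr(sol, "istate")[1] < 0) {
    stop("time integration failed (step-size underflow or step limit); ",
         "final time reached: ", max(sol[, 1]), " y", call. = FALSE)
  }
  out_times <- sol[, 1]
  n <- grid$n
  field_list <- list()
  for (j in seq_along(fields)) {
    m <- sol[, 1 + (j - 1) * n + seq_len(n), drop = FALSE]
    m[m < 0 & m > -neg_tol] <- 0
    m[m > 1 & m < 1 + neg_tol] <- 1
    dimnames(m) <- NULL
    field_list[[fields[j]]] <- m
  }
  final <- unlist(lapply(field_list, function(m) m[nrow(m), ]),
                  use.names = FALSE)
  structure(list(
    times = out_times, fields = field_list, grid = grid, forcing = forcing,
    params = params, variant = variant,
    seed = attr(state0, "seed", exact = TRUE),
    converged = NA, final_residual = max(abs(rhs(final)))
  ), class = "fs_sim")
}

# build the method-of-lines right-hand side with all rainfall-dependent
# coefficients precomputed on the grid
make_rhs <- function(forcing, params, variant, grid) {
  P <- rainfall_at(forcing, grid)
  z <- forcing$z
  n <- grid$n
  dx2 <- grid$dx^2
  nf <- params$n_fire
  ycn <- fire_threshold(P, params)^nf
  yc_pos <- ycn > 0
  inv_tau <- 1 / params$tau
  R_S <- growth_rate(P, "S", params)
  R_F <- growth_rate(P, "F", params)
  M_S <- mortality_rate(P, "S", params)
  M_T <- mortality_rate(P, "T", params)
  M_F <- mortality_rate(P, "F", params)
  Cz <- deforestation_rate(z, params)
  lap <- function(u) {
    l <- numeric(n)
    if (n > 2) l[2:(n - 1)] <- u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n]
    l[1] <- 2 * (u[2] - u[1])
    l[n] <- 2 * (u[n - 1] - u[n])
    l / dx2
  }
  phi_of <- function(w) {
    phi <- as.numeric(w == 0)           # degenerate-threshold limit
    phi[yc_pos] <- ycn[yc_pos] / (ycn[yc_pos] + w[yc_pos]^nf)
    phi * inv_tau
  }
  i1 <- seq_len(n)
  if (variant == "forest") {
    function(y) {
      F <- pmax(y, 0)
      phi <- phi_of(F)
      R_F * (1 - F) * F - params$b * phi * F - M_F * F - Cz * F +
        params$D_F * lap(y)
    }
  } else if (variant == "forest-savanna") {
    i2 <- n + i1; i3 <- 2 * n + i1
    function(y) {
      S <- pmax(y[i1], 0); T <- pmax(y[i2], 0); F <- pmax(y[i3], 0)
      phi <- phi_of(T + F)
      recr <- params$Q0 * (1 - params$h * phi)
      G <- 1 - S - T - F
      c(R_S * G * T - recr * S - M_S * S - R_F * S * F +
          params$D_S * lap(y[i1]),
        recr * S - M_T * T - R_F * T * F,
        R_F * (1 - F) * F - params$b * phi * F - M_F * F - Cz * F +
          params$D_F * lap(y[i3]))
    }
  } else {  # savanna-only: F fixed at 0
    i2 <- n + i1
    function(y) {
      S <- pmax(y[i1], 0); T <- pmax(y[i2], 0)
      phi <- phi_of(T)
      recr <- params$Q0 * (1 - params$h * phi)
      c(R_S * (1 - S - T) * T - recr * S - M_S * S +
          params$D_S * lap(y[i1]),
        recr * S - M_T * T)
    }
  }
}

state_to_vector <- function(state0, fields, n) {
  if (is.data.frame(state0)) {
    missing <- setdiff(fields, names(state0))
    if (length(missing)) {
      stop("initial state lacks field column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (nrow(state0) != n) {
      stop("initial state has ", nrow(state0), " rows but the grid has ",
           n, " nodes", call. = FALSE)
    }
    y0 <- unlist(state0[fields], use.names = FALSE)
  } else {
    y0 <- as.numeric(state0)
    if (length(y0) != n * length(fields)) {
      stop("initial state length ", length(y0), " does not match ",
           length(fields), " field(s) on ", n, " nodes", call. = FALSE)
    }
  }
  if (any(!is.finite(y0))) stop("initial state must be finite", call. = FALSE)
  y0
}

#' Integrate until (near-)stationarity
#'
#' Runs [simulate_model()] in windows, checking the residual `max |du/dt|`
#' at each window end, until it drops below `tol_steady` or `t_max` is
#' reached. Non-convergence is not an error — cycling regimes never settle —
#' but is flagged in the result.
#'
#' @inheritParams simulate_model
#' @param tol_steady stationarity tolerance on `max |du/dt|`, 1/y.
#' @param t_max maximum simulated time, years.
#' @param window window length between residual checks, years.
#' @return an `fs_sim` whose snapshots are the window ends, with
#'   `converged` set and `final_residual` the last residual.
#' @export
run_to_steady <- function(state0, forcing, params = fs_params(),
                          variant = c("forest", "forest-savanna",
                                      "savanna-only"),
                          grid = build_grid(), tol_steady = 1e-8,
                          t_max = 20000, window = 500,
                          rtol = 1e-8, atol = 1e-11) {
  variant <- match.arg(variant)
  fields <- variant_fields(variant)
  y <- state_to_vector(state0, fields, grid$n)
  rhs <- make_rhs(forcing, params, variant, grid)

  times <- 0
  snaps <- list(y)
  t_now <- 0
  res <- max(abs(rhs(y)))
  converged <- res < tol_steady
  while (!converged && t_now < t_max) {
    t_next <- min(t_now + window, t_max)
    sim <- simulate_model(y, forcing, params, variant, grid,
                          times = c(t_now, t_next), rtol = rtol, atol = atol)
    y <- unlist(lapply(sim$fields, function(m) m[nrow(m), ]),
                use.names = FALSE)
    t_now <- t_next
    times <- c(times, t_now)
    snaps[[length(snaps) + 1]] <- y
    res <- sim$final_residual
    converged <- res < tol_steady
  }

  n <- grid$n
  field_list <- list()
  for (j in seq_along(fields)) {
    idx <- (j - 1) * n + seq_len(n)
    field_list[[fields[j]]] <-
      do.call(rbind, lapply(snaps, function(s) s[idx]))
  }
  structure(list(
    times = times, fields = field_list, grid = grid, forcing = forcing,
    params = params, variant = variant,
    seed = attr(state0, "seed", exact = TRUE),
    converged = converged, final_residual = res
  ), class = "fs_sim")
}

#' @export
print.fs_sim <- function(x, ...) {
  cat("<fs_sim>", x$variant, "model,", x$grid$n, "nodes,",
      length(x$times), "snapshots, t in [", min(x$times), ",",
      max(x$times), "] y\n")
  cat("  forcing:", if (x$forcing$type == "linear") "P(x) = x" else
    paste("P =", x$forcing$P, "mm/y"), "| z =", x$forcing$z, "m\n")
  cat("  final residual:", format(x$final_residual), "1/y",
      if (isTRUE(x$converged)) "(converged)" else
        if (isFALSE(x$converged)) "(not converged)" else "", "\n")
  invisible(x)
}

#' Final spatial profile of a simulation
#'
#' @param sim an `fs_sim` object.
#' @return a tibble with columns `x` (km), `P` (mm/y) and one column per
#'   field, taken from the last stored snapshot.
#' @export
final_profile <- function(sim) {
  stopifnot(inherits(sim, "fs_sim"))
  out <- tibble::tibble(x = sim$grid$x,
                        P = rainfall_at(sim$forcing, sim$grid))
  for (f in names(sim$fields)) {
    out[[f]] <- sim$fields[[f]][length(sim$times), ]
  }
  out
}

#' Simulate the nonspatial model
#'
#' The plain ODE system (no diffusion, single location) used for cycle
#' diagnostics and equilibrium probes.
#'
#' @param state0 named vector with entries among `S`, `T`, `F` (missing
#'   entries default to 0), or a single number for the forest variant.
#' @inheritParams simulate_model
#' @param P rainfall, mm/y.
#' @param z distance from human cultivation, m.
#' @return a tibble with columns `time`, `S`, `T`, `F` (always all three;
#'   absent species are identically 0).
#' @export
simulate_nonspatial <- function(state0, P, z = Inf, params = fs_params(),
                                variant = c("forest-savanna", "forest",
                                            "savanna-only"),
                                t_end = 2000, n_out = 1001,
                                rtol = 1e-8, atol = 1e-10) {
  variant <- match.arg(variant)
  fields <- variant_fields(variant)
  if (length(state0) == 1 && is.null(names(state0))) {
    names(state0) <- fields[length(fields)]
  }
  y0 <- vapply(fields, function(f) {
    if (f %in% names(state0)) unname(state0[[f]]) else 0
  }, numeric(1))
  rhs <- function(t, y, p) {
    list(nonspatial_rhs(pmax(y, 0), P, z, params, variant))
  }
  sol <- deSolve::ode(y = y0, times = seq(0, t_end, length.out = n_out),
                      func = rhs, parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol, maxsteps = 1e6)
  out <- tibble::tibble(time = sol[, 1])
  for (f in c("S", "T", "F")) {
    out[[f]] <- if (f %in% fields) pmax(sol[, 1 + match(f, fields)], 0) else 0
  }
  out
}
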