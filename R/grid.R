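#' Uniform 1-D spatial grid
#'
#' Builds the discretization used by the simulator and the continuation
#' code. Defaults match the study domain: 0 to 3000 km with spacing
#' `dx = 0.67` km, so that under the linear forcing `P(x) = x` the node
#' coordinate in km doubles as rainfall in mm/y.
#'
#' @param x0,x1 domain bounds, km (`x1 > x0`).
#' @param dx node spacing, km (> 0).
#' @return an object of class `fs_grid` with fields `x0`, `x1`, `dx`, `n`
#'   and node coordinates `x` (length `n = round((x1 - x0)/dx) + 1`).
#' @examples
#' build_grid()$n              # 4479
#' build_grid(0, 10, 10)$n     # minimal two-node grid
#' @export
build_grid <- function(x0 = 0, x1 = 3000, dx = 0.67) {
  if (dx <= 0) stop("dx must be > 0", call. = FALSE)
  if (x1 <= x0) stop("x1 must exceed x0", call. = FALSE)
  n <- as.integer(round((x1 - x0) / dx) + 1)
  structure(list(x0 = x0, x1 = x1, dx = dx, n = n,
                 x = x0 + (seq_len(n) - 1) * dx),
            class = "fs_grid")
}

#' @export
print.fs_grid <- function(x, ...) {
  cat("<fs_grid> [", x$x0, ",", x$x1, "] km, dx =", x$dx, "km, n =", x$n,
      "nodes\n")
  invisible(x)
}

#' Environmental forcing
#'
#' `forcing_linear()` is the heterogeneous rainfall gradient `P(x) = x`
#' (1 mm/y of rainfall per km of distance); `forcing_homogeneous()` applies
#' one rainfall value everywhere. Both carry the distance `z` (meters) from
#' human cultivation, applied uniformly; `z = Inf` means no human impact.
#'
#' @param z distance from human cultivation, m.
#' @return an object of class `fs_forcing`.
#' @export
forcing_linear <- function(z = Inf) {
  stopifnot(z >= 0)
  structure(list(type = "linear", P = NULL, z = z), class = "fs_forcing")
}

#' @rdname forcing_linear
#' @param P homogeneous rainfall, mm/y.
#' @export
forcing_homogeneous <- function(P, z = Inf) {
  stopifnot(P >= 0, z >= 0)
  structure(list(type = "homogeneous", P = P, z = z), class = "fs_forcing")
}

#' @export
print.fs_forcing <- function(x, ...) {
  if (x$type == "linear") {
    cat("<fs_forcing> linear rainfall gradient P(x) = x, z =", x$z, "m\n")
  } else {
    cat("<fs_forcing> homogeneous P =", x$P, "mm/y, z =", x$z, "m\n")
  }
  invisible(x)
}

#' Rainfall at the grid nodes
#'
#' @param forcing an [forcing_linear()] / [forcing_homogeneous()] object.
#' @param grid an [build_grid()] object.
#' @return numeric vector of rainfall values, mm/y, one per node.
#' @export
rainfall_at <- function(forcing, grid) {
  stopifnot(inherits(forcing, "fs_forcing"), inherits(grid, "fs_grid"))
  if (forcing$type == "linear") grid$x else rep(forcing$P, grid$n)
}

#' Random initial condition
#'
#' Per-node i.i.d. Uniform(0, 1) draws; for multi-species variants the
#' triple (or pair) at each node is divided by `max(1, sum)` so the state
#' starts inside the simplex. Fully reproducible from the seed.
#'
#' @param grid an [build_grid()] object.
#' @param variant `"forest"` (single field `F`), `"forest-savanna"`
#'   (`S`, `T`, `F`) or `"savanna-only"` (`S`, `T`).
#' @param seed integer seed.
#' @return a tibble with column `x` plus one column per field, carrying the
#'   seed as attribute `"seed"`.
#' @export
random_initial_condition <- function(grid,
                                     variant = c("forest", "forest-savanna",
                                                 "savanna-only"),
                                     seed = 1) {
  variant <- match.arg(variant)
  stopifnot(inherits(grid, "fs_grid"))
  fields <- variant_fields(variant)
  m <- withr::with_seed(seed, {
    matrix(stats::runif(grid$n * length(fields)), nrow = grid$n)
  })
  if (length(fields) > 1) m <- m / pmax(1, rowSums(m))
  colnames(m) <- fields
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, x = grid$x, .before = 1)
  attr(out, "seed") <- seed
  out
}

variant_fields <- function(variant) {
  switch(variant,
         "forest" = "F",
         "forest-savanna" = c("S", "T", "F"),
         "savanna-only" = c("S", "T"),
         stop("unknown model variant: ", variant, call. = FALSE))
}

#' Discrete Laplacian with no-flux boundaries
#'
#' Central second difference `(u[i-1] - 2 u[i] + u[i+1]) / dx^2` with mirror
#' ghost nodes at both ends (`u[0] = u[2]`, `u[n+1] = u[n-1]`), the discrete
#' form of a zero-gradient (Neumann) boundary. The stencil telescopes, so
#' the scheme conserves total mass under pure diffusion.
#'
#' @param u field values on the grid (length >= 2).
#' @param dx node spacing.
#' @return vector of second differences, same length as `u`.
#' @export
laplacian_noflux <- function(u, dx) {
  n <- length(u)
  stopifnot(n >= 2)
  lap <- numeric(n)
  if (n > 2) lap[2:(n - 1)] <- u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n]
  lap[1] <- 2 * (u[2] - u[1])
  lap[n] <- 2 * (u[n - 1] - u[n])
  lap / dx^2
}
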