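#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a front fit
#'
#' @param x a `front_fit` from [fit_logistic_front()] or
#'   [front_from_gradient()].
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per parameter (`term`,
#'   `estimate`); `glance()`: a one-row summary (`method`, `P_f`, `A`, `k`,
#'   `R2`, `loss`, `n`).
#' @export
tidy.front_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "k", "P_f"),
                 estimate = c(x$A, x$k, x$P_f))
}

#' @rdname tidy.front_fit
#' @export
glance.front_fit <- function(x, ...) {
  tibble::tibble(method = x$method, P_f = x$P_f, A = x$A, k = x$k,
                 R2 = x$R2, loss = x$loss, n = x$n)
}

#' Tidy a continuation branch
#'
#' @param x a `front_branch` from [continue_branch()].
#' @param ... unused.
#' @return `tidy()`: the branch table (one row per accepted point);
#'   `glance()`: a one-row summary with the z-range, number of points, the
#'   worst Newton residual and the largest eigenvalue along the branch.
#' @export
tidy.front_branch <- function(x, ...) {
  out <- x
  attr(out, "profiles") <- NULL
  attr(out, "grid") <- NULL
  attr(out, "params") <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname tidy.front_branch
#' @export
glance.front_branch <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    z_min = min(x$z), z_max = max(x$z),
    max_newton_residual = max(x$newton_residual),
    max_re_lambda = if ("max_re_lambda" %in% names(x))
      max(x$max_re_lambda) else NA_real_,
    all_spectra_real = if ("spectrum_real" %in% names(x))
      all(x$spectrum_real) else NA
  )
}

#' Tidy a simulation
#'
#' @param x an `fs_sim`.
#' @param ... unused.
#' @return `tidy()`: a long tibble with columns `time`, `x`, `P`, `field`,
#'   `cover`; `glance()`: one row with `variant`, `n_nodes`, `n_times`,
#'   `t_end`, `converged`, `final_residual`.
#' @export
tidy.fs_sim <- function(x, ...) {
  P <- rainfall_at(x$forcing, x$grid)
  purrr::map_dfr(names(x$fields), function(f) {
    m <- x$fields[[f]]
    tibble::tibble(
      time = rep(x$times, each = x$grid$n),
      x = rep(x$grid$x, length(x$times)),
      P = rep(P, length(x$times)),
      field = f,
      cover = as.vector(t(m))
    )
  })
}

#' @rdname tidy.fs_sim
#' @export
glance.fs_sim <- function(x, ...) {
  tibble::tibble(variant = x$variant, n_nodes = x$grid$n,
                 n_times = length(x$times), t_end = max(x$times),
                 converged = x$converged,
                 final_residual = x$final_residual)
}

#' @rdname cycle_statistics
#' @param x a `cycle_stats` object.
#' @param ... unused.
#' @export
glance.cycle_stats <- function(x, ...) {
  tibble::tibble(classification = x$classification, n_peaks = x$n_peaks,
                 mean_period = x$mean_period, period_cv = x$period_cv,
                 amplitude = x$amplitude)
}
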