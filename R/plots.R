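#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation's final profile
#'
#' Cover fractions versus rainfall at the last stored snapshot, one line
#' per species.
#'
#' @param object an `fs_sim`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fs_sim <- function(object, ...) {
  prof <- final_profile(object)
  long <- tidyr::pivot_longer(prof, -c("x", "P"), names_to = "field",
                              values_to = "cover")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$P, y = .data$cover,
                                     colour = .data$field)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mean annual rainfall (mm/y)", y = "cover fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble scatter
#'
#' The cover-versus-rainfall cloud across all runs and nodes; alternative
#' stable states show up as two populated branches, cycling regimes as
#' vertical smears.
#'
#' @param object an `ensemble_scatter`.
#' @param fields which cover columns to show.
#' @param alpha point transparency.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ensemble_scatter <- function(object, fields = c("S", "T", "F"),
                                      alpha = 0.2, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(fields),
                              names_to = "field", values_to = "cover")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rainfall, y = .data$cover,
                                     colour = .data$field)) +
    ggplot2::geom_point(size = 0.3, alpha = alpha) +
    ggplot2::labs(x = "mean annual rainfall (mm/y)", y = "cover fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a continuation branch against the Maxwell-point curve
#'
#' @param object a `front_branch`.
#' @param mp optional output of [maxwell_curve()] to overlay (dashed).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.front_branch <- function(object, mp = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$P_f, y = .data$z / 1000)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::labs(x = "front rainfall P_f (mm/y)",
                  y = "distance from cultivation z (km)") +
    ggplot2::theme_minimal()
  if (!is.null(mp)) {
    p <- p + ggplot2::geom_path(
      data = mp, ggplot2::aes(x = .data$P_MP, y = .data$z / 1000),
      linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a logistic front fit
#'
#' Observed profile, fitted sigmoid and the extracted front rainfall.
#'
#' @param object a `front_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.front_fit <- function(object, ...) {
  df <- tibble::tibble(P = object$P, observed = object$observed)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$P, y = .data$observed)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$P_f, linetype = "dotted") +
    ggplot2::labs(x = "mean annual rainfall (mm/y)", y = "forest cover") +
    ggplot2::theme_minimal()
  if (!is.null(object$fitted)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(P = object$P, fitted = object$fitted),
      ggplot2::aes(x = .data$P, y = .data$fitted), colour = "red")
  }
  p
}

#' Hovmoller plot of a space-time export
#'
#' @param object an `fs_spacetime`.
#' @param ... unused.
#' @return a ggplot raster of cover over (rainfall, time).
#' @export
autoplot.fs_spacetime <- function(object, ...) {
  df <- tibble::tibble(
    time = rep(object$time, times = length(object$rainfall)),
    rainfall = rep(object$rainfall, each = length(object$time)),
    cover = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rainfall, y = .data$time,
                                   fill = .data$cover)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$field) +
    ggplot2::labs(x = "mean annual rainfall (mm/y)", y = "time (y)") +
    ggplot2::theme_minimal()
}

#' Plot the forest-model potential
#'
#' `V(u)` at one or more rainfall values; at the Maxwell point the grass
#' (`u = 0`) and forest wells are level.
#'
#' @param P rainfall values, mm/y.
#' @param z distance from cultivation, m.
#' @param params an [fs_params()] object.
#' @param u grid of cover values.
#' @return a ggplot.
#' @export
plot_potential <- function(P, z = Inf, params = fs_params(),
                           u = seq(0, 1, length.out = 201)) {
  nd <- nondimensionalize(params)
  df <- purrr::map_dfr(P, function(Pi) {
    tibble::tibble(P = Pi, u = u, V = potential(u, Pi, z, nd))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$V,
                                   colour = factor(.data$P))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "forest cover u", y = "potential V(u)",
                  colour = "P (mm/y)") +
    ggplot2::theme_minimal()
}
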