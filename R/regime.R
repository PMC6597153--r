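#' Ensemble of heterogeneous simulations
#'
#' Runs `n_runs` seeded simulations from independent random initial
#' conditions to `t_end` and collects the final cover of every node together
#' with its rainfall — the scatter-cloud protocol that reveals alternative
#' stable states (both branches populated across runs) and cycling regimes
#' (high within-bin variation).
#'
#' @param variant `"forest"`, `"forest-savanna"` or `"savanna-only"`.
#' @param params an [fs_params()] object.
#' @param z distance from human cultivation, m.
#' @param n_runs number of ensemble members.
#' @param seeds integer seeds, one per run (defaults to `1:n_runs`).
#' @param grid an [build_grid()] object; the scatter experiments default to
#'   a 2 km spacing for tractable ensembles.
#' @param t_end simulated time per run, years.
#' @param rtol,atol integration tolerances.
#' @return an object of class `ensemble_scatter`: a tibble with columns
#'   `rainfall` (mm/y), `run`, `seed`, `S`, `T`, `F` (absent species are 0;
#'   integrator under/overshoot is projected onto `[0, 1]`), with the run
#'   setup stored in attributes.
#' @export
ensemble_scatter <- function(variant, params = fs_params(), z = Inf,
                             n_runs = 8, seeds = seq_len(n_runs),
                             grid = build_grid(dx = 2), t_end = 10000,
                             rtol = 1e-6, atol = 1e-9) {
  stopifnot(length(seeds) == n_runs)
  forcing <- forcing_linear(z = z)
  P <- rainfall_at(forcing, grid)
  runs <- purrr::map_dfr(seq_len(n_runs), function(i) {
    ic <- random_initial_condition(grid, variant, seed = seeds[i])
    sim <- simulate_model(ic, forcing, params, variant, grid,
                          times = c(0, t_end), rtol = rtol, atol = atol)
    prof <- final_profile(sim)
    grab <- function(f) {
      if (f %in% names(prof)) pmin(pmax(prof[[f]], 0), 1) else 0
    }
    tibble::tibble(rainfall = P, run = i, seed = seeds[i],
                   S = grab("S"), T = grab("T"), F = grab("F"))
  })
  attr(runs, "variant") <- variant
  attr(runs, "params") <- params
  attr(runs, "z") <- z
  attr(runs, "t_end") <- t_end
  attr(runs, "grid") <- grid
  class(runs) <- c("ensemble_scatter", class(runs))
  runs
}

#' Detect alternative stable states in an ensemble scatter
#'
#' Bins the scatter by rainfall and, within each bin, splits the final
#' cover values across runs and nodes into two clusters (1-D two-means).
#' A bin is flagged bistable when the cluster centers are separated by more
#' than `gap` and neither cluster is a sliver; contiguous flagged bins are
#' merged into rainfall intervals.
#'
#' A unimodal cloud (one state plus noise) yields small cluster separation
#' and no interval, so pure scatter does not trigger detection.
#'
#' @param scatter an [ensemble_scatter()] result (>= 2 runs).
#' @param field which cover to cluster (default adult savanna trees `"T"`).
#' @param gap minimum cluster-center separation, cover fraction.
#' @param bin_width rainfall bin width, mm.
#' @param min_points bins with fewer points are skipped.
#' @param min_frac minimum fraction of a bin's points in the smaller
#'   cluster.
#' @return a tibble with columns `P_low`, `P_high`, one row per detected
#'   interval.
#' @export
detect_bistability <- function(scatter, field = "T", gap = 0.2,
                               bin_width = 50, min_points = 20,
                               min_frac = 0.1) {
  stopifnot(is.data.frame(scatter), field %in% names(scatter),
            "rainfall" %in% names(scatter))
  if (length(unique(scatter$run)) < 2) {
    stop("bistability detection needs at least 2 runs", call. = FALSE)
  }
  df <- tibble::tibble(
    bin = floor(scatter$rainfall / bin_width),
    v = scatter[[field]]
  )
  bins <- sort(unique(df$bin))
  flagged <- vapply(bins, function(b) {
    v <- df$v[df$bin == b]
    if (length(v) < min_points) return(FALSE)
    if (diff(range(v)) < gap) return(FALSE)
    km <- stats::kmeans(v, centers = c(min(v), max(v)))
    sep <- abs(diff(km$centers[, 1]))
    frac <- min(km$size) / length(v)
    sep > gap && frac >= min_frac
  }, logical(1))
  if (!any(flagged)) {
    return(tibble::tibble(P_low = numeric(0), P_high = numeric(0)))
  }
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- purrr::map_dfr(which(runs$values), function(j) {
    tibble::tibble(P_low = bins[starts[j]] * bin_width,
                   P_high = (bins[ends[j]] + 1) * bin_width)
  })
  out
}

#' Cycle statistics of a cover time series
#'
#' Discards an initial transient, resamples the series to a uniform time
#' step, detects peaks by topographic prominence, and summarizes the
#' inter-peak intervals. Classification uses the coefficient of variation
#' (CV) of the periods: below `cv_regular` the cycle is `"regular_cycle"`,
#' above `cv_irregular` it is `"irregular_cycle"`, in between
#' `"undetermined"`; fewer than 3 peaks gives `"steady"`.
#'
#' @param ts a data frame with a time column and a value column.
#' @param value_col,time_col column names.
#' @param min_prominence minimum peak prominence, cover units.
#' @param transient_frac fraction of the record discarded from the start.
#' @param cv_regular,cv_irregular classification thresholds on the period
#'   CV.
#' @return an object of class `cycle_stats`: list with `peak_times`,
#'   `periods`, `amplitude` (max minus min after the transient),
#'   `period_cv`, `mean_period`, `n_peaks` and `classification`.
#' @examples
#' ts <- synthetic_cycle_series(period = 120, t_end = 2000, seed = 1)
#' cycle_statistics(ts, value_col = "value")
#' @export
cycle_statistics <- function(ts, value_col = "T", time_col = "time",
                             min_prominence = 0.05, transient_frac = 0.3,
                             cv_regular = 0.02, cv_irregular = 0.1) {
  stopifnot(is.data.frame(ts), value_col %in% names(ts),
            time_col %in% names(ts))
  t <- ts[[time_col]]
  v <- ts[[value_col]]
  keep <- t >= min(t) + transient_frac * diff(range(t))
  t <- t[keep]; v <- v[keep]
  # uniform resampling (median step) so peak indices map linearly to time
  dt <- stats::median(diff(t))
  tu <- seq(min(t), max(t), by = dt)
  vu <- stats::approx(t, v, xout = tu)$y

  peaks <- find_prominent_peaks(vu, min_prominence)
  peak_times <- tu[peaks]
  periods <- diff(peak_times)
  amplitude <- max(vu) - min(vu)
  n_peaks <- length(peaks)
  if (n_peaks >= 3) {
    cv <- stats::sd(periods) / mean(periods)
    classification <- if (cv < cv_regular) "regular_cycle" else
      if (cv > cv_irregular) "irregular_cycle" else "undetermined"
  } else {
    cv <- NA_real_
    classification <- "steady"
  }
  structure(list(
    peak_times = peak_times, periods = periods, amplitude = amplitude,
    period_cv = cv, mean_period = if (length(periods)) mean(periods) else
      NA_real_,
    n_peaks = n_peaks, classification = classification
  ), class = "cycle_stats")
}

#' @export
print.cycle_stats <- function(x, ...) {
  cat("<cycle_stats>", x$classification, "|", x$n_peaks, "peaks")
  if (!is.na(x$period_cv)) {
    cat(", mean period", format(x$mean_period, digits = 4), "y, CV",
        format(x$period_cv, digits = 3))
  }
  cat(", amplitude", format(x$amplitude, digits = 3), "\n")
  invisible(x)
}

# local maxima filtered by topographic prominence: the drop from a peak to
# the highest saddle separating it from any higher peak
find_prominent_peaks <- function(v, min_prominence) {
  n <- length(v)
  if (n < 3) return(integer(0))
  is_peak <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  if (!length(is_peak)) return(integer(0))
  # straightforward O(n * peaks) prominence
  prom <- vapply(is_peak, function(i) {
    h <- v[i]
    lhs <- v[seq_len(i - 1)]
    hi_l <- which(lhs > h)
    left_base <- if (length(hi_l)) min(v[(max(hi_l) + 1):(i - 1)]) else
      min(lhs)
    rhs <- v[(i + 1):n]
    hi_r <- which(rhs > h)
    right_base <- if (length(hi_r)) min(rhs[seq_len(min(hi_r) - 1)]) else
      min(rhs)
    h - max(left_base, right_base)
  }, numeric(1))
  is_peak[prom >= min_prominence]
}

#' Space-time matrix of one field
#'
#' Extracts a field's stored snapshots as a matrix with rows = times and
#' columns = nodes (labelled by rainfall under the linear forcing), the
#' Hovmoller-style view used to display cycling regimes below the forest
#' front.
#'
#' @param sim an `fs_sim`.
#' @param field `"S"`, `"T"` or `"F"`.
#' @return an object of class `fs_spacetime`: list with `time` (y),
#'   `rainfall` (mm/y per node), `x` (km) and `values` (time x node
#'   matrix).
#' @export
spacetime_export <- function(sim, field = "F") {
  stopifnot(inherits(sim, "fs_sim"))
  if (!field %in% names(sim$fields)) {
    stop("field '", field, "' not stored in this simulation", call. = FALSE)
  }
  structure(list(
    time = sim$times,
    rainfall = rainfall_at(sim$forcing, sim$grid),
    x = sim$grid$x,
    values = sim$fields[[field]],
    field = field
  ), class = "fs_spacetime")
}

#' @rdname spacetime_export
#' @param st an `fs_spacetime`.
#' @param path output CSV path; first column is time, remaining columns are
#'   nodes named by rainfall.
#' @export
write_spacetime_csv <- function(st, path) {
  stopifnot(inherits(st, "fs_spacetime"))
  df <- as.data.frame(st$values)
  names(df) <- paste0("P", format(st$rainfall, trim = TRUE))
  df <- cbind(time = st$time, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
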