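#' Parameters of the forest-savanna model
#'
#' Constructs the full dimensional parameter set of the forest-savanna
#' reaction-diffusion model. The defaults are the published calibration for
#' average rainfall seasonality and soils, so that every rate depends only on
#' mean annual rainfall `P` (mm/y) and on the distance `z` (m) from human
#' cultivation.
#'
#' The model tracks savanna sapling cover `S`, savanna adult tree cover `T`
#' and forest tree cover `F` on the unit simplex (the remainder `1 - S - T - F`
#' is grass). Growth saturates with rainfall, drought mortality decays with
#' rainfall, and fire enters through the burnt-area fraction, a Hill function
#' of woody cover `T + F` with threshold [fire_threshold()].
#'
#' @param ... name-value pairs overriding any default, e.g.
#'   `fs_params(r_S = 0.13, Q0 = 0.2, tau = 1)` for the high-savanna regime.
#'
#' @details
#' Parameter meanings and defaults:
#' \describe{
#'   \item{`r_S`, `r_F`}{growth-rate ceilings of savanna saplings and forest
#'     trees, 1/y (0.09, 0.20).}
#'   \item{`k_RS`, `k_RF`}{rainfall steepness of the growth response, 1/mm
#'     (0.005, 0.003).}
#'   \item{`a_RS`, `a_RF`}{dimensionless growth offsets (0.25, 1.54).}
#'   \item{`m_So`, `m_Fo`}{baseline mortalities, 1/y (0.023, 0.041); savanna
#'     adults share the sapling baseline, `m_To = m_So`.}
#'   \item{`a_MS`, `a_MF`}{mortality offsets (0, -2.15). The savanna offset is
#'     not part of the published calibration table; it defaults to 0 so that
#'     `M_S(P) = m_So + exp(-k_MS * P)`, and is exposed here so other choices
#'     can be explored.}
#'   \item{`k_MS`, `k_MF`}{mortality steepness, 1/mm (0.008, 0.008);
#'     `k_MT = k_MS`.}
#'   \item{`Q0`, `h`}{maximum sapling-to-adult recruitment rate, 1/y (0.04),
#'     and its fire sensitivity in `[0, 1]` (0.85).}
#'   \item{`tau`, `n_fire`}{maximum fire return time, y (2.7), and the Hill
#'     exponent of the burnt-area function (4).}
#'   \item{`Y_c0`, `k_c`}{fire-spread threshold at zero rainfall, cover
#'     fraction (0.56), and its (negative) rainfall slope, 1/mm (-1.43e-4).}
#'   \item{`b`}{forest fire sensitivity, dimensionless (0.46).}
#'   \item{`c_def`, `k_C`}{deforestation amplitude, 1/y (0.092), and decay
#'     with distance from cultivation, 1/m (0.0015).}
#'   \item{`D_S`, `D_F`}{diffusion coefficients of saplings and forest trees,
#'     km^2/y (0.2, 0.1). Adult savanna trees do not diffuse.}
#' }
#'
#' @return An object of class `fs_params`: a validated named list.
#' @seealso [nondimensionalize()], [read_params()], [reaction_terms()]
#' @examples
#' p <- fs_params()
#' p_high <- fs_params(r_S = 0.13, Q0 = 0.2, tau = 1)
#' @export
fs_params <- function(...) {
  defaults <- list(
    r_S = 0.09, r_F = 0.20,
    k_RS = 0.005, k_RF = 0.003,
    a_RS = 0.25, a_RF = 1.54,
    m_So = 0.023, m_Fo = 0.041,
    a_MS = 0, a_MF = -2.15,
    k_MS = 0.008, k_MF = 0.008,
    Q0 = 0.04, h = 0.85,
    tau = 2.7, n_fire = 4,
    Y_c0 = 0.56, k_c = -1.43e-4,
    b = 0.46,
    c_def = 0.092, k_C = 0.0015,
    D_S = 0.2, D_F = 0.1
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all arguments to fs_params() must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[names(dots)] <- dots
  }
  validate_fs_params(structure(defaults, class = "fs_params"))
}

validate_fs_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(unclass(p))) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite number",
                             call. = FALSE)
  }
  nonneg <- c("r_S", "r_F", "k_RS", "k_RF", "m_So", "m_Fo", "k_MS", "k_MF",
              "Q0", "Y_c0", "b", "c_def", "k_C", "D_S", "D_F")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad)) stop("parameter(s) must be >= 0: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (p$tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (p$h < 0 || p$h > 1) stop("h must lie in [0, 1]", call. = FALSE)
  if (p$k_c >= 0) stop("k_c must be < 0 (fire threshold decreases with rainfall)",
                       call. = FALSE)
  if (p$n_fire < 1 || p$n_fire != round(p$n_fire)) {
    stop("n_fire must be an integer >= 1", call. = FALSE)
  }
  p
}

#' @export
print.fs_params <- function(x, ...) {
  cat("<fs_params> forest-savanna model parameters\n")
  v <- unlist(unclass(x))
  cat(paste0("  ", format(names(v), width = 6), " = ", format(v)),
      sep = "\n")
  invisible(x)
}

#' Read and write parameter configuration files
#'
#' Parameter sets are stored as flat `key = value` text files (one pair per
#' line, `#` for comments). The bundled file
#' `system.file("extdata", "table1_defaults.cfg", package = "treefronts")`
#' reproduces the default calibration bit-exactly.
#'
#' @param path file path.
#' @return `read_params()` returns an [fs_params()] object; `write_params()`
#'   invisibly returns `path`.
#' @examples
#' p <- read_params(system.file("extdata", "table1_defaults.cfg",
#'                              package = "treefronts"))
#' identical(p, fs_params())
#' @export
read_params <- function(path) {
  kv <- read_config(path)
  do.call(fs_params, kv)
}

#' @rdname read_params
#' @param params an [fs_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "fs_params"))
  write_config(unclass(params), path,
               header = "forest-savanna model parameters")
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Minimal `key = value` format: one pair per line, `#` starts a comment,
#' values are parsed as numbers where possible and kept as strings otherwise.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key = value'): ", ln,
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param x named list of scalar values.
#' @param header optional comment placed at the top of the file.
#' @export
write_config <- function(x, path, header = NULL) {
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  fmt <- vapply(x, function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, character(1))
  lines <- paste(names(x), "=", fmt)
  if (!is.null(header)) lines <- c(paste("#", header), lines)
  writeLines(lines, path)
  invisible(path)
}
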