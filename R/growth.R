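#' Growth curves and doubling times
#'
#' The external medium is shared by a growing population: per-cell fluxes are
#' multiplied by the instantaneous cell density. Growth between samples is
#' multiplicative, so the interpolation contract is piecewise linear in
#' log(cell density), with constant extrapolation beyond the endpoints.
#'
#' @name growth
NULL

#' Construct a growth curve
#'
#' @param times_h Strictly increasing sample times in hours (at least 2).
#' @param density_cells_ml Positive cell densities (cells/mL).
#' @return A `growth_curve` object.
#' @export
growth_curve <- function(times_h, density_cells_ml) {
  stopifnot(is.numeric(times_h), is.numeric(density_cells_ml),
            length(times_h) == length(density_cells_ml))
  if (length(times_h) < 2L) {
    stop("a growth curve needs at least 2 points", call. = FALSE)
  }
  if (any(diff(times_h) <= 0)) {
    stop("growth-curve times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(density_cells_ml)) || any(density_cells_ml <= 0)) {
    stop("cell densities must be positive and finite", call. = FALSE)
  }
  structure(
    list(times_h = as.numeric(times_h),
         density_cells_ml = as.numeric(density_cells_ml)),
    class = "growth_curve"
  )
}

#' Evaluate a growth curve
#'
#' Piecewise-linear interpolation in log density (exponential growth between
#' samples); constant beyond the first/last sample.
#'
#' @param growth A `growth_curve`.
#' @param t Times (h) at which to evaluate.
#' @return Cell density in cells/mL.
#' @export
growth_density <- function(growth, t) {
  stopifnot(inherits(growth, "growth_curve"))
  exp(stats::approx(growth$times_h, log(growth$density_cells_ml),
                    xout = t, rule = 2)$y)
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve: %d points, %g-%g h, %.3g-%.3g cells/mL>\n",
              length(x$times_h), min(x$times_h), max(x$times_h),
              min(x$density_cells_ml), max(x$density_cells_ml)))
  invisible(x)
}

#' Windowed doubling time
#'
#' ln(2) divided by the least-squares slope of log(cell density) against time
#' using the samples that fall inside `window` (inclusive). A flat or
#' decreasing density yields `Inf` with a warning.
#'
#' @param growth A `growth_curve`.
#' @param window Two-element numeric `[lo, hi]` in hours.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(growth, window) {
  stopifnot(inherits(growth, "growth_curve"),
            is.numeric(window), length(window) == 2L, window[1] < window[2])
  keep <- growth$times_h >= window[1] & growth$times_h <= window[2]
  if (sum(keep) < 2L) {
    stop("need at least 2 growth samples inside the window", call. = FALSE)
  }
  t <- growth$times_h[keep]
  y <- log(growth$density_cells_ml[keep])
  slope <- stats::cov(t, y) / stats::var(t)
  if (!is.finite(slope) || slope <= 0) {
    warning("non-increasing density in window; doubling time is infinite")
    return(Inf)
  }
  log(2) / slope
}
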