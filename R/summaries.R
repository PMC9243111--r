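#' Trajectory summary statistics
#'
#' Onset and depletion times are linearly interpolated threshold crossings;
#' peaks use parabolic refinement around the grid argmax (exact for a
#' quadratic and accurate for smooth maxima on a 0.1 h grid).
#'
#' @name summaries
NULL

check_series <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) == 0L || length(times) != length(values)) {
    stop("series must be nonempty with matching times and values",
         call. = FALSE)
  }
}

#' First upward threshold crossing of a concentration series
#'
#' @param times Times, h.
#' @param values Concentrations, mM.
#' @param threshold Positive threshold, mM (default 1, a value near the
#'   bottom of the HPLC calibration range).
#' @return Interpolated crossing time (h), or `NA` if never crossed from
#'   below.
#' @export
onset_time <- function(times, values, threshold = 1) {
  check_series(times, values)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (values[1] >= threshold) return(times[1])
  i <- which(values >= threshold)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- times[i - 1]; t1 <- times[i]
  v0 <- values[i - 1]; v1 <- values[i]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' First downward crossing below a threshold
#'
#' @param times Times, h.
#' @param values Concentrations, mM.
#' @param threshold Depletion threshold, mM; default 1% of the initial value.
#' @return Interpolated crossing time (h), or `NA` if the series never falls
#'   below the threshold.
#' @export
depletion_time <- function(times, values, threshold = 0.01 * values[1]) {
  check_series(times, values)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (values[1] <= threshold) return(times[1])
  i <- which(values <= threshold)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- times[i - 1]; t1 <- times[i]
  v0 <- values[i - 1]; v1 <- values[i]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Peak of a concentration series
#'
#' Grid argmax refined by fitting a parabola through the maximal point and
#' its neighbours; ties break to the earliest time, and boundary maxima are
#' returned unrefined.
#'
#' @param times Times, h.
#' @param values Concentrations, mM.
#' @return Named vector `c(t_peak, c_peak)`.
#' @export
peak <- function(times, values) {
  check_series(times, values)
  i <- which.max(values)
  if (i == 1L || i == length(values)) {
    return(c(t_peak = times[i], c_peak = values[i]))
  }
  t3 <- times[(i - 1):(i + 1)]
  v3 <- values[(i - 1):(i + 1)]
  d1 <- (v3[3] - v3[1]) / 2
  d2 <- v3[1] - 2 * v3[2] + v3[3]
  if (d2 >= 0) {
    return(c(t_peak = times[i], c_peak = values[i]))
  }
  delta <- -d1 / d2
  h <- t3[2] - t3[1]
  c(t_peak = t3[2] + delta * h,
    c_peak = v3[2] - d1^2 / (2 * d2))
}
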