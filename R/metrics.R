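# Kinetic landmark metrics extracted from ratio (or concentration) traces.
# All metrics use linear interpolation between samples, matching the
# sub-frame precision of the reported landmark times.

# first upward/downward linear-interpolated crossing of `level` in y(t),
# restricted to t >= after.  direction +1: upward, -1: downward.
first_crossing <- function(t, y, level, direction = 1, after = 0) {
  keep <- t >= after
  t <- t[keep]; y <- y[keep]
  if (length(t) < 2) return(NA_real_)
  if (direction > 0) hit <- y[-1] >= level & y[-length(y)] < level
  else hit <- y[-1] <= level & y[-length(y)] > level
  i <- which(hit)
  if (!length(i)) {
    # the first sample may already be past the level
    if ((direction > 0 && y[1] >= level) || (direction < 0 && y[1] <= level))
      return(t[1])
    return(NA_real_)
  }
  i <- i[1L]
  frac <- (level - y[i]) / (y[i + 1L] - y[i])
  t[i] + frac * (t[i + 1L] - t[i])
}

baseline_mean <- function(t, y, lh_time = 0, baseline_window = NULL) {
  pre <- if (is.null(baseline_window)) t < lh_time
  else t >= lh_time - baseline_window & t < lh_time
  if (sum(pre) < 5)
    stop("need at least 5 baseline samples before LH")
  mean(y[pre])
}

#' Time to reach a fraction of the peak rise
#'
#' Time after LH at which a trace first reaches
#' baseline + fraction * (peak - baseline), where the baseline is the mean
#' over the pre-LH window and the peak is the post-LH maximum.  Crossing
#' times are linearly interpolated between samples.  This is the
#' "time to reach 50% of the peak ratio" landmark used to order the
#' mural -> cumulus -> oocyte propagation of the cAMP rise.
#'
#' @param t Time grid (min, LH at `lh_time`).
#' @param y Trace values on that grid (ratio or concentration).
#' @param fraction Fraction of the rise (default 0.5).
#' @param lh_time Time of LH addition (min, default 0).
#' @param baseline_window Minutes of baseline before LH to average; `NULL`
#'   (default) uses all pre-LH samples.
#' @return Time in min after LH.
#' @export
time_to_fraction_of_peak <- function(t, y, fraction = 0.5, lh_time = 0,
                                     baseline_window = NULL) {
  stopifnot(length(t) == length(y), fraction > 0, fraction <= 1)
  base <- baseline_mean(t, y, lh_time, baseline_window)
  post <- t >= lh_time
  peak <- max(y[post])
  if (peak <= base) stop("trace has no post-LH rise above baseline")
  level <- base + fraction * (peak - base)
  first_crossing(t, y, level, direction = 1, after = lh_time) - lh_time
}

#' Time to a fractional decline toward the post-LH minimum
#'
#' Time after LH at which a trace has decreased by `fraction` of the way
#' from the pre-LH baseline to the post-LH minimum (the "decreased by 25%
#' from the baseline to the minimum level" landmark used to show that the
#' oocyte cGMP fall precedes the cAMP fall).
#'
#' @inheritParams time_to_fraction_of_peak
#' @param fraction Fraction of the total decline (default 0.25).
#' @return Time in min after LH.
#' @export
time_to_fractional_decline <- function(t, y, fraction = 0.25, lh_time = 0,
                                       baseline_window = NULL) {
  stopifnot(length(t) == length(y), fraction > 0, fraction <= 1)
  base <- baseline_mean(t, y, lh_time, baseline_window)
  post <- t >= lh_time
  mn <- min(y[post])
  if (mn >= base) stop("trace has no post-LH decline below baseline")
  level <- base - fraction * (base - mn)
  first_crossing(t, y, level, direction = -1, after = lh_time) - lh_time
}

#' Time at which a trace first falls below its pre-LH baseline
#'
#' First downward crossing of the baseline after the post-LH peak (the
#' oocyte cAMP transient rises first, so the crossing is searched after
#' the peak time).
#'
#' @inheritParams time_to_fraction_of_peak
#' @return Time in min after LH, or `NA` if the trace never falls below
#'   baseline.
#' @export
time_below_baseline <- function(t, y, lh_time = 0, baseline_window = NULL) {
  base <- baseline_mean(t, y, lh_time, baseline_window)
  post <- t >= lh_time
  tpk <- t[post][which.max(y[post])]
  ans <- first_crossing(t, y, base, direction = -1, after = tpk)
  if (is.na(ans)) NA_real_ else ans - lh_time
}

#' Time at which a trace first comes within a tolerance of its post-LH minimum
#'
#' First time after LH at which the trace is within `within` of the total
#' drop from baseline to the post-LH minimum, i.e. y(t) <= min +
#' within * (baseline - min).  Used for the "time to reach the minimum
#' level" comparison of mural cGMP between wild-type and
#' dephosphorylation-blocked follicles.
#'
#' @inheritParams time_to_fraction_of_peak
#' @param within Fractional tolerance of the drop (default 0.05).
#' @return Time in min after LH.
#' @export
time_to_minimum <- function(t, y, within = 0.05, lh_time = 0,
                            baseline_window = NULL) {
  time_to_fractional_decline(t, y, fraction = 1 - within, lh_time = lh_time,
                             baseline_window = baseline_window)
}

#' Kinetic landmark summary of a single trace
#'
#' Computes the full set of landmark metrics for one trace: baseline,
#' post-LH peak and minimum (values and times), time to 50% of the peak
#' rise, time to 25% decline, and time below baseline.
#'
#' @inheritParams time_to_fraction_of_peak
#' @return A one-row data.frame of class `kinetic_metrics`.
#' @export
kinetic_metrics <- function(t, y, lh_time = 0, baseline_window = NULL) {
  base <- baseline_mean(t, y, lh_time, baseline_window)
  post <- t >= lh_time
  tp <- t[post]; yp <- y[post]
  pk <- which.max(yp); mn <- which.min(yp)
  out <- data.frame(
    baseline = base,
    peak_value = yp[pk], peak_time = tp[pk] - lh_time,
    min_value = yp[mn], min_time = tp[mn] - lh_time,
    t50_peak = tryCatch(
      time_to_fraction_of_peak(t, y, 0.5, lh_time, baseline_window),
      error = function(e) NA_real_),
    t25_decline = tryCatch(
      time_to_fractional_decline(t, y, 0.25, lh_time, baseline_window),
      error = function(e) NA_real_),
    t_below_baseline = time_below_baseline(t, y, lh_time, baseline_window)
  )
  class(out) <- c("kinetic_metrics", "data.frame")
  out
}
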