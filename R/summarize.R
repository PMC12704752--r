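#' Per-timepoint summary across follicles
#'
#' Mean, SEM and 95% confidence interval of the corrected ratio per ROI
#' and timepoint across a collection of follicles (the format of the
#' published group traces).  Traces on different grids are resampled to a
#' common grid by linear interpolation.
#'
#' @param traces A list of `ratio_traces` data.frames (one per follicle).
#' @param grid Optional common time grid; default the first follicle's.
#' @return A data.frame with `t_min`, `roi`, `n`, `mean`, `sem`, `ci_lo`,
#'   `ci_hi`.
#' @export
summarize_traces <- function(traces, grid = NULL) {
  if (length(traces) < 2) stop("SEM undefined for a single trace")
  if (is.null(grid)) grid <- sort(unique(traces[[1]]$t_min))
  rois <- unique(traces[[1]]$roi)
  out <- list()
  for (r in rois) {
    vals <- vapply(traces, function(tr) {
      sub <- tr[tr$roi == r & !is.na(tr$ratio), ]
      stats::approx(sub$t_min, sub$ratio, xout = grid, rule = 2)$y
    }, numeric(length(grid)))
    n <- ncol(vals)
    mu <- rowMeans(vals)
    sem <- apply(vals, 1, stats::sd) / sqrt(n)
    tcrit <- stats::qt(0.975, n - 1)
    out[[r]] <- data.frame(t_min = grid, roi = r, n = n, mean = mu,
                           sem = sem, ci_lo = mu - tcrit * sem,
                           ci_hi = mu + tcrit * sem, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Bin NEBD times in 15-min increments
#'
#' Histogram and cumulative percentage of nuclear-envelope-breakdown
#' times, binned in 15-min increments from t = 0 (the format used to
#' compare NEBD timing between arms).
#'
#' @param nebd_times NEBD times (min after LH); `NA`s (no NEBD) are
#'   counted in the denominator of the cumulative percentage.
#' @param bin_width Bin width in min (default 15).
#' @return A data.frame with `bin_start`, `bin_end`, `count`,
#'   `cum_percent`.
#' @export
bin_nebd_times <- function(nebd_times, bin_width = 15) {
  n_total <- length(nebd_times)
  obs <- nebd_times[!is.na(nebd_times)]
  if (!length(obs))
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer(), cum_percent = numeric()))
  top <- ceiling(max(obs) / bin_width) * bin_width
  edges <- seq(0, top, by = bin_width)
  idx <- findInterval(obs, edges, rightmost.closed = FALSE)
  count <- tabulate(idx, nbins = length(edges) - 1)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             count = count,
             cum_percent = 100 * cumsum(count) / n_total)
}
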