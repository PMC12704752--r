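# Channel correction and ROI trace extraction.

#' Background and spectral-overlap correction
#'
#' Applies the measurement pipeline's fixed order of operations: first
#' background subtraction in each channel, then spectral-overlap
#' correction of the YFP channel by subtracting `alpha` (default 0.23)
#' times the background-subtracted CFP intensity.  If the corrected YFP
#' signal falls at or below `floor`, the ratio is undefined and flagged
#' rather than raising an error.
#'
#' @param cfp_mean,yfp_mean_raw Mean ROI intensities (counts).
#' @param cfp_bg,yfp_bg Background intensities per channel (counts).
#' @param alpha Bleed-through fraction of CFP into YFP, in [0, 1).
#' @param floor Minimum corrected YFP signal for a defined ratio.
#' @return A list with `cfp_corr`, `yfp_corr`, `ratio` (NA when
#'   undefined) and `qc` (`"ok"` or `"low_yfp"`), vectorised.
#' @examples
#' correct_channels(200, 446, 0, 0, alpha = 0.23)  # ratio 0.5
#' @export
correct_channels <- function(cfp_mean, yfp_mean_raw, cfp_bg, yfp_bg,
                             alpha = 0.23, floor = 1) {
  stopifnot(all(cfp_mean >= 0), all(yfp_mean_raw >= 0),
            alpha >= 0, alpha < 1)
  cfp_corr <- cfp_mean - cfp_bg
  yfp_corr <- (yfp_mean_raw - yfp_bg) - alpha * cfp_corr
  bad <- yfp_corr <= floor
  ratio <- ifelse(bad, NA_real_, cfp_corr / yfp_corr)
  # zero signal in both channels is a defined (zero) ratio only when cfp is 0
  ratio[!bad & cfp_corr <= 0] <- pmax(cfp_corr, 0)[!bad & cfp_corr <= 0]
  list(cfp_corr = cfp_corr, yfp_corr = yfp_corr, ratio = ratio,
       qc = ifelse(bad, "low_yfp", "ok"))
}

#' Extract corrected ratio traces from a stack
#'
#' For each frame and ROI, computes the mean CFP and raw YFP intensities
#' over the mask and applies [correct_channels()].  Backgrounds are taken
#' per channel either from a set of "uninjected" fixture stacks
#' (autofluorescence only, averaged over follicles and frames — the
#' protocol used in the original measurements) or, by default, from the
#' stack's own extra-follicular background ROI, per frame.
#'
#' @param stack An `image_stack` (aligned, if it carries jitter).
#' @param rois A `roi_set`.
#' @param alpha Bleed-through fraction (default 0.23).
#' @param background_stacks Optional list of `image_stack`s of uninjected
#'   follicles used to determine the per-channel background.
#' @return A data.frame of class `ratio_traces`: `t_min`, `roi`,
#'   `cfp_corr`, `yfp_corr`, `ratio`, `qc`.
#' @export
extract_traces <- function(stack, rois, alpha = 0.23,
                           background_stacks = NULL) {
  signal_rois <- setdiff(names(rois), c("background", "nucleus"))
  if (any(vapply(rois[signal_rois], function(m) sum(m) == 0, logical(1))))
    stop("empty ROI mask")

  fixed_bg <- NULL
  if (!is.null(background_stacks)) {
    pool <- function(ch) mean(vapply(background_stacks, function(s)
      mean(vapply(s$frames, function(f) mean(f[[ch]]), numeric(1))),
      numeric(1)))
    fixed_bg <- c(cfp = pool("cfp"), yfp = pool("yfp"))
  }

  out <- vector("list", length(stack$frames))
  for (i in seq_along(stack$frames)) {
    f <- stack$frames[[i]]
    if (is.null(fixed_bg)) {
      bg_c <- mean(f$cfp[rois$background])
      bg_y <- mean(f$yfp[rois$background])
    } else {
      bg_c <- fixed_bg[["cfp"]]; bg_y <- fixed_bg[["yfp"]]
    }
    cfp <- vapply(signal_rois, function(r) mean(f$cfp[rois[[r]]]), numeric(1))
    yfp <- vapply(signal_rois, function(r) mean(f$yfp[rois[[r]]]), numeric(1))
    cc <- correct_channels(cfp, yfp, bg_c, bg_y, alpha)
    out[[i]] <- data.frame(t_min = stack$frame_times[i], roi = signal_rois,
                           cfp_corr = cc$cfp_corr, yfp_corr = cc$yfp_corr,
                           ratio = cc$ratio, qc = cc$qc,
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("ratio_traces", "data.frame")
  res
}

#' Detect nuclear envelope breakdown in a stack
#'
#' NEBD is detected as the appearance of fluorescence in the previously
#' sensor-excluded nuclear region: the first frame at which the mean
#' nuclear intensity reaches `high` times the mean oocyte-cytoplasm
#' intensity, after having been below `low` times it in all prior frames.
#'
#' @param stack An `image_stack`.
#' @param rois A `roi_set` with non-empty `nucleus` and `oocyte` masks.
#' @param low,high Relative intensity thresholds (defaults 0.4 / 0.7).
#' @return Frame time (min) of NEBD, or `NA` if not detected.
#' @export
detect_nebd <- function(stack, rois, low = 0.4, high = 0.7) {
  if (!any(rois$nucleus)) stop("nucleus mask is empty")
  rel <- vapply(stack$frames, function(f) {
    tot <- f$cfp + f$yfp
    mean(tot[rois$nucleus]) / mean(tot[rois$oocyte])
  }, numeric(1))
  for (i in seq_along(rel)) {
    if (rel[i] >= high && (i == 1 || all(rel[seq_len(i - 1)] < low)))
      return(stack$frame_times[i])
  }
  NA_real_
}
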