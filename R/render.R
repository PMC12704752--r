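# Rendering of two-channel 16-bit time-lapse stacks from compartment traces.

#' Acquisition schedule
#'
#' Frame times matching the recording protocol: one frame per minute for
#' 10 min of baseline and for the first hour after LH addition (no frame
#' at t = 0, when LH is perfused), then one frame every 5 min.
#'
#' @param t_end Last frame time (min after LH).
#' @param baseline Minutes of baseline recording (default 10).
#' @return Numeric vector of frame times (min).
#' @examples
#' length(acquisition_times(310))  # 120 frames
#' @export
acquisition_times <- function(t_end, baseline = 10) {
  stopifnot(t_end > 60, baseline >= 5)
  c(seq(-baseline, -1), seq(1, 60), seq(65, t_end, by = 5))
}

# split total sensor brightness B into CFP and YFP so that CFP/YFP = R
channel_split <- function(B, R) list(cfp = B * R / (1 + R), yfp = B / (1 + R))

#' Render one two-channel frame
#'
#' Renders the CFP and YFP channels of the scene for given per-region
#' concentrations.  Per pixel, the total sensor brightness is the region's
#' expression level; it is split between the channels so that the
#' corrected CFP/YFP ratio equals the calibration ratio of the region's
#' concentration.  The nucleus excludes the sensor before `nebd_time` and
#' fills with oocyte-level fluorescence after it; antral patches and the
#' area outside the follicle carry only autofluorescence background.
#' CFP spectral bleed-through (`bleedthrough_alpha` x CFP) is added to the
#' YFP channel before noise; Poisson shot noise and Gaussian read noise
#' are then applied and the result clipped to the 16-bit range.
#'
#' @param scene A [follicle_scene()] object.
#' @param conc Named concentrations (nM): `mural`, `cumulus`, `oocyte`.
#' @param calib A [sensor_calibration()] object.
#' @param t Frame time (min), used only for the NEBD switch.
#' @param shift Translation of the follicle in pixels, `c(dx, dy)`.
#' @param noise Logical; apply shot and read noise (default TRUE).
#' @return List with integer matrices `cfp` and `yfp` (counts in
#'   0..65535) and the label matrix `labels`.
#' @export
render_frame <- function(scene, conc, calib, t = 0, shift = c(0, 0),
                         noise = TRUE) {
  req <- c("mural", "cumulus", "oocyte")
  if (!all(req %in% names(conc)) || any(!is.finite(unlist(conc[req]))))
    stop("conc must supply finite 'mural', 'cumulus' and 'oocyte' values")
  lab <- scene_label_image(scene, shift)
  bg <- scene$background_level

  # mural brightness so baseline YFP signal = s2b x background
  R0 <- ratio_from_concentration(700, calib)
  B_mural <- scene$signal_to_background * bg[["yfp"]] * (1 + R0)
  B <- c(outer_mural = B_mural, inner_granulosa = B_mural,
         cumulus = B_mural * scene$cumulus_expression,
         oocyte = B_mural * scene$oocyte_expression,
         theca = 0.25 * B_mural)
  Rg <- c(outer_mural = ratio_from_concentration(conc[["mural"]], calib),
          inner_granulosa = ratio_from_concentration(conc[["mural"]], calib),
          cumulus = ratio_from_concentration(conc[["cumulus"]], calib),
          oocyte = ratio_from_concentration(conc[["oocyte"]], calib),
          theca = R0)

  n <- scene$frame_size
  cfp <- matrix(bg[["cfp"]], n, n)
  yfp <- matrix(bg[["yfp"]], n, n)
  nebd_done <- !is.na(scene$nebd_time) && t >= scene$nebd_time
  for (rg in names(B)) {
    m <- lab == region_labels[[rg]]
    if (rg == "oocyte") {
      # nucleus: sensor-excluded before NEBD, oocyte-like after
      if (nebd_done) m <- m | lab == region_labels[["nucleus"]]
    }
    if (!any(m)) next
    ch <- channel_split(B[[rg]], Rg[[rg]])
    cfp[m] <- cfp[m] + ch$cfp
    yfp[m] <- yfp[m] + ch$yfp
  }
  yfp <- yfp + scene$bleedthrough_alpha * cfp

  if (noise) {
    cfp <- stats::rpois(length(cfp), cfp) +
      stats::rnorm(length(cfp), 0, scene$read_noise_frac * cfp)
    yfp <- stats::rpois(length(yfp), yfp) +
      stats::rnorm(length(yfp), 0, scene$read_noise_frac * yfp)
    dim(cfp) <- c(n, n); dim(yfp) <- c(n, n)
  }
  clip16 <- function(m) {
    m <- round(m); m[m < 0] <- 0; m[m > 65535] <- 65535
    storage.mode(m) <- "integer"; m
  }
  list(cfp = clip16(cfp), yfp = clip16(yfp), labels = lab)
}

#' Render a two-channel time-lapse stack
#'
#' Drives [render_frame()] over the acquisition schedule covered by the
#' supplied compartment traces, with per-frame translational jitter drawn
#' from Normal(0, `jitter_sd`).  The result carries full ground truth:
#' label masks (from the unshifted scene), the true per-region CFP/YFP
#' ratio traces, the true shifts, and the NEBD frame index.  Deterministic
#' for a fixed scene seed.
#'
#' @param scene A [follicle_scene()] object.
#' @param traces A `compartment_traces` data.frame from
#'   [simulate_follicle()]; must cover the acquisition window.
#' @param calib A [sensor_calibration()] object.
#' @param times Frame times (min); default the standard schedule over the
#'   trace window.
#' @param noise Logical; apply shot/read noise.
#' @return An object of class `image_stack`: list with `frames` (list of
#'   `cfp`/`yfp` integer matrices), `frame_times`, and `ground_truth`
#'   (label masks, true ratio traces, true shifts, `nebd_frame`).
#' @export
render_timelapse <- function(scene, traces, calib = sensor_calibration("cAMPFIRE-M"),
                             times = NULL, noise = TRUE) {
  if (is.null(times))
    times <- acquisition_times(floor(max(traces$t_min)),
                               baseline = min(10, -floor(min(traces$t_min))))
  if (min(times) < min(traces$t_min) || max(times) > max(traces$t_min))
    stop("traces do not cover the acquisition schedule")
  set.seed(scene$seed)
  shifts <- matrix(stats::rnorm(2 * length(times), 0, scene$jitter_sd),
                   ncol = 2, dimnames = list(NULL, c("dx", "dy")))
  interp <- function(col) stats::approx(traces$t_min, traces[[col]],
                                        xout = times)$y
  conc <- data.frame(mural = interp("cAMP_mural"),
                     cumulus = interp("cAMP_cumulus"),
                     oocyte = interp("cAMP_oocyte"))

  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    fr <- render_frame(scene, as.list(conc[i, ]), calib, t = times[i],
                       shift = shifts[i, ], noise = noise)
    frames[[i]] <- fr[c("cfp", "yfp")]
  }
  truth_ratio <- data.frame(
    t_min = times,
    outer_mural = ratio_from_concentration(conc$mural, calib),
    cumulus = ratio_from_concentration(conc$cumulus, calib),
    oocyte = ratio_from_concentration(conc$oocyte, calib))
  nebd_frame <- if (!is.na(scene$nebd_time))
    which(times >= scene$nebd_time)[1] else NA_integer_

  structure(list(
    frames = frames, frame_times = times,
    ground_truth = list(labels = scene_label_image(scene),
                        ratio = truth_ratio, shifts = shifts,
                        nebd_frame = nebd_frame),
    scene = scene, calib = calib
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("Two-channel 16-bit image stack: %d frames of %dx%d px, t = %g..%g min\n",
              length(x$frames), x$scene$frame_size, x$scene$frame_size,
              min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' Write an image stack to TIFF plus sidecar files
#'
#' Writes one multi-page 16-bit TIFF per channel, a JSON sidecar with the
#' frame times, seed and NEBD frame, a CSV of the true ratio traces, and a
#' PNG-style label TIFF of the ground-truth masks.
#'
#' @param stack An `image_stack`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_image_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tos <- function(ch) lapply(stack$frames, function(f) f[[ch]] / 65535)
  paths <- c(cfp = file.path(dir, "cfp.tif"), yfp = file.path(dir, "yfp.tif"),
             labels = file.path(dir, "labels.tif"),
             sidecar = file.path(dir, "stack.json"),
             truth = file.path(dir, "true_ratio.csv"))
  tiff::writeTIFF(tos("cfp"), paths[["cfp"]], bits.per.sample = 16L)
  tiff::writeTIFF(tos("yfp"), paths[["yfp"]], bits.per.sample = 16L)
  tiff::writeTIFF(stack$ground_truth$labels / 255, paths[["labels"]],
                  bits.per.sample = 8L)
  jsonlite::write_json(list(frame_times = stack$frame_times,
                            seed = stack$scene$seed,
                            nebd_frame = stack$ground_truth$nebd_frame,
                            shifts = stack$ground_truth$shifts),
                       paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(stack$ground_truth$ratio, paths[["truth"]],
                   row.names = FALSE)
  invisible(paths)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param dir Directory containing `cfp.tif`, `yfp.tif`, `labels.tif` and
#'   `stack.json`.
#' @return An `image_stack` (without the generating scene).
#' @export
read_image_stack <- function(dir) {
  cfp <- tiff::readTIFF(file.path(dir, "cfp.tif"), all = TRUE)
  yfp <- tiff::readTIFF(file.path(dir, "yfp.tif"), all = TRUE)
  side <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  labs <- tiff::readTIFF(file.path(dir, "labels.tif"))
  frames <- Map(function(a, b) list(
    cfp = matrix(as.integer(round(a * 65535)), nrow(a), ncol(a)),
    yfp = matrix(as.integer(round(b * 65535)), nrow(b), ncol(b))), cfp, yfp)
  truth_file <- file.path(dir, "true_ratio.csv")
  structure(list(frames = frames, frame_times = side$frame_times,
                 ground_truth = list(labels = round(labs * 255),
                                     ratio = if (file.exists(truth_file))
                                       utils::read.csv(truth_file) else NULL,
                                     shifts = side$shifts,
                                     nebd_frame = side$nebd_frame),
                 scene = NULL, calib = NULL),
            class = "image_stack")
}
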