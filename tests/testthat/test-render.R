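# Synthetic two-channel time-lapse generator.

test_that("acquisition schedule matches the recording protocol", {
  tt <- acquisition_times(310)
  expect_length(tt, 120)  # 10 baseline + 60 one-min + 50 five-min
  expect_true(all(diff(tt) > 0))
  expect_equal(sum(tt < 0), 10)
  expect_true(all(diff(tt[tt >= 65]) == 5))
})

test_that("rendering is deterministic for a fixed seed", {
  scene <- small_scene(frame_size = 96, jitter_sd = 0.8)
  tr <- simulate_follicle(t_end = 70, dt_out = 1)
  times <- acquisition_times(70)[1:15]
  s1 <- render_timelapse(scene, tr, times = times)
  s2 <- render_timelapse(scene, tr, times = times)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$ground_truth$shifts, s2$ground_truth$shifts)
})

test_that("zero jitter gives zero true shifts", {
  scene <- small_scene(frame_size = 96, jitter_sd = 0)
  tr <- simulate_follicle(t_end = 70, dt_out = 1)
  st <- render_timelapse(scene, tr, times = acquisition_times(70)[1:5],
                         noise = FALSE)
  expect_true(all(st$ground_truth$shifts == 0))
})

test_that("noise-free ROI ratio equals the calibration ratio", {
  scene <- small_scene(frame_size = 128, bleedthrough_alpha = 0)
  cal <- sensor_calibration("cAMPFIRE-M")
  conc <- list(mural = 3400, cumulus = 1200, oocyte = 450)
  fr <- render_frame(scene, conc, cal, t = 0, noise = FALSE)
  rois <- rois_from_scene(scene)
  for (rg in c("outer_mural", "cumulus", "oocyte")) {
    key <- c(outer_mural = "mural", cumulus = "cumulus", oocyte = "oocyte")[[rg]]
    cfp <- mean(fr$cfp[rois[[rg]]]) - scene$background_level[["cfp"]]
    yfp <- mean(fr$yfp[rois[[rg]]]) - scene$background_level[["yfp"]]
    expect_equal(cfp / yfp, ratio_from_concentration(conc[[key]], cal),
                 tolerance = 1e-3)
  }
})

test_that("nucleus is dark before NEBD and filled after", {
  scene <- small_scene(frame_size = 128, nebd_time = 130)
  cal <- sensor_calibration("cAMPFIRE-M")
  conc <- list(mural = 3400, cumulus = 1200, oocyte = 450)
  rois <- rois_from_scene(scene)
  pre <- render_frame(scene, conc, cal, t = 100, noise = FALSE)
  post <- render_frame(scene, conc, cal, t = 135, noise = FALSE)
  rel <- function(fr) mean((fr$cfp + fr$yfp)[rois$nucleus]) /
    mean((fr$cfp + fr$yfp)[rois$oocyte])
  expect_lt(rel(pre), 0.4)
  expect_gt(rel(post), 0.8)
})

test_that("corrected ratio is invariant to 5-fold expression scaling", {
  cal <- sensor_calibration("cAMPFIRE-M")
  conc <- list(mural = 700, cumulus = 700, oocyte = 700)
  ratios <- vapply(c(0.5, 1, 2.5), function(expr) {
    scene <- small_scene(frame_size = 128, oocyte_expression = expr)
    fr <- render_frame(scene, conc, cal, t = -5, noise = FALSE)
    rois <- rois_from_scene(scene)
    # backgrounds measured from the extra-follicular ROI, which carries
    # the same bleed-through as the tissue pixels
    cc <- correct_channels(mean(fr$cfp[rois$oocyte]),
                           mean(fr$yfp[rois$oocyte]),
                           mean(fr$cfp[rois$background]),
                           mean(fr$yfp[rois$background]),
                           alpha = scene$bleedthrough_alpha)
    cc$ratio
  }, numeric(1))
  expect_lt(max(abs(ratios - ratios[1]) / ratios[1]), 0.005)
})

test_that("baseline mural signal-to-background is within the 3-10x window", {
  scene <- small_scene(frame_size = 128)
  cal <- sensor_calibration("cAMPFIRE-M")
  fr <- render_frame(scene, list(mural = 700, cumulus = 700, oocyte = 700),
                     cal, t = -5, noise = TRUE)
  rois <- rois_from_scene(scene)
  s2b <- (mean(fr$yfp[rois$outer_mural]) - mean(fr$yfp[rois$background])) /
    mean(fr$yfp[rois$background])
  # bleed-through adds CFP counts on top of the nominal YFP signal
  expect_gt(s2b, 3)
  expect_lt(s2b, 10 * (1 + scene$bleedthrough_alpha))
})

test_that("stacks round-trip through TIFF plus sidecar", {
  scene <- small_scene(frame_size = 64, jitter_sd = 0.3, seed = 5)
  tr <- simulate_follicle(t_end = 70, dt_out = 1)
  st <- render_timelapse(scene, tr, times = acquisition_times(70)[1:6])
  dir <- tempfile("stack")
  write_image_stack(st, dir)
  st2 <- read_image_stack(dir)
  expect_equal(st2$frame_times, st$frame_times)
  expect_identical(st2$frames[[3]]$cfp, st$frames[[3]]$cfp)
  expect_identical(st2$frames[[6]]$yfp, st$frames[[6]]$yfp)
  expect_equal(as.vector(st2$ground_truth$shifts),
               as.vector(st$ground_truth$shifts), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
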