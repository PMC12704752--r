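# Measurement pipeline: channel correction, registration, ROIs, trace
# extraction and NEBD detection.

test_that("channel correction follows the fixed order of operations", {
  # background first, then 23% spectral overlap
  cc <- correct_channels(200, 446, 0, 0, alpha = 0.23)
  expect_equal(cc$yfp_corr, 400)
  expect_equal(cc$ratio, 0.5)
  # identity when alpha = 0 and no background
  cc0 <- correct_channels(120, 300, 0, 0, alpha = 0)
  expect_equal(cc0$ratio, 120 / 300)
  # fully backgrounded CFP gives zero ratio
  ccz <- correct_channels(50, 400, 50, 100, alpha = 0.23)
  expect_equal(ccz$cfp_corr, 0)
  expect_equal(ccz$ratio, 0)
  # low corrected YFP is QC-flagged, not an error
  ccl <- correct_channels(400, 120, 0, 30, alpha = 0.23)
  expect_true(is.na(ccl$ratio))
  expect_equal(ccl$qc, "low_yfp")
  # regression: overlap before background is NOT equivalent
  wrong_yfp <- (446 - 0.23 * 250) - 40        # overlap on raw cfp, then bg
  right <- correct_channels(250, 446, 50, 40, alpha = 0.23)
  expect_false(isTRUE(all.equal(right$yfp_corr, wrong_yfp)))
})

test_that("geometric ROI bands have the configured widths", {
  rois <- define_rois(frame_size = 512, pixel_size = 0.8,
                      center = c(256.5, 256.5),
                      follicle_radius = 175, oocyte_radius = 37.5,
                      nucleus_radius = 15)
  # mural band 40 um at 0.8 um/px -> 50 px wide along a radius
  row <- rois$outer_mural[257, ]
  width <- max(which(row)) - min(which(row[1:256])) + 1
  # width counted on one side of the follicle
  one_side <- sum(row[1:256])
  expect_lt(abs(one_side - 50), 2)
  cum_side <- sum(rois$cumulus[257, 1:256])
  expect_lt(abs(cum_side - 25 / 0.8), 2)
  # disjoint masks
  overlap <- rois$outer_mural & (rois$cumulus | rois$oocyte | rois$nucleus)
  expect_false(any(overlap))
  expect_error(define_rois(256, 0.8, c(128, 128), follicle_radius = 30,
                           oocyte_radius = 37.5), "inside")
  expect_error(define_rois(256, 0.8, c(128, 128), follicle_radius = 80,
                           oocyte_radius = 37.5), "too small")
})

test_that("ground-truth label masks pass through unchanged", {
  scene <- small_scene(frame_size = 96)
  labels <- follisim:::scene_label_image(scene)
  rois <- rois_from_labels(labels)
  expect_s3_class(rois, "roi_set")
  expect_equal(attr(rois, "provenance"), "ground-truth")
  expect_equal(sum(rois$oocyte), sum(labels == 4))
  expect_false(any(rois$oocyte & rois$cumulus))
})

test_that("registration recovers seeded jitter within 0.5 px RMS", {
  scene <- small_scene(frame_size = 128, jitter_sd = 1, seed = 7)
  tr <- simulate_follicle(t_end = 70, dt_out = 1)
  st <- render_timelapse(scene, tr, times = acquisition_times(70)[1:20])
  reg <- register_stack(st)
  rel_truth <- sweep(st$ground_truth$shifts, 2, st$ground_truth$shifts[1, ])
  err <- reg$estimated_shifts - rel_truth
  expect_lt(sqrt(mean(err^2)), 0.5)
  expect_error(register_stack(list(frames = st$frames[1])), "2 frames")
})

test_that("extracted traces close the loop against generator ground truth", {
  scene <- small_scene(frame_size = 128)
  tr <- simulate_follicle(t_end = 90, dt_out = 0.5)
  st <- render_timelapse(scene, tr, noise = FALSE,
                         times = acquisition_times(90))
  rois <- rois_from_scene(scene)
  rt <- extract_traces(st, rois, alpha = scene$bleedthrough_alpha)
  truth <- st$ground_truth$ratio
  for (rg in c("outer_mural", "cumulus", "oocyte")) {
    sub <- rt[rt$roi == rg, ]
    expect_lt(max(abs(sub$ratio - truth[[rg]]) / truth[[rg]]), 0.005,
              label = paste("closed-loop ratio error,", rg))
  }
  # bleed-through injected at 0.23 and corrected at 0.23: bias < 0.5%
  expect_equal(scene$bleedthrough_alpha, 0.23)
})

test_that("background fixtures from uninjected follicles are usable", {
  scene <- small_scene(frame_size = 96)
  tr <- simulate_follicle(t_end = 70, dt_out = 1)
  times <- acquisition_times(70)[1:6]
  st <- render_timelapse(scene, tr, times = times, noise = FALSE)
  # "uninjected" fixtures: autofluorescence only (zero expression
  # approximated by a vanishing sensor level)
  bg_scenes <- lapply(1:5, function(i)
    small_scene(frame_size = 96, seed = 100 + i))
  bg_stacks <- lapply(bg_scenes, function(sc) {
    sc$signal_to_background <- 3
    fr <- lapply(times, function(t) {
      n <- sc$frame_size
      list(cfp = matrix(as.integer(sc$background_level[["cfp"]]), n, n),
           yfp = matrix(as.integer(round(sc$background_level[["yfp"]] +
                        sc$bleedthrough_alpha * sc$background_level[["cfp"]])),
                        n, n))
    })
    structure(list(frames = fr, frame_times = times), class = "image_stack")
  })
  rois <- rois_from_scene(scene)
  rt <- extract_traces(st, rois, alpha = 0.23, background_stacks = bg_stacks)
  expect_true(all(rt$qc == "ok"))
  # note: fixture background includes the bleed-through of background CFP,
  # matching what an uninjected follicle's YFP channel actually records
  truth <- st$ground_truth$ratio
  sub <- rt[rt$roi == "outer_mural", ]
  expect_lt(max(abs(sub$ratio - truth$outer_mural) / truth$outer_mural), 0.01)
})

test_that("a background ROI used as signal is QC-flagged undefined", {
  scene <- small_scene(frame_size = 96)
  tr <- simulate_follicle(t_end = 70, dt_out = 1)
  st <- render_timelapse(scene, tr, times = acquisition_times(70)[1:4],
                         noise = FALSE)
  rois <- rois_from_scene(scene)
  rois$oocyte <- rois$background  # signal ROI outside the follicle
  rt <- extract_traces(st, rois, alpha = 0.23)
  oo <- rt[rt$roi == "oocyte", ]
  expect_true(all(oo$qc == "low_yfp"))
  expect_true(all(is.na(oo$ratio)))
})

test_that("NEBD is detected within one frame interval of ground truth", {
  tr <- simulate_follicle(t_end = 160, dt_out = 1)
  times <- c(seq(-10, -1), seq(1, 60), seq(65, 160, 5))
  scene <- small_scene(frame_size = 96, nebd_time = 130)
  st <- render_timelapse(scene, tr, times = times, noise = FALSE)
  rois <- rois_from_scene(scene)
  expect_lt(abs(detect_nebd(st, rois) - 130), 5 + 1e-9)
  # no NEBD: none detected
  scene0 <- small_scene(frame_size = 96)
  st0 <- render_timelapse(scene0, tr, times = times, noise = FALSE)
  expect_true(is.na(detect_nebd(st0, rois)))
  rois_empty <- rois; rois_empty$nucleus <- rois$nucleus & FALSE
  expect_error(detect_nebd(st, rois_empty), "empty")
})

test_that("NEBD detection is robust to noise across seeded replicates", {
  tr <- simulate_follicle(t_end = 160, dt_out = 1)
  times <- seq(100, 160, by = 5)
  rois <- rois_from_scene(small_scene(frame_size = 96))
  hits <- vapply(1:20, function(s) {
    scene <- small_scene(frame_size = 96, nebd_time = 130, jitter_sd = 0,
                         seed = 200 + s)
    st <- render_timelapse(scene, tr, times = times, noise = TRUE)
    det <- detect_nebd(st, rois)
    !is.na(det) && abs(det - 130) <= 5
  }, logical(1))
  expect_gte(sum(hits), 19)
})
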