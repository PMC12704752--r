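# Scenario orchestration, perturbation effects, and configuration IO.

test_that("scenario runs are deterministic and match direct simulation", {
  sc <- scenario("wild_type", n_follicles = 1, jitter_cv = 0,
                 t_end = 60, dt_out = 1)
  r1 <- run_scenario(sc)
  r2 <- run_scenario(sc)
  expect_identical(r1$metrics, r2$metrics)
  # no jitter: the single follicle equals the direct simulation
  tr <- simulate_follicle(t_end = 60, dt_out = 1)
  expect_equal(r1$traces[[1]], tr, tolerance = 1e-12)
  # jitter changes the traces but keeps the same seed reproducible
  scj <- scenario("wild_type", n_follicles = 3, jitter_cv = 0.1,
                  t_end = 30, dt_out = 1, seed = 4)
  j1 <- run_scenario(scj); j2 <- run_scenario(scj)
  expect_identical(j1$metrics, j2$metrics)
  expect_false(identical(j1$traces[[1]], j1$traces[[2]]))
})

test_that("blocking NPR2 dephosphorylation delays the mural cGMP fall", {
  wt <- wt_traces()
  mut <- simulate_follicle(perturb = perturbation_config(
    npr2_7E = TRUE, pde5a_S92A = TRUE), t_end = 300, dt_out = 0.5)
  t_wt <- time_to_minimum(wt$t_min, wt$cGMP_mural, within = 0.10)
  t_mut <- time_to_minimum(mut$t_min, mut$cGMP_mural, within = 0.10)
  expect_gt(t_mut, t_wt)
  # oocyte cGMP and cAMP declines correspondingly delayed (a trace that
  # never declines within the window counts as an infinite delay)
  t25 <- function(tr, col) tryCatch(
    time_to_fractional_decline(tr$t_min, tr[[col]], 0.25),
    error = function(e) Inf)
  expect_gt(t25(mut, "cGMP_oocyte"), t25(wt, "cGMP_oocyte"))
  expect_gt(t25(mut, "cAMP_oocyte"), t25(wt, "cAMP_oocyte"))
})

test_that("preventing the Cx43 dip delays the oocyte cAMP decline", {
  wt <- wt_traces()
  ag <- simulate_follicle(perturb = perturbation_config(ag1478 = TRUE),
                          t_end = 330, dt_out = 0.5)
  wt_min <- min(wt$cAMP_oocyte[wt$t_min >= 0])
  t_wt <- follisim:::first_crossing(wt$t_min, wt$cAMP_oocyte, wt_min * 1.001,
                                    direction = -1, after = 5)
  t_ag <- follisim:::first_crossing(ag$t_min, ag$cAMP_oocyte, wt_min * 1.001,
                                    direction = -1, after = 5)
  expect_gt(t_ag, t_wt)
  # NEBD correspondingly delayed
  expect_gt(nebd_time(ag$t_min, ag$cAMP_oocyte),
            nebd_time(wt$t_min, wt$cAMP_oocyte))
  # cGMP kinetics unaffected by the dip
  t25_wt <- time_to_fractional_decline(wt$t_min, wt$cGMP_oocyte, 0.25)
  t25_ag <- time_to_fractional_decline(ag$t_min, ag$cGMP_oocyte, 0.25)
  expect_lt(abs(t25_ag - t25_wt), 1)
})

test_that("carbenoxolone attenuates propagation into cumulus and oocyte", {
  wt <- wt_traces()
  cb <- simulate_follicle(perturb = perturbation_config(carbenoxolone = TRUE),
                          t_end = 60, dt_out = 0.5)
  cal <- sensor_calibration("cAMPFIRE-M")
  rise <- function(tr, col) {
    r <- ratio_from_concentration(tr[[col]], cal)
    max(r[tr$t_min >= 0]) - mean(r[tr$t_min < 0])
  }
  # cumulus response reduced, oocyte response almost abolished
  frac_c <- rise(cb, "cAMP_cumulus") / rise(wt, "cAMP_cumulus")
  frac_o <- rise(cb, "cAMP_oocyte") / rise(wt, "cAMP_oocyte")
  expect_lt(frac_c, 0.5)
  expect_lt(abs(frac_o), 0.10)
})

test_that("clamping CNP holds mural cGMP at baseline", {
  cl <- simulate_follicle(perturb = perturbation_config(
    npr2_7E = TRUE, pde5a_S92A = TRUE, cnp_clamp = TRUE),
    t_end = 300, dt_out = 1)
  base <- mean(cl$cGMP_mural[cl$t_min < 0])
  dev <- abs(cl$cGMP_mural[cl$t_min >= 0] - base) / base
  expect_lt(max(dev), 0.15)
})

test_that("YAML scenario configuration round-trips with strict keys", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "parameters:",
    "  tau_LH: 3.0",
    "perturbation:",
    "  ag1478: true",
    "simulation:",
    "  t_end: 45",
    "  dt_out: 1"), cfg)
  sc <- read_scenario_config(cfg)
  expect_equal(sc$parameters$tau_LH, 3.0)
  expect_true(sc$perturb$ag1478)
  tr <- simulate_from_config(cfg)
  expect_equal(max(tr$t_min), 45)
  writeLines(c("parameters:", "  not_a_rate: 1"), cfg)
  expect_error(read_scenario_config(cfg), "unknown key")
  writeLines(c("bogus_block:", "  a: 1"), cfg)
  expect_error(read_scenario_config(cfg), "unknown configuration block")
  unlink(cfg)
})

test_that("trace CSVs round-trip", {
  tr <- simulate_follicle(t_end = 30, dt_out = 1)
  f <- tempfile(fileext = ".csv")
  write_traces_csv(tr, f)
  tr2 <- read_traces_csv(f)
  expect_equal(tr2$cAMP_oocyte, tr$cAMP_oocyte, tolerance = 1e-5)
  expect_equal(names(tr2)[1], "t_min")
  unlink(f)
})

test_that("collapsed fitting bounds return the start point with its report", {
  free <- follisim:::default_free_vector()
  fit <- fit_default_parameters(free,
                                lower = as.list(free), upper = as.list(free),
                                anchor_ids = c("t4"), dt_out = 1)
  expect_equal(fit$free, free, tolerance = 1e-12)
  expect_true(is.finite(fit$value))
  expect_error(fit_default_parameters(free, as.list(free), as.list(free),
                                      anchor_ids = character(0)), "empty")
})
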