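# Scenario orchestration: named experimental arms, multi-follicle runs,
# and the closed-loop simulate -> render -> analyze validation.

scenario_presets <- list(
  wild_type = list(),
  npr2_7E_pde5a_S92A = list(npr2_7E = TRUE, pde5a_S92A = TRUE),
  ag1478 = list(ag1478 = TRUE),
  carbenoxolone = list(carbenoxolone = TRUE),
  cnp_clamp = list(npr2_7E = TRUE, pde5a_S92A = TRUE, cnp_clamp = TRUE)
)

#' Define a scenario
#'
#' A named experimental arm: a perturbation preset (or custom
#' perturbation), optional parameter overrides, the number of follicles,
#' and a seed for the inter-follicle variability.
#'
#' @param name One of `"wild_type"`, `"npr2_7E_pde5a_S92A"`, `"ag1478"`,
#'   `"carbenoxolone"`, `"cnp_clamp"`, or `"custom"`.
#' @param parameters A [model_parameters()] object.
#' @param perturb A [perturbation_config()]; required for `"custom"`,
#'   otherwise derived from the preset.
#' @param n_follicles Number of follicles to simulate (>= 1).
#' @param jitter_cv Coefficient of variation of the lognormal
#'   inter-follicle jitter applied to `k_GPR3` and `V_NPR2` (default 0.1;
#'   0 disables it).
#' @param seed Integer seed.
#' @param t_end,dt_out Simulation window and output spacing (min).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name = "wild_type",
                     parameters = model_parameters(),
                     perturb = NULL,
                     n_follicles = 1L, jitter_cv = 0,
                     seed = 1L, t_end = 300, dt_out = 0.5) {
  if (is.null(perturb)) {
    if (!name %in% names(scenario_presets))
      stop(sprintf("unknown scenario '%s' and no perturbation supplied", name))
    perturb <- do.call(perturbation_config, scenario_presets[[name]])
  }
  stopifnot(n_follicles >= 1, jitter_cv >= 0)
  structure(list(name = name, parameters = parameters, perturb = perturb,
                 n_follicles = as.integer(n_follicles),
                 jitter_cv = jitter_cv, seed = as.integer(seed),
                 t_end = t_end, dt_out = dt_out),
            class = "scenario")
}

#' Run a scenario
#'
#' Simulates `n_follicles` follicles under the scenario's perturbation.
#' Inter-follicle variability is injected as lognormal jitter (cv
#' `jitter_cv`) on the oocyte cAMP synthesis rate `k_GPR3` and the NPR2
#' rate `V_NPR2`; metrics are computed on the CFP/YFP ratio traces
#' obtained through the cAMP sensor calibration.  Deterministic for a
#' fixed seed.
#'
#' @param sc A [scenario()] object.
#' @param geometry A [follicle_geometry()] object.
#' @param calib A [sensor_calibration()] object for the ratio transform.
#' @return A list with `traces` (list of `compartment_traces`),
#'   `metrics` (data.frame of per-follicle [kinetic_metrics()] on the
#'   oocyte, cumulus and mural cAMP ratio traces), and the scenario.
#' @export
run_scenario <- function(sc, geometry = follicle_geometry(),
                         calib = sensor_calibration("cAMPFIRE-M")) {
  set.seed(sc$seed)
  sdlog <- sqrt(log(1 + sc$jitter_cv^2))
  traces <- vector("list", sc$n_follicles)
  mets <- list()
  for (i in seq_len(sc$n_follicles)) {
    p <- sc$parameters
    if (sc$jitter_cv > 0) {
      fac <- stats::rlnorm(2, -sdlog^2 / 2, sdlog)
      p$k_GPR3 <- p$k_GPR3 * fac[1]
      p$V_NPR2 <- p$V_NPR2 * fac[2]
    }
    tr <- simulate_follicle(p, geometry, sc$perturb,
                            t_end = sc$t_end, dt_out = sc$dt_out)
    traces[[i]] <- tr
    for (reg in c("mural", "cumulus", "oocyte")) {
      r <- ratio_from_concentration(tr[[paste0("cAMP_", reg)]], calib)
      km <- kinetic_metrics(tr$t_min, r, lh_time = sc$perturb$lh_time)
      km$follicle <- i; km$roi <- reg
      mets[[length(mets) + 1]] <- km
    }
  }
  list(traces = traces, metrics = do.call(rbind, mets), scenario = sc)
}

#' Closed-loop validation: simulate, render, analyze, compare
#'
#' Runs the full pipeline end to end: simulates the wild-type model,
#' renders a seeded noisy time-lapse, registers it, extracts corrected
#' ratio traces using geometric ROIs, and compares the recovered
#' time-to-half-peak of each region with the value computed directly on
#' the simulated ratio traces.  Passing means agreement within one frame
#' interval (1 min during the early rise).
#'
#' @param seed Integer seed for rendering noise and jitter.
#' @param frame_size Rendered frame side (pixels); the default downscales
#'   the full 512-px frame for speed at identical geometry coverage.
#' @param t_end Simulated window (min).
#' @param tolerance_min Pass tolerance on t50 recovery (min).
#' @return A data.frame with per-region direct and recovered t50, the
#'   absolute difference, and a `pass` flag.
#' @export
closed_loop_validation <- function(seed = 1L, frame_size = 160,
                                   t_end = 90, tolerance_min = 1) {
  geom <- follicle_geometry()
  px <- geom$follicle_diameter * 1.18 / frame_size
  tr <- simulate_follicle(t_end = t_end, dt_out = 0.5)
  calib <- sensor_calibration("cAMPFIRE-M")
  scene <- follicle_scene(geom, frame_size = frame_size, pixel_size = px,
                          jitter_sd = 0.5, seed = seed)
  stack <- render_timelapse(scene, tr, calib,
                            times = acquisition_times(t_end))
  stack <- register_stack(stack)
  rois <- rois_from_scene(scene)
  rt <- extract_traces(stack, rois, alpha = scene$bleedthrough_alpha)

  region_map <- c(outer_mural = "cAMP_mural", cumulus = "cAMP_cumulus",
                  oocyte = "cAMP_oocyte")
  out <- lapply(names(region_map), function(rg) {
    sub <- rt[rt$roi == rg & !is.na(rt$ratio), ]
    rec <- time_to_fraction_of_peak(sub$t_min, sub$ratio)
    dir <- time_to_fraction_of_peak(
      tr$t_min, ratio_from_concentration(tr[[region_map[[rg]]]], calib))
    data.frame(roi = rg, direct_t50 = dir, recovered_t50 = rec,
               abs_diff = abs(rec - dir),
               pass = abs(rec - dir) <= tolerance_min)
  })
  do.call(rbind, out)
}
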