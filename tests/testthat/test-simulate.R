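# Steady state, integration accuracy, conservation, and scenario
# monotonicity properties of the compartment model.

test_that("pre-LH steady state is a true fixed point with basal levels", {
  p <- model_parameters()
  g <- follicle_geometry()
  ss <- pre_lh_steady_state(p, g)
  expect_true(all(ss > 0))
  # oocyte cAMP is calibrated to the basal level
  expect_equal(unname(ss[["cAMP_oocyte"]]), 700, tolerance = 1e-6)
  # basal oocyte and mural cAMP similar (ratios similar before LH)
  expect_lt(abs(ss[["cAMP_oocyte"]] - ss[["cAMP_mural"]]) / ss[["cAMP_mural"]],
            0.15)
  # feeding the state back gives a derivative norm below tolerance
  rhs <- follisim:::follicle_rhs(-100, ss,
    list(params = p, geom = g, perturb = perturbation_config()))[[1]]
  expect_lt(sqrt(sum(rhs^2)), 1e-8)
  # trivial fixed point with no synthesis
  p0 <- model_parameters(k_GPR3 = 0, k_FSH = 0, k_LH = 0, V_NPR2 = 0)
  expect_equal(max(abs(pre_lh_steady_state(p0, g))), 0, tolerance = 1e-10)
})

test_that("adaptive solution matches a fine-step explicit Euler oracle", {
  p <- model_parameters()
  g <- follicle_geometry()
  pe <- perturbation_config()
  tr <- simulate_follicle(p, g, pe, t_end = 30, dt_out = 1)
  or <- euler_oracle(p, g, pe, t_start = -10, t_end = 30, dt = 0.001)
  for (col in names(tr)[-1]) {
    ref <- approx(or$t_min, or[[col]], xout = tr$t_min)$y
    expect_lt(max(abs(tr[[col]] - ref) / pmax(abs(ref), 1)), 0.005)
  }
})

test_that("pure diffusion conserves amount and equilibrates to the mixed mean", {
  # all synthesis and degradation off: gap junctions only
  p <- model_parameters(k_GPR3 = 0, k_FSH = 0, k_LH = 0, V_NPR2 = 0,
                        k_degA_g = 0, k5_basal = 0, dk5_LH = 0,
                        k_degG_o = 0, Vmax3 = 0, dip_depth = 1)
  g <- follicle_geometry()
  init <- c(cAMP_mural = 500, cAMP_cumulus = 1500, cAMP_oocyte = 3000,
            cGMP_mural = 2000, cGMP_cumulus = 100, cGMP_oocyte = 800)
  tr <- simulate_follicle(p, g, perturbation_config(), t_end = 2000,
                          dt_out = 20, init = init)
  V <- c(g$V_m, g$V_c, g$V_o)
  for (sp in c("cAMP", "cGMP")) {
    cols <- paste0(sp, c("_mural", "_cumulus", "_oocyte"))
    amount <- as.matrix(tr[cols]) %*% V
    expect_lt(max(abs(amount - amount[1]) / amount[1]), 1e-6)
    mixed <- sum(V * init[cols]) / sum(V)
    expect_equal(unname(unlist(tr[nrow(tr), cols])), rep(mixed, 3),
                 tolerance = 1e-4)
  }
})

test_that("cAMP rise propagates mural -> cumulus -> oocyte", {
  tr <- wt_traces()
  cal <- sensor_calibration("cAMPFIRE-M")
  t50 <- vapply(c("cAMP_mural", "cAMP_cumulus", "cAMP_oocyte"),
    function(col) time_to_fraction_of_peak(
      tr$t_min, ratio_from_concentration(tr[[col]], cal)), numeric(1))
  expect_true(t50[1] < t50[2] && t50[2] < t50[3])
})

test_that("oocyte cGMP falls before oocyte cAMP", {
  tr <- wt_traces()
  t_g <- time_to_fractional_decline(tr$t_min, tr$cGMP_oocyte, 0.25)
  t_a <- time_to_fractional_decline(tr$t_min, tr$cAMP_oocyte, 0.25)
  expect_lt(t_g, t_a)
})

test_that("states stay non-negative across scenarios and parameter jitter", {
  set.seed(7)
  flags <- expand.grid(npr2_7E = c(FALSE, TRUE), ag1478 = c(FALSE, TRUE),
                       carbenoxolone = c(FALSE, TRUE))
  base <- model_parameters()
  jitter_names <- c("k_GPR3", "k_FSH", "k_LH", "Vmax3", "V_NPR2",
                    "k5_basal", "P_mc", "P_co")
  for (i in seq_len(nrow(flags))) {
    p <- base
    for (nm in jitter_names) p[[nm]] <- p[[nm]] * runif(1, 0.5, 1.5)
    pe <- perturbation_config(npr2_7E = flags$npr2_7E[i],
                              pde5a_S92A = flags$npr2_7E[i],
                              ag1478 = flags$ag1478[i],
                              carbenoxolone = flags$carbenoxolone[i])
    tr <- simulate_follicle(p, perturb = pe, t_end = 120, dt_out = 2)
    expect_true(all(as.matrix(tr[-1]) >= 0),
                info = paste("scenario row", i))
  }
})

test_that("NEBD surrogate finds the first sustained sub-threshold time", {
  t <- seq(0, 300, by = 1)
  # constant trace above threshold: never
  expect_true(is.na(nebd_time(t, rep(500, length(t)), threshold = 350)))
  # step trace dropping at t = 100, hold 30
  y <- ifelse(t < 100, 600, 100)
  expect_equal(nebd_time(t, y, threshold = 350, hold = 30), 100)
  expect_error(nebd_time(t, y, threshold = 350, hold = 400), "extent")
})
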