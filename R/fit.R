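# Anchor registry and calibration of the shipped default parameters.

#' Registered kinetic and concentration anchors
#'
#' The published kinetic and concentration landmarks that the default model is
#' calibrated to reproduce: half-rise times of the cAMP ratio in the three
#' regions, basal / minimum / peak cAMP concentrations, the timing of the
#' oocyte cAMP trough, the mural cGMP time-to-minimum in wild-type and
#' dephosphorylation-blocked follicles, the delayed oocyte cAMP fall when
#' gap-junction closure is prevented, and the cumulus attenuation under
#' carbenoxolone.
#'
#' @return A data.frame with columns `id`, `description`, `units`,
#'   `target` and `tol` (relative tolerance: 0.10 for mean +/- SEM values,
#'   0.15 for "~" values).
#' @export
anchor_registry <- function() {
  data.frame(
    id = paste0("t", 1:12),
    description = c(
      "time to 50% of peak cAMP ratio, outer mural (min)",
      "time to 50% of peak cAMP ratio, cumulus (min)",
      "time to 50% of peak cAMP ratio, oocyte (min)",
      "pre-LH steady-state oocyte cAMP (nM)",
      "post-LH minimum oocyte cAMP (nM)",
      "post-LH maximum mural cAMP (nM)",
      "time oocyte cAMP first falls below baseline (h)",
      "time of the oocyte cAMP minimum (h)",
      "time for mural cGMP to reach its minimum, wild type (min)",
      "time for mural cGMP to reach its minimum, Npr2-7E;Pde5a-S92A (h)",
      "time for oocyte cAMP to reach the wild-type minimum, no Cx43 dip (h)",
      "cumulus ratio change under carbenoxolone (% of control)"),
    units = c("min", "min", "min", "nM", "nM", "nM", "h", "h", "min",
              "h", "h", "%"),
    target = c(2.9, 5.5, 7.1, 700, 170, 3400, 1, 3, 20, 3, 5, 30),
    tol = c(0.10, 0.10, 0.10, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15,
            0.15, 0.15, 0.15)
  )
}

#' Compute all anchor values for a parameter set
#'
#' Recomputes every registered anchor from scratch: wild-type,
#' dephosphorylation-blocked, gap-junction-dip-disabled and carbenoxolone
#' simulations, ratio transformation through the cAMP sensor calibration,
#' and the landmark metrics.  This is the quantity the calibration
#' minimizes and the acceptance evaluation reports.
#'
#' @param params A [model_parameters()] object.
#' @param geometry A [follicle_geometry()] object.
#' @param dt_out Output grid spacing for the simulations (min).
#' @return Named numeric vector `t1` .. `t12` (units as in
#'   [anchor_registry()]).
#' @export
compute_anchor_values <- function(params = model_parameters(),
                                  geometry = follicle_geometry(),
                                  dt_out = 0.25) {
  cal <- sensor_calibration("cAMPFIRE-M")
  ss <- pre_lh_steady_state(params, geometry)

  wt <- simulate_follicle(params, geometry, perturbation_config(),
                          t_end = 300, dt_out = dt_out)
  mut <- simulate_follicle(params, geometry,
                           perturbation_config(npr2_7E = TRUE, pde5a_S92A = TRUE),
                           t_end = 300, dt_out = dt_out)
  ag <- simulate_follicle(params, geometry, perturbation_config(ag1478 = TRUE),
                          t_end = 330, dt_out = dt_out)
  cb <- simulate_follicle(params, geometry,
                          perturbation_config(carbenoxolone = TRUE),
                          t_end = 60, dt_out = dt_out)

  t <- wt$t_min; post <- t >= 0
  r_m <- ratio_from_concentration(wt$cAMP_mural, cal)
  r_c <- ratio_from_concentration(wt$cAMP_cumulus, cal)
  r_o <- ratio_from_concentration(wt$cAMP_oocyte, cal)
  wt_min <- min(wt$cAMP_oocyte[post])

  base_c <- ratio_from_concentration(ss[["cAMP_cumulus"]], cal)
  d_ctrl <- max(r_c[post]) - base_c
  cbpost <- cb$t_min >= 0
  d_cb <- max(ratio_from_concentration(cb$cAMP_cumulus[cbpost], cal)) - base_c

  c(t1 = time_to_fraction_of_peak(t, r_m),
    t2 = time_to_fraction_of_peak(t, r_c),
    t3 = time_to_fraction_of_peak(t, r_o),
    t4 = unname(ss[["cAMP_oocyte"]]),
    t5 = wt_min,
    t6 = max(wt$cAMP_mural[post]),
    t7 = time_below_baseline(t, wt$cAMP_oocyte) / 60,
    t8 = t[post][which.min(wt$cAMP_oocyte[post])] / 60,
    t9 = time_to_minimum(t, wt$cGMP_mural),
    t10 = time_to_minimum(mut$t_min, mut$cGMP_mural) / 60,
    t11 = first_crossing(ag$t_min, ag$cAMP_oocyte, wt_min,
                         direction = -1, after = 5) / 60,
    t12 = 100 * d_cb / d_ctrl)
}

#' Anchor report for a parameter set
#'
#' Compares computed anchor values with the registered targets at the
#' registered tolerances.
#'
#' @inheritParams compute_anchor_values
#' @return The [anchor_registry()] data.frame with added columns `value`,
#'   `rel_dev` and `pass`.
#' @export
anchor_report <- function(params = model_parameters(),
                          geometry = follicle_geometry(),
                          dt_out = 0.25) {
  reg <- anchor_registry()
  v <- compute_anchor_values(params, geometry, dt_out)
  reg$value <- unname(v[reg$id])
  reg$rel_dev <- (reg$value - reg$target) / reg$target
  reg$pass <- !is.na(reg$value) & abs(reg$rel_dev) <= reg$tol
  reg
}

# free-parameter vector matching the shipped defaults (the starting point
# and reference of scripts/fit_parameters.R)
default_free_vector <- function(geometry = follicle_geometry()) {
  d <- .follisim_defaults
  c(tau_LH = d$tau_LH, k_degA_g = d$k_degA_g,
    rate_mc = d$P_mc / geometry$V_c, rate_co = d$P_co / geometry$V_o,
    Vmax3 = d$Vmax3, Km3 = d$Km3, Ki3 = d$Ki3,
    G_base = d$V_NPR2 / d$k5_basal, tau_dephos = d$tau_dephos,
    phi_min = d$phi_min, tau_CNP = d$tau_CNP, k5_basal = d$k5_basal,
    dk5_LH = d$dk5_LH, k_degG_o = d$k_degG_o, dip_depth = d$dip_depth)
}

# Free parameter vector <-> full model_parameters, with structural
# constraints eliminated analytically:
#   k_FSH = 700 k_degA_g         (basal granulosa cAMP 700 nM)
#   k_LH  = 2700 k_degA_g        (mural plateau ~3,400 nM)
#   V_NPR2 = G_base k5_basal     (basal granulosa cGMP = G_base)
#   k_GPR3 chosen so basal oocyte cAMP is exactly 700 nM
free_parameter_names <- c(
  "tau_LH", "k_degA_g", "rate_mc", "rate_co", "Vmax3", "Km3", "Ki3",
  "G_base", "tau_dephos", "phi_min", "tau_CNP", "k5_basal", "dk5_LH",
  "k_degG_o", "dip_depth")

#' Build model parameters from the free calibration vector
#'
#' `rate_mc` and `rate_co` are the junction exchange rates normalised by
#' the receiving volume (`P_mc / V_c` and `P_co / V_o`, 1/min), which is
#' how the kinetics constrain them; `G_base` is the basal granulosa cGMP
#' concentration (nM).
#'
#' @param free Named numeric vector with entries
#'   `r free_parameter_names`.
#' @param geometry A [follicle_geometry()] object.
#' @return A [model_parameters()] object.
#' @export
parameters_from_free <- function(free, geometry = follicle_geometry()) {
  v <- as.list(free)
  g <- geometry
  k_FSH <- 700 * v$k_degA_g
  k_LH <- 2700 * v$k_degA_g
  P_mc <- v$rate_mc * g$V_c
  P_co <- v$rate_co * g$V_o
  V_NPR2 <- v$G_base * v$k5_basal

  p0 <- model_parameters(k_GPR3 = 1, k_FSH = k_FSH, k_LH = k_LH,
    tau_LH = v$tau_LH, k_degA_g = v$k_degA_g, Vmax3 = v$Vmax3,
    Km3 = v$Km3, Ki3 = v$Ki3, V_NPR2 = V_NPR2, tau_dephos = v$tau_dephos,
    phi_min = v$phi_min, tau_CNP = v$tau_CNP, k5_basal = v$k5_basal,
    dk5_LH = v$dk5_LH, tau_PDE5 = 3, k_degG_o = v$k_degG_o,
    P_mc = P_mc, P_co = P_co, dip_depth = v$dip_depth)

  # basal cGMP (linear system, independent of k_GPR3)
  Ag <- rbind(
    c(-v$k5_basal - P_mc / g$V_m, P_mc / g$V_m, 0),
    c(P_mc / g$V_c, -v$k5_basal - P_mc / g$V_c - P_co / g$V_c, P_co / g$V_c),
    c(0, P_co / g$V_o, -v$k_degG_o - P_co / g$V_o))
  G <- as.numeric(solve(Ag, c(-V_NPR2, -V_NPR2, 0)))
  # basal granulosa cAMP with the oocyte held at 700 nM
  Aa <- rbind(c(-v$k_degA_g - P_mc / g$V_m, P_mc / g$V_m),
              c(P_mc / g$V_c, -v$k_degA_g - P_mc / g$V_c - P_co / g$V_c))
  Agr <- as.numeric(solve(Aa, c(-k_FSH, -k_FSH - P_co / g$V_c * 700)))
  k_GPR3 <- pde3a_rate(700, G[3], p0) - P_co / g$V_o * (Agr[2] - 700)
  if (k_GPR3 <= 0)
    stop("infeasible free vector: implied oocyte synthesis rate <= 0")
  p0$k_GPR3 <- k_GPR3
  validate_model_parameters(p0)
  p0
}

#' Calibrate default parameters against the anchors
#'
#' Bounded least squares on log-parameters minimizing the summed squared
#' relative deviations of the registered anchors (Nelder-Mead within a
#' log-box; evaluations outside the box or failing simulation are
#' penalised).  The shipped defaults were produced by this routine via
#' `scripts/fit_parameters.R`.
#'
#' @param start Named free-parameter vector to start from.
#' @param lower,upper Named bounds on the free parameters (natural scale).
#' @param anchor_ids Anchors to fit (default all twelve).
#' @param geometry A [follicle_geometry()] object.
#' @param maxit Maximum optimizer iterations.
#' @param weights Optional named per-anchor weights.
#' @param dt_out Simulation output spacing used in the loss (min).
#' @return List with `params` (fitted [model_parameters()]), `free`
#'   (fitted free vector), `value` (final loss) and `report`
#'   (final [anchor_report()]).
#' @export
fit_default_parameters <- function(start, lower, upper,
                                   anchor_ids = paste0("t", 1:12),
                                   geometry = follicle_geometry(),
                                   maxit = 200, weights = NULL,
                                   dt_out = 0.5) {
  if (!length(anchor_ids)) stop("anchor list is empty")
  stopifnot(all(free_parameter_names %in% names(start)),
            all(names(lower) %in% free_parameter_names),
            all(names(upper) %in% free_parameter_names))
  reg <- anchor_registry()
  tg <- stats::setNames(reg$target, reg$id)[anchor_ids]
  w <- stats::setNames(rep(1, length(anchor_ids)), anchor_ids)
  if (!is.null(weights)) w[names(weights)] <- weights
  lo <- log(unlist(lower)[names(start)])
  hi <- log(unlist(upper)[names(start)])

  loss <- function(x) {
    if (any(x < lo - 1e-12) || any(x > hi + 1e-12)) return(1e6)
    v <- stats::setNames(exp(x), names(start))
    vals <- tryCatch(
      compute_anchor_values(parameters_from_free(v, geometry), geometry,
                            dt_out = dt_out)[anchor_ids],
      error = function(e) NULL)
    if (is.null(vals)) return(1e6)
    vals[is.na(vals)] <- 10 * tg[is.na(vals)]
    sum(w * ((vals - tg) / tg)^2)
  }
  if (all(lo == hi)) {
    x <- lo
    val <- loss(x)
  } else {
    o <- stats::optim(pmin(pmax(log(unlist(start)), lo), hi), loss,
                      control = list(maxit = maxit, reltol = 1e-8))
    x <- o$par; val <- o$value
  }
  free <- stats::setNames(exp(x), names(start))
  params <- parameters_from_free(free, geometry)
  list(params = params, free = free, value = val,
       report = anchor_report(params, geometry, dt_out = dt_out))
}
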