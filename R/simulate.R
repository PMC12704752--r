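# The three-compartment ODE system and its integration.

# Right-hand side for deSolve.  State order:
# A_m, A_c, A_o, G_m, G_c, G_o (nM).
follicle_rhs <- function(t, state, ctx) {
  p <- ctx$params; g <- ctx$geom; pe <- ctx$perturb
  A_m <- state[1L]; A_c <- state[2L]; A_o <- state[3L]
  G_m <- state[4L]; G_c <- state[5L]; G_o <- state[6L]

  lam <- lh_activation(t, p$tau_LH, pe$lh_time)
  th5 <- if (isTRUE(pe$pde5a_S92A)) 0 else lh_activation(t, p$tau_PDE5, pe$lh_time)
  act <- npr2_activity(t, p, pe)
  d   <- cx43_permeability_factor(t, p, pe)

  eps_mc <- if (isTRUE(pe$carbenoxolone)) pe$eps_mc else 1
  eps_co <- if (isTRUE(pe$carbenoxolone)) pe$eps_co else 1
  pmc <- p$P_mc * d * eps_mc
  pco <- p$P_co * eps_co

  # junction amount fluxes (nM * um^3 / min), positive toward 2nd compartment
  J_mc_A <- pmc * (A_m - A_c)
  J_co_A <- pco * (A_c - A_o)
  J_mc_G <- pmc * (G_m - G_c)
  J_co_G <- pco * (G_c - G_o)

  k5 <- p$k5_basal + p$dk5_LH * th5

  dA_m <- p$k_FSH + p$k_LH * lam - p$k_degA_g * A_m - J_mc_A / g$V_m
  dA_c <- p$k_FSH - p$k_degA_g * A_c + J_mc_A / g$V_c - J_co_A / g$V_c
  dA_o <- p$k_GPR3 - pde3a_rate(max(A_o, 0), max(G_o, 0), p) + J_co_A / g$V_o
  dG_m <- p$V_NPR2 * act - k5 * G_m - J_mc_G / g$V_m
  dG_c <- p$V_NPR2 * act - k5 * G_c + J_mc_G / g$V_c - J_co_G / g$V_c
  dG_o <- -p$k_degG_o * G_o + J_co_G / g$V_o

  list(c(dA_m, dA_c, dA_o, dG_m, dG_c, dG_o))
}

state_names <- c("cAMP_mural", "cAMP_cumulus", "cAMP_oocyte",
                 "cGMP_mural", "cGMP_cumulus", "cGMP_oocyte")

#' Pre-LH steady state
#'
#' Fixed point of the model with all LH-dependent terms off (no receptor
#' activation, Cx43 junctions fully open, NPR2 fully active).  This is the
#' state of the follicle during the baseline recording, in which the
#' measured CFP/YFP ratios of oocyte and granulosa regions are similar.
#'
#' The cGMP subsystem is linear and solved directly; the cAMP subsystem is
#' linear in the granulosa compartments given the oocyte value, leaving a
#' scalar root problem in oocyte cAMP (the PDE3A Michaelis-Menten term)
#' solved by bisection to machine precision.
#'
#' @param params A [model_parameters()] object.
#' @param geometry A [follicle_geometry()] object.
#' @return Named numeric vector with components `cAMP_mural`,
#'   `cAMP_cumulus`, `cAMP_oocyte`, `cGMP_mural`, `cGMP_cumulus`,
#'   `cGMP_oocyte` (nM).
#' @examples
#' pre_lh_steady_state(model_parameters(), follicle_geometry())
#' @export
pre_lh_steady_state <- function(params, geometry = follicle_geometry()) {
  validate_model_parameters(params)
  p <- params; g <- geometry

  # cGMP: linear 3x3 system
  kg <- p$k5_basal
  Ag <- rbind(
    c(-kg - p$P_mc / g$V_m, p$P_mc / g$V_m, 0),
    c(p$P_mc / g$V_c, -kg - p$P_mc / g$V_c - p$P_co / g$V_c, p$P_co / g$V_c),
    c(0, p$P_co / g$V_o, -p$k_degG_o - p$P_co / g$V_o))
  bg <- c(-p$V_NPR2, -p$V_NPR2, 0)
  G <- as.numeric(solve(Ag, bg))

  # cAMP: granulosa pair is linear given the oocyte concentration
  granulosa_cAMP <- function(A_o) {
    Aa <- rbind(
      c(-p$k_degA_g - p$P_mc / g$V_m, p$P_mc / g$V_m),
      c(p$P_mc / g$V_c, -p$k_degA_g - p$P_mc / g$V_c - p$P_co / g$V_c))
    ba <- c(-p$k_FSH, -p$k_FSH - p$P_co / g$V_c * A_o)
    as.numeric(solve(Aa, ba))
  }
  resid <- function(A_o) {
    Ac <- granulosa_cAMP(A_o)[2L]
    p$k_GPR3 - pde3a_rate(A_o, G[3L], p) + p$P_co / g$V_o * (Ac - A_o)
  }
  upper <- (p$k_FSH + p$k_GPR3) / p$k_degA_g + p$k_GPR3 / (p$P_co / g$V_o + 1e-12) + 1
  if (p$k_GPR3 == 0 && p$k_FSH == 0) {
    A_o <- 0
  } else {
    A_o <- stats::uniroot(resid, c(0, max(upper, 10)), tol = 1e-13)$root
    # polish by Newton steps on the scalar residual
    for (i in 1:5) {
      h <- max(abs(A_o), 1) * 1e-7
      fp <- (resid(A_o + h) - resid(A_o - h)) / (2 * h)
      if (!is.finite(fp) || fp == 0) break
      A_o <- max(A_o - resid(A_o) / fp, 0)
    }
  }
  Agr <- granulosa_cAMP(A_o)
  ss <- c(Agr[1L], Agr[2L], A_o, G)
  names(ss) <- state_names

  res <- follicle_rhs(-1e6, ss, list(params = p, geom = g,
                                     perturb = perturbation_config(lh_time = 0)))[[1]]
  if (sqrt(sum(res^2)) >= 1e-8)
    stop(sprintf("steady-state residual %.3g nM/min exceeds 1e-8", sqrt(sum(res^2))))
  if (any(ss < 0)) stop("steady state has negative concentrations")
  ss
}

#' Simulate the LH response of a follicle
#'
#' Integrates the three-compartment cAMP/cGMP model from the pre-LH steady
#' state through the LH response, with adaptive stiff-capable integration
#' (`deSolve::lsoda`, atol 1e-9 nM, rtol 1e-8) and output interpolated on
#' the requested grid.  Times are in minutes relative to LH addition; the
#' output grid starts at `t_start` (default -10 min of baseline).
#'
#' @param params A [model_parameters()] object.
#' @param geometry A [follicle_geometry()] object.
#' @param perturb A [perturbation_config()] object.
#' @param t_end End of the simulated window (min after LH), > 0.
#' @param dt_out Output grid spacing (min).
#' @param t_start Start of the output grid (min, default -10).
#' @param init Optional named initial state (`cAMP_mural`, ...,
#'   `cGMP_oocyte`); default the pre-LH steady state.  Supplying an
#'   arbitrary state is mainly useful for studying the free relaxation of
#'   the system (e.g. pure gap-junction equilibration with synthesis and
#'   degradation switched off).
#' @return A data.frame of class `compartment_traces` with column `t_min`
#'   and one column per species/compartment (nM): `cAMP_mural`,
#'   `cAMP_cumulus`, `cAMP_oocyte`, `cGMP_mural`, `cGMP_cumulus`,
#'   `cGMP_oocyte`.
#' @examples
#' tr <- simulate_follicle(t_end = 30, dt_out = 1)
#' head(tr)
#' @export
simulate_follicle <- function(params = model_parameters(),
                              geometry = follicle_geometry(),
                              perturb = perturbation_config(),
                              t_end = 300, dt_out = 0.5, t_start = -10,
                              init = NULL) {
  stopifnot(t_end > 0, dt_out > 0, t_start < t_end)
  ss <- if (is.null(init)) pre_lh_steady_state(params, geometry) else {
    stopifnot(all(state_names %in% names(init)), all(init >= 0))
    init[state_names]
  }
  times <- seq(t_start, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  ctx <- list(params = params, geom = geometry, perturb = perturb)
  sol <- deSolve::lsoda(y = ss, times = times, func = follicle_rhs,
                        parms = ctx, atol = 1e-9, rtol = 1e-8)
  if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol)))
    stop(sprintf("integration failed near t = %.3g min", sol[nrow(sol), 1L]))
  out <- as.data.frame(sol)
  names(out)[1L] <- "t_min"
  # clip solver-scale negative undershoot
  out[-1L][out[-1L] < 0 & out[-1L] > -1e-6] <- 0
  if (any(out[-1L] < 0))
    stop("negative concentrations beyond solver tolerance")
  class(out) <- c("compartment_traces", "data.frame")
  out
}

#' Predicted time of nuclear envelope breakdown from an oocyte cAMP trace
#'
#' Returns the first time at which oocyte cAMP stays below `threshold` for
#' at least `hold` minutes, as a simple surrogate for commitment to
#' meiotic resumption (NEBD is observed ~2-4 h after LH, when oocyte cAMP
#' has fallen well below its pre-LH baseline).
#'
#' @param t Time grid (min).
#' @param A_o Oocyte cAMP trace (nM) on that grid.
#' @param threshold Concentration threshold (nM); the shipped default
#'   (350 nM, half the basal level) is a model convention, not a measured
#'   quantity.
#' @param hold Minutes the trace must remain below threshold (default 30).
#' @return Time (min) or `NA` if the condition is never met.
#' @export
nebd_time <- function(t, A_o, threshold = 350, hold = 30) {
  stopifnot(length(t) == length(A_o), length(t) >= 2)
  if (hold > diff(range(t)))
    stop("hold window longer than the trace extent")
  below <- A_o < threshold
  for (i in seq_along(t)) {
    if (!below[i]) next
    j <- which(t >= t[i] & t <= t[i] + hold)
    if (max(t) - t[i] < hold) return(NA_real_)
    if (all(below[j])) return(t[i])
  }
  NA_real_
}
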