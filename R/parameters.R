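#' Model rate parameters
#'
#' Rate constants and time-course parameters of the three-compartment
#' cyclic-nucleotide model.  Concentrations are in nM and time in minutes,
#' with t = 0 at LH addition.  The shipped defaults were obtained by
#' bounded least squares against reported kinetic and concentration
#' landmarks of LH-induced follicle imaging (see the package vignette and
#' `fit_default_parameters()`); they are not independently measured rate
#' constants.
#'
#' @param k_GPR3 Constitutive oocyte cAMP synthesis rate (nM/min), driven
#'   by the constitutively active GPR3 receptor.
#' @param k_FSH Basal granulosa cAMP synthesis rate (nM/min), FSH-driven.
#' @param k_LH Maximal extra LH-induced cAMP synthesis in the outer mural
#'   compartment (nM/min).
#' @param tau_LH LH receptor activation time constant (min).
#' @param k_degA_g First-order cAMP hydrolysis rate in the granulosa
#'   compartments (1/min).
#' @param Vmax3 PDE3A maximal cAMP hydrolysis rate in the oocyte (nM/min).
#' @param Km3 PDE3A Michaelis constant for cAMP (nM).
#' @param Ki3 Competitive inhibition constant of PDE3A by cGMP (nM).
#' @param V_NPR2 Maximal NPR2 cGMP synthesis rate in granulosa (nM/min).
#' @param tau_dephos Time constant (min) of LH-induced NPR2
#'   dephosphorylation/inactivation.
#' @param phi_min Residual NPR2 activity fraction after dephosphorylation.
#' @param tau_CNP Time constant (min) of the slow decline of NPR2 activity
#'   that follows the LH-induced fall in follicle CNP content.
#' @param k5_basal Basal cGMP hydrolysis rate in granulosa (1/min),
#'   PDE5A and other cGMP phosphodiesterases.
#' @param dk5_LH LH-induced increment of the granulosa cGMP hydrolysis
#'   rate (1/min), via PDE5A phosphorylation.
#' @param tau_PDE5 Time constant (min) of LH-induced PDE5A phosphorylation.
#' @param k_degG_o Minor first-order oocyte cGMP loss (1/min).
#' @param P_mc Mural-cumulus gap-junction exchange coefficient
#'   (um^3/min; connexin-43 junctions, transiently closed after LH).
#' @param P_co Cumulus-oocyte gap-junction exchange coefficient
#'   (um^3/min; connexin-37 junctions, open throughout 0-5 h).
#' @param dip_depth Minimum fraction of Cx43 permeability retained at the
#'   bottom of the LH-induced closure.
#' @param dip_onset,dip_min_time,dip_recovery_time Landmarks (min) of the
#'   Cx43 permeability dip: closure begins, reaches its minimum, and has
#'   recovered.  Defaults 20 / 60 / 300 min follow the reported time
#'   course (closure starting between 10 and 30 min, minimum at ~1 h,
#'   back to the pre-LH level by 5 h).
#'
#' @return An object of class `model_parameters` (a named list).
#' @seealso [perturbation_config()], [simulate_follicle()]
#' @export
model_parameters <- function(k_GPR3 = .follisim_defaults$k_GPR3,
                             k_FSH = .follisim_defaults$k_FSH,
                             k_LH = .follisim_defaults$k_LH,
                             tau_LH = .follisim_defaults$tau_LH,
                             k_degA_g = .follisim_defaults$k_degA_g,
                             Vmax3 = .follisim_defaults$Vmax3,
                             Km3 = .follisim_defaults$Km3,
                             Ki3 = .follisim_defaults$Ki3,
                             V_NPR2 = .follisim_defaults$V_NPR2,
                             tau_dephos = .follisim_defaults$tau_dephos,
                             phi_min = .follisim_defaults$phi_min,
                             tau_CNP = .follisim_defaults$tau_CNP,
                             k5_basal = .follisim_defaults$k5_basal,
                             dk5_LH = .follisim_defaults$dk5_LH,
                             tau_PDE5 = .follisim_defaults$tau_PDE5,
                             k_degG_o = .follisim_defaults$k_degG_o,
                             P_mc = .follisim_defaults$P_mc,
                             P_co = .follisim_defaults$P_co,
                             dip_depth = .follisim_defaults$dip_depth,
                             dip_onset = 20,
                             dip_min_time = 60,
                             dip_recovery_time = 300) {
  p <- list(k_GPR3 = k_GPR3, k_FSH = k_FSH, k_LH = k_LH, tau_LH = tau_LH,
            k_degA_g = k_degA_g, Vmax3 = Vmax3, Km3 = Km3, Ki3 = Ki3,
            V_NPR2 = V_NPR2, tau_dephos = tau_dephos, phi_min = phi_min,
            tau_CNP = tau_CNP, k5_basal = k5_basal, dk5_LH = dk5_LH,
            tau_PDE5 = tau_PDE5, k_degG_o = k_degG_o,
            P_mc = P_mc, P_co = P_co, dip_depth = dip_depth,
            dip_onset = dip_onset, dip_min_time = dip_min_time,
            dip_recovery_time = dip_recovery_time)
  validate_model_parameters(p)
  structure(p, class = "model_parameters")
}

validate_model_parameters <- function(p) {
  pos <- c("tau_LH", "Km3", "Ki3", "tau_dephos", "tau_CNP", "tau_PDE5")
  nonneg <- c("k_GPR3", "k_FSH", "k_LH", "V_NPR2", "dk5_LH", "k_degG_o",
              "P_mc", "P_co", "k_degA_g", "k5_basal", "Vmax3")
  for (nm in c(pos, nonneg)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a finite numeric scalar", nm))
  }
  if (any(unlist(p[pos]) <= 0))
    stop("time constants and Michaelis/inhibition constants must be > 0")
  if (any(unlist(p[nonneg]) < 0))
    stop("synthesis and exchange coefficients must be >= 0")
  if (p$dip_depth < 0 || p$dip_depth > 1)
    stop("dip_depth must lie in [0, 1]")
  if (p$phi_min < 0 || p$phi_min > 1)
    stop("phi_min must lie in [0, 1]")
  if (!(p$dip_onset < p$dip_min_time && p$dip_min_time < p$dip_recovery_time))
    stop("Cx43 dip landmarks must satisfy dip_onset < dip_min_time < dip_recovery_time")
  invisible(p)
}

#' Perturbation / scenario switches
#'
#' Genotype and drug switches that define an experimental arm.  All flags
#' are independent and freely combinable.
#'
#' @param npr2_7E Logical; `TRUE` blocks LH-induced NPR2 dephosphorylation
#'   (the *Npr2*-7E knock-in, which locks NPR2 in the phosphorylated,
#'   active state).
#' @param pde5a_S92A Logical; `TRUE` blocks LH-induced PDE5A activation
#'   (the *Pde5a*-S92A knock-in).
#' @param ag1478 Logical; `TRUE` abolishes the LH-induced Cx43
#'   permeability dip (EGF-receptor kinase inhibition).
#' @param carbenoxolone Logical; `TRUE` applies the gap-junction blocker,
#'   scaling the junction coefficients by `eps_mc` and `eps_co`.
#' @param eps_mc,eps_co Residual permeability fractions (0-1) of the
#'   mural-cumulus and cumulus-oocyte junctions under carbenoxolone.
#'   The shipped values are calibrated so the cumulus cAMP response is
#'   ~30% of control and the oocyte response is almost fully blocked.
#' @param cnp_clamp Logical; `TRUE` disables the slow CNP-driven decline
#'   of NPR2 activity (exogenous CNP in the medium).
#' @param lh_time Time of LH addition (min); default 0.
#'
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(npr2_7E = FALSE,
                                pde5a_S92A = FALSE,
                                ag1478 = FALSE,
                                carbenoxolone = FALSE,
                                eps_mc = .follisim_defaults$eps_mc,
                                eps_co = .follisim_defaults$eps_co,
                                cnp_clamp = FALSE,
                                lh_time = 0) {
  for (fl in list(npr2_7E, pde5a_S92A, ag1478, carbenoxolone, cnp_clamp))
    stopifnot(is.logical(fl), length(fl) == 1L, !is.na(fl))
  stopifnot(is.numeric(eps_mc), eps_mc >= 0, eps_mc <= 1,
            is.numeric(eps_co), eps_co >= 0, eps_co <= 1,
            is.numeric(lh_time), is.finite(lh_time))
  structure(list(npr2_7E = npr2_7E, pde5a_S92A = pde5a_S92A,
                 ag1478 = ag1478, carbenoxolone = carbenoxolone,
                 eps_mc = eps_mc, eps_co = eps_co,
                 cnp_clamp = cnp_clamp, lh_time = lh_time),
            class = "perturbation_config")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Three-compartment cyclic-nucleotide model parameters (nM, min):\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.perturbation_config <- function(x, ...) {
  on <- names(Filter(isTRUE, x[c("npr2_7E", "pde5a_S92A", "ag1478",
                                 "carbenoxolone", "cnp_clamp")]))
  cat("Perturbation:", if (length(on)) paste(on, collapse = " + ")
      else "none (wild type)", "\n")
  if (isTRUE(x$carbenoxolone))
    cat(sprintf("  residual permeability eps_mc = %g, eps_co = %g\n",
                x$eps_mc, x$eps_co))
  cat(sprintf("  LH added at t = %g min\n", x$lh_time))
  invisible(x)
}
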