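# Elementary rate laws and time-course factors of the signaling model.

# C1 smoothstep: 0 at u<=0, 1 at u>=1, zero derivative at both ends.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Cx43 gap-junction permeability factor
#'
#' Dimensionless multiplier d(t) on the mural-cumulus exchange coefficient
#' describing the transient LH-induced closure of the connexin-43
#' junctions between granulosa cells: permeability is unchanged until
#' `dip_onset`, falls smoothly (a C1 smoothstep ramp) to the fraction
#' `dip_depth` at exactly `dip_min_time`, then recovers along a Gaussian
#' ramp `exp(-((t - dip_min_time)/s)^2)` whose width s is set so that
#' permeability is back within 2% of the pre-LH level at
#' `dip_recovery_time` (reopening accelerates as the accumulated
#' phospho-Cx43 is turned over).  Both limbs have zero slope at the
#' minimum, so d(t) is continuously differentiable.  With the `ag1478`
#' flag set the dip is abolished and d(t) = 1 throughout.
#'
#' @param t Time (min, vectorised), relative to the recording; LH is added
#'   at `perturb$lh_time`.
#' @param params A [model_parameters()] object.
#' @param perturb A [perturbation_config()] object.
#' @return Numeric vector of factors in `[dip_depth, 1]`.
#' @examples
#' p <- model_parameters()
#' cx43_permeability_factor(c(-5, 60, 300), p, perturbation_config())
#' @export
cx43_permeability_factor <- function(t, params, perturb = perturbation_config()) {
  stopifnot(all(is.finite(t)))
  validate_model_parameters(params)
  if (isTRUE(perturb$ag1478)) return(rep(1, length(t)))
  ts <- t - perturb$lh_time
  # Gaussian recovery width: exp(-(X/s)^2) = 0.02 at the recovery landmark
  s <- (params$dip_recovery_time - params$dip_min_time) / sqrt(log(1 / 0.02))
  x <- ts - params$dip_min_time
  bump <- ifelse(ts <= params$dip_min_time,
                 smoothstep((ts - params$dip_onset) /
                            (params$dip_min_time - params$dip_onset)),
                 exp(-(x / s)^2))
  1 - (1 - params$dip_depth) * bump
}

#' NPR2 guanylyl cyclase activity
#'
#' Fractional activity of the granulosa guanylyl cyclase NPR2 after LH:
#' the product of a fast dephosphorylation relaxation phi(t) (from 1
#' toward `phi_min` with time constant `tau_dephos`; held at 1 by the
#' `npr2_7E` flag) and a slow decline psi(t) (from 1 toward 0 with time
#' constant `tau_CNP`, reflecting the gradual LH-induced loss of the NPR2
#' agonist CNP; held at 1 by the `cnp_clamp` flag).  Activity is 1 before
#' LH.
#'
#' @inheritParams cx43_permeability_factor
#' @return Numeric vector of activity fractions in `[0, 1]`.
#' @export
npr2_activity <- function(t, params, perturb = perturbation_config()) {
  stopifnot(all(is.finite(t)))
  ts <- pmax(t - perturb$lh_time, 0)
  phi <- if (isTRUE(perturb$npr2_7E)) rep(1, length(t)) else
    params$phi_min + (1 - params$phi_min) * exp(-ts / params$tau_dephos)
  psi <- if (isTRUE(perturb$cnp_clamp)) rep(1, length(t)) else
    exp(-ts / params$tau_CNP)
  phi * psi
}

#' PDE3A hydrolysis rate with competitive cGMP inhibition
#'
#' Michaelis-Menten hydrolysis of cAMP by the oocyte phosphodiesterase
#' PDE3A, competitively inhibited by cGMP:
#' rate = Vmax3 * A / (Km3 * (1 + G / Ki3) + A).
#'
#' @param A cAMP concentration (nM, vectorised).
#' @param G cGMP concentration (nM, vectorised).
#' @param params A [model_parameters()] object.
#' @return Hydrolysis rate (nM/min).
#' @examples
#' p <- model_parameters(Vmax3 = 100, Km3 = 500)
#' pde3a_rate(500, 0, p)  # half-saturation: 50 nM/min
#' @export
pde3a_rate <- function(A, G, params) {
  if (any(A < 0) || any(G < 0))
    stop("concentrations must be non-negative")
  params$Vmax3 * A / (params$Km3 * (1 + G / params$Ki3) + A)
}

#' Gap-junction exchange between two compartments
#'
#' Fickian exchange of a solute between two well-mixed compartments
#' through gap junctions with permeability-area coefficient `P`
#' (volume/min).  The amount flux is J = P * (conc_b - conc_a); dividing
#' by the receiving volumes gives the concentration derivatives, so the
#' total amount V_a * C_a + V_b * C_b is conserved exactly.
#'
#' @param conc_a,conc_b Concentrations (nM) in compartments a and b.
#' @param P Exchange coefficient (volume/min), >= 0.
#' @param V_a,V_b Compartment volumes (> 0).
#' @return Named numeric vector `c(dC_a, dC_b)` in nM/min.
#' @examples
#' junction_exchange(1000, 2000, P = 10, V_a = 100, V_b = 10000)
#' @export
junction_exchange <- function(conc_a, conc_b, P, V_a, V_b) {
  if (V_a <= 0 || V_b <= 0) stop("volumes must be positive")
  if (P < 0) stop("exchange coefficient must be non-negative")
  J <- P * (conc_b - conc_a)
  c(dC_a = J / V_a, dC_b = -J / V_b)
}

# Saturating LH-receptor (or PDE5A-phosphorylation) activation:
# 1 - exp(-(t - t0)/tau) for t >= t0, else 0.
lh_activation <- function(t, tau, t0 = 0) {
  ts <- pmax(t - t0, 0)
  ifelse(t >= t0, 1 - exp(-ts / tau), 0)
}
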