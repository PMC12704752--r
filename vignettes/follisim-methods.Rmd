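---
title: "Modelling LH-induced cyclic-nucleotide dynamics in preovulatory follicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling LH-induced cyclic-nucleotide dynamics in preovulatory follicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(follisim)
```

## The biological system

Mammalian oocytes are held in meiotic prophase arrest by a high
concentration of cAMP in the oocyte.  In the mouse preovulatory follicle
the arrest is maintained by a relay that spans three coupled cellular
compartments: the outer mural granulosa cells (which carry the LH
receptors), the cumulus cells surrounding the oocyte, and the oocyte
itself.  Gap junctions connect the compartments: connexin-43 (Cx43)
junctions among the granulosa cells and connexin-37 (Cx37) junctions
between cumulus cells and the oocyte.

Before LH: the granulosa guanylyl cyclase NPR2, driven by its agonist CNP,
keeps granulosa cGMP high; cGMP diffuses into the oocyte and competitively
inhibits the oocyte phosphodiesterase PDE3A, protecting the cAMP made
constitutively by GPR3.  After LH: cAMP surges in the mural layer and
diffuses inward; NPR2 is rapidly dephosphorylated and inactivated (and,
more slowly, CNP levels fall), granulosa cGMP collapses, cGMP drains out
of the oocyte into the much larger granulosa volume, PDE3A is released
from inhibition, and oocyte cAMP falls below baseline — releasing the
meiotic arrest (nuclear envelope breakdown, NEBD).  A transient closure of
the Cx43 junctions (beginning ~10–30 min after LH, deepest at ~1 h,
recovered by ~5 h) cuts the resupply of cAMP from the mural layer while
the oocyte sink is most active, shaping the depth and timing of the oocyte
cAMP trough.

`follisim` implements this working model as a deterministic
three-compartment ODE system, together with the ratiometric FRET
measurement pipeline used to observe these dynamics (sensor calibration,
synthetic two-channel image stacks with ground truth, registration, ROI
traces, kinetic landmark metrics).

## The compartment model

State variables are cAMP and cGMP concentrations (nM) in mural (m),
cumulus (c) and oocyte (o) compartments; time is in minutes with LH at
t = 0.  With $\lambda(t) = 1 - e^{-t/\tau_{LH}}$ (LH receptor activation),
$\theta_5(t)$ of the same form (PDE5A phosphorylation, time constant
$\tau_{PDE5}$), NPR2 activity $a(t) = \varphi(t)\,\psi(t)$ (fast
dephosphorylation relaxation to `phi_min`, slow CNP-driven decay
$e^{-t/\tau_{CNP}}$), and Cx43 permeability factor $d(t)$:

$$
\begin{aligned}
\dot A_m &= k_{FSH} + k_{LH}\lambda(t) - k_{degA}A_m
           - P_{mc} d(t) (A_m - A_c)/V_m\\
\dot A_c &= k_{FSH} - k_{degA}A_c + P_{mc} d(t)(A_m - A_c)/V_c
           - P_{co}(A_c - A_o)/V_c\\
\dot A_o &= k_{GPR3} - \frac{V_{max,3}\,A_o}{K_{m,3}\,(1 + G_o/K_{i,3}) + A_o}
           + P_{co}(A_c - A_o)/V_o\\
\dot G_m &= V_{NPR2}\,a(t) - (k_{5}^{bas} + \Delta k_5\,\theta_5(t))\,G_m
           - P_{mc} d(t)(G_m - G_c)/V_m\\
\dot G_c &= \text{(as } G_m\text{, exchanging with both neighbours)}\\
\dot G_o &= -k_{degG,o}G_o + P_{co}(G_c - G_o)/V_o
\end{aligned}
$$

Junction fluxes are written as amount fluxes $P\,(C_1 - C_2)$ divided by
the receiving volume, so total amounts are conserved exactly by
construction — this is tested to 1e-6 relative with all synthesis and
degradation switched off.

Key modelling choices, where the biology gives a mechanism but not an
equation:

* **PDE3A**: Michaelis–Menten with classical competitive inhibition
  ($K_m$ scaled by $1 + G/K_i$) — the standard form for a competing,
  hydrolysable ligand.  Granulosa nucleotide hydrolysis is first order (no
  saturation information is available at tissue level).
* **Synthesis terms** are zero-order rates modulated by dimensionless
  activation factors; LH onset is a smooth exponential with
  $\tau_{LH}\approx 2$ min rather than a step, so the ~3-min mural
  half-rise is a fitted quantity and not an artifact of a discontinuity.
* **NPR2 inactivation** factorises into the fast dephosphorylation arm
  (blocked by the *Npr2*-7E genotype flag) and the slow CNP-loss arm
  (blocked by the CNP-clamp flag); with both blocked, activity stays at 1
  and mural cGMP holds near baseline for the full 5-h window, which is the
  exogenous-CNP control behaviour.
* **Compartment volumes** come from the imaging geometry: a ~340-µm
  follicle flattened to a ~200-µm disc, 15% antral space, a 75-µm oocyte
  (a typical fully grown mouse oocyte; this diameter is a convention, not
  a reported measurement) and a 25-µm cumulus shell.  Only the
  volume ratios matter dynamically: the granulosa is a ~60-fold larger
  reservoir than the oocyte, which is what makes junctional drainage of
  oocyte cGMP effective.  Halving or doubling the oocyte volume rescales
  `P_co` at fixed `P_co/V_o` and leaves the calibrated dynamics unchanged.

### The Cx43 permeability dip

Only four landmarks of the transient Cx43 closure are constrained:
closure begins between 10 and 30 min (we use 20), the minimum is at ~1 h,
permeability is comparable to baseline again by ~5 h, and the depth is not
directly known.  The shipped functional form is a C1 curve with an exact
minimum:

* closing limb: a smoothstep from 1 (at `dip_onset`) to `dip_depth`
  (at `dip_min_time`), identically 1 before onset;
* recovery limb: a Gaussian ramp
  $1-(1-\text{depth})\,e^{-((t-t_{min})/s)^2}$ with $s$ set so permeability
  is within 2% of baseline at `dip_recovery_time`.

Both limbs have zero slope at the minimum.  The Gaussian recovery — a
reopening *rate* that grows with time, as the accumulated phospho-Cx43
pool is turned over — was chosen over an exponential-tailed
(logistic-type) recovery because the latter's junctional resupply term
decays more slowly at late times than the CNP-driven cGMP tail, which
flattens the late oocyte cAMP trajectory into a long monotone slide.  The
accelerating recovery sharpens the trough.  Even so, the timing of the
trough and the AG1478 delay pull the calibration in opposite directions;
see "Known limitations" for how the shipped defaults resolve this.

```{r dipshape}
p <- model_parameters()
t <- seq(-10, 330, by = 1)
plot(t, cx43_permeability_factor(t, p), type = "l",
     xlab = "min after LH", ylab = "Cx43 permeability factor")
abline(v = c(p$dip_onset, p$dip_min_time, p$dip_recovery_time), lty = 3)
```

### Steady state and integration

The pre-LH state is computed as the exact fixed point (the cGMP subsystem
is linear; the cAMP subsystem reduces to a scalar root problem in oocyte
cAMP), with a residual tolerance of 1e-8 nM/min.  Integration uses
`deSolve::lsoda` (atol 1e-9, rtol 1e-8) from that state; the adaptive
solution is checked against a fixed-step explicit-Euler oracle at
dt = 0.001 min to within 0.5%.

### Calibration of the shipped defaults

The imaging measurements provide landmark numbers, not rate constants.  Four structural
constraints are eliminated analytically (basal granulosa cAMP 700 nM,
mural plateau ~3,400 nM, basal oocyte cAMP exactly 700 nM, basal granulosa
cGMP = `G_base`); the remaining free parameters were fitted by staged
Nelder–Mead least squares on log-parameters against the twelve registered
anchors (`anchor_registry()`): the three half-rise times, the basal /
minimum / peak concentrations, the trough timing, the wild-type and
phospho-mutant mural cGMP kinetics, the AG1478 delay, and the
carbenoxolone attenuation.  `scripts/fit_parameters.R` reproduces the
final stage from the shipped starting point; `anchor_report()` recomputes
every anchor with the shipped defaults.

Two scales deserve comment.  First, the calibrated PDE3A operates near
saturation (small $K_{m,3}$ relative to basal cAMP): this is what lets the
junctional resupply term, rather than the enzyme, control the shape of the
late oocyte cAMP trajectory.  Second, the competitive inhibition constant
$K_{i,3}$ is small relative to basal cGMP, so PDE3A is strongly inhibited
at rest and the residual late cGMP (a few nM) still modulates the
asymptote of the trough — this is what makes the AG1478 trace keep
declining slowly for hours.  Neither constant is separately identifiable
from the landmark data; they are effective, tissue-level values.

The carbenoxolone arm is modelled as static multiplicative factors on the
junction coefficients (`eps_mc`, `eps_co`), chosen so the cumulus ratio
response is ~30% of control and the oocyte response is almost fully
blocked.

## FRET sensor calibration

Both cAMPFIRE-M (cAMP) and cGi500 (cGMP) lose FRET on ligand binding, so
the CFP/YFP emission ratio increases monotonically with concentration.
The package uses a Hill curve
$R(c) = R_{min} + (R_{max}-R_{min})\,c^n/(EC_{50}^n + c^n)$ with an exact
algebraic inverse.  The numeric constants of the in-vitro calibration are
not published alongside the landmark measurements; the shipped values ($EC_{50}$ 1000 nM for
cAMPFIRE-M, 500 nM for cGi500, $n = 1$, ratio span 1–3) place the three
cAMP landmarks (170 / 700 / 3,400 nM) inside the quasi-linear range where
the ratio is approximately proportional to log concentration (residual of
a straight-line fit of $R$ against $\log_{10} c$ over $EC_{50}/3$ to
$3\,EC_{50}$ is below 2% of the span).  All constants are overridable per
sensor.

## Synthetic time-lapse generation

`follicle_scene()` + `render_timelapse()` emulate the recordings: a
flattened follicle with concentric regions, a dark prophase nucleus that
fills with fluorescence at NEBD (rendered as an instantaneous fill — the
detection criterion is the appearance of fluorescence, and no transition
kinetics are reported), dark antral patches, a dim theca rim, uniform
autofluorescence background, sensor brightness 3–10x background, up to
5-fold expression variation, CFP→YFP spectral bleed-through (default 23%),
Poisson shot noise plus 2% Gaussian read noise, per-frame translational
jitter, 16-bit quantisation, and the acquisition schedule (1-min frames
for 10 min of baseline and the first post-LH hour, 5-min frames after; no
frame at t = 0, when LH is perfused).

Total per-region brightness is split between channels as
CFP $= B\,R/(1+R)$, YFP $= B/(1+R)$, so the corrected CFP/YFP ratio equals
the calibration ratio by construction; any monotone split would do, and
this one makes closed-loop checks exact.  Because antral patches carry
only background counts in both channels, they cancel from
background-subtracted ROI means and do not bias ratios; geometric ROIs may
therefore overlap them safely.

What the generator does *not* emulate: optical sectioning and PSF blur,
photobleaching, the sometimes-observed cumulus cAMP oscillations (cause
unknown, deliberately not modelled), follicle shape changes after LH, and
theca responses.  Closed-loop tests passing on synthetic stacks therefore
validate the *pipeline arithmetic* (registration, background and overlap
correction, ROI means, landmark metrics), not the segmentation robustness
needed for real micrographs.

## Measurement pipeline

The analysis follows the published order of operations exactly: per-frame
translation registration (FFT cross-correlation against the first frame,
parabolic subpixel refinement — shifts are recovered relative to the first
frame), ROI means, background subtraction, then spectral-overlap
correction (YFP minus 23% of corrected CFP), then the ratio.  A regression
test pins the order: applying overlap correction before background
subtraction gives a different ratio.  Backgrounds come either from the
extra-follicular ROI or from "uninjected" fixture stacks averaged over
five follicles, mirroring the published protocol.  Landmark times
(half-rise, 25% decline, time-to-minimum within 5% of the drop, time below
baseline) are linearly interpolated between frames, which is what gives
sub-frame precision such as 2.9 ± 0.1 min.  NEBD is detected when mean
nuclear intensity reaches 70% of the oocyte cytoplasm after having been
below 40% in all prior frames; the 0.4/0.7 thresholds are conventions of
this package, exposed as arguments.

## Problem sizes and tolerances

Default simulations run on a 0.25–0.5 min output grid over −10…300 min
(330 for the AG1478 arm); each scenario integrates in well under a second.
Rendering tests use downscaled frames (96–160 px at correspondingly larger
pixel size) covering the identical geometry; a full-resolution 512-px
stack renders identically, only slower, and is exercised through the same
code path.  The NEBD Monte-Carlo check uses 20 seeded replicates.
Numerical tolerances: steady-state residual < 1e-8 nM/min, solver atol
1e-9 / rtol 1e-8, conservation 1e-6 relative, calibration round-trip
1e-9 relative, closed-loop landmark recovery within one frame interval.

## Known limitations

* The model is well-mixed per compartment; no intra-compartment gradients.
* Theca cells are rendered for visual realism but never simulated or
  analysed.
* The trough of oocyte cAMP is a shallow valley, and its strict argmin
  time is the one landmark the shipped defaults do not reproduce.  Within
  this model structure the two late-time anchors are in direct tension:
  holding the argmin strictly interior at ~3 h requires a post-trough
  rebound of a few nM as the junctions reopen, which places the wild-type
  minimum below the open-junction trajectory that the AG1478 arm relaxes
  along — and then the AG1478 trace never reaches that minimum at all,
  contradicting its ~5-h landmark.  The calibration resolves the tension
  in favour of the AG1478 behaviour (and the other ten anchors): with the
  shipped defaults the wild-type trace approaches its minimum
  asymptotically, reaching within 5% of the full drop at ~2.8 h — the
  same "time to reach the minimum level" landmark used for mural cGMP —
  while the strict argmin lands at the end of the 5-h window.
  `anchor_report()` reports this deviation rather than masking it.
* The fitted LH-induced increment of granulosa cGMP hydrolysis
  (`dk5_LH`, ~9x the basal rate) is an effective value that carries part
  of the fast wild-type mural cGMP fall; biochemically the LH-induced
  PDE5A activation is described as modest, and the two arms
  (NPR2 inactivation vs PDE5A activation) are not separable from the
  landmark data.
* Cumulus cAMP re-rise toward mural levels emerges qualitatively from
  junction reopening but its final level is sensitive to the ratio of
  junctional exchange to granulosa hydrolysis, which the anchors do not
  pin down.
* Ratio-to-concentration conversion assumes one calibration for all
  compartments, as the measurements did.
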