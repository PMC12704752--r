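# Shipped default rate parameters.  Produced by scripts/fit_parameters.R
# (staged bounded least squares on the published kinetic/concentration
# landmarks; carbenoxolone factors eps_mc/eps_co calibrated by root-finding
# against the cumulus/oocyte attenuation); regenerate with that script
# rather than editing by hand.
.follisim_defaults <- list(
  k_GPR3 = 4.73012,
  k_FSH = 210,
  k_LH = 810,
  tau_LH = 2.31201,
  k_degA_g = 0.3,
  Vmax3 = 884.779,
  Km3 = 123.233,
  Ki3 = 1.7754,
  V_NPR2 = 344.394,
  tau_dephos = 40.3558,
  phi_min = 0.0448806,
  tau_CNP = 60.9301,
  k5_basal = 0.172197,
  dk5_LH = 1.48816,
  tau_PDE5 = 3,
  k_degG_o = 0.02,
  P_mc = 156850,
  P_co = 85840.7,
  dip_depth = 0.701849,
  eps_mc = 0.1321,
  eps_co = 0.1692
)
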