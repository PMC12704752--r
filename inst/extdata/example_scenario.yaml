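# Example scenario configuration: AG1478-treated follicle (no Cx43 dip),
# simulated for 5.5 h after LH.  All omitted fields use shipped defaults.
perturbation:
  ag1478: true
simulation:
  t_end: 330
  dt_out: 0.5
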