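model:
  dimer:
    epsilon: 0.148706647561
    delta: 0.001
    units: eV
  gamma_nj: 0.0
bath:
  kind: gaussian
  mode_freqs:
  - 0.103650789862
  - 0.1239841984
  - 0.153740406016
  - 0.19837471744
  gamma: 0.0
  linewidth: 0.005
  units: eV
thermal:
  kbt: 0.025
ensemble:
  n_traj: 1
  master_seed: 1
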