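model:
  dimer:
    epsilon: 0.148706647561
    delta: 0.01
    units: eV
  vibronic:
    omega: 0.1487
    coupling: 0.2
    fock_cutoff: 10
    units: eV
  gamma_nj: 0.02
bath:
  kind: gaussian
  mode_freqs:
  - 836.0
  - 1000.0
  - 1240.0
  - 1600.0
  gamma: 0.01
  linewidth: 40.327719697545
  units: cm-1
thermal:
  kbt: 0.025
ensemble:
  n_traj: 2000
  master_seed: 1
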