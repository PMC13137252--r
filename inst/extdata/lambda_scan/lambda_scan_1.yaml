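model:
  dimer:
    epsilon: 0.148706647561
    delta: 0.001
    units: eV
  vibronic:
    omega: 0.1487
    coupling: 0.2
    fock_cutoff: 10
    units: eV
  gamma_nj: 0.02
bath:
  kind: poisson
  rate: 0.005
  mark:
    family: twopoint
    a0: 0.135106024496
  filter_kappa: 0.005
  filter_omega: 0.1487
  amplitude: 0.009126818928
  units: eV
thermal:
  kbt: 0.025
ensemble:
  n_traj: 2000
  master_seed: 1
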