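---
title: "Modeling donor-acceptor electron transfer with Gaussian and shot-noise baths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling donor-acceptor electron transfer with Gaussian and shot-noise baths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nmsse)
```

## The model

`nmsse` simulates donor-to-acceptor electron transfer (ET) in a minimal
receptor-ligand platform: a two-level electronic dimer (donor `|D>`,
acceptor `|A>`) with energy bias `epsilon = eps_D - eps_A` and tunneling
coupling `Delta`, coupled to one discrete vibrational mode of quantum
`omega` through a vibronic term `sigma_z * omega * gamma * (b + b')`, and
embedded in a structured, possibly non-Gaussian environment. In units with
`hbar = 1` (energies in eV, times in 1/eV; 1 eV^-1 ~ 0.6582 fs) the system
Hamiltonian is

    H_S = (epsilon/2) sigma_z + (Delta/2) sigma_x
        + omega (b'b + 1/2) + sigma_z omega gamma (b + b')

on a Fock-truncated tensor space (electronic index slow, Fock index fast;
`|D>` is the `sigma_z` eigenvector with eigenvalue +1). For the isolated
dimer the acceptor population oscillates at the Rabi frequency
`Omega = sqrt(epsilon^2 + Delta^2)` with maximum
`Delta^2/(Delta^2 + epsilon^2)`; at zero bias the maximum transfer
probability is 1. These closed-form results anchor the test suite.

The environment couples through the Hermitian dephasing-type operator
`L = gamma_nj * sigma_z` and enters the dynamics only through its two-time
correlation kernel `alpha(t - s)` and, for the shot-noise bath, through
explicit event realizations.

## Trajectory equation

Single normalized trajectories follow the perturbative, time-local
nonlinear stochastic Schrodinger equation

    d psi / dt = -i H_S psi
               + gamma_nj (sz - <sz>) psi * Conj(ztilde_t)
               - g0(t) gamma_nj^2 [ (sz - <sz>) sz - <(sz - <sz>) sz> ] psi
               + i g1(t) gamma_nj^2 Delta [ (sz - <sz>) sy - 2 <(sz - <sz>) sy> ] psi

with the Pauli operators acting on the electronic factor, and the shifted
(Girsanov) noise `ztilde_t = z_t + int_0^t alpha(t-s) <L'>_s ds` using the
trajectory's own causal expectation history. The memory coefficients are
moments of the kernel,

    g0(t) = int_0^t alpha(u) du,   g1(t) = int_0^t alpha(u) u du,

computed by cumulative trapezoidal quadrature on the simulation grid — the
same discretization the noise shift uses, so the two stay consistent. The
second-order coefficient `g2` (a double kernel convolution) is available
from `memory_coefficients(order = 2)` for completeness, but for a Hermitian
dephasing coupling the corresponding term in the expanded equation is
proportional to `[L', L] = 0` and never contributes to the drift.

Two deliberate readings of the propagated equation are worth recording:

* the `g0` bracket is implemented as `<(sz - <sz>) sz>`; the degenerate
  form `<sz - <sz>>` (identically zero) that a literal transcription would
  give is clearly a typographical slip, as the expansion it derives from
  contains `<Delta_t(L') L>`;
* the factor 2 on the `g1` expectation bracket is implemented as printed;
  `integrator_config(bracket_factor = 1)` switches to the symmetric
  reading. At the default coupling amplitudes the difference is far below
  Monte-Carlo resolution.

The reduced density matrix is the ensemble average of trajectory
projectors; populations, the mode-traced electronic coherence, and the
vibrational occupation `<b'b>(t)` are read off it, with Monte-Carlo
standard errors attached to the acceptor population.

## The two baths

**Harmonic (Gaussian) bath.** A structured spectral density composed of
narrow bands,

    J(w) = sum_i gamma * Gamma * w_i^2 * w / ((w_i^2 - w^2)^2 + Gamma^2 w^2),

with band centres at 836, 1000, 1240 and 1600 cm^-1 (converted to eV),
coupling strength `gamma` and linewidth `Gamma = 0.005` eV by default. The
finite-temperature kernel is the frequency integral of `J(w)` times the
`coth(w/2kBT)` factor; the default `kernel_form = "printed"` applies the
coth to both quadratures, `"standard"` gives the conventional
`coth * cos - i sin` split (they coincide at `T = 0`, and for these
parameters differ negligibly because `coth ~ 1` across the bands at
`kBT = 0.025` eV). The integral is evaluated by composite Simpson
quadrature with the exact `w -> 0` limit at the origin node, a cutoff of
10x the highest band, and automatic grid doubling to a relative tolerance
of 1e-6. Colored complex Gaussian noise with this kernel is synthesized by
eigendecomposition of the covariance matrix on the time grid, clipping
eigenvalues in `[-1e-10 * lambda_max, 0)` to zero.

**Anharmonic (shot-noise) bath.** Discrete environmental events arrive as
a Poisson stream at rate `lambda_p` with amplitudes (marks) drawn from a
zero-mean two-point distribution `+/- a0` by default (the simplest family
with all even cumulants nonzero; Gaussian, exponential and degenerate
marks are available). Each trajectory's driving process is the compensated
filtered sum of its events with causal filter
`phi(u) = N exp(-kappa u) cos(omega_P u)`; `N` normalizes the filter
energy to the pure-exponential value so the stationary variance is
`lambda_p E[a^2] / (2 kappa)` for every modulation frequency. Event
streams are warmed up over `8/kappa` before `t = 0`, so the process is
stationary throughout the observation window. At the second-cumulant level
the bath is summarized by the effective kernel
`alpha_P(tau) = A0 exp(-kappa |tau|) cos(omega_P tau)`, which also supplies
`g0` and `g1` for the shot-noise runs. The same event stream additionally
applies unitary kicks `U(a) = exp(-i a K)` with generator
`K = sigma_z (x) (b + b')` at event times (Trotter splitting between
integrator steps), so one random source drives both the colored noise and
the impulsive perturbations of the electron-vibration manifold. The kick
generator and the mark-to-angle mapping (`kick_scale`, default 1) are
modeling choices — nothing in the second-cumulant description fixes them —
and both are configurable.

**Variance matching.** `variance_match()` calibrates a shot-noise bath to
a target kernel: `A0 = Re alpha_target(0)` and
`lambda_p E[a^2] = 2 kappa A0`, leaving `lambda_p` free. The
event-per-memory parameter `Lambda = lambda_p * tau_c` (with
`tau_c = 1/kappa`) can then be scanned at fixed variance: `Lambda >> 1` is
the effectively-Gaussian frequent-small-event regime, `Lambda << 1` the
intermittency-dominated sparse-event regime. For isolating intermittency
effects the package also provides the *gaussianized twin* of a shot-noise
bath (`simulate_ensemble(..., gaussianize = TRUE)`): a real colored
Gaussian process with the identical effective kernel and no kicks, i.e.
the central-limit endpoint of the compound-Poisson process.

## Default parameters

| quantity | default | origin |
|---|---|---|
| bias `epsilon` | 0.1487 eV (1199.4 cm^-1) | study conditions |
| coupling `Delta` | scanned over 1e-4..1e-1 eV | study conditions |
| mode quantum `omega` | 0.1487 eV | study conditions |
| bands `w_i` | 836, 1000, 1240, 1600 cm^-1 | study conditions |
| linewidth `Gamma` | 0.005 eV (`tau_c = 200`) | study conditions |
| `kBT` | 0.025 eV | study conditions |
| vibronic `gamma` | 0.2 | chosen: mid-range, coupling energy `omega*gamma` ~ 0.03 eV |
| `gamma_nj` | 0.02 | chosen: centre of the quoted 0.005-0.05 range |
| spectral `gamma` | 0.01 eV | chosen: weak-coupling end of the 0-0.49 range, keeps variance-matched kick angles well inside the Fock truncation |
| `kappa` | `Gamma` | chosen: same memory for both baths |
| `omega_P` | `omega` | chosen: couples the shot noise to the dominant vibrational scale |
| Fock cutoff | 10 | convergence-checked (lowest eigenvalues stable to 1e-8 against N+5) |
| `dt` | `0.045/Omega` | step-size bound `dt * Omega <= 0.05`; halving changes populations < 1e-4 |
| window | 10 Rabi periods | covers several oscillations of the slowest scanned dimer |
| `n_traj` | 2000 | Monte-Carlo SEs ~ 0.01 on populations |

The bias sign follows `epsilon = eps_D - eps_A`; configuration files
written in the opposite convention declare
`bias_convention: acceptor-minus-donor` and are negated on load. Energies
in configs carry explicit `units` keys (`eV` or `cm-1`), converted with
the CODATA `hc` factor at the I/O boundary only.

## Numerical scheme

The stepper is a stochastic Heun predictor-corrector that treats the
colored process as smooth within a step — valid because `tau_c >> dt`
throughout (colored noise is differentiable in distribution on the step
scale, which also sidesteps any Ito/Stratonovich ambiguity that a
white-noise limit would raise). A classical four-stage scheme (`"rk4"`) is
available where high deterministic accuracy matters, e.g. closed-system
checks, and converges at `O(dt^4)` on smooth drives. States are
renormalized every step (the normalized equation is the one being
truncated); pre-normalization norms are kept for diagnostics, and a norm
below 1e-12 aborts the trajectory with a message. The noise shift is a
causal memory convolution, `O(n)` per step; trajectories cost `O(n^2)` in
the number of steps and are propagated in compiled code.

Per-trajectory seeds derive from the master seed by a counter scheme
(kept below 2^31), so ensembles are bitwise reproducible and
embarrassingly parallel in principle.

## What the property suite does and does not show

The synthetic conditions exercise every code path against independent
oracles: closed-form Rabi dynamics; displaced-oscillator (polaron)
spectra; exact pure-dephasing decoherence; a hand-built Lindblad
dephasing Liouvillian in the short-memory (Markovian) limit, where the
ensemble matches the master equation with rate
`2 gamma_nj^2 Re g0(infinity)`; compound-Poisson cumulant identities
`kappa_n[dX] = lambda_p E[a^n] dt`; and the kernel-faithfulness of both
noise generators. Gaussianization is checked against the gaussianized
twin: the L-infinity distance between Poisson and Gaussian ensemble
populations decreases across `Lambda = 0.1 -> 1 -> 10` at matched
variance, and at strong electronic coupling (`Delta = 0.1` eV) the
max-transfer gap between the two descriptions is statistically zero.
For these stochastic checks the suite uses a shorter bath memory
(`kappa = 0.05` eV) than the production default, so that the window holds
many correlation times and the ordering is resolved above the Monte-Carlo
floor at the ensemble sizes used (500-2000 trajectories per cell; the
problem sizes are stated in each test). The Gaussianization comparison
additionally uses (i) a nested-thinning construction — one master event
stream per trajectory subsampled to each `Lambda`, so the three ensembles
share randomness — (ii) step-averaged shot-noise paths, which integrate
each filtered jump analytically across the step instead of localizing it
at a grid node, and (iii) zero-mean *Gaussian* marks. The mark family
matters: with the default two-point `+/- a0` marks the `Lambda = 1`
ensemble happens to sit anomalously close to its Gaussian twin — the
sixth- and higher-cumulant contributions (which grow as `1/Lambda^2`)
partially cancel the fourth-cumulant term at that event rate — so the
distance is not monotone through `Lambda = 1` even though both ends
behave as expected. With Gaussian marks (`E[a^4] = 3 E[a^2]^2`, three
times the excess kurtosis at matched variance) the fourth cumulant
dominates throughout and the monotone Gaussianization is cleanly
expressed. Both observations are reproducible and worth knowing when
choosing a mark model. The kick channel is excluded from
the Gaussianization comparison by design: variance matching fixes
`lambda_p E[a^2]`, so the summed squared kick angle per window is
`Lambda`-independent and kicks do not gaussianize — they are tested
separately (vacuum displacement by `a^2`, heating, positivity under
kicks).

None of this certifies behavior on real receptor-ligand systems: the
synthetic bath has four sharp bands and exponential shot-noise memory,
real spectral densities are broader and structured; the kick generator is
a modeling default; and the perturbative truncation at `g0/g1` is accurate
for `eta_NM` moderate but is not an exact solver at strong coupling.

## Known limitations

* The time-local `g0/g1` truncation is the simulated equation, not an
  exact unraveling; no hierarchy (HOPS/HEOM-style) correction is
  attempted.
* One discrete vibronic mode; the configuration accepts only a single
  mode even though the spectral density carries four bands.
* The shot-noise bath's complex structure is a choice: the driving
  process is real-valued, since the Hermitian dephasing coupling supplies
  no phase to the events.
* Scans share one window and step per cell pair; `Delta P` surfaces at
  very small `Delta` are dominated by slow environment-assisted growth
  and need longer windows than the default to saturate.

## A worked example

```{r example, eval = FALSE}
dimer <- dimer_spec(wavenumber_to_ev(1199.4), 0.01)
model <- model_spec(dimer, vibronic_spec(0.1487, 0.2, 10), gamma_nj = 0.02)
bath <- spectral_density_spec(wavenumber_to_ev(c(836, 1000, 1240, 1600)),
                              gamma = 0.01, linewidth = 0.005)
ens <- simulate_ensemble(model, bath, n_traj = 500, master_seed = 3)
glance(ens)
autoplot(ens)
```

The closed dimer at this bias would transfer at most
`rabi_max_probability(dimer)` = `r round(0.01^2 / (0.01^2 + 0.1487^2), 4)`;
the resonant vibronic mode (`omega ~ epsilon`) raises the maximum transfer
probability by two orders of magnitude over ten Rabi periods — the
vibration-assisted pathway the model is built to expose.
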