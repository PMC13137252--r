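# Shared fixtures and independent oracles, built in code at test time.

# Matrix exponential of a Hermitian matrix via eigendecomposition.
expm_herm <- function(h, t) {
  es <- eigen(h, symmetric = TRUE)
  es$vectors %*% (exp(-1i * es$values * t) * Conj(t(es$vectors)))
}

# Closed-system propagation oracle: acceptor population of the bare dimer
# started in |D>, by dense matrix exponentials (independent of the
# trajectory integrator).
closed_pa_oracle <- function(t, dimer) {
  h <- build_receptor_hamiltonian(dimer)
  vapply(t, function(tt) Mod((expm_herm(h, tt) %*% c(1, 0))[2])^2, numeric(1))
}

# Lindblad dephasing oracle for the two-level system: vectorized Liouvillian
# rho_dot = -i[H, rho] + rate * (sz rho sz - rho), exponentiated by
# eigendecomposition. Returns the acceptor population over `t`.
lindblad_pa_oracle <- function(t, dimer, rate) {
  h <- build_receptor_hamiltonian(dimer)
  sz <- matrix(c(1, 0, 0, -1), 2, 2)
  lv <- -1i * (kronecker(diag(2), h) - kronecker(t(h), diag(2))) +
    rate * (kronecker(t(sz), sz) - diag(4))
  es <- eigen(lv)
  c0 <- solve(es$vectors, c(1, 0, 0, 0))   # column-major vec of |D><D|
  vapply(t, function(tt)
    Re((es$vectors %*% (exp(es$values * tt) * c0))[4]), numeric(1))
}

# A noise path that is identically zero (closed-system driving).
zero_path <- function(grid) {
  structure(list(t_grid = grid, z = complex(real = numeric(length(grid))),
                 events = list(times = numeric(0), marks = numeric(0)),
                 seed = NULL),
            class = "noise_path")
}

# Exponential test kernel alpha(tau) = a0 * exp(-kappa * tau) on a grid.
exp_kernel <- function(grid, a0, kappa) {
  correlation_kernel(grid, complex(real = a0 * exp(-kappa * grid)))
}

# A path object wrapping a precomputed complex series.
wrap_path <- function(grid, z, events = NULL) {
  if (is.null(events)) events <- list(times = numeric(0), marks = numeric(0))
  structure(list(t_grid = grid, z = z, events = events, seed = NULL),
            class = "noise_path")
}

table1_bath <- function(gamma = 0.01) {
  spectral_density_spec(wavenumber_to_ev(c(836, 1000, 1240, 1600)),
                        gamma, 0.005)
}

table1_dimer <- function(delta = 0.1) dimer_spec(wavenumber_to_ev(1199.4), delta)
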