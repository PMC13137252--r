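# Model construction: electronic dimer, discrete vibrational mode, and the
# coupled system Hamiltonian. Units: hbar = 1, energies in eV, time in eV^-1
# (1 eV^-1 ~ 0.6582 fs). Conversions happen only at I/O boundaries.

#' Convert wavenumbers to energies
#'
#' Linear conversion from spectroscopic wavenumbers (cm^-1) to energies (eV)
#' using the CODATA value of hc. Negative values pass through with their sign.
#'
#' @param value Numeric vector of wavenumbers in cm^-1.
#' @return Energies in eV.
#' @examples
#' wavenumber_to_ev(836)     # ~0.1037 eV
#' wavenumber_to_ev(1199.4)  # ~0.1487 eV, a typical donor-acceptor bias
#' @export
wavenumber_to_ev <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  value * .hc_ev_cm
}

#' Electronic dimer specification
#'
#' Defines the two-level donor/acceptor subsystem: energy bias
#' `epsilon` = eps_D - eps_A and tunneling coupling `delta`, both in eV.
#'
#' @param epsilon Donor-acceptor energy bias (eV). May be negative.
#' @param delta Tunneling coupling (eV), non-negative.
#' @return An object of class `dimer_spec`.
#' @export
dimer_spec <- function(epsilon, delta) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (delta < 0) abort("`delta` (tunneling coupling) must be >= 0.")
  structure(list(epsilon = as.numeric(epsilon), delta = as.numeric(delta)),
            class = "dimer_spec")
}

#' Discrete vibrational mode specification
#'
#' One harmonic mode of quantum `omega` (eV) coupled to the electronic
#' populations with dimensionless vibronic coupling `coupling` (the coupling
#' energy is `omega * coupling`), truncated at `fock_cutoff` quanta.
#'
#' @param omega Mode quantum (eV), positive.
#' @param coupling Dimensionless vibronic coupling strength.
#' @param fock_cutoff Highest Fock state retained (integer >= 1); the mode
#'   Hilbert space has dimension `fock_cutoff + 1`.
#' @return An object of class `vibronic_spec`.
#' @export
vibronic_spec <- function(omega, coupling, fock_cutoff = 10L) {
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega),
            is.numeric(coupling), length(coupling) == 1L, is.finite(coupling))
  if (omega <= 0) abort("`omega` must be > 0.")
  fock_cutoff <- as.integer(fock_cutoff)
  if (is.na(fock_cutoff) || fock_cutoff < 1L) abort("`fock_cutoff` must be an integer >= 1.")
  structure(list(omega = as.numeric(omega), coupling = as.numeric(coupling),
                 fock_cutoff = fock_cutoff),
            class = "vibronic_spec")
}

#' Full system specification
#'
#' Combines the electronic dimer, an optional discrete vibrational mode, and
#' the dimensionless system-bath coupling amplitude `gamma_nj` entering the
#' dephasing-type coupling operator L = gamma_nj * sigma_z.
#'
#' @param dimer A [dimer_spec()].
#' @param vibronic A [vibronic_spec()] or `NULL` for a bare two-level system.
#' @param gamma_nj System-bath coupling amplitude, >= 0.
#' @return An object of class `model_spec`. The Hilbert dimension is
#'   `2 * (fock_cutoff + 1)` with a mode, else 2.
#' @export
model_spec <- function(dimer, vibronic = NULL, gamma_nj = 0) {
  stopifnot(inherits(dimer, "dimer_spec"))
  if (!is.null(vibronic)) stopifnot(inherits(vibronic, "vibronic_spec"))
  stopifnot(is.numeric(gamma_nj), length(gamma_nj) == 1L, is.finite(gamma_nj))
  if (gamma_nj < 0) abort("`gamma_nj` must be >= 0.")
  structure(list(dimer = dimer, vibronic = vibronic,
                 gamma_nj = as.numeric(gamma_nj)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat(sprintf("  dimer: epsilon = %g eV, delta = %g eV\n",
              x$dimer$epsilon, x$dimer$delta))
  if (is.null(x$vibronic)) {
    cat("  vibronic mode: none (bare two-level system)\n")
  } else {
    cat(sprintf("  vibronic mode: omega = %g eV, coupling = %g, fock_cutoff = %d\n",
                x$vibronic$omega, x$vibronic$coupling, x$vibronic$fock_cutoff))
  }
  cat(sprintf("  gamma_nj = %g  (L = gamma_nj * sigma_z)\n", x$gamma_nj))
  invisible(x)
}

model_dim <- function(model) {
  if (is.null(model$vibronic)) 2L else 2L * (model$vibronic$fock_cutoff + 1L)
}

# Pauli matrices in the {|D>, |A>} basis; |D> is the sigma_z eigenvector
# with eigenvalue +1.
pauli_z <- function() matrix(c(1, 0, 0, -1), 2, 2)
pauli_x <- function() matrix(c(0, 1, 1, 0), 2, 2)
pauli_y <- function() matrix(c(0, 1i, -1i, 0), 2, 2)

# Truncated ladder operator b on an (n_max + 1)-dimensional Fock space.
fock_annihilation <- function(n_max) {
  d <- n_max + 1L
  b <- matrix(0, d, d)
  if (n_max >= 1L) for (n in 1:n_max) b[n, n + 1L] <- sqrt(n)
  b
}

#' Receptor (dimer) Hamiltonian
#'
#' The bare two-level Hamiltonian H_R = (epsilon/2) sigma_z +
#' (delta/2) sigma_x in the donor/acceptor basis. Traceless and Hermitian,
#' with eigenvalues +/- Omega/2 where Omega = sqrt(epsilon^2 + delta^2).
#'
#' @param dimer A [dimer_spec()].
#' @return A 2x2 Hermitian matrix (eV).
#' @export
build_receptor_hamiltonian <- function(dimer) {
  stopifnot(inherits(dimer, "dimer_spec"))
  dimer$epsilon / 2 * pauli_z() + dimer$delta / 2 * pauli_x()
}

#' Coupled system Hamiltonian
#'
#' Tensor-product Hamiltonian of the dimer and the discrete vibrational mode:
#' H_S = (epsilon/2) sigma_z + (delta/2) sigma_x + omega (b'b + 1/2)
#'       + sigma_z * omega * gamma (b + b'),
#' on the truncated space with the electronic index slow and the Fock index
#' fast. For a model without a mode this reduces to the receptor Hamiltonian.
#'
#' @param model A [model_spec()].
#' @return A Hermitian matrix of dimension `2 * (fock_cutoff + 1)` (or 2x2).
#' @export
build_system_hamiltonian <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  hr <- build_receptor_hamiltonian(model$dimer)
  if (is.null(model$vibronic)) return(hr)
  vib <- model$vibronic
  nf <- vib$fock_cutoff + 1L
  b <- fock_annihilation(vib$fock_cutoff)
  nvib <- crossprod(b)                      # b' b
  id_f <- diag(nf)
  h <- kronecker(hr, id_f) +
    kronecker(diag(2), vib$omega * (nvib + 0.5 * id_f)) +
    kronecker(pauli_z(), vib$omega * vib$coupling * (b + t(b)))
  h
}

# sigma_z, sigma_y, sigma_x lifted to the full space (identity on the mode).
lift_electronic <- function(op, model) {
  if (is.null(model$vibronic)) op else kronecker(op, diag(model$vibronic$fock_cutoff + 1L))
}

# Vibrational number operator on the full space.
lift_number <- function(model) {
  stopifnot(!is.null(model$vibronic))
  b <- fock_annihilation(model$vibronic$fock_cutoff)
  kronecker(diag(2), crossprod(b))
}

#' Intrinsic electronic frequency
#'
#' Omega = sqrt(epsilon^2 + delta^2), the Rabi/tunneling frequency of the
#' isolated dimer; tau_sys = 1/Omega is the intrinsic system time scale.
#'
#' @param dimer A [dimer_spec()].
#' @return Omega in eV.
#' @export
effective_frequency <- function(dimer) {
  stopifnot(inherits(dimer, "dimer_spec"))
  sqrt(dimer$epsilon^2 + dimer$delta^2)
}

#' Maximum closed-dimer transfer probability
#'
#' For the isolated dimer started in the donor state, the acceptor
#' population oscillates with maximum delta^2 / (delta^2 + epsilon^2); at
#' zero bias the maximum transfer probability is 1.
#'
#' @param dimer A [dimer_spec()] with Omega > 0.
#' @return Probability in \[0, 1\].
#' @export
rabi_max_probability <- function(dimer) {
  omega <- effective_frequency(dimer)
  if (omega == 0) abort("Maximum transfer probability undefined at epsilon = delta = 0.")
  dimer$delta^2 / omega^2
}

#' Closed-dimer acceptor population
#'
#' The textbook two-level result P_{D->A}(t) = (delta^2/Omega^2)
#' sin^2(Omega t / 2) for the isolated dimer initialized in |D>.
#'
#' @param t Times (eV^-1), non-negative; vectorized.
#' @param dimer A [dimer_spec()].
#' @return Acceptor population at each `t`.
#' @export
closed_population <- function(t, dimer) {
  stopifnot(is.numeric(t), all(t >= 0))
  omega <- effective_frequency(dimer)
  if (omega == 0) return(rep(0, length(t)))
  (dimer$delta^2 / omega^2) * sin(omega * t / 2)^2
}
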