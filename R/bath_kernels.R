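# Bath description: structured spectral densities, finite-temperature
# Gaussian correlation kernels, effective shot-noise kernels, the memory
# coefficients g_i(t) of the time-local perturbative expansion, and
# dimensionless regime diagnostics.

#' Structured spectral density specification
#'
#' A sum of narrow bands J(w) = sum_i gamma * Gamma * w_i^2 * w /
#' ((w_i^2 - w^2)^2 + Gamma^2 w^2) centred on the dominant environmental
#' mode frequencies `mode_freqs`.
#'
#' @param mode_freqs Mode frequencies w_i (eV), all positive.
#' @param gamma Coupling strength (eV), >= 0.
#' @param linewidth Bandwidth Gamma (eV), > 0; sets the bath correlation
#'   time tau_c ~ 1/Gamma.
#' @return An object of class `spectral_density_spec`.
#' @export
spectral_density_spec <- function(mode_freqs, gamma, linewidth) {
  stopifnot(is.numeric(mode_freqs), length(mode_freqs) >= 1L,
            all(is.finite(mode_freqs)), all(mode_freqs > 0),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma), gamma >= 0,
            is.numeric(linewidth), length(linewidth) == 1L, is.finite(linewidth),
            linewidth > 0)
  structure(list(mode_freqs = as.numeric(mode_freqs), gamma = as.numeric(gamma),
                 linewidth = as.numeric(linewidth)),
            class = "spectral_density_spec")
}

#' Thermal bath specification
#'
#' @param kbt Thermal energy k_B*T in eV; `0` selects the zero-temperature
#'   limit (coth factor -> 1).
#' @return An object of class `thermal_spec`.
#' @export
thermal_spec <- function(kbt) {
  stopifnot(is.numeric(kbt), length(kbt) == 1L, is.finite(kbt), kbt >= 0)
  structure(list(kbt = as.numeric(kbt)), class = "thermal_spec")
}

#' Evaluate the structured spectral density
#'
#' @param omega Frequencies (eV), >= 0; vectorized.
#' @param spec A [spectral_density_spec()].
#' @return J(omega), non-negative. At a band centre the peak value is
#'   gamma * w_i / Gamma.
#' @export
spectral_density <- function(omega, spec) {
  stopifnot(inherits(spec, "spectral_density_spec"),
            is.numeric(omega), all(omega >= 0))
  out <- numeric(length(omega))
  for (wi in spec$mode_freqs) {
    out <- out + spec$gamma * spec$linewidth * wi^2 * omega /
      ((wi^2 - omega^2)^2 + spec$linewidth^2 * omega^2)
  }
  out
}

#' Thermal occupation number
#'
#' Bose-Einstein occupation n_th = 1 / (exp(omega / kbt) - 1). At
#' `kbt = 0` the occupation is 0 by convention (zero-temperature limit).
#'
#' @param omega Mode energy (eV), > 0; vectorized.
#' @param thermal A [thermal_spec()].
#' @return Occupation number(s).
#' @export
thermal_occupation <- function(omega, thermal) {
  stopifnot(inherits(thermal, "thermal_spec"), is.numeric(omega), all(omega > 0))
  if (thermal$kbt == 0) return(rep(0, length(omega)))
  1 / expm1(omega / thermal$kbt)
}

#' Two-time bath correlation kernel
#'
#' Container for a stationary complex kernel alpha(tau) sampled on a lag
#' grid. Stationary kernels satisfy alpha(-tau) = Conj(alpha(tau)), so only
#' tau >= 0 is stored.
#'
#' @param tau Lag grid (eV^-1), sorted, starting at 0.
#' @param alpha Complex kernel values on `tau`.
#' @param stationary Logical flag (only stationary kernels are produced by
#'   the built-in constructors).
#' @param kind Optional label ("gaussian", "poisson", ...).
#' @return An object of class `correlation_kernel`.
#' @export
correlation_kernel <- function(tau, alpha, stationary = TRUE, kind = "custom") {
  stopifnot(is.numeric(tau), length(tau) >= 2L, !is.unsorted(tau), tau[1] == 0,
            length(alpha) == length(tau))
  alpha <- as.complex(alpha)
  a0 <- alpha[1]
  if (abs(Im(a0)) > 1e-10 * max(1, abs(a0)))
    abort("Kernel value at tau = 0 must be real.")
  if (Re(a0) < 0) abort("Kernel value at tau = 0 must be >= 0.")
  alpha[1] <- complex(real = Re(a0), imaginary = 0)
  structure(list(tau = as.numeric(tau), alpha = alpha,
                 stationary = isTRUE(stationary), kind = kind),
            class = "correlation_kernel")
}

#' @export
print.correlation_kernel <- function(x, ...) {
  cat(sprintf("<correlation_kernel: %s> %d lags on [0, %g], alpha(0) = %g\n",
              x$kind, length(x$tau), max(x$tau), Re(x$alpha[1])))
  invisible(x)
}

#' @method as_tibble correlation_kernel
#' @export
as_tibble.correlation_kernel <- function(x, ...) {
  tibble(tau = x$tau, re = Re(x$alpha), im = Im(x$alpha))
}

#' Write a kernel to CSV
#'
#' Three columns (tau, re, im), for inspection and fixtures.
#'
#' @param kernel A [correlation_kernel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  stopifnot(inherits(kernel, "correlation_kernel"))
  utils::write.csv(as_tibble(kernel), path, row.names = FALSE)
  invisible(path)
}

#' Finite-temperature Gaussian bath kernel
#'
#' Computes alpha_G(tau) = Int_0^Inf dw J(w) * coth(w / 2 kbt) *
#' (cos(w tau) - i sin(w tau)) on the requested lag grid by composite
#' Simpson quadrature on a dense frequency grid, with automatic
#' grid-doubling until the kernel changes by less than `tol` (relative to
#' alpha(0)).
#'
#' The default `form = "printed"` multiplies both the cosine and the -i*sine
#' by the coth factor; `form = "standard"` applies coth only to the cosine
#' (the conventional symmetric/antisymmetric split of the finite-temperature
#' kernel). At `kbt = 0` both coincide.
#'
#' @param grid Lag grid (eV^-1), sorted, starting at 0.
#' @param spec A [spectral_density_spec()].
#' @param thermal A [thermal_spec()].
#' @param form `"printed"` or `"standard"` (see Details).
#' @param cutoff Upper integration frequency; default 10x the largest band
#'   centre.
#' @param tol Relative convergence tolerance for grid doubling.
#' @param max_doublings Maximum number of refinement steps before the
#'   quadrature is declared non-convergent.
#' @return A [correlation_kernel()] of kind `"gaussian"`.
#' @export
gaussian_kernel <- function(grid, spec, thermal,
                            form = c("printed", "standard"),
                            cutoff = NULL, tol = 1e-6, max_doublings = 8L) {
  stopifnot(inherits(spec, "spectral_density_spec"),
            inherits(thermal, "thermal_spec"),
            is.numeric(grid), !is.unsorted(grid), grid[1] == 0)
  form <- match.arg(form)
  if (spec$gamma == 0) {
    return(correlation_kernel(grid, complex(real = rep(0, length(grid))),
                              kind = "gaussian"))
  }
  if (is.null(cutoff)) cutoff <- 10 * max(spec$mode_freqs)
  tau_max <- max(grid, 1)
  # resolve both the narrow bands and the oscillation e^{-i w tau_max}
  n0 <- max(2048L,
            2L * ceiling(cutoff / min(spec$linewidth / 8, pi / (8 * tau_max))))

  eval_kernel <- function(n) {
    w <- seq(0, cutoff, length.out = n + 1L)
    dw <- w[2] - w[1]
    jw <- spectral_density(w, spec)
    jcth <- if (thermal$kbt == 0) jw else {
      x <- w / (2 * thermal$kbt)
      c0 <- 1 / tanh(pmax(x, .Machine$double.eps))
      v <- jw * c0
      # finite w -> 0 limit of J(w) coth(w/2kbt): J ~ w * sum_i gamma Gamma / w_i^2
      v[1] <- 2 * thermal$kbt * spec$gamma * spec$linewidth *
        sum(1 / spec$mode_freqs^2)
      v
    }
    wts <- dw / 3 * rep(c(2, 4), length.out = length(w))
    wts[c(1, length(w))] <- dw / 3
    ph <- outer(w, grid)                   # w_k * tau_j
    if (form == "printed") {
      f <- wts * jcth
      re <- drop(crossprod(cos(ph), f))
      im <- -drop(crossprod(sin(ph), f))
    } else {
      re <- drop(crossprod(cos(ph), wts * jcth))
      im <- -drop(crossprod(sin(ph), wts * jw))
    }
    complex(real = re, imaginary = im)
  }

  a_prev <- eval_kernel(n0)
  n <- n0
  for (k in seq_len(max_doublings)) {
    n <- n * 2L
    a_new <- eval_kernel(n)
    err <- max(abs(a_new - a_prev)) / max(abs(a_new[1]), .Machine$double.eps)
    a_prev <- a_new
    if (err < tol) {
      return(correlation_kernel(grid, a_new, kind = "gaussian"))
    }
  }
  abort(sprintf(
    "Bath-kernel quadrature did not converge (last rel. change %.3g at %d nodes); increase `max_doublings` or lower resolution demands.",
    err, n))
}

#' Mark (kick-amplitude) distribution
#'
#' Families: `"twopoint"` (+/- a0 with equal probability; zero mean, all even
#' moments a0^n), `"fixed"` (degenerate at a0; all moments a0^n),
#' `"gaussian"` (zero mean, sd `sd`), `"exponential"` (mean `mean`; the
#' nonzero first moment makes the compensation term active).
#'
#' @param family Distribution family.
#' @param a0,sd,mean Family parameter (only the one matching `family` is used).
#' @return An object of class `mark_dist`.
#' @export
mark_dist <- function(family = c("twopoint", "fixed", "gaussian", "exponential"),
                      a0 = 1, sd = 1, mean = 1) {
  family <- match.arg(family)
  par <- switch(family,
                twopoint = list(a0 = a0),
                fixed = list(a0 = a0),
                gaussian = list(sd = sd),
                exponential = list(mean = mean))
  stopifnot(all(vapply(par, is.finite, logical(1))))
  structure(c(list(family = family), par), class = "mark_dist")
}

#' Raw moments of a mark distribution
#'
#' @param mark A [mark_dist()].
#' @param n Moment order (1..4).
#' @return E\[a^n\].
#' @export
mark_moment <- function(mark, n) {
  stopifnot(inherits(mark, "mark_dist"), n %in% 1:4)
  switch(mark$family,
         twopoint = if (n %% 2 == 1) 0 else mark$a0^n,
         fixed = mark$a0^n,
         gaussian = if (n %% 2 == 1) 0 else if (n == 2) mark$sd^2 else 3 * mark$sd^4,
         exponential = factorial(n) * mark$mean^n)
}

sample_marks <- function(mark, n) {
  switch(mark$family,
         twopoint = mark$a0 * sample(c(-1, 1), n, replace = TRUE),
         fixed = rep(mark$a0, n),
         gaussian = rnorm(n, 0, mark$sd),
         exponential = rexp(n, 1 / mark$mean))
}

#' Compound-Poisson (shot-noise) bath specification
#'
#' Discrete environmental events at rate `rate` with amplitudes (marks) from
#' `mark`, filtered by a causal exponential response with inverse memory
#' `filter_kappa` and modulation `filter_omega`. At the second-cumulant level
#' the bath is summarized by the effective kernel
#' alpha_P(tau) = amplitude * exp(-kappa |tau|) * cos(omega_P tau),
#' with correlation time tau_c = 1/kappa.
#'
#' @param rate Event rate lambda_p (events per eV^-1), >= 0.
#' @param mark A [mark_dist()].
#' @param filter_kappa kappa (eV), > 0.
#' @param filter_omega omega_P (eV), >= 0.
#' @param amplitude Kernel value A0 at tau = 0; defaults to the stationary
#'   variance of the exponentially filtered process,
#'   rate * E\[a^2\] / (2 kappa).
#' @return An object of class `poisson_bath_spec`.
#' @export
poisson_bath_spec <- function(rate, mark = mark_dist("twopoint", a0 = 1),
                              filter_kappa, filter_omega = 0,
                              amplitude = NULL) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate), rate >= 0,
            inherits(mark, "mark_dist"),
            is.numeric(filter_kappa), filter_kappa > 0,
            is.numeric(filter_omega), filter_omega >= 0)
  if (is.null(amplitude)) amplitude <- rate * mark_moment(mark, 2) / (2 * filter_kappa)
  stopifnot(is.numeric(amplitude), amplitude >= 0)
  structure(list(rate = as.numeric(rate), mark = mark,
                 filter_kappa = as.numeric(filter_kappa),
                 filter_omega = as.numeric(filter_omega),
                 amplitude = as.numeric(amplitude)),
            class = "poisson_bath_spec")
}

#' Second jump moment
#'
#' The weight lambda_p * E\[a^2\] = Int a^2 nu(da) controlling the second
#' cumulant of the shot-noise bath.
#'
#' @param spec A [poisson_bath_spec()].
#' @return Scalar moment value.
#' @export
second_jump_moment <- function(spec) {
  stopifnot(inherits(spec, "poisson_bath_spec"))
  spec$rate * mark_moment(spec$mark, 2)
}

#' Effective shot-noise kernel
#'
#' Closed-form second-cumulant kernel of the filtered compound-Poisson bath:
#' alpha_P(tau) = A0 * exp(-kappa |tau|) * cos(omega_P tau).
#'
#' @param grid Lag grid (eV^-1), sorted, starting at 0.
#' @param spec A [poisson_bath_spec()].
#' @return A [correlation_kernel()] of kind `"poisson"`.
#' @export
poisson_kernel <- function(grid, spec) {
  stopifnot(inherits(spec, "poisson_bath_spec"),
            is.numeric(grid), !is.unsorted(grid), grid[1] == 0)
  vals <- spec$amplitude * exp(-spec$filter_kappa * abs(grid)) *
    cos(spec$filter_omega * grid)
  correlation_kernel(grid, complex(real = vals), kind = "poisson")
}

#' Shot-noise kernel from a causal filter
#'
#' Second moment of the filtered compound-Poisson process under stationary
#' conditions: alpha_P(tau) = lambda_p E\[a^2\] *
#' Int_0^Inf phi(u + |tau|) Conj(phi(u)) du, evaluated by quadrature. For the
#' pure exponential filter phi(u) = exp(-kappa u) this equals
#' lambda_p E\[a^2\] exp(-kappa |tau|) / (2 kappa).
#'
#' @param filter A list with `kappa` (> 0) and optional `omega` (default 0)
#'   describing phi(u) = exp(-kappa u) cos(omega u), or a function of u.
#' @param jump_moment The second jump moment lambda_p * E\[a^2\].
#' @param grid Lag grid, sorted, starting at 0.
#' @return A [correlation_kernel()] of kind `"poisson"`.
#' @export
filtered_kernel_from_phi <- function(filter, jump_moment, grid) {
  stopifnot(is.numeric(jump_moment), jump_moment >= 0,
            is.numeric(grid), !is.unsorted(grid), grid[1] == 0)
  if (is.function(filter)) {
    phi <- filter
    kappa <- NULL
  } else {
    stopifnot(is.numeric(filter$kappa), filter$kappa > 0)
    kappa <- filter$kappa
    om <- if (is.null(filter$omega)) 0 else filter$omega
    phi <- function(u) exp(-kappa * u) * cos(om * u)
  }
  norm2 <- stats::integrate(function(u) abs(phi(u))^2, 0, Inf,
                            rel.tol = 1e-10)$value
  if (!is.finite(norm2) || norm2 > 1e12) abort("Filter norm diverges.")
  vals <- vapply(abs(grid), function(tau) {
    stats::integrate(function(u) phi(u + tau) * phi(u), 0, Inf,
                     rel.tol = 1e-10, abs.tol = 1e-14)$value
  }, numeric(1))
  correlation_kernel(grid, complex(real = jump_moment * vals), kind = "poisson")
}

# cumulative trapezoid of (possibly complex) y over x, starting at 0
cumtrapz_ <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

#' Memory coefficients of the time-local expansion
#'
#' From a stationary kernel alpha(tau):
#' g0(t) = Int_0^t alpha(u) du, g1(t) = Int_0^t alpha(u) u du, and
#' (order 2 only) g2(t) = Int_0^t ds alpha(t-s) (t-s) g0(s), all by
#' cumulative trapezoidal quadrature on the kernel grid — the same
#' discretization used by the trajectory integrator.
#'
#' @param kernel A [correlation_kernel()].
#' @param t_grid Times at which coefficients are needed; must equal the
#'   kernel lag grid.
#' @param order 0, 1 or 2 (g2 is kept off the propagated equation by
#'   default; see [integrator_config()]).
#' @return An object of class `memory_coefficients` with fields `t_grid`,
#'   `g0`, `g1` and optionally `g2` (complex vectors; g0(0) = g1(0) = 0).
#' @export
memory_coefficients <- function(kernel, t_grid = kernel$tau, order = 1) {
  stopifnot(inherits(kernel, "correlation_kernel"), order %in% 0:2)
  if (!isTRUE(all.equal(t_grid, kernel$tau)))
    abort("`t_grid` must coincide with the kernel lag grid.")
  tau <- kernel$tau
  a <- kernel$alpha
  g0 <- cumtrapz_(tau, a)
  g1 <- if (order >= 1) cumtrapz_(tau, a * tau) else NULL
  g2 <- NULL
  if (order == 2) {
    n <- length(tau)
    if (n < 8L) abort("Grid too coarse for the order-2 coefficient.")
    g2 <- complex(real = numeric(n))
    for (i in 2:n) {
      s <- tau[1:i]
      integrand <- a[i:1] * (tau[i] - s) * g0[1:i]
      g2[i] <- cumtrapz_(s, integrand)[i]
    }
  }
  structure(list(t_grid = tau, g0 = g0, g1 = g1, g2 = g2, order = order,
                 kernel = kernel),
            class = "memory_coefficients")
}

#' @method as_tibble memory_coefficients
#' @export
as_tibble.memory_coefficients <- function(x, ...) {
  out <- tibble(t = x$t_grid, g0_re = Re(x$g0), g0_im = Im(x$g0))
  if (!is.null(x$g1)) {
    out$g1_re <- Re(x$g1); out$g1_im <- Im(x$g1)
  }
  if (!is.null(x$g2)) {
    out$g2_re <- Re(x$g2); out$g2_im <- Im(x$g2)
  }
  out
}

#' Match the shot-noise variance to a target kernel
#'
#' Calibrates a Poisson bath so its second cumulant agrees with a target
#' (typically Gaussian) kernel at tau = 0: sets A0 = Re alpha_target(0) and
#' rescales the mark amplitude so that lambda_p E\[a^2\] = 2 kappa A0 (the
#' exponential-filter identity), leaving the event rate free so the
#' event-per-memory parameter Lambda can be scanned at fixed variance.
#'
#' @param target A [correlation_kernel()] with Re alpha(0) > 0.
#' @param spec A [poisson_bath_spec()] with `rate > 0`.
#' @return The calibrated `poisson_bath_spec`.
#' @export
variance_match <- function(target, spec) {
  stopifnot(inherits(target, "correlation_kernel"),
            inherits(spec, "poisson_bath_spec"))
  v <- Re(target$alpha[1])
  if (v <= 0) abort("Target kernel has no variance to match (alpha(0) <= 0).")
  if (spec$rate == 0) abort("Cannot variance-match at zero event rate.")
  ea2 <- 2 * spec$filter_kappa * v / spec$rate
  mark <- spec$mark
  new_mark <- switch(mark$family,
                     twopoint = mark_dist("twopoint", a0 = sqrt(ea2)),
                     fixed = mark_dist("fixed", a0 = sqrt(ea2)),
                     gaussian = mark_dist("gaussian", sd = sqrt(ea2)),
                     exponential = mark_dist("exponential", mean = sqrt(ea2 / 2)))
  poisson_bath_spec(rate = spec$rate, mark = new_mark,
                    filter_kappa = spec$filter_kappa,
                    filter_omega = spec$filter_omega,
                    amplitude = v)
}

#' Dimensionless regime controls
#'
#' Time-scale diagnostics that organize the dynamical regimes: the bath
#' correlation time tau_c = 1/Gamma (or 1/kappa), the system time
#' tau_sys = 1/Omega, the non-Markovianity measure eta_NM = Omega * tau_c,
#' and the event-per-memory parameter Lambda = lambda_p * tau_c
#' (Lambda >> 1: effectively Gaussian; Lambda << 1: intermittency-dominated).
#'
#' @param model A [model_spec()] (only the dimer enters Omega).
#' @param gamma_bath Bath linewidth Gamma or filter kappa (eV), > 0.
#' @param rate Event rate lambda_p; `NA` for a Gaussian bath.
#' @return A one-row tibble with `omega_sys`, `tau_c`, `tau_sys`, `eta_nm`,
#'   `lam`.
#' @export
regime_controls <- function(model, gamma_bath, rate = NA_real_) {
  stopifnot(inherits(model, "model_spec"),
            is.numeric(gamma_bath), gamma_bath > 0)
  omega_sys <- effective_frequency(model$dimer)
  tau_c <- 1 / gamma_bath
  tibble(omega_sys = omega_sys,
         tau_c = tau_c,
         tau_sys = if (omega_sys > 0) 1 / omega_sys else NA_real_,
         eta_nm = omega_sys * tau_c,
         lam = rate * tau_c)
}
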