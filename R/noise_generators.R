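# Per-trajectory driving processes: colored complex Gaussian noise with a
# prescribed kernel, compensated filtered compound-Poisson shot noise,
# unitary kick events, and cumulant diagnostics.

#' Factorize a kernel covariance for colored-noise synthesis
#'
#' Builds the Hermitian covariance matrix C\[i,j\] = alpha(t_i - t_j) on a
#' uniform grid and returns its symmetric square-root factor A (C = A A*)
#' from an eigendecomposition. Small negative eigenvalues (within
#' `-clip_tol * lambda_max`) are clipped to zero; larger negative parts
#' signal an indefinite kernel.
#'
#' @param kernel A stationary [correlation_kernel()].
#' @param t_grid Uniform time grid; lags must be covered by the kernel grid.
#' @param clip_tol Relative clipping tolerance for negative eigenvalues.
#' @return A complex matrix factor A.
#' @export
gaussian_path_factor <- function(kernel, t_grid = kernel$tau, clip_tol = 1e-10) {
  stopifnot(inherits(kernel, "correlation_kernel"), kernel$stationary)
  if (!isTRUE(all.equal(t_grid, kernel$tau)))
    abort("`t_grid` must coincide with the kernel lag grid.")
  n <- length(t_grid)
  idx <- outer(seq_len(n), seq_len(n), "-")   # i - j in grid steps
  av <- kernel$alpha
  cmat <- matrix(complex(real = 0), n, n)
  pos <- idx >= 0
  cmat[pos] <- av[idx[pos] + 1L]
  cmat[!pos] <- Conj(av[-idx[!pos] + 1L])
  if (max(abs(av)) == 0) return(matrix(complex(real = 0), n, n))
  es <- eigen(cmat, symmetric = TRUE)
  lam <- es$values
  lmax <- max(lam)
  if (min(lam) < -clip_tol * lmax)
    abort(sprintf("Kernel covariance indefinite beyond tolerance (min eig %.3g vs max %.3g).",
                  min(lam), lmax))
  lam[lam < 0] <- 0
  es$vectors %*% (sqrt(lam) * Conj(t(es$vectors)))
}

#' Sample colored complex Gaussian noise paths
#'
#' Zero-mean circularly symmetric complex Gaussian processes with
#' E\[z_t Conj(z_s)\] = alpha(t - s) and E\[z_t z_s\] = 0, synthesized as
#' A %*% xi with xi standard circular complex normals.
#'
#' @param kernel A stationary [correlation_kernel()].
#' @param t_grid Uniform time grid (defaults to the kernel grid).
#' @param n_paths Number of independent paths.
#' @param seed Integer seed (R RNG); identical seed and spec give identical
#'   paths.
#' @param factor Optional precomputed [gaussian_path_factor()] for reuse
#'   across ensembles.
#' @return A complex matrix, `length(t_grid)` rows by `n_paths` columns.
#' @export
sample_gaussian_paths <- function(kernel, t_grid = kernel$tau, n_paths = 1L,
                                  seed = NULL, factor = NULL) {
  if (is.null(factor)) factor <- gaussian_path_factor(kernel, t_grid)
  n <- nrow(factor)
  if (!is.null(seed)) set.seed(seed)
  xi <- matrix(complex(real = rnorm(n * n_paths, sd = sqrt(0.5)),
                       imaginary = rnorm(n * n_paths, sd = sqrt(0.5))),
               n, n_paths)
  factor %*% xi
}

#' Sample real colored Gaussian noise paths
#'
#' Real-valued zero-mean Gaussian processes with covariance
#' E\[z_t z_s\] = Re alpha(t - s): the central-limit twin of the real
#' filtered shot-noise process at matched second cumulant.
#'
#' @inheritParams sample_gaussian_paths
#' @return A real matrix, `length(t_grid)` rows by `n_paths` columns.
#' @export
sample_real_gaussian_paths <- function(kernel, t_grid = kernel$tau,
                                       n_paths = 1L, seed = NULL,
                                       factor = NULL) {
  if (is.null(factor)) factor <- gaussian_path_factor(kernel, t_grid)
  if (max(abs(Im(kernel$alpha))) > 1e-12 * max(abs(kernel$alpha), 1))
    abort("Real-process synthesis needs a real kernel.")
  n <- nrow(factor)
  if (!is.null(seed)) set.seed(seed)
  xi <- matrix(rnorm(n * n_paths), n, n_paths)
  Re(factor %*% xi)
}

#' Sample one colored Gaussian noise path
#'
#' Single-path convenience wrapper around [sample_gaussian_paths()].
#'
#' @inheritParams sample_gaussian_paths
#' @return An object of class `noise_path` with fields `t_grid`, `z`
#'   (complex), `events` (empty), `seed`.
#' @export
sample_gaussian_path <- function(kernel, t_grid = kernel$tau, seed = NULL,
                                 factor = NULL) {
  z <- drop(sample_gaussian_paths(kernel, t_grid, 1L, seed, factor))
  structure(list(t_grid = t_grid, z = z,
                 events = list(times = numeric(0), marks = numeric(0)),
                 seed = seed),
            class = "noise_path")
}

#' Sample a compound-Poisson event stream
#'
#' Homogeneous Poisson arrivals at rate lambda_p on \[0, t_max\] with i.i.d.
#' marks from the bath's amplitude distribution p(a).
#'
#' @param spec A [poisson_bath_spec()].
#' @param t_max End of the observation window (eV^-1).
#' @param seed Integer seed, optional.
#' @param t_min Start of the sampling window; a negative value warms up the
#'   filtered process so it is stationary at t = 0 (use ~ -8/kappa).
#' @return An object of class `event_stream`: sorted `times`, `marks`,
#'   `rate`, `t_max`, `t_min`.
#' @export
sample_events <- function(spec, t_max, seed = NULL, t_min = 0) {
  stopifnot(inherits(spec, "poisson_bath_spec"), t_max > t_min)
  if (!is.null(seed)) set.seed(seed)
  times <- numeric(0)
  span <- t_max - t_min
  if (spec$rate > 0) {
    # draw arrivals in blocks of exponential gaps until t_max is passed
    t_cur <- t_min
    repeat {
      gaps <- rexp(max(16L, ceiling(1.5 * spec$rate * span)), spec$rate)
      arr <- t_cur + cumsum(gaps)
      times <- c(times, arr[arr <= t_max])
      t_cur <- arr[length(arr)]
      if (t_cur > t_max) break
    }
  }
  marks <- if (length(times)) sample_marks(spec$mark, length(times)) else numeric(0)
  structure(list(times = times, marks = marks, rate = spec$rate,
                 t_max = t_max, t_min = t_min),
            class = "event_stream")
}

# cumulative integral of the filter from 0 to t (analytic, exponential-cosine)
filter_cumint <- function(t, kappa, om) {
  if (om == 0) (1 - exp(-kappa * t)) / kappa
  else (kappa - exp(-kappa * t) * (kappa * cos(om * t) - om * sin(om * t))) /
    (kappa^2 + om^2)
}

# Normalization making the modulated filter carry the same energy as the
# pure exponential: int phi^2 du = 1/(2 kappa) for every omega_P, so the
# stationary process variance is lambda_p E[a^2] / (2 kappa) exactly.
filter_norm <- function(kappa, om) {
  if (om == 0) return(1)
  c2 <- 1 / (4 * kappa) + kappa / (4 * (kappa^2 + om^2))
  sqrt(1 / (2 * kappa) / c2)
}

#' Filter and compensate an event stream
#'
#' Builds the driving shot-noise process
#' z(t) = sum_k phi(t - t_k) a_k - lambda_p E\[a\] Int_0^t phi(u) du
#' with the causal filter phi(u) = N exp(-kappa u) cos(omega_P u), where N
#' normalizes the filter energy to the pure-exponential value
#' (Int phi^2 = 1 / (2 kappa)), so the stationary variance equals
#' lambda_p E\[a^2\] / (2 kappa) for every modulation frequency. The
#' compensation term vanishes for zero-mean marks. The process is real
#' valued (the shot-noise bath couples through a Hermitian dephasing
#' operator and carries no complex structure).
#'
#' @param events An [sample_events()] stream.
#' @param spec A [poisson_bath_spec()] supplying the filter (and rate and
#'   mark mean for compensation).
#' @param t_grid Time grid.
#' @param step_average Replace the node value of the process by its exact
#'   average over the step-centred window. Node sampling localizes every
#'   jump at a grid node, an O(dt) error per event that grows with the
#'   event rate; step averaging integrates the filtered jump analytically
#'   across the window, leaving only O(dt^2) distortion (negligible for
#'   the smooth between-event decay when tau_c >> dt). The ensemble driver
#'   uses averaged paths.
#' @return An object of class `noise_path` (real-valued `z`, events kept for
#'   kick application).
#' @export
filter_and_compensate <- function(events, spec, t_grid, step_average = FALSE) {
  stopifnot(inherits(events, "event_stream"),
            inherits(spec, "poisson_bath_spec"), is.numeric(t_grid))
  kappa <- spec$filter_kappa
  om <- spec$filter_omega
  nf <- filter_norm(kappa, om)
  z <- numeric(length(t_grid))
  if (length(events$times)) {
    if (!step_average) {
      for (k in seq_along(events$times)) {
        u <- t_grid - events$times[k]
        live <- u >= 0
        z[live] <- z[live] + nf * events$marks[k] * exp(-kappa * u[live]) * cos(om * u[live])
      }
    } else {
      dt <- t_grid[2] - t_grid[1]
      cx <- complex(real = kappa, imaginary = -om)
      ph <- function(u) (1 - exp(-cx * u)) / cx   # int_0^u e^{-k v} cos(w v) dv (Re)
      for (k in seq_along(events$times)) {
        tk <- events$times[k]
        lo <- pmax(0, t_grid - dt / 2 - tk)
        hi <- t_grid + dt / 2 - tk
        live <- hi > 0
        z[live] <- z[live] + nf * events$marks[k] *
          Re(ph(hi[live]) - ph(lo[live])) / dt
      }
    }
  }
  mu <- events$rate * mark_moment(spec$mark, 1)
  t_min <- if (is.null(events$t_min)) 0 else events$t_min
  if (mu != 0) z <- z - mu * nf * filter_cumint(t_grid - t_min, kappa, om)
  structure(list(t_grid = t_grid, z = z,
                 events = list(times = events$times, marks = events$marks),
                 seed = NULL),
            class = "noise_path")
}

# Fisher k-statistics (unbiased cumulant estimators) for one sample vector.
kstat_ <- function(x, order) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  switch(as.character(order),
         "2" = n / (n - 1) * m2,
         "3" = n^2 / ((n - 1) * (n - 2)) * m3,
         "4" = n^2 * ((n + 1) * m4 - 3 * (n - 1) * m2^2) /
           ((n - 1) * (n - 2) * (n - 3)))
}

#' Empirical cumulants of an ensemble
#'
#' k-statistics (unbiased cumulant estimators) applied column-wise to a
#' matrix whose columns are independent replicates (e.g. per-path increment
#' series, or per-time cross-path samples), with a standard error from the
#' spread across columns.
#'
#' @param x Numeric matrix; each column one replicate sample.
#' @param order Cumulant order: 2, 3 or 4.
#' @param min_cols Minimum number of replicates required.
#' @return A list with `estimate` (mean of per-column k-statistics), `se`,
#'   `order`, `n_rep`.
#' @export
empirical_cumulant <- function(x, order = 2, min_cols = 2L) {
  stopifnot(is.matrix(x), order %in% c(2, 3, 4))
  if (ncol(x) < min_cols) abort("Too few replicates for a cumulant estimate.")
  if (nrow(x) <= order) abort("Too few observations per replicate.")
  ks <- apply(x, 2, kstat_, order = order)
  list(estimate = mean(ks), se = sd(ks) / sqrt(length(ks)),
       order = order, n_rep = ncol(x))
}

#' Per-step increments of the compensated compound-Poisson process
#'
#' Raw (unfiltered) compensated increments dX over each grid step: the sum
#' of marks arriving in the step minus lambda_p E\[a\] dt. Their cumulants
#' satisfy kappa_n\[dX\] = lambda_p E\[a^n\] dt for n >= 2 and E\[dX\] = 0.
#'
#' @param events An [sample_events()] stream.
#' @param spec The generating [poisson_bath_spec()].
#' @param t_grid Uniform time grid.
#' @return Numeric vector of increments, length `length(t_grid) - 1`.
#' @export
compensated_increments <- function(events, spec, t_grid) {
  stopifnot(inherits(events, "event_stream"),
            inherits(spec, "poisson_bath_spec"))
  dt <- diff(t_grid)
  bins <- findInterval(events$times, t_grid, left.open = TRUE)
  inc <- numeric(length(dt))
  keep <- bins >= 1 & bins <= length(dt)
  if (any(keep)) {
    agg <- tapply(events$marks[keep], bins[keep], sum)
    inc[as.integer(names(agg))] <- agg
  }
  inc - spec$rate * mark_moment(spec$mark, 1) * dt
}

#' Unitary kick operator
#'
#' Instantaneous environmental event acting on the coupled
#' electronic-vibrational manifold: U(a) = exp(-i a * kick_scale * K) with
#' generator K = sigma_z (x) (b + b') by default. Built from the exact
#' eigendecomposition of the mode quadrature, so it is unitary on the
#' truncated space by construction; a defect check guards against numerical
#' degradation.
#'
#' @param mark Kick amplitude a.
#' @param model A [model_spec()] with a vibronic mode.
#' @param kick_scale Global multiplier mapping mark amplitude to kick angle.
#' @param generator Optional custom Hermitian generator matrix on the full
#'   space (overrides the default).
#' @return A unitary matrix of the model dimension.
#' @export
kick_unitary <- function(mark, model, kick_scale = 1, generator = NULL) {
  stopifnot(inherits(model, "model_spec"))
  if (is.null(model$vibronic) && is.null(generator))
    abort("Kick events act on the vibrational manifold; the model has no mode.")
  if (is.null(generator)) {
    b <- fock_annihilation(model$vibronic$fock_cutoff)
    x <- b + t(b)
    es <- eigen(x, symmetric = TRUE)
    ph_plus <- es$vectors %*% (exp(-1i * mark * kick_scale * es$values) * t(es$vectors))
    ph_minus <- Conj(ph_plus)
    u <- kronecker(diag(c(1, 0)), ph_plus) + kronecker(diag(c(0, 1)), ph_minus)
  } else {
    es <- eigen(generator, symmetric = TRUE)
    u <- es$vectors %*% (exp(-1i * mark * kick_scale * es$values) * Conj(t(es$vectors)))
  }
  defect <- max(abs(Conj(t(u)) %*% u - diag(nrow(u))))
  if (defect > 1e-8)
    warn(sprintf("Kick unitary defect %.3g exceeds 1e-8 (truncation too tight?).", defect))
  u
}

# Derive per-trajectory seeds from a master seed (counter scheme; kept below
# 2^31 so they remain valid R integer seeds).
derive_seeds <- function(master_seed, n) {
  (as.numeric(master_seed) * 48271 + 104729 * seq_len(n)) %% 2147483647
}
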