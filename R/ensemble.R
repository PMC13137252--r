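# Ensemble simulation and observables: reduced density matrix from
# trajectory averages, donor/acceptor populations, electronic coherence,
# vibrational occupation, maximum transfer probability, and Delta-P scans.

new_ensemble_result <- function(t_grid, rho, n_traj, master_seed, model,
                                bath_kind, pa_se) {
  d <- dim(rho)[1]
  half <- d / 2
  n <- length(t_grid)
  p_d <- numeric(n); p_a <- numeric(n); coh <- numeric(n); nv <- rep(NA_real_, n)
  has_mode <- !is.null(model$vibronic)
  nop <- if (has_mode) lift_number(model) else NULL
  for (i in seq_len(n)) {
    r <- rho[, , i]
    p_d[i] <- Re(sum(diag(r)[seq_len(half)]))
    p_a[i] <- Re(sum(diag(r)[(half + 1):d]))
    # electronic coherence: trace over the mode of the donor-acceptor block
    coh[i] <- Mod(sum(diag(r[seq_len(half), (half + 1):d, drop = FALSE])))
    if (has_mode) nv[i] <- Re(sum(nop * t(r)))
  }
  data <- tibble(t = t_grid, p_donor = p_d, p_acceptor = p_a,
                 coherence_abs = coh, n_vib = nv, se_p_a = pa_se)
  structure(list(data = data, t_grid = t_grid, rho = rho, n_traj = n_traj,
                 master_seed = master_seed, model = model,
                 bath_kind = bath_kind),
            class = "nmsse_ensemble")
}

#' @export
print.nmsse_ensemble <- function(x, ...) {
  cat(sprintf("<nmsse_ensemble> %d trajectories, %s bath, %d time points on [0, %g] eV^-1\n",
              x$n_traj, x$bath_kind, length(x$t_grid), max(x$t_grid)))
  cat(sprintf("  max P(D->A) = %.4f\n", transfer_probability_max(x)))
  invisible(x)
}

#' Ensemble-average trajectories into a reduced density matrix
#'
#' rho(t) = mean over trajectories of |psi(t)><psi(t)|; donor/acceptor
#' populations are the electronic-block partial traces, the coherence is
#' the magnitude of the mode-traced off-diagonal block, and a Monte-Carlo
#' standard error is attached to the acceptor population.
#'
#' @param trajs List of [propagate_trajectory()] results on a common grid.
#' @param model The [model_spec()] the trajectories were generated from.
#' @param master_seed Seed recorded as provenance.
#' @param bath_kind Label recorded as provenance.
#' @return An object of class `nmsse_ensemble`; see [tidy.nmsse_ensemble()].
#' @export
ensemble_density <- function(trajs, model, master_seed = NA_integer_,
                             bath_kind = "unspecified") {
  stopifnot(length(trajs) >= 1L,
            all(vapply(trajs, inherits, logical(1), "trajectory_result")))
  grid <- trajs[[1]]$t_grid
  for (tr in trajs) if (!isTRUE(all.equal(tr$t_grid, grid)))
    abort("Trajectories do not share a common time grid.")
  n <- length(grid)
  d <- nrow(trajs[[1]]$psi)
  half <- d / 2
  rho <- array(0i, dim = c(d, d, n))
  pa <- matrix(0, n, length(trajs))
  for (k in seq_along(trajs)) {
    psi <- trajs[[k]]$psi
    for (i in seq_len(n)) {
      rho[, , i] <- rho[, , i] + psi[, i] %*% Conj(t(psi[, i, drop = FALSE]))
      pa[i, k] <- sum(Mod(psi[(half + 1):d, i])^2)
    }
  }
  rho <- rho / length(trajs)
  se <- if (length(trajs) > 1) apply(pa, 1, sd) / sqrt(length(trajs)) else rep(NA_real_, n)
  new_ensemble_result(grid, rho, length(trajs), master_seed, model, bath_kind, se)
}

default_window <- function(model, n_periods = 10) {
  n_periods * 2 * pi / effective_frequency(model$dimer)
}

#' Simulate an NMSSE trajectory ensemble
#'
#' End-to-end driver: builds the bath kernel on the simulation grid, derives
#' the memory coefficients, draws the per-trajectory driving processes
#' (colored complex Gaussian noise, or compensated filtered shot noise plus
#' unitary kicks sharing one event stream), propagates all trajectories in
#' compiled code, and ensemble-averages the results.
#'
#' @param model A [model_spec()].
#' @param bath A [spectral_density_spec()] (harmonic/Gaussian bath) or a
#'   [poisson_bath_spec()] (anharmonic shot-noise bath).
#' @param n_traj Number of trajectories.
#' @param t_max Simulation window (eV^-1); default ten Rabi periods of the
#'   dimer.
#' @param dt Step (eV^-1); default `0.045 / Omega`.
#' @param master_seed Master seed; per-trajectory seeds are derived by a
#'   counter scheme and recorded.
#' @param thermal [thermal_spec()] for the Gaussian kernel (default
#'   room temperature, k_B T = 0.025 eV).
#' @param config [integrator_config()]; default Heun at the chosen `dt`.
#' @param kernel_form Finite-temperature kernel form, see
#'   [gaussian_kernel()].
#' @param init_state Initial state; default donor x vacuum.
#' @param gaussianize For a shot-noise bath: replace the compound-Poisson
#'   process by a colored *Gaussian* process with the identical effective
#'   kernel alpha_P (and no kick events). This is the central-limit twin of
#'   the shot-noise bath — all second-order statistics agree, all higher
#'   cumulants vanish — and is the reference against which intermittency
#'   effects are isolated.
#' @return An `nmsse_ensemble` object.
#' @export
simulate_ensemble <- function(model, bath, n_traj = 2000L, t_max = NULL,
                              dt = NULL, master_seed = 1L,
                              thermal = thermal_spec(0.025), config = NULL,
                              kernel_form = "printed", init_state = NULL,
                              gaussianize = FALSE) {
  stopifnot(inherits(model, "model_spec"))
  om <- effective_frequency(model$dimer)
  if (om <= 0) abort("The dimer has Omega = 0; nothing oscillates.")
  if (is.null(t_max)) t_max <- default_window(model)
  if (is.null(dt)) dt <- 0.045 / om
  n <- floor(t_max / dt) + 1L
  grid <- seq(0, by = dt, length.out = n)
  if (is.null(config)) config <- integrator_config(dt = dt)
  if (!isTRUE(all.equal(config$dt, dt)))
    abort("`config$dt` disagrees with `dt`.")

  bath_kind <- if (inherits(bath, "spectral_density_spec")) "gaussian"
  else if (inherits(bath, "poisson_bath_spec")) "poisson"
  else abort("`bath` must be a spectral_density_spec or poisson_bath_spec.")

  if (bath_kind == "gaussian") {
    kernel <- gaussian_kernel(grid, bath, thermal, form = kernel_form)
  } else {
    kernel <- poisson_kernel(grid, bath)
    if (isTRUE(gaussianize)) bath_kind <- "poisson-gaussianized"
  }
  coeffs <- memory_coefficients(kernel, order = 1)

  kick_times <- list(); kick_marks <- list()
  if (bath_kind == "gaussian") {
    paths <- sample_gaussian_paths(kernel, grid, n_traj, seed = master_seed)
  } else if (bath_kind == "poisson-gaussianized") {
    paths <- sample_real_gaussian_paths(kernel, grid, n_traj,
                                        seed = master_seed) + 0i
  } else {
    seeds <- derive_seeds(master_seed, n_traj)
    paths <- matrix(0i, n, n_traj)
    use_kicks <- config$apply_kicks && !is.null(model$vibronic)
    warm <- 8 / bath$filter_kappa   # stationary driving at t = 0
    for (k in seq_len(n_traj)) {
      ev <- sample_events(bath, t_max = max(grid), seed = seeds[k],
                          t_min = -warm)
      paths[, k] <- filter_and_compensate(ev, bath, grid, step_average = TRUE)$z
      if (use_kicks) {
        live <- ev$times >= 0   # kicks act only inside the observation window
        kick_times[[k]] <- ev$times[live]
        kick_marks[[k]] <- ev$marks[live]
      }
    }
    if (!use_kicks) { kick_times <- list(); kick_marks <- list() }
  }

  if (is.null(init_state)) init_state <- default_init_state(model)
  om_check <- dt * om
  if (om_check > config$max_dt_omega)
    abort(sprintf("dt * Omega = %.3g exceeds the configured bound %.3g.",
                  om_check, config$max_dt_omega))

  h <- build_system_hamiltonian(model) + 0i
  sz <- lift_electronic(pauli_z(), model) + 0i
  sy <- lift_electronic(pauli_y(), model)
  g1v <- if (is.null(coeffs$g1)) complex(real = numeric(n)) else coeffs$g1
  if (length(kick_times) > 0) {
    kb <- kick_basis(model)
  } else {
    kb <- list(V = matrix(0i, 0, 0), E = numeric(0))
  }
  nop <- if (!is.null(model$vibronic)) lift_number(model) + 0i else matrix(0i, 0, 0)

  res <- cpp_ensemble(h, sz, sy, model$gamma_nj, model$dimer$delta,
                      kernel$alpha, coeffs$g0, g1v, paths,
                      as.complex(init_state), dt, config$bracket_factor,
                      config$scheme == "rk4", kick_times, kick_marks,
                      kb$V, kb$E, config$kick_scale, nop)

  rho <- res$rho_sum / n_traj
  pa_mean <- drop(res$pa_sum) / n_traj
  pa_var <- pmax(0, (drop(res$pa_sq) - n_traj * pa_mean^2) / max(1, n_traj - 1))
  se <- sqrt(pa_var / n_traj)
  out <- new_ensemble_result(grid, rho, n_traj, master_seed, model, bath_kind, se)
  if (!is.null(model$vibronic)) out$data$n_vib <- drop(res$nvib_sum) / n_traj
  out$kernel <- kernel
  out$config <- config
  out
}

#' Maximum transfer probability of an ensemble
#'
#' max over the simulated window of the acceptor population.
#'
#' @param result An `nmsse_ensemble`.
#' @return Probability.
#' @export
transfer_probability_max <- function(result) {
  stopifnot(inherits(result, "nmsse_ensemble"))
  max(result$data$p_acceptor)
}

#' Vibronic enhancement of the transfer probability
#'
#' Delta-P = max_t P(D->A) with vibronic coupling minus the same maximum
#' without it, on matched grids and windows. "Without" keeps the mode in
#' the Hilbert space with its coupling set to zero, so the two ensembles
#' are directly comparable.
#'
#' @param with_vib,without_vib `nmsse_ensemble` objects on the same grid.
#' @return Delta-P in \[-1, 1\].
#' @export
delta_p <- function(with_vib, without_vib) {
  stopifnot(inherits(with_vib, "nmsse_ensemble"),
            inherits(without_vib, "nmsse_ensemble"))
  if (!isTRUE(all.equal(with_vib$t_grid, without_vib$t_grid)))
    abort("Delta-P requires matched time grids and windows.")
  transfer_probability_max(with_vib) - transfer_probability_max(without_vib)
}

#' Vibrational occupation time series
#'
#' <n(t)> = Tr\[rho(t) (I (x) b'b)\] of the discrete mode.
#'
#' @param result An `nmsse_ensemble` whose model includes the mode.
#' @return A tibble with `t`, `n_vib`.
#' @export
vibrational_energy_series <- function(result) {
  stopifnot(inherits(result, "nmsse_ensemble"))
  if (is.null(result$model$vibronic))
    abort("The model has no vibrational mode.")
  result$data[, c("t", "n_vib")]
}

regime_label <- function(lam) {
  dplyr::case_when(is.na(lam) ~ NA_character_,
                   lam >= 5 ~ "weak",
                   lam > 0.5 ~ "intermediate",
                   TRUE ~ "strong")
}

#' Two-dimensional transfer-enhancement scan
#'
#' Runs matched with/without-vibronic ensembles over a grid of electronic
#' couplings `delta` crossed with either vibronic couplings `coupling` or
#' event-per-memory values `lam` (shot-noise bath; the event rate is
#' lambda_p = lam / tau_c at fixed, variance-matched kernel), for each
#' requested bath kind, and records Delta-P with Monte-Carlo errors and the
#' anharmonicity regime label.
#'
#' @param model Base [model_spec()] (must include a vibronic mode).
#' @param gaussian_bath A [spectral_density_spec()].
#' @param delta Electronic couplings (eV) to scan.
#' @param coupling Vibronic couplings to scan (`NULL` keeps the base value).
#' @param lam Event-per-memory values for the Poisson bath (`NULL` keeps a
#'   single default of 1).
#' @param bath Bath kinds to include.
#' @param poisson_kappa Shot-noise inverse memory kappa (eV); default the
#'   Gaussian linewidth so both baths share tau_c.
#' @param n_traj Trajectories per ensemble.
#' @param t_max,dt Window and step (defaults as in [simulate_ensemble()],
#'   shared across the scan using the smallest `delta`).
#' @param master_seed Master seed; each cell derives its own stream.
#' @param thermal,kernel_form Passed to [simulate_ensemble()].
#' @return An object of class `nmsse_scan` whose `data` is a long tibble
#'   (delta, coupling, lam, bath, delta_p, se, max_p_with, max_p_without,
#'   regime); failed cells carry `NA` and an error message.
#' @export
scan_map <- function(model, gaussian_bath, delta, coupling = NULL, lam = NULL,
                     bath = c("gaussian", "poisson"), poisson_kappa = NULL,
                     n_traj = 2000L, t_max = NULL, dt = NULL, master_seed = 1L,
                     thermal = thermal_spec(0.025), kernel_form = "printed") {
  stopifnot(inherits(model, "model_spec"), !is.null(model$vibronic),
            inherits(gaussian_bath, "spectral_density_spec"))
  bath <- match.arg(bath, several.ok = TRUE)
  if (is.null(coupling)) coupling <- model$vibronic$coupling
  if (is.null(poisson_kappa)) poisson_kappa <- gaussian_bath$linewidth
  tau_c <- 1 / poisson_kappa

  cells <- tidyr::expand_grid(delta = delta, coupling = coupling, bath = bath)
  cells <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(cells, bath == "gaussian"), lam = NA_real_),
    tidyr::expand_grid(dplyr::filter(cells, bath == "poisson"),
                       lam = if (is.null(lam)) 1 else lam))
  if (is.null(t_max)) {
    slow <- dimer_spec(model$dimer$epsilon, min(delta))
    t_max <- 10 * 2 * pi / effective_frequency(slow)
  }

  run_cell <- function(row, idx) {
    dm <- dimer_spec(model$dimer$epsilon, row$delta)
    vib_on <- vibronic_spec(model$vibronic$omega, row$coupling,
                            model$vibronic$fock_cutoff)
    vib_off <- vibronic_spec(model$vibronic$omega, 0,
                             model$vibronic$fock_cutoff)
    m_with <- model_spec(dm, vib_on, model$gamma_nj)
    m_without <- model_spec(dm, vib_off, model$gamma_nj)
    seed_w <- derive_seeds(master_seed, 2 * idx - 1)[2 * idx - 1]
    seed_o <- derive_seeds(master_seed, 2 * idx)[2 * idx]
    make_bath <- function(mdl) {
      if (row$bath == "gaussian") return(gaussian_bath)
      grid0 <- seq(0, t_max, by = if (is.null(dt))
        0.045 / effective_frequency(dm) else dt)
      target <- gaussian_kernel(grid0, gaussian_bath, thermal,
                                form = kernel_form)
      template <- poisson_bath_spec(rate = row$lam / tau_c,
                                    filter_kappa = poisson_kappa,
                                    filter_omega = mdl$vibronic$omega)
      variance_match(target, template)
    }
    e_with <- simulate_ensemble(m_with, make_bath(m_with), n_traj = n_traj,
                                t_max = t_max, dt = dt, master_seed = seed_w,
                                thermal = thermal, kernel_form = kernel_form)
    e_without <- simulate_ensemble(m_without, make_bath(m_without),
                                   n_traj = n_traj, t_max = t_max, dt = dt,
                                   master_seed = seed_o, thermal = thermal,
                                   kernel_form = kernel_form)
    iw <- which.max(e_with$data$p_acceptor)
    io <- which.max(e_without$data$p_acceptor)
    tibble(delta_p = delta_p(e_with, e_without),
           se = sqrt(e_with$data$se_p_a[iw]^2 + e_without$data$se_p_a[io]^2),
           max_p_with = e_with$data$p_acceptor[iw],
           max_p_without = e_without$data$p_acceptor[io],
           error = NA_character_)
  }

  out <- purrr::imap(split(cells, seq_len(nrow(cells))), function(row, idx) {
    idx <- as.integer(idx)
    tryCatch(run_cell(row, idx),
             error = function(e) tibble(delta_p = NA_real_, se = NA_real_,
                                        max_p_with = NA_real_,
                                        max_p_without = NA_real_,
                                        error = conditionMessage(e)))
  })
  data <- dplyr::bind_cols(cells, dplyr::bind_rows(out))
  data$regime <- regime_label(data$lam)
  structure(list(data = data, model = model, master_seed = master_seed,
                 n_traj = n_traj, t_max = t_max),
            class = "nmsse_scan")
}

#' @export
print.nmsse_scan <- function(x, ...) {
  cat(sprintf("<nmsse_scan> %d cells, %d trajectories per ensemble\n",
              nrow(x$data), x$n_traj))
  print(x$data)
  invisible(x)
}

#' Write ensemble time series to CSV
#'
#' Columns t, P_D, P_A, Re/Im of the electronic coherence, n_vib, se_P_A.
#'
#' @param result An `nmsse_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(result, path) {
  stopifnot(inherits(result, "nmsse_ensemble"))
  d <- dim(result$rho)[1]; half <- d / 2
  coh <- vapply(seq_along(result$t_grid), function(i)
    sum(diag(matrix(result$rho[seq_len(half), (half + 1):d, i], half, half))),
    complex(1))
  df <- data.frame(t = result$t_grid,
                   P_D = result$data$p_donor, P_A = result$data$p_acceptor,
                   re_rho_DA = Re(coh), im_rho_DA = Im(coh),
                   n_vib = result$data$n_vib, se_P_A = result$data$se_p_a)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
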