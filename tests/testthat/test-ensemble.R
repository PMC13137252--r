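test_that("ensemble density: projector purity, unit trace, population identity", {
  dm <- dimer_spec(0.1487, 0.1)
  om <- effective_frequency(dm)
  m <- model_spec(dm, NULL, gamma_nj = 0.2)
  dt <- 0.045 / om
  grid <- seq(0, 50, by = dt)
  kern <- exp_kernel(grid, 0.02, 0.01)
  co <- memory_coefficients(kern, order = 1)
  cfg <- integrator_config(dt = dt)
  trs <- lapply(1:4, function(k) {
    propagate_trajectory(m, co, sample_gaussian_path(kern, grid, seed = k), cfg)
  })

  one <- ensemble_density(trs[1], m)
  pur <- vapply(seq_along(grid), function(i)
    Re(sum(diag(one$rho[, , i] %*% one$rho[, , i]))), numeric(1))
  expect_equal(pur, rep(1, length(grid)), tolerance = 1e-10)

  res <- ensemble_density(trs, m, master_seed = 1, bath_kind = "custom")
  tr1 <- vapply(seq_along(grid), function(i)
    Re(sum(diag(res$rho[, , i]))), numeric(1))
  expect_equal(tr1, rep(1, length(grid)), tolerance = 1e-10)
  expect_equal(res$data$p_donor + res$data$p_acceptor, rep(1, length(grid)),
               tolerance = 1e-10)
  expect_true(all(vapply(seq_along(grid), function(i) {
    r <- res$rho[, , i]
    max(abs(r - t(Conj(r))))
  }, numeric(1)) < 1e-12))

  short <- trs[[1]]; short$t_grid <- grid[-1]
  expect_error(ensemble_density(list(trs[[1]], short), m), "common")
})

test_that("noise-free ensembles reproduce the closed dimer exactly", {
  dm <- dimer_spec(0.1487, 0.1)
  om <- effective_frequency(dm)
  m0 <- model_spec(dm, NULL, gamma_nj = 0)
  pb <- poisson_bath_spec(rate = 0.01, filter_kappa = 0.005, amplitude = 0.01)
  e <- simulate_ensemble(m0, pb, n_traj = 3, t_max = 2 * 2 * pi / om,
                         dt = 0.01 / om, master_seed = 5,
                         config = integrator_config(dt = 0.01 / om,
                                                    scheme = "rk4"))
  expect_lt(max(abs(e$data$p_acceptor - closed_population(e$t_grid, dm))), 1e-6)
  expect_equal(transfer_probability_max(e), rabi_max_probability(dm),
               tolerance = 1e-5)
})

test_that("maximum transfer probability is monotone under window extension", {
  dm <- dimer_spec(0, 0.05)
  m0 <- model_spec(dm, NULL, gamma_nj = 0)
  pb <- poisson_bath_spec(rate = 0, filter_kappa = 0.005, amplitude = 0)
  run_T <- function(tt) transfer_probability_max(
    simulate_ensemble(m0, pb, n_traj = 1, t_max = tt, master_seed = 1))
  p_half <- run_T(0.5 * pi / 0.05)
  p_full <- run_T(1.2 * pi / 0.05)
  expect_gt(p_full, p_half)
  expect_equal(p_full, 1, tolerance = 1e-4)
})

test_that("Delta-P is antisymmetric, null on identical inputs, grid-checked", {
  dm <- dimer_spec(0.1487, 0.05)
  om <- effective_frequency(dm)
  pb <- poisson_bath_spec(rate = 0.005, filter_kappa = 0.005, amplitude = 0.005)
  mk <- function(cpl) model_spec(dm, vibronic_spec(0.1487, cpl, 4), 0.02)
  t_max <- 2 * 2 * pi / om
  e_with <- simulate_ensemble(mk(0.25), pb, n_traj = 30, t_max = t_max,
                              master_seed = 2)
  e_without <- simulate_ensemble(mk(0), pb, n_traj = 30, t_max = t_max,
                                 master_seed = 3)
  expect_equal(delta_p(e_with, e_with), 0)
  expect_equal(delta_p(e_with, e_without), -delta_p(e_without, e_with))
  expect_true(abs(delta_p(e_with, e_without)) <= 1)

  e_short <- simulate_ensemble(mk(0), pb, n_traj = 5, t_max = t_max / 2,
                               master_seed = 3)
  expect_error(delta_p(e_with, e_short), "grid")

  # a gamma = 0 "with" run equals the mode-free dimer: the mode decouples
  m_free <- model_spec(dm, NULL, gamma_nj = 0.02)
  e_free <- simulate_ensemble(m_free, pb, n_traj = 30, t_max = t_max,
                              master_seed = 2)
  expect_lt(abs(transfer_probability_max(e_without) -
                  transfer_probability_max(e_free)),
            3 * max(e_free$data$se_p_a, e_without$data$se_p_a, 1e-3))
})

test_that("vibrational occupation starts at zero and is conserved when decoupled", {
  dm <- dimer_spec(0.1487, 0.05)
  om <- effective_frequency(dm)
  m <- model_spec(dm, vibronic_spec(0.1487, 0, 4), gamma_nj = 0.1)
  pb <- poisson_bath_spec(rate = 0.01, filter_kappa = 0.005, amplitude = 0.01)
  e <- simulate_ensemble(m, pb, n_traj = 20, t_max = 2 * 2 * pi / om,
                         master_seed = 9,
                         config = integrator_config(dt = 0.045 / om,
                                                    apply_kicks = FALSE))
  nv <- vibrational_energy_series(e)
  expect_equal(nv$n_vib[1], 0, tolerance = 1e-12)
  expect_lt(max(abs(nv$n_vib)), 1e-10)

  m2 <- model_spec(dm, NULL, gamma_nj = 0.1)
  e2 <- simulate_ensemble(m2, pb, n_traj = 2, t_max = 50, master_seed = 1)
  expect_error(vibrational_energy_series(e2), "mode")
})

test_that("density positivity holds within sampling error under kicks", {
  dm <- dimer_spec(0.1487, 0.05)
  om <- effective_frequency(dm)
  m <- model_spec(dm, vibronic_spec(0.1487, 0.2, 4), gamma_nj = 0.02)
  pb <- poisson_bath_spec(rate = 0.02, mark = mark_dist("twopoint", a0 = 0.3),
                          filter_kappa = 0.005)
  e <- simulate_ensemble(m, pb, n_traj = 40, t_max = 2 * 2 * pi / om,
                         master_seed = 11)
  min_eig <- min(vapply(seq_along(e$t_grid), function(i)
    min(eigen(e$rho[, , i], symmetric = TRUE, only.values = TRUE)$values),
    numeric(1)))
  expect_gt(min_eig, -3 * max(e$data$se_p_a))
  expect_true(all(e$data$n_vib >= -1e-10))
})

test_that("scan map runs matched cells and degenerates to delta_p on 1x1", {
  m <- model_spec(table1_dimer(0.05), vibronic_spec(0.1487, 0.2, 3), 0.02)
  gb <- table1_bath()
  sc <- scan_map(m, gb, delta = 0.05, lam = 1, bath = c("gaussian", "poisson"),
                 n_traj = 25, t_max = 60, master_seed = 4)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_true(all(c("delta", "coupling", "lam", "bath", "delta_p", "se",
                    "regime") %in% names(td)))
  expect_true(all(is.na(td$error)))
  expect_true(all(abs(td$delta_p) <= 1))
  expect_equal(td$regime[td$bath == "poisson"], "intermediate")
  g <- glance(sc)
  expect_equal(g$n_cells, 2)
  expect_equal(g$n_failed, 0)
})

test_that("tidiers and plots expose the ensemble surface", {
  dm <- dimer_spec(0, 0.05)
  m0 <- model_spec(dm, NULL, gamma_nj = 0)
  pb <- poisson_bath_spec(rate = 0, filter_kappa = 0.005, amplitude = 0)
  e <- simulate_ensemble(m0, pb, n_traj = 2, t_max = 100, master_seed = 1)
  td <- tidy(e)
  expect_true(all(c("t", "p_donor", "p_acceptor", "coherence_abs",
                    "se_p_a") %in% names(td)))
  g <- glance(e)
  expect_equal(g$n_traj, 2)
  expect_s3_class(autoplot(e), "ggplot")
  f <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(e, f)
  expect_true(file.exists(f))
  expect_equal(nrow(utils::read.csv(f)), length(e$t_grid))
})

test_that("ensembles are bitwise reproducible from the master seed", {
  dm <- dimer_spec(0.1487, 0.05)
  m <- model_spec(dm, vibronic_spec(0.1487, 0.1, 3), 0.02)
  pb <- poisson_bath_spec(rate = 0.02, mark = mark_dist("twopoint", a0 = 0.2),
                          filter_kappa = 0.005)
  e1 <- simulate_ensemble(m, pb, n_traj = 10, t_max = 50, master_seed = 123)
  e2 <- simulate_ensemble(m, pb, n_traj = 10, t_max = 50, master_seed = 123)
  expect_identical(e1$data, e2$data)
  expect_identical(e1$rho, e2$rho)
})
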