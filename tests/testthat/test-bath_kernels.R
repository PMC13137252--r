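test_that("spectral density: zero at origin, band peaks, superposition", {
  spec1 <- spectral_density_spec(0.1, gamma = 0.01, linewidth = 0.005)
  expect_equal(spectral_density(0, spec1), 0)
  # at a band centre J = gamma * w_i / Gamma
  expect_equal(spectral_density(0.1, spec1), 0.2)
  spec4 <- table1_bath()
  w <- seq(0, 1, by = 0.01)
  expect_true(all(spectral_density(w, spec4) >= 0))
  parts <- sapply(spec4$mode_freqs, function(wi)
    spectral_density(w, spectral_density_spec(wi, 0.01, 0.005)))
  expect_equal(spectral_density(w, spec4), rowSums(parts))
})

test_that("thermal occupation: value at study conditions and limits", {
  th <- thermal_spec(0.025)
  expect_equal(signif(thermal_occupation(0.1487, th), 2), 2.6e-3)
  expect_equal(thermal_occupation(0.025 * log(2), th), 1, tolerance = 1e-12)
  expect_equal(thermal_occupation(0.1, thermal_spec(0)), 0)
})

test_that("Gaussian kernel quadrature agrees with an independent scheme", {
  skip_if_not_installed("pracma")
  grid <- seq(0, 40, by = 0.5)
  spec <- table1_bath()
  th <- thermal_spec(0.025)
  k <- gaussian_kernel(grid, spec, th, tol = 1e-8)
  expect_s3_class(k, "correlation_kernel")
  expect_true(Re(k$alpha[1]) > 0)
  expect_equal(Im(k$alpha[1]), 0)
  # alpha(0) against adaptive Gauss-Kronrod split at the band centres
  f <- function(w) spectral_density(w, spec) / tanh(w / (2 * th$kbt))
  lims <- sort(c(1e-12, spec$mode_freqs, 10 * max(spec$mode_freqs)))
  oracle <- sum(sapply(seq_len(length(lims) - 1), function(i)
    pracma::quadgk(f, lims[i], lims[i + 1], tol = 1e-12)))
  expect_equal(Re(k$alpha[1]), oracle, tolerance = 1e-6)

  # zero coupling gives the zero kernel
  k0 <- gaussian_kernel(grid, spectral_density_spec(0.1, 0, 0.005), th)
  expect_true(all(k0$alpha == 0))

  # T = 0 limit: kernel is the plain Fourier transform of J
  kT0 <- gaussian_kernel(grid, spec, thermal_spec(0), tol = 1e-8)
  g <- function(w) spectral_density(w, spec)
  or0 <- sum(sapply(seq_len(length(lims) - 1), function(i)
    pracma::quadgk(g, lims[i], lims[i + 1], tol = 1e-12)))
  expect_equal(Re(kT0$alpha[1]), or0, tolerance = 1e-6)
  # printed and standard forms coincide at T = 0
  kT0s <- gaussian_kernel(grid, spec, thermal_spec(0), form = "standard",
                          tol = 1e-8)
  expect_equal(kT0$alpha, kT0s$alpha, tolerance = 1e-10)
})

test_that("shot-noise kernel closed form and filter quadrature agree", {
  grid <- seq(0, 400, by = 2)
  spec <- poisson_bath_spec(rate = 0.01, mark = mark_dist("twopoint", a0 = 1),
                            filter_kappa = 0.005, filter_omega = 0.1,
                            amplitude = 0.01)
  k <- poisson_kernel(grid, spec)
  expect_equal(Re(k$alpha[1]), 0.01)
  expect_true(all(abs(k$alpha) <= 0.01 * exp(-0.005 * grid) + 1e-15))
  i100 <- which(grid == 100)
  expect_equal(Re(k$alpha[i100]), 0.01 * exp(-0.5) * cos(10), tolerance = 1e-12)

  kexp <- poisson_kernel(grid, poisson_bath_spec(rate = 0.01,
                                                 filter_kappa = 0.005,
                                                 amplitude = 0.02))
  expect_equal(Re(kexp$alpha[grid == 200]), 0.02 / exp(1), tolerance = 1e-12)

  # Eq.-level quadrature route: lambda E[a^2] * int phi(u+tau) phi(u) du
  jm <- second_jump_moment(spec)
  kf <- filtered_kernel_from_phi(list(kappa = 0.005), jm, grid)
  expect_equal(Re(kf$alpha), jm * exp(-0.005 * grid) / (2 * 0.005),
               tolerance = 1e-8)
  k0 <- filtered_kernel_from_phi(list(kappa = 0.005), 0, grid)
  expect_true(all(k0$alpha == 0))
})

test_that("second jump moment follows the mark distribution", {
  expect_equal(second_jump_moment(
    poisson_bath_spec(0, filter_kappa = 1)), 0)
  expect_equal(second_jump_moment(
    poisson_bath_spec(2, mark_dist("fixed", a0 = 3), filter_kappa = 1)), 18)
  expect_equal(second_jump_moment(
    poisson_bath_spec(2, mark_dist("gaussian", sd = 0.5), filter_kappa = 1)),
    2 * 0.25)
})

test_that("memory coefficients match exponential-kernel closed forms", {
  a0 <- 0.7; kappa <- 0.2
  grid <- seq(0, 10, by = 5e-4)
  co <- memory_coefficients(exp_kernel(grid, a0, kappa), order = 2)
  expect_equal(co$g0[1], 0 + 0i)
  expect_equal(co$g1[1], 0 + 0i)
  g0_exact <- a0 * (1 - exp(-kappa * grid)) / kappa
  g1_exact <- a0 * (1 - (1 + kappa * grid) * exp(-kappa * grid)) / kappa^2
  expect_equal(Re(co$g0), g0_exact, tolerance = 1e-8)
  expect_equal(Re(co$g1), g1_exact, tolerance = 1e-8)
  expect_true(all(Im(co$g0) == 0))
  # order-2 coefficient: spot-check the convolution form
  #   g2(t) = int_0^t alpha(t-s) (t-s) g0(s) ds
  i <- length(grid)
  s <- grid
  integrand <- a0 * exp(-kappa * (10 - s)) * (10 - s) * g0_exact
  ref <- sum((integrand[-1] + integrand[-i]) / 2 * diff(s))
  expect_equal(Re(co$g2[i]), ref, tolerance = 1e-6)
})

test_that("kernel memory ratio g1/g0 vanishes in the short-memory limit", {
  ratio <- function(kappa) {
    grid <- seq(0, 50, by = 0.01)
    co <- memory_coefficients(exp_kernel(grid, kappa / 2, kappa), order = 1)
    n <- length(grid)
    Mod(co$g1[n]) / Mod(co$g0[n])
  }
  r <- sapply(c(0.5, 5, 50), ratio)   # alpha(0)-weight g0(inf) fixed at 1/2
  expect_true(all(diff(r) < 0))
  expect_lt(r[3], 0.03)
})

test_that("variance matching preserves alpha(0) exactly and is idempotent", {
  grid <- seq(0, 100, by = 1)
  target <- exp_kernel(grid, 0.0123, 0.01)
  spec <- poisson_bath_spec(rate = 0.05, filter_kappa = 0.005)
  matched <- variance_match(target, spec)
  expect_equal(mark_moment(matched$mark, 2), 2 * 0.005 * 0.0123 / 0.05)
  expect_identical(Re(poisson_kernel(grid, matched)$alpha[1]), 0.0123)
  # doubling the rate halves E[a^2]
  m2 <- variance_match(target, poisson_bath_spec(rate = 0.1, filter_kappa = 0.005))
  expect_equal(mark_moment(m2$mark, 2), mark_moment(matched$mark, 2) / 2)
  again <- variance_match(target, matched)
  expect_equal(again$mark$a0, matched$mark$a0)
  expect_error(variance_match(target, poisson_bath_spec(rate = 0,
                                                        filter_kappa = 0.005)),
               "rate")
})

test_that("matched shot-noise kernel equals the filtered-phi kernel pointwise", {
  grid <- seq(0, 600, by = 2)
  target <- exp_kernel(grid, 0.02, 0.005)
  matched <- variance_match(target,
                            poisson_bath_spec(rate = 0.02, filter_kappa = 0.005))
  kp <- poisson_kernel(grid, matched)
  kf <- filtered_kernel_from_phi(list(kappa = 0.005),
                                 second_jump_moment(matched), grid)
  expect_equal(kp$alpha, kf$alpha, tolerance = 1e-8)
})

test_that("regime controls reproduce the dimensionless time-scale numbers", {
  m <- model_spec(table1_dimer(0.1), NULL, 0.02)
  rc <- regime_controls(m, gamma_bath = 0.005, rate = 0.05)
  expect_equal(rc$tau_c, 200)
  expect_equal(rc$eta_nm, rc$omega_sys * rc$tau_c)
  expect_equal(round(rc$eta_nm, 1), 35.8, tolerance = 1e-8)
  expect_equal(rc$lam, 10)
  expect_equal(regime_controls(m, 0.005, 5e-4)$lam, 0.1)
})

test_that("kernel containers enforce stationarity conventions", {
  expect_error(correlation_kernel(c(0, 1), c(-1, 0)), ">= 0")
  expect_error(correlation_kernel(c(0, 1), c(1i, 0)), "real")
  k <- exp_kernel(seq(0, 5, by = 0.5), 1, 0.3)
  tb <- tibble::as_tibble(k)
  expect_named(tb, c("tau", "re", "im"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_kernel_csv(k, f)
  back <- utils::read.csv(f)
  expect_equal(back$re, Re(k$alpha))
})
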