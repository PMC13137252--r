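test_that("colored Gaussian paths are seeded, zero-mean, kernel-faithful", {
  grid <- seq(0, 40, by = 0.5)
  kern <- exp_kernel(grid, 2, 0.1)

  z1 <- sample_gaussian_paths(kern, n_paths = 3, seed = 99)
  z2 <- sample_gaussian_paths(kern, n_paths = 3, seed = 99)
  expect_identical(z1, z2)

  fac <- gaussian_path_factor(kern)
  z <- sample_gaussian_paths(kern, n_paths = 5000, seed = 1, factor = fac)
  # empirical mean within 3 SE of zero at every grid point
  se <- sqrt(2 / 5000)   # |alpha(0)| = 2, complex components
  expect_true(all(Mod(rowMeans(z)) < 3 * se))
  # covariance at lags {0, tau_c/2, tau_c} within 5 relative %
  tauc_i <- which(grid == 10)   # tau_c = 1/kappa = 10
  half_i <- which(grid == 5)
  i0 <- 40
  cov_at <- function(lag_i) mean(z[i0 + lag_i - 1, ] * Conj(z[i0, ]))
  for (li in c(1, half_i, tauc_i)) {
    expect_equal(Re(cov_at(li)), Re(kern$alpha[li]), tolerance = 0.05)
  }
  # E[z z] (pseudo-covariance) vanishes for circular noise
  expect_lt(Mod(mean(z[i0, ]^2)), 3 * 2 / sqrt(5000))

  # zero kernel -> all-zero paths
  z0 <- sample_gaussian_paths(correlation_kernel(grid, rep(0, length(grid))),
                              n_paths = 2, seed = 5)
  expect_true(all(z0 == 0))
})

test_that("real Gaussian twin paths reproduce the kernel covariance", {
  grid <- seq(0, 40, by = 0.5)
  kern <- exp_kernel(grid, 1.5, 0.1)
  z <- sample_real_gaussian_paths(kern, n_paths = 5000, seed = 2)
  expect_true(is.numeric(z))
  expect_equal(mean(z[30, ]^2), 1.5, tolerance = 0.05)
  expect_equal(mean(z[40, ] * z[30, ]), Re(kern$alpha[11]), tolerance = 0.07)
})

test_that("event streams follow the Poisson law and are reproducible", {
  spec <- poisson_bath_spec(rate = 0.2, mark = mark_dist("twopoint", a0 = 1),
                            filter_kappa = 0.01)
  expect_length(sample_events(poisson_bath_spec(0, filter_kappa = 1), 10)$times, 0)

  e1 <- sample_events(spec, 100, seed = 7)
  e2 <- sample_events(spec, 100, seed = 7)
  expect_identical(e1, e2)
  expect_true(all(diff(e1$times) > 0))
  expect_true(all(e1$times <= 100))

  counts <- vapply(1:2000, function(k)
    length(sample_events(spec, 50, seed = k)$times), numeric(1))
  mu <- 0.2 * 50
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 2000))
  expect_lt(abs(var(counts) - mu), 4 * mu * sqrt(2 / 2000))
})

test_that("filtered compensated shot noise: single-event response and variance", {
  grid <- seq(0, 1000, by = 1)
  spec <- poisson_bath_spec(rate = 0.02, mark = mark_dist("twopoint", a0 = 1.5),
                            filter_kappa = 0.01)
  # no events, zero-mean marks -> identically zero
  p0 <- filter_and_compensate(
    structure(list(times = numeric(0), marks = numeric(0), rate = 0.02,
                   t_max = 1000), class = "event_stream"), spec, grid)
  expect_true(all(p0$z == 0))

  # one event: exponential tail from the arrival time
  ev <- structure(list(times = 100, marks = 2, rate = 0, t_max = 1000),
                  class = "event_stream")
  p1 <- filter_and_compensate(ev, spec, grid)
  expect_equal(p1$z[grid >= 100], 2 * exp(-0.01 * (grid[grid >= 100] - 100)))
  expect_true(all(p1$z[grid < 100] == 0))

  # stationary variance lambda E[a^2] / (2 kappa) within 5% (n = 5000)
  zs <- vapply(1:5000, function(k) {
    e <- sample_events(spec, 1000, seed = k)
    filter_and_compensate(e, spec, grid)$z[c(701, 851, 1001)]
  }, numeric(3))
  target <- second_jump_moment(spec) / (2 * 0.01)
  expect_equal(mean(apply(zs, 1, var)), target, tolerance = 0.05)

  # compensation makes the nonzero-mean case zero-mean after the transient
  spec_e <- poisson_bath_spec(rate = 0.05, mark = mark_dist("exponential", mean = 1),
                              filter_kappa = 0.01)
  zm <- vapply(1:3000, function(k) {
    e <- sample_events(spec_e, 1000, seed = k)
    filter_and_compensate(e, spec_e, grid)$z[1001]
  }, numeric(1))
  expect_lt(abs(mean(zm)), 3 * sd(zm) / sqrt(3000))
})

test_that("increment cumulants satisfy the compound-Poisson identity", {
  grid <- seq(0, 100, by = 0.5)
  dt <- 0.5
  spec <- poisson_bath_spec(rate = 0.5, mark = mark_dist("fixed", a0 = 1.2),
                            filter_kappa = 0.01)
  incs <- vapply(1:2000, function(k)
    compensated_increments(sample_events(spec, 100, seed = k), spec, grid),
    numeric(length(grid) - 1))
  # E[dX] = 0 by compensation
  expect_lt(abs(mean(incs)), 3 * sd(colMeans(incs)) / sqrt(2000))
  for (ord in 2:4) {
    k_est <- empirical_cumulant(incs, ord)
    target <- 0.5 * 1.2^ord * dt
    expect_lt(abs(k_est$estimate - target), 3 * k_est$se)
  }
  expect_error(empirical_cumulant(incs[, 1, drop = FALSE], 2, min_cols = 2),
               "replicates")
})

test_that("Gaussian paths have vanishing excess kurtosis", {
  grid <- seq(0, 20, by = 0.5)
  kern <- exp_kernel(grid, 1, 0.2)
  z <- sample_gaussian_paths(kern, n_paths = 4000, seed = 3)
  # marginal real parts across independent paths at well-separated times
  x <- t(Re(z[c(11, 21, 31, 41), ]))
  k4 <- empirical_cumulant(x, 4)
  k2 <- empirical_cumulant(x, 2)
  expect_lt(abs(k4$estimate), 3 * max(k4$se, 1e-3))
  expect_equal(k2$estimate, 0.5, tolerance = 0.1)   # Re part carries half
})

test_that("excess kurtosis of the filtered process scales like 1/Lambda", {
  kappa <- 0.02; tau_c <- 1 / kappa
  grid <- seq(0, 12 * tau_c, by = 2)
  sel <- which(grid >= 6 * tau_c)[1:4 * 10]    # spaced stationary samples
  lams <- c(0.1, 1, 10)
  kurt <- sapply(seq_along(lams), function(j) {
    lam <- lams[j]
    rate <- lam * kappa
    a0 <- sqrt(2 * kappa * 1 / rate)   # variance matched to 1
    spec <- poisson_bath_spec(rate = rate, mark = mark_dist("twopoint", a0 = a0),
                              filter_kappa = kappa)
    z <- vapply(1:4000, function(k) {
      e <- sample_events(spec, max(grid), seed = 10000 * j + k)
      filter_and_compensate(e, spec, grid)$z[sel]
    }, numeric(length(sel)))
    k4 <- empirical_cumulant(t(z), 4)
    k2 <- empirical_cumulant(t(z), 2)
    k4$estimate / k2$estimate^2
  })
  fit <- stats::lm(log(kurt) ~ log(lams))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.25)
})

test_that("kick unitaries displace the vacuum by the squared mark", {
  m <- model_spec(dimer_spec(0.1, 0.05), vibronic_spec(0.15, 0.2, 40), 0.02)
  u0 <- kick_unitary(0, m)
  expect_equal(u0, diag(nrow(u0)) + 0i, tolerance = 1e-12)
  a <- 0.8
  u <- kick_unitary(a, m)
  expect_lt(max(abs(Conj(t(u)) %*% u - diag(nrow(u)))), 1e-10)
  psi <- complex(real = numeric(82)); psi[1] <- 1   # |D, n = 0>
  phi <- u %*% psi
  nop <- kronecker(diag(2), crossprod(nmsse:::fock_annihilation(40)))
  expect_equal(Re(Conj(t(phi)) %*% nop %*% phi)[1], a^2, tolerance = 1e-6)
  # matrix-exponential cross-check of the generator route
  k <- kronecker(matrix(c(1, 0, 0, -1), 2), nmsse:::fock_annihilation(40) +
                   t(nmsse:::fock_annihilation(40)))
  es <- eigen(k, symmetric = TRUE)
  u_ref <- es$vectors %*% (exp(-1i * a * es$values) * t(es$vectors))
  expect_equal(u, u_ref, tolerance = 1e-10)
  expect_error(kick_unitary(1, model_spec(dimer_spec(0.1, 0.05), NULL, 0)),
               "mode")
})
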