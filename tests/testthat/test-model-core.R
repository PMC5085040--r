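test_that("phase-type representation matches the initiation scheme", {
  # pure exponential step
  pt1 <- build_phase_type(initiation_model(1))
  expect_equal(unname(pt1$sub_generator), matrix(-1, 1, 1))
  expect_equal(pt1$initial_distribution, 1)

  # full scheme, all rates 1: 4 transient states; on-state exit rate 2
  ptf <- build_phase_type(initiation_model(c(1, 1, 1), k_on = 1, k_off = 1))
  expect_equal(length(ptf$state_labels), 4L)
  expect_equal(ptf$sub_generator[1, 1], -2)        # total exit rate k_off + k1
  expect_true(all(rowSums(ptf$sub_generator) <= 1e-12))  # sub-generator rows

  # switching + one step: hand-solved sub-generator and mean absorption time
  pt <- build_phase_type(pivot_model())
  expect_equal(unname(pt$sub_generator), matrix(c(-2, 1, 1, -1), 2, 2))
  m_abs <- solve(-pt$sub_generator, rep(1, 2))  # -T m = 1
  expect_equal(m_abs[[1]], 2)

  expect_error(initiation_model(c(1, -1)), "positive")
  expect_error(initiation_model(numeric(0)), "1, 2 or 3")
  expect_error(initiation_model(1, k_on = 1), "both")
})

test_that("interval density and cdf agree with closed forms and quadrature", {
  e1 <- initiation_model(1)
  expect_equal(interval_density(e1, c(0, 1)), c(1, exp(-1)))
  expect_equal(interval_cdf(e1, 1), 1 - exp(-1))
  expect_equal(interval_cdf(e1, 0), 0)
  expect_error(interval_density(e1, -1), "non-negative")

  # Erlang(2,1): equal rates exercise the matrix-exponential fallback
  er2 <- initiation_model(c(1, 1))
  expect_equal(interval_density(er2, 1), stats::dgamma(1, 2, 1),
               tolerance = 1e-10)

  # switching model cdf vs quadrature of the density
  m <- pivot_model()
  quad <- stats::integrate(function(t) interval_density(m, t), 0, 2,
                           rel.tol = 1e-10)$value
  expect_equal(interval_cdf(m, 2), quad, tolerance = 1e-8)
})

test_that("densities integrate to one for randomized models", {
  set.seed(401)
  for (i in 1:8) {
    m <- random_model()
    total <- stats::integrate(function(t) interval_density(m, t), 0, Inf,
                              rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("interval distribution is invariant under step permutation", {
  set.seed(402)
  k <- exp(stats::runif(3, log(1e-3), 0))
  tpts <- exp(seq(log(1), log(5e3), length.out = 10))
  base <- interval_cdf(initiation_model(k), tpts)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(interval_cdf(initiation_model(k[perm]), tpts), base,
                 tolerance = 1e-10)
  }
  # with switching, permuting the post-commit steps only
  bsw <- interval_cdf(initiation_model(k, k_on = 0.01, k_off = 0.1), tpts)
  psw <- interval_cdf(initiation_model(k[c(1, 3, 2)], k_on = 0.01, k_off = 0.1),
                      tpts)
  expect_equal(psw, bsw, tolerance = 1e-10)
})

test_that("moments match the closed-form mean and the matrix formulas", {
  mo <- interval_moments(pivot_model())
  expect_equal(mo$mean, 2)
  expect_equal(mo$sd^2, 6, tolerance = 1e-10)
  expect_equal(mo$cv_sq, 1.5, tolerance = 1e-10)
  expect_equal(mo$cv_sq, mo$cv^2)

  mo3 <- interval_moments(initiation_model(c(1, 1, 1)))
  expect_equal(mo3$mean, 3)
  expect_equal(mo3$sd^2, 3, tolerance = 1e-10)

  set.seed(403)
  for (i in 1:300) {
    m <- random_model()
    ora <- matrix_moments(m)
    mo <- interval_moments(m)
    expect_equal(mo$mean, ora$mean, tolerance = 1e-10)
    expect_equal(mo$sd^2, ora$var, tolerance = 1e-8 * ora$var)
  }
})

test_that("pre-commit cv-squared: closed form, ranges, and grid oracle", {
  set.seed(404)
  for (i in 1:200) {
    kon <- exp(stats::runif(1, log(1e-4), 0))
    koff <- exp(stats::runif(1, log(1e-4), 0))
    k1 <- exp(stats::runif(1, log(1e-4), 0))
    ora <- matrix_moments(initiation_model(k1, k_on = kon, k_off = koff))
    expect_equal(precommit_cv_sq(kon, koff, k1), ora$var / ora$mean^2,
                 tolerance = 1e-10)
  }

  m <- initiation_model(1, k_on = 1, k_off = 1)
  expect_equal(precommit_cv_sq_range(m, "k_on"), c(1, 3))
  expect_equal(precommit_cv_sq_range(m, "k_off"), c(1, 1.5))
  expect_error(precommit_cv_sq_range(initiation_model(1), "k_on"), "switching")

  # grid-search oracle: varying k_off at k1 = k_on = 1 peaks at k_off = 1
  koff_grid <- exp(seq(log(1e-3), log(1e3), length.out = 2001))
  cv2 <- precommit_cv_sq(1, koff_grid, 1)
  expect_equal(max(cv2), 1.5, tolerance = 1e-4)
  expect_equal(koff_grid[which.max(cv2)], 1, tolerance = 1e-2)
})

test_that("post-commit cv-squared lower bound behaves as derived", {
  expect_equal(cv_sq_lower_bound(2 / 3, 2), 1 / 3)
  expect_equal(cv_sq_lower_bound(0, 5), 1)
  expect_equal(cv_sq_lower_bound(1, 4), 0.25)
  expect_error(cv_sq_lower_bound(1.2, 2), "\\[0, 1\\]")
  for (n in 1:5) {
    r <- seq(0, 1, by = 1e-3)
    vals <- cv_sq_lower_bound(r, n)
    expect_true(all(vals >= 1 / (n + 1) - 1e-12))
    expect_equal(r[which.min(vals)], n / (n + 1), tolerance = 1e-3)
    expect_equal(cv_sq_lower_bound(n / (n + 1), n), 1 / (n + 1))
  }
})

test_that("burst statistics follow their definitions", {
  b <- burst_statistics(initiation_model(1, k_on = 1, k_off = 3))
  expect_equal(b$duty_cycle, 0.25)
  b2 <- burst_statistics(initiation_model(0.05, k_on = 0.1, k_off = 0.05))
  expect_equal(b2$mean_burst_size, 1)
  b3 <- burst_statistics(initiation_model(2, k_on = 0.1, k_off = 1))
  expect_equal(b3$mean_burst_size, 2)
  expect_equal(b3$mean_burst_interval, 10)
  expect_error(burst_statistics(initiation_model(1)), "switching")
})

test_that("canonical coefficients sort steps fastest-first", {
  m <- initiation_model(c(0.001, 0.1, 0.01), k_on = 0.5, k_off = 0.2)
  k <- coef_canonical(m)
  expect_equal(names(k), c("k_on", "k_off", "k1", "k2", "k3"))
  expect_equal(unname(k[3:5]), c(0.1, 0.01, 0.001))
})
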