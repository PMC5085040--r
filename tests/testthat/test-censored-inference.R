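test_that("censored log-likelihood matches closed-form contributions", {
  e1 <- initiation_model(1)
  # survival term of a right-censored record
  expect_equal(censored_loglik(e1, recs(2, Inf)), -2)
  # a (0, Inf) record carries total probability
  expect_equal(censored_loglik(pivot_model(), recs(0, Inf)), 0)
  # grid-censored record under a slow exponential: log(1 - e^-0.6)
  expect_equal(censored_loglik(initiation_model(0.01), recs(0, 60)),
               -0.7958704, tolerance = 1e-6)
  # additivity: duplicating every record doubles the log-likelihood
  set.seed(601)
  r <- quantize_records(sample_intervals(pivot_model(), 50) * 500)
  m <- initiation_model(1 / 400, k_on = 1 / 300, k_off = 1 / 100)
  expect_equal(censored_loglik(m, rbind(r, r)), 2 * censored_loglik(m, r))
  # impossible record under a gamma spec -> -Inf, not an error
  g <- list(dist = "gamma", shape = 2, rate = 1)
  expect_identical(censored_loglik(g, recs(0, 0.5)) > -Inf, TRUE)
  expect_error(as_interval_records(recs(5, 5)), "malformed")
})

test_that("maximum likelihood recovers an exponential rate from censored data", {
  set.seed(602)
  w <- sample_intervals(initiation_model(0.01), 5000)
  r <- quantize_records(w)
  f <- fit_model(r, model_structure(FALSE, 1), n_starts = 6, seed = 1)
  expect_true(f$converged)
  se <- sqrt(diag(f$covariance))
  expect_lt(abs(f$estimates[[1]] - log(0.01)), 3 * se[1])
})

test_that("fitted likelihood beats or matches the truth most of the time", {
  set.seed(603)
  m <- initiation_model(c(1 / 200, 1 / 500))
  hits <- 0L
  for (r in 1:10) {
    rec <- quantize_records(sample_intervals(m, 400))
    f <- fit_model(rec, model_structure(FALSE, 2), n_starts = 4, seed = r)
    if (f$loglik >= censored_loglik(m, rec) - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("censoring-aware estimation is unbiased where the naive mean is not", {
  # heavily censored design: ignoring open intervals underestimates the mean
  set.seed(604)
  m <- initiation_model(1 / 2000)
  des <- observation_design(movie_length = 3600, n_cells = 60)
  bias_ml <- numeric(30); bias_naive <- numeric(30)
  for (r in 1:30) {
    rec <- simulate_records(m, des, "C")
    f <- fit_model(rec, model_structure(FALSE, 1), n_starts = 4, seed = r)
    bias_ml[r] <- 1 / exp(f$estimates[[1]]) - 2000
    b <- is.finite(rec$ub_s)
    bias_naive[r] <- mean((rec$lb_s[b] + rec$ub_s[b]) / 2) - 2000
  }
  cens_frac <- mean(!is.finite(simulate_records(m, des, "C")$ub_s))
  expect_gt(cens_frac, 0.3)
  expect_lt(abs(mean(bias_ml)), 2 * stats::sd(bias_ml) / sqrt(30))
  expect_lt(mean(bias_naive), -200)  # gross underestimate
})

test_that("likelihood is invariant under permutation of sequential rates", {
  set.seed(605)
  rec <- quantize_records(sample_intervals(initiation_model(c(0.005, 0.001)), 200))
  a <- censored_loglik(initiation_model(c(0.005, 0.001)), rec)
  b <- censored_loglik(initiation_model(c(0.001, 0.005)), rec)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("censored gamma fit recovers moments and the exponential identity", {
  set.seed(606)
  # exponential data: gamma shape ~ 1, median/mean -> ln 2
  r <- quantize_records(sample_intervals(initiation_model(1 / 600), 4000))
  f <- fit_censored_gamma(r, seed = 2)
  expect_true(f$converged)
  expect_equal(f$moments$median_to_mean, log(2), tolerance = 0.05)
  # gamma(2.2) data: shape recovered within 3 SE
  set.seed(607)
  w <- stats::rgamma(5000, shape = 2.2, rate = 1 / 300)
  f2 <- fit_censored_gamma(quantize_records(w), seed = 3)
  se_shape <- sqrt(diag(f2$covariance))[1]
  expect_lt(abs(f2$estimates[[1]] - log(2.2)), 3 * se_shape)
  # all-censored data is not identifiable
  expect_error(fit_censored_gamma(recs(c(100, 200), c(Inf, Inf))),
               "not identifiable")
})

test_that("gamma median-to-mean is scale-free across a temperature sweep", {
  # scaling all durations (k1^-1 only rescales time) leaves the shape alone
  set.seed(608)
  base <- sample_intervals(initiation_model(1, k_on = 2, k_off = 1), 3000)
  ratio <- vapply(c(500, 800, 1200), function(s) {
    f <- fit_censored_gamma(quantize_records(base * s), seed = 4)
    f$moments$median_to_mean
  }, numeric(1))
  expect_lt(max(ratio) - min(ratio), 0.03)
})

test_that("delta method reproduces the reference confidence intervals", {
  # identity transform: half-width is 1.96 sd
  fit <- list(estimates = c(x = 5), covariance = matrix(4), converged = TRUE)
  d <- delta_method_interval(fit, function(th) th[[1]])
  expect_equal(d$ci95, c(5 - 1.96 * 2, 5 + 1.96 * 2))

  # qPCR/WB commit-split estimates: (22.5, 14.6)% and (77.1, 6.64)%
  f1 <- list(estimates = c(x = 22.5), covariance = matrix(14.6^2),
             converged = TRUE)
  ci1 <- delta_method_interval(f1, function(th) th[[1]])$ci95
  expect_equal(signif(ci1[2], 3), 51.1)
  expect_equal(signif(ci1[1], 3), -6.12)
  f2 <- list(estimates = c(x = 77.1), covariance = matrix(6.64^2),
             converged = TRUE)
  ci2 <- delta_method_interval(f2, function(th) th[[1]])$ci95
  expect_equal(signif(ci2[2], 3), 90.1)
  expect_equal(signif(ci2[1], 3), 64.1)

  expect_error(
    delta_method_interval(list(converged = FALSE), identity), "converged")
})
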