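test_that("temperature laws evaluate polynomial inverse rates", {
  law <- temperature_law(k1 = 500)
  expect_equal(eval_rate(law, "k1", c(24, 37)), c(0.002, 0.002))
  law1 <- temperature_law(k1 = c(-100, 4000))
  expect_equal(1 / eval_rate(law1, "k1", 30), 1000)
  # convexity of a quadratic inverse rate with A > 0
  law2 <- temperature_law(k1 = c(2, -130, 3600))
  inv <- function(T) 1 / eval_rate(law2, "k1", T)
  expect_lte(inv(32.5), (inv(24) + inv(41)) / 2)
  expect_error(eval_rate(law1, "k1", 45), "non-positive")
  expect_error(eval_rate(law1, "k9", 30), "not in law")
  m <- model_at_temperature(temperature_law(k1 = 500, k_on = 1000, k_off = 100),
                            30)
  expect_true(m$has_switching)
  expect_equal(m$seq_rates, 0.002)
  co <- law_coefficients(law2)
  expect_equal(co$A, 2); expect_equal(co$B, -130); expect_equal(co$C, 3600)
})

test_that("all-constant joint fit coincides with the pooled fit", {
  set.seed(801)
  m <- initiation_model(1 / 400)
  rec <- rbind(
    cbind(quantize_records(sample_intervals(m, 400)), temperature_C = 24),
    cbind(quantize_records(sample_intervals(m, 400)), temperature_C = 37))
  pooled <- fit_model(rec, model_structure(FALSE, 1), n_starts = 4, seed = 2)
  joint <- fit_joint_temperature(rec, model_structure(FALSE, 1),
                                 n_starts = 4, seed = 2, init_fit = pooled)
  expect_true(joint$converged)
  expect_equal(joint$loglik, pooled$loglik, tolerance = 1e-6)
  expect_equal(1 / eval_rate(joint$law, "k1", 30), 1 / exp(pooled$estimates[[1]]),
               tolerance = 1e-3)
})

test_that("a two-temperature linear law interpolates per-temperature optima", {
  set.seed(802)
  rec <- rbind(
    cbind(quantize_records(sample_intervals(initiation_model(1 / 300), 600)),
          temperature_C = 24),
    cbind(quantize_records(sample_intervals(initiation_model(1 / 700), 600)),
          temperature_C = 41))
  joint <- fit_joint_temperature(rec, model_structure(FALSE, 1),
                                 order_spec = c(k1 = 1), n_starts = 6, seed = 3)
  per <- vapply(c(24, 41), function(Tc) {
    f <- fit_model(rec[rec$temperature_C == Tc, ], model_structure(FALSE, 1),
                   n_starts = 4, seed = 3)
    1 / exp(f$estimates[[1]])
  }, numeric(1))
  expect_equal(1 / eval_rate(joint$law, "k1", 24), per[1], tolerance = 1e-3)
  expect_equal(1 / eval_rate(joint$law, "k1", 41), per[2], tolerance = 1e-3)
  expect_error(
    fit_joint_temperature(rec[rec$temperature_C == 24, ],
                          model_structure(FALSE, 1), order_spec = c(k1 = 1)),
    "2 distinct temperatures")
})

test_that("a quadratic first-step law is recovered across temperatures", {
  set.seed(803)
  law <- temperature_law(k1 = txinit:::.poly_from_anchors(c(236, 146, 205), 2L),
                        k_on = 1250, k_off = 60)
  des <- observation_design(movie_length = 7200, n_cells = 350)
  temps <- c(24, 28, 32.5, 37, 41)
  rec <- do.call(rbind, lapply(temps, function(Tc) {
    r <- simulate_records(model_at_temperature(law, Tc), des, "C")
    cbind(r, temperature_C = Tc)
  }))
  fit <- fit_joint_temperature(rec, model_structure(TRUE, 1),
                               order_spec = c(k1 = 2), n_starts = 6, seed = 4)
  expect_true(fit$converged)
  for (Tc in temps) {
    est <- 1 / eval_rate(fit$law, "k1", Tc)
    truth <- 1 / eval_rate(law, "k1", Tc)
    expect_lt(abs(est - truth) / truth, 0.15)
  }
})

test_that("order selection finds the temperature-dependent parameter", {
  set.seed(804)
  law <- temperature_law(k1 = txinit:::.poly_from_anchors(c(700, 420, 600), 2L))
  des <- observation_design(movie_length = 7200, n_cells = 150)
  temps <- c(24, 30, 35, 41)
  rec <- do.call(rbind, lapply(temps, function(Tc) {
    r <- simulate_records(model_at_temperature(law, Tc), des, "C")
    cbind(r, temperature_C = Tc)
  }))
  cmp <- select_temperature_model(rec, model_structure(FALSE, 1),
                                  n_starts = 4, seed = 4)
  expect_match(cmp$labels[cmp$best], "^k1")

  # null data: the all-constant specification wins
  set.seed(805)
  lawc <- temperature_law(k1 = 500)
  recc <- do.call(rbind, lapply(temps, function(Tc) {
    r <- simulate_records(model_at_temperature(lawc, Tc),
                          observation_design(movie_length = 7200,
                                             n_cells = 120), "C")
    cbind(r, temperature_C = Tc)
  }))
  cmp0 <- select_temperature_model(recc, model_structure(FALSE, 1),
                                   n_starts = 4, seed = 5)
  expect_equal(cmp0$labels[cmp0$best], "all constant")
})

test_that("shared-shape fit recovers per-scheme scales and beats the free model", {
  set.seed(806)
  g <- c(600, 380, 520)  # quadratic anchors of the shared shape (s)
  scales <- c(Full = 1, IPTG = 1.8)
  des <- observation_design(movie_length = 7200, n_cells = 130)
  temps <- c(24, 32.5, 41)
  rec <- do.call(rbind, lapply(names(scales), function(s) {
    law <- temperature_law(
      k1 = txinit:::.poly_from_anchors(scales[[s]] * g, 2L))
    do.call(rbind, lapply(temps, function(Tc) {
      r <- simulate_records(model_at_temperature(law, Tc), des,
                            paste0(s, Tc))
      cbind(r, temperature_C = Tc, scheme = s)
    }))
  }))
  fit <- fit_shared_shape(rec, model_structure(FALSE, 1), n_starts = 6,
                          seed = 6)
  expect_true(fit$converged)
  expect_equal(unname(fit$scales["Full"]), 1)
  expect_lt(abs(fit$scales[["IPTG"]] - 1.8) / 1.8, 0.15)

  # unconstrained alternative: independent quadratic per scheme
  free <- lapply(names(scales), function(s)
    fit_joint_temperature(rec[rec$scheme == s, ], model_structure(FALSE, 1),
                          order_spec = c(k1 = 2), n_starts = 4, seed = 7))
  free_fit <- list(loglik = sum(vapply(free, `[[`, numeric(1), "loglik")),
                   df = sum(vapply(free, `[[`, numeric(1), "df")),
                   n_exact = fit$n_exact, n_censored = fit$n_censored,
                   converged = TRUE)
  d <- delta_bic_with_lb(fit, free_fit)
  expect_equal(d$better, "a")  # constrained model has the smaller BIC
})

test_that("single-scheme shared-shape reduces to the joint quadratic fit", {
  set.seed(807)
  rec <- do.call(rbind, lapply(c(24, 37), function(Tc) {
    r <- quantize_records(sample_intervals(initiation_model(1 / 500), 300))
    cbind(r, temperature_C = Tc, scheme = "only")
  }))
  a <- fit_shared_shape(rec, model_structure(FALSE, 1), n_starts = 4, seed = 8)
  b <- fit_joint_temperature(rec, model_structure(FALSE, 1),
                             order_spec = c(k1 = 2), n_starts = 4, seed = 8)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-6)
})

test_that("RNAP-constrained fit recovers the per-polymerase rate", {
  prof <- rnap_profile(c(24, 37, 41), c(0.415, 1, 0.562))
  expect_equal(eval_rnap(prof, 37), 1)
  expect_error(eval_rnap(prof, 20), "hull")
  expect_error(rnap_profile(c(24, 37), c(0.5, 2)), "abundance 1")

  set.seed(808)
  k1_tilde <- 1 / 400
  des <- observation_design(movie_length = 7200, n_cells = 250)
  temps <- c(24, 37, 41)
  rec <- do.call(rbind, lapply(temps, function(Tc) {
    m <- initiation_model(k1_tilde * eval_rnap(prof, Tc))
    cbind(simulate_records(m, des, "C"), temperature_C = Tc)
  }))
  fit <- fit_rnap_constrained(rec, model_structure(FALSE, 1), prof,
                              n_starts = 6, seed = 9)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$covariance))[1]
  expect_lt(abs(fit$estimates[[1]] - log(k1_tilde)), 3 * se)

  # a non-proportional temperature response is detected: the free
  # quadratic law fits better by BIC than the RNAP-constrained model
  set.seed(809)
  law <- temperature_law(k1 = txinit:::.poly_from_anchors(c(800, 350, 700), 2L))
  rec2 <- do.call(rbind, lapply(temps, function(Tc) {
    cbind(simulate_records(model_at_temperature(law, Tc), des, "C"),
          temperature_C = Tc)
  }))
  con <- fit_rnap_constrained(rec2, model_structure(FALSE, 1), prof,
                              n_starts = 6, seed = 10)
  quad <- fit_joint_temperature(rec2, model_structure(FALSE, 1),
                                order_spec = c(k1 = 2), n_starts = 6, seed = 10)
  expect_lt(bic(quad), bic(con))

  # constant profile reduces to the pooled constant-rate fit
  prof1 <- rnap_profile(c(24, 41), c(1, 1))
  con1 <- fit_rnap_constrained(rec[, c("lb_s", "ub_s", "temperature_C")],
                               model_structure(FALSE, 1), prof1,
                               n_starts = 4, seed = 11)
  pooled <- fit_model(rec, model_structure(FALSE, 1), n_starts = 4, seed = 11)
  expect_equal(con1$loglik, pooled$loglik, tolerance = 1e-6)
})
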