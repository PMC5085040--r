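fake_fit <- function(loglik, df, n_exact, n_censored)
  list(loglik = loglik, df = df, n_exact = n_exact, n_censored = n_censored,
       converged = TRUE)

test_that("BIC uses the censored-sample-weighted effective size", {
  f <- fake_fit(-100, 4, 50, 10)
  expect_equal(bic(f), 200 + 4 * log(55), tolerance = 1e-10)
  expect_equal(bic(f, censored_weight = 0), 200 + 4 * log(50))
  expect_equal(bic(fake_fit(-100, 0, 50, 10)), 200)
  expect_error(bic(fake_fit(-1, 1, 0, 1), censored_weight = 0), "below 1")
  expect_error(bic(list(converged = FALSE)), "converged")
})

test_that("Delta-BIC lower bound is the worst case over censoring worth", {
  # equal parameter counts: weight-independent
  a <- fake_fit(-100, 3, 80, 20); b <- fake_fit(-103, 3, 80, 20)
  d <- delta_bic_with_lb(a, b)
  expect_equal(d$delta_bic_lb, d$delta_bic)
  expect_equal(d$delta_bic, 6)

  # no censored samples: lower bound equals Delta-BIC
  a2 <- fake_fit(-100, 2, 100, 0); b2 <- fake_fit(-101, 4, 100, 0)
  d2 <- delta_bic_with_lb(a2, b2)
  expect_equal(d2$delta_bic_lb, d2$delta_bic)

  # endpoint-evaluation oracle: dp = 1, n_exact 100, n_censored 40,
  # d(-2 loglik) = -3 in favor of the larger model
  a3 <- fake_fit(-100, 2, 100, 40)        # smaller model
  b3 <- fake_fit(-98.5, 3, 100, 40)       # larger model, +1.5 loglik
  d3 <- delta_bic_with_lb(a3, b3)
  oracle <- min(-3 + log(100), -3 + log(140))
  expect_equal(d3$delta_bic, -3 + log(120), tolerance = 1e-10)
  expect_equal(d3$delta_bic_lb, oracle, tolerance = 1e-10)
  expect_lte(d3$delta_bic_lb, d3$delta_bic)

  expect_error(delta_bic_with_lb(a3, fake_fit(-1, 2, 99, 40)), "same data")
})

test_that("structure selection ranks, grades, and handles one candidate", {
  set.seed(701)
  m <- initiation_model(c(1 / 150, 1 / 600))
  rec <- quantize_records(sample_intervals(m, 1500))
  cmp <- select_structure(rec, n_starts = 3, seed = 5)
  expect_s3_class(cmp, "model_comparison")
  expect_equal(nrow(cmp$table), 6L)
  # best by BIC is first in the table; lower bound never exceeds Delta-BIC
  expect_equal(cmp$table$delta_bic[1], 0)
  expect_true(all(cmp$table$delta_bic_lb <= cmp$table$delta_bic + 1e-9))
  expect_true(cmp$evidence_grade %in% c("weak", "positive", "strong"))
  # the generating structure (2 steps, no switching) wins here
  expect_equal(cmp$labels[cmp$best], "2-step")

  one <- select_structure(rec, candidates = list(model_structure(FALSE, 1)),
                          n_starts = 3, seed = 5)
  expect_equal(one$labels[one$best], "1-step")
  expect_true(is.na(one$delta_bic_second_best))

  # nested likelihood dominance (multi-start adequacy): larger models fit
  # at least as well, up to the irreducible gap left by the bounded rate box
  ll <- setNames(cmp$table$loglik, cmp$table$structure)
  expect_gte(ll[["3-step"]], ll[["2-step"]] - 0.5)
  expect_gte(ll[["2-step"]], ll[["1-step"]] - 0.5)
  expect_gte(ll[["on/off + 2-step"]], ll[["2-step"]] - 0.5)
})

test_that("selection is invariant to relabeling interchangeable steps", {
  set.seed(702)
  rec <- quantize_records(sample_intervals(initiation_model(c(1 / 150, 1 / 600)),
                                           800))
  f_a <- fit_model(rec, model_structure(FALSE, 2), n_starts = 4, seed = 1)
  # report in canonical order: fastest step first, regardless of fit order
  k <- coef_canonical(f_a$model)
  expect_true(k[["k1"]] >= k[["k2"]])
})

test_that("selection reports round-trip through CSV", {
  set.seed(703)
  rec <- quantize_records(sample_intervals(initiation_model(1 / 300), 300))
  cmp <- select_structure(rec, candidates = list(model_structure(FALSE, 1),
                                                 model_structure(FALSE, 2)),
                          n_starts = 3, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_selection_report(cmp, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$bic, cmp$table$bic, tolerance = 1e-8)
})
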