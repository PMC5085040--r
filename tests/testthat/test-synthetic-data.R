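test_that("the frame-grid observation operator follows the recording dialect", {
  des <- observation_design(movie_length = 7200, sampling_interval = 60,
                            n_cells = 1)
  # two productions: detections at 60 and 180; first interval discarded,
  # one bounded record (120-60, 120] plus the open interval at movie end
  r <- censor_to_records(c(30, 150), des, "C1", 1)
  bounded <- r[is.finite(r$ub_s), ]
  expect_equal(nrow(bounded), 1L)
  expect_equal(bounded$lb_s, 60)
  expect_equal(bounded$ub_s, 120)
  expect_equal(bounded$ub_s - bounded$lb_s, des$sampling_interval)
  open <- r[!is.finite(r$ub_s), ]
  expect_equal(nrow(open), 1L)
  expect_equal(open$lb_s, 7200 - 180)

  # a single production: only the right-censored tail interval
  r1 <- censor_to_records(30, des, "C1", 1, window = 330)
  expect_equal(nrow(r1), 1L)
  expect_false(is.finite(r1$ub_s))
  expect_equal(r1$lb_s, 300 - 60)

  # no productions: nothing to record
  expect_equal(nrow(censor_to_records(numeric(0), des)), 0L)

  # keep_first retains the window-start interval
  rk <- censor_to_records(c(30, 150), des, "C1", 1, keep_first = TRUE)
  expect_equal(nrow(rk[is.finite(rk$ub_s), ]), 2L)

  expect_error(censor_to_records(c(30, 9999), des, window = 300), "outside")
})

test_that("event simulation matches Poisson and analytic-moment oracles", {
  # exponential events: count ~ Poisson(window * rate)
  set.seed(501)
  ev <- simulate_event_times(initiation_model(0.01), 1e6)
  expect_lt(abs(length(ev) - 1e4), 3 * sqrt(1e4))

  # pivot model: sample mean within the CLT band around analytic mean 2
  set.seed(502)
  w <- sample_intervals(pivot_model(), 1e5)
  expect_lt(abs(mean(w) - 2), 3 * sqrt(6 / 1e5))
  expect_equal(stats::var(w), 6, tolerance = 0.15)
})

test_that("simulated interval cdf matches the phase-type cdf (KS)", {
  set.seed(503)
  for (i in 1:3) {
    m <- random_model()
    w <- sample_intervals(m, 5e3)
    ks <- suppressWarnings(stats::ks.test(w, function(q) interval_cdf(m, q)))
    expect_lt(unname(ks$statistic), 1.63 / sqrt(5e3))
  }
})

test_that("study generation is seeded, referentially intact, and censoring-monotone", {
  law <- temperature_law(k1 = c(-20, 2000), k_on = 1500, k_off = 100)
  des <- observation_design(movie_length = 7200, n_cells = 25)
  schemes <- list(list(name = "Full", promoter = "Plac/ara-1", iptg_mM = 1,
                       ara_pct = 0.1))
  s1 <- generate_study(des, law, schemes, c(24, 37), seed = 42)
  s2 <- generate_study(des, law, schemes, c(24, 37), seed = 42)
  expect_identical(s1, s2)
  s3 <- generate_study(des, law, schemes, c(24, 37), seed = 43)
  expect_false(identical(s1$intervals, s3$intervals))

  iv <- s1$intervals
  expect_true(all(iv$condition_id %in% s1$conditions$condition_id))
  expect_true(all(iv$lb_s >= 0 & iv$lb_s < iv$ub_s))
  # chained predecessors exist earlier in the same condition
  chained <- which(!is.na(iv$prev_interval_id))
  pos <- match(iv$prev_interval_id[chained], iv$interval_id)
  expect_false(anyNA(pos))
  expect_true(all(pos < chained))
  expect_equal(iv$condition_id[pos], iv$condition_id[chained])

  # identical parameters at all temperatures under a constant law
  lawc <- temperature_law(k1 = 600)
  expect_equal(model_at_temperature(lawc, 24)$seq_rates,
               model_at_temperature(lawc, 41)$seq_rates)

  # shorter movies censor a larger fraction of intervals
  m <- initiation_model(1 / 900)
  frac <- vapply(c(14400, 7200, 3600), function(L) {
    set.seed(77)
    d <- observation_design(movie_length = L, n_cells = 150)
    r <- simulate_records(m, d, "C")
    mean(!is.finite(r$ub_s))
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("generated records carry grid-consistent bounds", {
  set.seed(504)
  des <- observation_design(movie_length = 3600, n_cells = 80)
  r <- simulate_records(initiation_model(c(1 / 200, 1 / 400)), des, "C")
  b <- is.finite(r$ub_s)
  expect_true(all(r$ub_s[b] - r$lb_s[b] == des$sampling_interval))
  expect_true(all(r$lb_s %% des$sampling_interval == 0))
  expect_gt(sum(!b), 0)  # every cell ends with an open interval
})
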