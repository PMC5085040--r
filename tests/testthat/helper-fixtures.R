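# shared fixtures for the test suite (all data generated in code)

pivot_model <- function() initiation_model(1, k_on = 1, k_off = 1)

# random valid model with rates in [1e-4, 1] 1/s; switching for even draws
random_model <- function(switching = NULL) {
  if (is.null(switching)) switching <- stats::runif(1) < 0.5
  m <- sample(1:3, 1)
  k <- exp(stats::runif(m, log(1e-4), 0))
  if (switching)
    initiation_model(k, k_on = exp(stats::runif(1, log(1e-4), 0)),
                     k_off = exp(stats::runif(1, log(1e-4), 0)))
  else initiation_model(k)
}

# matrix-formula moments (independent oracle for the closed forms)
matrix_moments <- function(model) {
  pt <- build_phase_type(model)
  Minv <- solve(-pt$sub_generator)
  ones <- rep(1, ncol(Minv))
  m1 <- as.numeric(pt$initial_distribution %*% Minv %*% ones)
  m2 <- 2 * as.numeric(pt$initial_distribution %*% Minv %*% Minv %*% ones)
  list(mean = m1, var = m2 - m1^2)
}

# quick bounded/censored record table
recs <- function(lb, ub) data.frame(lb_s = lb, ub_s = ub)

# per-interval grid censoring of raw durations (no window): the record
# dialect assumed by the likelihood
quantize_records <- function(w, delta = 60) {
  d <- delta * ceiling(w / delta)
  data.frame(lb_s = pmax(d - delta, 0), ub_s = pmax(d, delta))
}
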