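#' Kinetic model of transcription initiation
#'
#' Constructs the stochastic model of transcription initiation used
#' throughout the package: an optional on/off (telegraph) promoter switch
#' composed with a sequence of one to three effective forward steps.  While
#' the promoter is on, the first forward step (rate `k1`, the effective
#' closed-complex formation rate for an active gene) competes with
#' deactivation (rate `k_off`); an off promoter reactivates with rate
#' `k_on`.  Once the first step fires the system is committed and proceeds
#' through the remaining steps (rates `k2`, `k3`) to RNA production, after
#' which the promoter restarts in the on state.  The interval between
#' consecutive productions is therefore a phase-type random variable.
#'
#' All rates are in 1/s.  Steps in series are exchangeable: the interval
#' distribution is invariant under permutation of `seq_rates`, so fitted
#' step orders are reported sorted (fastest first) by [coef_canonical()].
#'
#' @param seq_rates numeric vector of 1-3 sequential step rates (1/s); the
#'   first entry is the effective forward rate `k1` for an active gene.
#' @param k_on,k_off promoter activation/deactivation rates (1/s); both
#'   `NULL` for a model without on/off switching.
#' @return an object of class `initiation_model`.
#' @examples
#' initiation_model(seq_rates = 1/543)                      # single step
#' initiation_model(seq_rates = 1/350, k_on = 1/500, k_off = 1/50)
#' @export
initiation_model <- function(seq_rates, k_on = NULL, k_off = NULL) {
  if (is.null(k_on) != is.null(k_off))
    stop("supply both `k_on` and `k_off`, or neither", call. = FALSE)
  has_switching <- !is.null(k_on)
  seq_rates <- as.numeric(seq_rates)
  if (length(seq_rates) < 1L || length(seq_rates) > 3L)
    stop("`seq_rates` must contain 1, 2 or 3 rates", call. = FALSE)
  rates <- c(if (has_switching) c(k_on, k_off), seq_rates)
  if (!all(is.finite(rates)) || any(rates <= 0))
    stop("all rates must be strictly positive and finite", call. = FALSE)
  structure(
    list(has_switching = has_switching,
         k_on = if (has_switching) as.numeric(k_on),
         k_off = if (has_switching) as.numeric(k_off),
         seq_rates = seq_rates),
    class = "initiation_model")
}

#' @export
print.initiation_model <- function(x, ...) {
  cat("Transcription initiation model\n")
  if (x$has_switching)
    cat(sprintf("  on/off switching: k_on = %g, k_off = %g (1/s)\n",
                x$k_on, x$k_off))
  else
    cat("  no on/off switching\n")
  cat(sprintf("  sequential steps: %s (1/s)\n",
              paste(signif(x$seq_rates, 6), collapse = ", ")))
  invisible(x)
}

#' Number of free rate parameters of a model structure
#' @param structure list with elements `switching` (logical) and
#'   `n_steps` (1-3), as produced by [model_structure()].
#' @return integer parameter count (switching contributes 2).
#' @export
n_free_rates <- function(structure) {
  structure$n_steps + if (isTRUE(structure$switching)) 2L else 0L
}

#' Describe a candidate model structure
#' @param switching logical; include the on/off promoter switch?
#' @param n_steps number of sequential steps (1-3).
#' @return list with class `model_structure`.
#' @export
model_structure <- function(switching, n_steps) {
  n_steps <- as.integer(n_steps)
  if (!n_steps %in% 1:3) stop("`n_steps` must be 1, 2 or 3", call. = FALSE)
  structure(list(switching = isTRUE(switching), n_steps = n_steps),
            class = "model_structure")
}

#' @export
format.model_structure <- function(x, ...) {
  paste0(if (x$switching) "on/off + " else "", x$n_steps, "-step")
}

#' @export
print.model_structure <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Absorbing-chain (phase-type) representation of the interval distribution
#'
#' Converts an [initiation_model()] into the canonical phase-type form of
#' its inter-production interval distribution: an initial distribution over
#' transient states, a sub-generator matrix `T` (row sums non-positive,
#' off-diagonals non-negative), and state labels.  Production restarts the
#' promoter in the on state, so all initial mass sits on `on@step1`.
#'
#' @param model an `initiation_model`.
#' @return object of class `phase_type` with fields `initial_distribution`,
#'   `sub_generator`, `state_labels`.
#' @examples
#' build_phase_type(initiation_model(1, k_on = 1, k_off = 1))$sub_generator
#' @export
build_phase_type <- function(model) {
  stopifnot(inherits(model, "initiation_model"))
  m <- length(model$seq_rates)
  k <- model$seq_rates
  if (model$has_switching) {
    n <- m + 1L
    labels <- c("on@step1", "off@step1", if (m > 1) paste0("step", 2:m))
    Tm <- matrix(0, n, n, dimnames = list(labels, labels))
    Tm[1, 1] <- -(model$k_off + k[1])
    Tm[1, 2] <- model$k_off
    if (m > 1) Tm[1, 3] <- k[1]
    Tm[2, 1] <- model$k_on
    Tm[2, 2] <- -model$k_on
    if (m > 1) for (j in 2:m) {
      i <- j + 1L
      Tm[i, i] <- -k[j]
      if (j < m) Tm[i, i + 1L] <- k[j]
    }
  } else {
    n <- m
    labels <- paste0("step", seq_len(m))
    labels[1] <- "on@step1"
    Tm <- matrix(0, n, n, dimnames = list(labels, labels))
    for (j in seq_len(m)) {
      Tm[j, j] <- -k[j]
      if (j < m) Tm[j, j + 1L] <- k[j]
    }
  }
  alpha <- numeric(n); alpha[1] <- 1
  structure(list(initial_distribution = alpha, sub_generator = Tm,
                 state_labels = labels),
            class = "phase_type")
}

# Closed-form survival mixture for the initiation scheme.  The interval
# Laplace transform factorizes into the pre-commit stage (a 2-phase
# block whose poles solve s^2 + (k_on+k_off+k1)s + k_on k1 = 0) times
# exponential post-commit steps; partial fractions over the (distinct)
# poles give S(t) = sum_i w_i exp(-p_i t).  Returns NULL when poles are
# nearly degenerate (caller falls back to the matrix path).
.closed_surv_weights <- function(k_on, k_off, kseq) {
  if (is.null(k_on)) {
    p <- kseq
  } else {
    a <- k_on + k_off + kseq[1]
    disc <- a * a - 4 * k_on * kseq[1]
    if (disc <= 0) return(NULL)
    sq <- sqrt(disc)
    p_big <- (a + sq) / 2
    p <- c(p_big, k_on * kseq[1] / p_big, kseq[-1])  # small root via product
  }
  n <- length(p)
  if (n > 1) {
    dmin <- min(abs(outer(p, p, "-"))[lower.tri(matrix(0, n, n))])
    if (dmin < 1e-9 * max(p)) return(NULL)
  }
  w <- numeric(n)
  post <- prod(kseq[-1])
  for (i in seq_len(n)) {
    denom <- if (n > 1) prod(p[-i] - p[i]) else 1
    num <- if (is.null(k_on)) prod(kseq)
           else kseq[1] * (k_on - p[i]) * post
    w[i] <- num / denom / p[i]
  }
  list(p = p, w = w)
}

.closed_surv_eval <- function(cw, t) {
  out <- numeric(length(t))
  fin <- is.finite(t)
  if (any(fin))
    out[fin] <- colSums(cw$w * exp(-outer(cw$p, t[fin])))
  pmin(pmax(out, 0), 1)
}

# Spectral decomposition of the sub-generator for fast evaluation of
# S(t) = alpha' exp(Tt) 1 and f(t) = alpha' exp(Tt) t0 as sums of
# exponentials.  Falls back to NULL (caller uses Matrix::expm) when
# eigenvalues are nearly degenerate (e.g. Erlang with tied rates) or the
# eigenbasis is ill-conditioned.
.pt_spectral <- function(pt) {
  Tm <- pt$sub_generator
  eg <- tryCatch(eigen(Tm), error = function(e) NULL)
  if (is.null(eg)) return(NULL)
  lam <- eg$values
  scale <- max(abs(lam))
  d <- abs(outer(lam, lam, "-")); diag(d) <- Inf
  if (min(d) < 1e-9 * scale) return(NULL)
  V <- eg$vectors
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  if (rcond(V) < 1e-12) return(NULL)
  alpha <- pt$initial_distribution
  ones <- rep(1, ncol(Tm))
  t0 <- -Tm %*% ones
  aV <- as.vector(alpha %*% V)
  list(lambda = lam,
       w_surv = aV * as.vector(Vi %*% ones),
       w_dens = aV * as.vector(Vi %*% t0))
}

.pt_mix_eval <- function(lambda, w, t) {
  out <- numeric(length(t))
  fin <- is.finite(t)
  if (any(fin))
    out[fin] <- Re(colSums(w * exp(outer(lambda, t[fin]))))
  out
}

.pt_expm_eval <- function(pt, t, what = c("surv", "dens")) {
  what <- match.arg(what)
  Tm <- pt$sub_generator
  alpha <- pt$initial_distribution
  v <- if (what == "surv") rep(1, ncol(Tm)) else as.vector(-Tm %*% rep(1, ncol(Tm)))
  vapply(t, function(ti) {
    if (!is.finite(ti)) return(0)
    as.numeric(alpha %*% as.matrix(Matrix::expm(Tm * ti)) %*% v)
  }, numeric(1))
}

#' Survival function of the interval distribution
#'
#' @param pt a `phase_type` object (or an `initiation_model`, converted
#'   internally).
#' @param t vector of times (s), each `>= 0` (`Inf` allowed, giving 0).
#' @return S(t) = P(interval > t), clamped to \[0, 1\] against roundoff.
#' @export
interval_survival <- function(pt, t) {
  if (inherits(pt, "initiation_model")) pt <- build_phase_type(pt)
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be non-negative", call. = FALSE)
  dec <- .pt_spectral(pt)
  s <- if (!is.null(dec)) .pt_mix_eval(dec$lambda, dec$w_surv, t)
       else .pt_expm_eval(pt, t, "surv")
  pmin(pmax(s, 0), 1)
}

#' Probability density of the interval distribution
#'
#' f(t) = alpha' exp(Tt) t0, with t0 the exit-rate vector of the
#' absorbing chain.
#'
#' @inheritParams interval_survival
#' @return density values (1/s), non-negative.
#' @export
interval_density <- function(pt, t) {
  if (inherits(pt, "initiation_model")) pt <- build_phase_type(pt)
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be non-negative", call. = FALSE)
  dec <- .pt_spectral(pt)
  f <- if (!is.null(dec)) .pt_mix_eval(dec$lambda, dec$w_dens, t)
       else .pt_expm_eval(pt, t, "dens")
  pmax(f, 0)
}

#' Cumulative distribution function of the interval distribution
#'
#' @inheritParams interval_survival
#' @return F(t) = 1 - S(t).
#' @export
interval_cdf <- function(pt, t) {
  1 - interval_survival(pt, t)
}

#' Moments of the inter-production interval
#'
#' The mean uses the closed form
#' \deqn{E[W] = (1 + k_{on}^{-1} / k_{off}^{-1})\,k_1^{-1} + k_2^{-1} + k_3^{-1}}
#' (reducing to the sum of step durations without switching); the second
#' moment comes from the phase-type matrix formulas
#' \eqn{E[W] = \alpha(-T)^{-1}\mathbf 1}, \eqn{E[W^2] = 2\alpha(-T)^{-2}\mathbf 1}.
#' The median is located numerically from the cdf.
#'
#' @param model an `initiation_model`.
#' @return list of class `moments_summary`: `mean`, `sd`, `cv`, `cv_sq`,
#'   `median_to_mean` (all durations in seconds).
#' @examples
#' interval_moments(initiation_model(1, k_on = 1, k_off = 1))  # mean 2, var 6
#' @export
interval_moments <- function(model) {
  stopifnot(inherits(model, "initiation_model"))
  k <- model$seq_rates
  mean_cf <- if (model$has_switching)
    (1 + (1 / model$k_on) / (1 / model$k_off)) / k[1] + sum(1 / k[-1])
  else sum(1 / k)
  pt <- build_phase_type(model)
  mTi <- solve(-pt$sub_generator)
  ones <- rep(1, ncol(mTi))
  m1 <- as.numeric(pt$initial_distribution %*% mTi %*% ones)
  m2 <- 2 * as.numeric(pt$initial_distribution %*% mTi %*% mTi %*% ones)
  v <- m2 - m1^2
  med <- stats::uniroot(function(t) interval_cdf(pt, t) - 0.5,
                        lower = 0, upper = max(1, 100 * m1),
                        extendInt = "upX", tol = 1e-10 * max(1, m1))$root
  structure(list(mean = mean_cf, sd = sqrt(v), cv = sqrt(v) / mean_cf,
                 cv_sq = v / mean_cf^2, median_to_mean = med / mean_cf),
            class = "moments_summary")
}

#' @export
print.moments_summary <- function(x, ...) {
  cat(sprintf(
    "interval moments: mean %.4g s, sd %.4g s, cv %.4g, median/mean %.4g\n",
    x$mean, x$sd, x$cv, x$median_to_mean))
  invisible(x)
}

#' Attainable squared coefficient of variation of the pre-commit stage
#'
#' For the pre-commit stage (on/off switching plus the first forward step)
#' the squared coefficient of variation is
#' \eqn{c_v^2 = 1 + 2 k_1 k_{off} / (k_{on} + k_{off})^2}.  Varying only
#' `k_on` over (0, Inf) sweeps \eqn{[1, 1 + 2k_1/k_{off}]}; varying only
#' `k_off` sweeps \eqn{[1, 1 + k_1/(2 k_{on})]}, the maximum attained at
#' `k_off = k_on`.
#'
#' @param model an `initiation_model` with switching.
#' @param vary which parameter is varied: `"k_on"` or `"k_off"`.
#' @return numeric length-2 vector `c(lo, hi)`.
#' @export
precommit_cv_sq_range <- function(model, vary = c("k_on", "k_off")) {
  stopifnot(inherits(model, "initiation_model"))
  if (!model$has_switching)
    stop("model has no on/off switching", call. = FALSE)
  vary <- match.arg(vary)
  k1 <- model$seq_rates[1]
  if (vary == "k_on") c(1, 1 + 2 * k1 / model$k_off)
  else c(1, 1 + k1 / (2 * model$k_on))
}

#' Squared coefficient of variation of the pre-commit stage (closed form)
#'
#' @param k_on,k_off,k1 rates (1/s).
#' @return \eqn{1 + 2 k_1 k_{off} / (k_{on} + k_{off})^2}.
#' @export
precommit_cv_sq <- function(k_on, k_off, k1) {
  1 + 2 * k1 * k_off / (k_on + k_off)^2
}

#' Lower bound of the interval cv-squared given the commit split
#'
#' For a post-commit stage of `n` steps with relative duration `r` of the
#' mean interval, the squared coefficient of variation of the interval is
#' bounded below by \eqn{(r-1)^2 + r^2/n}; over `r` the minimum is
#' \eqn{1/(n+1)}, attained at \eqn{r^* = n/(n+1)} (exponential-like
#' pre-commit stage and n equal post-commit steps).
#'
#' @param r relative duration of the post-commit stage, in \[0, 1\].
#' @param n number of post-commit steps (>= 1).
#' @return the bound (dimensionless); vectorized over `r`.
#' @export
cv_sq_lower_bound <- function(r, n) {
  if (any(r < 0 | r > 1)) stop("`r` must lie in [0, 1]", call. = FALSE)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  (r - 1)^2 + r^2 / n
}

#' Burst statistics of the on/off promoter
#'
#' @param model an `initiation_model` with switching.
#' @return list with `duty_cycle` = k_on/(k_on + k_off) (fraction of time
#'   the gene is on), `mean_burst_size` = k1/k_off (mean initiations per
#'   on-period), and `mean_burst_interval` = 1/k_on (mean off-period, s).
#' @export
burst_statistics <- function(model) {
  stopifnot(inherits(model, "initiation_model"))
  if (!model$has_switching)
    stop("burst statistics require on/off switching", call. = FALSE)
  list(duty_cycle = model$k_on / (model$k_on + model$k_off),
       mean_burst_size = model$seq_rates[1] / model$k_off,
       mean_burst_interval = 1 / model$k_on)
}

#' Canonically ordered rate parameters
#'
#' Sequential step order is unidentifiable (steps in series commute), so
#' reported step rates are sorted descending (fastest first); switching
#' rates, if present, come first.
#'
#' @param model an `initiation_model`.
#' @return named numeric vector of rates (1/s).
#' @export
coef_canonical <- function(model) {
  stopifnot(inherits(model, "initiation_model"))
  k <- sort(model$seq_rates, decreasing = TRUE)
  names(k) <- paste0("k", seq_along(k))
  if (model$has_switching) c(k_on = model$k_on, k_off = model$k_off, k)
  else k
}
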