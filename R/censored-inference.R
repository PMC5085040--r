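#' Validate and normalize a table of interval records
#'
#' @param records data.frame with at least `lb_s` and `ub_s` columns
#'   (`ub_s = Inf` marks a right-censored interval).
#' @return the validated data.frame.
#' @export
as_interval_records <- function(records) {
  if (!is.data.frame(records) || !all(c("lb_s", "ub_s") %in% names(records)))
    stop("records must be a data.frame with columns `lb_s` and `ub_s`",
         call. = FALSE)
  if (nrow(records) < 1) stop("at least one record is required", call. = FALSE)
  bad <- which(!(records$lb_s >= 0 & records$lb_s < records$ub_s))
  if (length(bad))
    stop("malformed records (need 0 <= lb < ub) at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  records
}

# Collapse records to unique (lb, ub) pairs with counts; the censored
# likelihood only needs the survival function at the distinct bounds.
.aggregate_records <- function(records) {
  records <- as_interval_records(records)
  cens <- !is.finite(records$ub_s)
  key <- paste(records$lb_s, records$ub_s)
  agg <- stats::aggregate(list(n = rep(1L, nrow(records))),
                          by = list(lb = records$lb_s, ub = records$ub_s,
                                    cens = cens), FUN = sum)
  times <- sort(unique(c(agg$lb, agg$ub[is.finite(agg$ub)])))
  list(lb = agg$lb, ub = agg$ub, n = agg$n, cens = agg$cens,
       times = times,
       i_lb = match(agg$lb, times),
       i_ub = ifelse(is.finite(agg$ub), match(agg$ub, times), NA_integer_),
       n_exact = sum(records$lb_s >= 0 & is.finite(records$ub_s)),
       n_censored = sum(cens))
}

# Survival-function factory: returns function(t_vec) -> S(t_vec)
.surv_fun <- function(object) {
  if (inherits(object, "initiation_model")) {
    cw <- .closed_surv_weights(object$k_on, object$k_off, object$seq_rates)
    if (!is.null(cw)) return(function(t) .closed_surv_eval(cw, t))
    object <- build_phase_type(object)
  }
  if (inherits(object, "phase_type")) {
    dec <- .pt_spectral(object)
    if (!is.null(dec))
      return(function(t) pmin(pmax(.pt_mix_eval(dec$lambda, dec$w_surv, t), 0), 1))
    return(function(t) pmin(pmax(.pt_expm_eval(object, t, "surv"), 0), 1))
  }
  if (is.list(object) && identical(object$dist, "gamma"))
    return(function(t) stats::pgamma(t, shape = object$shape,
                                     rate = object$rate, lower.tail = FALSE))
  stop("unsupported model object for the censored likelihood", call. = FALSE)
}

.ll_from_S <- function(S, agg, floor_p = 0) {
  p <- numeric(length(agg$n))
  b <- !agg$cens
  p[b] <- S[agg$i_lb[b]] -
    ifelse(is.na(agg$i_ub[b]), 0, S[agg$i_ub[b]])  # bounded with ub=Inf -> F mass
  p[!b] <- S[agg$i_lb[!b]]
  if (floor_p > 0) p <- pmax(p, floor_p)
  if (any(p <= 0)) return(-Inf)
  sum(agg$n * log(p))
}

.loglik_agg <- function(surv, agg, floor_p = 0) {
  .ll_from_S(surv(agg$times), agg, floor_p)
}

# Fast model log-likelihood on aggregated records: closed-form survival
# mixture when poles are distinct, matrix path otherwise.
.model_loglik_fast <- function(k_on, k_off, kseq, agg, floor_p = 1e-300) {
  cw <- .closed_surv_weights(k_on, k_off, kseq)
  if (!is.null(cw)) return(.ll_from_S(.closed_surv_eval(cw, agg$times),
                                      agg, floor_p))
  m <- if (is.null(k_on)) initiation_model(kseq)
       else initiation_model(kseq, k_on = k_on, k_off = k_off)
  .loglik_agg(.surv_fun(build_phase_type(m)), agg, floor_p)
}

#' Censoring-aware log-likelihood of interval records
#'
#' Bounded records (lb, ub\] contribute log(F(ub) - F(lb)); right-censored
#' records contribute log(1 - F(lb)), under the interval distribution of
#' the given model.
#'
#' @param object an `initiation_model`, `phase_type`, or a gamma spec
#'   `list(dist = "gamma", shape =, rate =)`.
#' @param records interval records (see [as_interval_records()]).
#' @return the log-likelihood; `-Inf` if any record has zero probability.
#' @export
censored_loglik <- function(object, records) {
  agg <- .aggregate_records(records)
  .loglik_agg(.surv_fun(object), agg)
}

.rate_bounds <- c(lower = 1e-7, upper = 10)  # 1/s

.theta_to_model <- function(theta, structure) {
  k <- exp(theta)
  if (structure$switching)
    initiation_model(seq_rates = k[-(1:2)], k_on = k[1], k_off = k[2])
  else
    initiation_model(seq_rates = k)
}

.theta_names <- function(structure) {
  nm <- paste0("log_k", seq_len(structure$n_steps))
  if (structure$switching) c("log_k_on", "log_k_off", nm) else nm
}

# Multi-start bounded maximization of a negative log-likelihood over
# log-parameters. Starts: caller-supplied heuristic rows + seeded Latin
# hypercube over the box. Returns best optimum and diagnostics.
.multistart_optim <- function(negll, p, n_starts, seed, heuristic = NULL,
                              lower = log(.rate_bounds[["lower"]]),
                              upper = log(.rate_bounds[["upper"]]),
                              maxit = 400L) {
  if (!is.null(seed)) set.seed(seed)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  n_lhs <- max(0L, n_starts - NROW(heuristic))
  starts <- heuristic
  if (n_lhs > 0) {
    u <- lhs::randomLHS(n_lhs, p)
    lhs_pts <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
    starts <- rbind(starts, lhs_pts)
  }
  starts <- t(pmin(pmax(t(starts), lower + 1e-8), upper - 1e-8))
  starts <- matrix(starts, ncol = p)
  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_used <- n_used + 1L
    if (is.null(best) || res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && res$convergence == 0 &&
         best$convergence != 0))
      best <- res
  }
  if (is.null(best))
    return(list(par = rep(NA_real_, p), value = Inf, convergence = 99L,
                n_starts_used = 0L))
  # polish: if the incumbent hit the iteration cap, restart from it
  tries <- 0L
  while (best$convergence != 0L && tries < 3L) {
    res <- tryCatch(
      stats::optim(best$par, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) break
    if (res$value <= best$value + 1e-12) best <- res
    tries <- tries + 1L
  }
  # accept a KKT point the optimizer flagged (e.g. abnormal line-search
  # termination on a flat ridge): projected gradient ~ 0 at the incumbent
  if (best$convergence != 0L && all(is.finite(best$par))) {
    g <- tryCatch(pracma::grad(negll, best$par), error = function(e) NULL)
    if (!is.null(g) && all(is.finite(g))) {
      viol <- ifelse(best$par <= lower + 1e-6, pmin(g, 0),
                     ifelse(best$par >= upper - 1e-6, pmax(g, 0), g))
      if (max(abs(viol)) < 0.05) best$convergence <- 0L
    }
  }
  best$n_starts_used <- n_used
  best
}

.observed_information_cov <- function(negll, theta) {
  H <- tryCatch(pracma::hessian(negll, theta), error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H)))
    return(list(cov = matrix(NA_real_, length(theta), length(theta)),
                singular = TRUE))
  H <- (H + t(H)) / 2
  singular <- rcond(H) < 1e-10 || any(eigen(H, only.values = TRUE)$values <= 0)
  cov <- if (singular) MASS::ginv(H) else solve(H)
  cov <- (cov + t(cov)) / 2
  list(cov = cov, singular = singular)
}

#' Maximum-likelihood fit of an initiation model to censored intervals
#'
#' Maximizes the censored log-likelihood over log-rates (bounded to rates
#' in \[1e-7, 10\] 1/s) with multi-start local optimization (one
#' moment-matched start plus a seeded Latin hypercube).  The covariance is
#' the inverse numerical observed information at the optimum
#' (pseudo-inverse, flagged, when near-singular — interchangeable steps
#' create flat directions).
#'
#' @param records interval records.
#' @param structure a [model_structure()].
#' @param n_starts number of optimizer starts.
#' @param seed integer seed for the start design.
#' @param maxit per-start iteration cap.
#' @param extra_starts optional matrix of additional start points (rows of
#'   log-rates), e.g. warm starts from nested fits.
#' @return object of class `interval_fit`: `model_spec`, `estimates`
#'   (named log-rates, raw fitted order), `model` (an `initiation_model`),
#'   `loglik`, `covariance`, `df`, `n_exact`, `n_censored`, `converged`,
#'   `n_starts_used`, `singular_information`.
#' @export
fit_model <- function(records, structure, n_starts = 20L, seed = 1L,
                      maxit = 400L, extra_starts = NULL) {
  stopifnot(inherits(structure, "model_structure") || is.list(structure))
  agg <- .aggregate_records(records)
  p <- n_free_rates(structure)
  sw <- isTRUE(structure$switching)
  negll <- function(theta) {
    k <- exp(theta)
    ll <- if (sw) .model_loglik_fast(k[1], k[2], k[-(1:2)], agg)
          else .model_loglik_fast(NULL, NULL, k, agg)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  # moment-matched heuristic start: crude mean from interval midpoints.
  # Step rates are jittered so equal-rate (defective-eigenbasis) starts do
  # not force the slow matrix-exponential fallback.
  mids <- ifelse(is.finite(agg$ub), (agg$lb + agg$ub) / 2, agg$lb)
  mhat <- max(stats::weighted.mean(mids, agg$n), 1)
  jit <- seq(-0.15, 0.15, length.out = structure$n_steps)
  h1 <- log(rep(structure$n_steps / mhat, structure$n_steps)) + jit
  heur <- if (structure$switching)
    rbind(c(log(1 / mhat), log(4 / mhat), h1),
          c(log(0.2 / mhat), log(10 / mhat), h1 + log(2)))
  else rbind(h1, h1 + log(2))
  if (!is.null(extra_starts)) heur <- rbind(matrix(extra_starts, ncol = p), heur)
  best <- .multistart_optim(negll, p, n_starts, seed, heuristic = heur,
                            maxit = maxit)
  theta <- best$par
  names(theta) <- .theta_names(structure)
  info <- if (all(is.finite(theta))) .observed_information_cov(negll, theta)
          else list(cov = matrix(NA_real_, p, p), singular = TRUE)
  model <- if (all(is.finite(theta))) .theta_to_model(theta, structure)
  out <- list(model_spec = structure, estimates = theta, model = model,
              loglik = -best$value, covariance = info$cov, df = p,
              n_exact = agg$n_exact, n_censored = agg$n_censored,
              converged = best$convergence == 0L && all(is.finite(theta)),
              n_starts_used = best$n_starts_used,
              singular_information = info$singular)
  class(out) <- "interval_fit"
  out
}

#' @export
print.interval_fit <- function(x, ...) {
  lbl <- if (inherits(x$model_spec, "model_structure")) format(x$model_spec)
         else "custom"
  cat(sprintf("censored ML fit (%s): loglik %.3f, %d exact + %d censored records\n",
              lbl, x$loglik, x$n_exact, x$n_censored))
  if (!is.null(x$model) && inherits(x$model, "initiation_model")) {
    k <- coef_canonical(x$model)
    cat("  rates (1/s): ",
        paste(sprintf("%s=%.4g", names(k), k), collapse = ", "), "\n")
  }
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Censored maximum-likelihood gamma fit and descriptive moments
#'
#' Fits a gamma distribution to the records under the same
#' interval/right-censoring likelihood (no moment matching: a model must
#' be assumed to estimate moments from censored data).  The gamma can have
#' any mean and sd independently, so it serves as the model-free
#' descriptive summary of each condition.
#'
#' @inheritParams fit_model
#' @return an `interval_fit` with `model_spec = "gamma"`, plus a
#'   `moments` field (`moments_summary`: mean, sd, cv, median/mean of the
#'   fitted gamma).
#' @export
fit_censored_gamma <- function(records, n_starts = 10L, seed = 1L,
                               maxit = 400L) {
  agg <- .aggregate_records(records)
  if (agg$n_exact == 0)
    stop("all records are right-censored: gamma moments are not identifiable",
         call. = FALSE)
  negll <- function(theta) {
    g <- list(dist = "gamma", shape = exp(theta[1]), rate = exp(theta[2]))
    ll <- .loglik_agg(.surv_fun(g), agg, floor_p = 1e-300)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  mids <- ifelse(is.finite(agg$ub), (agg$lb + agg$ub) / 2, agg$lb)
  mhat <- max(stats::weighted.mean(mids, agg$n), 1)
  heur <- rbind(c(0, log(1 / mhat)), c(log(2), log(2 / mhat)))
  best <- .multistart_optim(negll, 2L, n_starts, seed, heuristic = heur,
                            lower = c(log(1e-3), log(1e-7)),
                            upper = c(log(1e3), log(10)), maxit = maxit)
  theta <- best$par
  names(theta) <- c("log_shape", "log_rate")
  negll2 <- negll
  info <- .observed_information_cov(negll2, theta)
  shape <- exp(theta[[1]]); rate <- exp(theta[[2]])
  mom <- structure(list(
    mean = shape / rate, sd = sqrt(shape) / rate, cv = 1 / sqrt(shape),
    cv_sq = 1 / shape,
    median_to_mean = stats::qgamma(0.5, shape, rate) / (shape / rate)),
    class = "moments_summary")
  out <- list(model_spec = "gamma", estimates = theta,
              model = list(dist = "gamma", shape = shape, rate = rate),
              loglik = -best$value, covariance = info$cov, df = 2L,
              n_exact = agg$n_exact, n_censored = agg$n_censored,
              converged = best$convergence == 0L && all(is.finite(theta)),
              n_starts_used = best$n_starts_used,
              singular_information = info$singular, moments = mom)
  class(out) <- "interval_fit"
  out
}

#' Delta-method uncertainty of a transformed estimate
#'
#' Propagates the fit covariance through a differentiable transform of
#' the estimated (log-scale) parameter vector:
#' sd = sqrt(g' Sigma g) with g the numerical gradient, and
#' ci95 = estimate +/- 1.96 sd.
#'
#' @param fit a converged `interval_fit` (or any list with `estimates`
#'   and `covariance`).
#' @param transform function mapping the estimate vector to a scalar.
#' @return list with `estimate`, `sd`, `ci95` (length-2 vector).
#' @export
delta_method_interval <- function(fit, transform) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged))
    stop("delta method requires a converged fit", call. = FALSE)
  theta <- fit$estimates
  est <- transform(theta)
  g <- pracma::grad(transform, theta)
  sd <- sqrt(max(0, as.numeric(t(g) %*% fit$covariance %*% g)))
  list(estimate = est, sd = sd, ci95 = c(est - 1.96 * sd, est + 1.96 * sd))
}
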