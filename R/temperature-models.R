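#' Polynomial inverse-rate temperature law
#'
#' Each kinetic parameter's inverse rate is a polynomial in temperature:
#' \deqn{k_x(T)^{-1} = A T^2 + B T + C,\quad T\ \mathrm{in\ ^\circ C}}
#' Order 0 (constant), 1 (linear) or 2 (quadratic) per parameter.  The
#' polynomial form is deliberately phenomenological: with few points on
#' the temperature axis it can represent independence, linear, or
#' nonlinear (bitonic) responses without committing to a biochemical
#' (e.g. Arrhenius) mechanism.
#'
#' @param ... named numeric vectors, one per parameter (`k_on`, `k_off`,
#'   `k1`, `k2`, `k3`): length 1 = `C`, length 2 = `(B, C)`,
#'   length 3 = `(A, B, C)`, seconds-based units.
#' @return object of class `temperature_law`: named list of `c(A, B, C)`.
#' @examples
#' temperature_law(k1 = c(2, -130, 3600), k_on = 2000, k_off = 50)
#' @export
temperature_law <- function(...) {
  entries <- list(...)
  if (is.null(names(entries)) || any(names(entries) == ""))
    stop("all law entries must be named after model parameters", call. = FALSE)
  law <- lapply(entries, function(v) {
    v <- as.numeric(v)
    if (!length(v) %in% 1:3)
      stop("each entry needs 1-3 coefficients", call. = FALSE)
    c(rep(0, 3 - length(v)), v)  # pad to (A, B, C)
  })
  class(law) <- "temperature_law"
  law
}

#' Evaluate a rate from a temperature law
#'
#' @param law a [temperature_law()].
#' @param parameter parameter name present in the law.
#' @param T temperature (degrees C); vectorized.
#' @return rate(s) in 1/s; errors if the inverse-rate polynomial is
#'   non-positive at any requested temperature.
#' @export
eval_rate <- function(law, parameter, T) {
  stopifnot(inherits(law, "temperature_law"))
  co <- law[[parameter]]
  if (is.null(co)) stop("parameter `", parameter, "` not in law", call. = FALSE)
  inv <- co[1] * T^2 + co[2] * T + co[3]
  if (any(inv <= 0))
    stop("inverse rate for `", parameter,
         "` is non-positive at T = ",
         paste(T[inv <= 0], collapse = ", "), call. = FALSE)
  1 / inv
}

#' Instantiate an initiation model at a temperature
#'
#' @param law a [temperature_law()] containing `k1` (and optionally
#'   `k_on`/`k_off`, `k2`, `k3`).
#' @param T temperature (degrees C).
#' @return an [initiation_model()].
#' @export
model_at_temperature <- function(law, T) {
  nm <- names(law)
  seq_nm <- intersect(c("k1", "k2", "k3"), nm)
  if (!"k1" %in% seq_nm) stop("law must contain `k1`", call. = FALSE)
  k <- vapply(seq_nm, function(p) eval_rate(law, p, T), numeric(1))
  if (all(c("k_on", "k_off") %in% nm))
    initiation_model(seq_rates = k, k_on = eval_rate(law, "k_on", T),
                     k_off = eval_rate(law, "k_off", T))
  else
    initiation_model(seq_rates = k)
}

#' Serialize a temperature law as a coefficient table
#' @param law a [temperature_law()].
#' @return data.frame with columns `parameter`, `A`, `B`, `C`
#'   (inverse rate = A T^2 + B T + C).
#' @export
law_coefficients <- function(law) {
  stopifnot(inherits(law, "temperature_law"))
  data.frame(parameter = names(law),
             A = vapply(law, `[`, numeric(1), 1),
             B = vapply(law, `[`, numeric(1), 2),
             C = vapply(law, `[`, numeric(1), 3),
             row.names = NULL, stringsAsFactors = FALSE)
}

# --- anchor reparameterization -------------------------------------------
# Polynomial coefficients are poorly conditioned in raw (A, B, C) form;
# laws are optimized as log inverse-rate values at anchor temperatures
# 24 / 32.5 / 41 C, mapped to coefficients through a Vandermonde solve.
.anchor_T <- c(24, 32.5, 41)

.poly_from_anchors <- function(vals, order) {
  if (order == 0L) return(c(0, 0, vals[1]))
  if (order == 1L) {
    Ts <- .anchor_T[c(1, 3)]
    B <- (vals[2] - vals[1]) / diff(Ts)
    return(c(0, B, vals[1] - B * Ts[1]))
  }
  V <- cbind(.anchor_T^2, .anchor_T, 1)
  as.numeric(solve(V, vals))
}

.inv_rate_at <- function(anch_log, order, T) {
  co <- .poly_from_anchors(exp(anch_log), order)
  co[1] * T^2 + co[2] * T + co[3]
}

.law_param_names <- function(structure) {
  nm <- paste0("k", seq_len(structure$n_steps))
  if (structure$switching) c("k_on", "k_off", nm) else nm
}

.log_inv_bounds <- c(lower = log(0.1), upper = log(1e7))  # inverse rates, s

# Generic joint ML over grouped records: theta -> list of models, one per
# group (NULL signals an invalid parameter point).
.fit_grouped <- function(agg_list, theta_to_models, p, n_starts, seed,
                         heuristic, lower, upper, maxit = 500L,
                         counts = NULL) {
  negll <- function(theta) {
    models <- theta_to_models(theta)
    if (is.null(models)) return(1e12)
    ll <- 0
    for (g in seq_along(agg_list)) {
      m <- models[[g]]
      if (is.null(m)) return(1e12)
      lg <- .model_loglik_fast(m$k_on, m$k_off, m$seq_rates, agg_list[[g]])
      if (!is.finite(lg)) return(1e12)
      ll <- ll + lg
    }
    -ll
  }
  best <- .multistart_optim(negll, p, n_starts, seed, heuristic = heuristic,
                            lower = lower, upper = upper, maxit = maxit)
  info <- if (all(is.finite(best$par)))
    .observed_information_cov(negll, best$par)
  else list(cov = matrix(NA_real_, p, p), singular = TRUE)
  list(best = best, cov = info$cov, singular = info$singular, negll = negll)
}

.require_cols <- function(records, cols) {
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop("records need column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' Joint censored ML fit across temperatures with a polynomial law
#'
#' A single likelihood sums the per-temperature censored log-likelihoods
#' with each parameter tied through its polynomial inverse-rate law
#' (order 0, 1 or 2 per parameter, see [temperature_law()]).  Optimized
#' in log inverse-rate values at anchor temperatures (24/32.5/41 C) for
#' conditioning; fitted laws are checked positive at all data
#' temperatures.
#'
#' @param records interval records with a `temperature_C` column.
#' @param structure a [model_structure()].
#' @param order_spec named integer vector (0/1/2) over the structure's
#'   parameters; omitted parameters default to 0 (constant).
#' @param n_starts,seed,maxit optimizer controls.
#' @param init_fit optional pooled `interval_fit` of the same structure
#'   used as a warm start.
#' @return an `interval_fit` whose `model_spec` records the structure and
#'   `order_spec`, with extra fields `law` (fitted [temperature_law()])
#'   and `temperatures`.
#' @export
fit_joint_temperature <- function(records, structure, order_spec = NULL,
                                  n_starts = 10L, seed = 1L, maxit = 500L,
                                  init_fit = NULL) {
  .require_cols(records, c("lb_s", "ub_s", "temperature_C"))
  pnames <- .law_param_names(structure)
  spec <- stats::setNames(rep(0L, length(pnames)), pnames)
  if (!is.null(order_spec)) {
    bad <- setdiff(names(order_spec), pnames)
    if (length(bad)) stop("unknown parameter(s) in order_spec: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    spec[names(order_spec)] <- as.integer(order_spec)
  }
  temps <- sort(unique(records$temperature_C))
  if (length(temps) < 2 && any(spec > 0))
    stop("non-constant temperature laws need >= 2 distinct temperatures",
         call. = FALSE)
  agg_list <- lapply(temps, function(Tc)
    .aggregate_records(records[records$temperature_C == Tc, , drop = FALSE]))
  ncoef <- spec + 1L
  offs <- c(0L, cumsum(ncoef))
  p <- sum(ncoef)
  theta_to_models <- function(theta) {
    inv <- matrix(NA_real_, length(temps), length(pnames))
    for (j in seq_along(pnames)) {
      a <- theta[(offs[j] + 1L):offs[j + 1L]]
      inv[, j] <- .inv_rate_at(a, spec[[j]], temps)
    }
    if (any(inv <= 0)) return(NULL)
    lapply(seq_along(temps), function(g) {
      k <- 1 / inv[g, ]
      names(k) <- pnames
      if (structure$switching)
        initiation_model(seq_rates = k[-(1:2)], k_on = k[["k_on"]],
                         k_off = k[["k_off"]])
      else initiation_model(seq_rates = k)
    })
  }
  heur <- .joint_heuristic(records, structure, ncoef, init_fit)
  res <- .fit_grouped(agg_list, theta_to_models, p, n_starts, seed, heur,
                      lower = .log_inv_bounds[["lower"]],
                      upper = .log_inv_bounds[["upper"]], maxit = maxit)
  theta <- res$best$par
  names(theta) <- unlist(lapply(seq_along(pnames), function(j)
    paste0("log_inv_", pnames[j], "_a", seq_len(ncoef[j]))))
  law <- NULL
  if (all(is.finite(theta))) {
    co <- lapply(seq_along(pnames), function(j)
      .poly_from_anchors(exp(theta[(offs[j] + 1L):offs[j + 1L]]), spec[[j]]))
    names(co) <- pnames
    law <- do.call(temperature_law, co)
  }
  agg_all <- .aggregate_records(records)
  out <- list(model_spec = list(structure = structure, order_spec = spec),
              estimates = theta, law = law, temperatures = temps,
              loglik = -res$best$value, covariance = res$cov, df = p,
              n_exact = agg_all$n_exact, n_censored = agg_all$n_censored,
              converged = res$best$convergence == 0L && all(is.finite(theta)),
              n_starts_used = res$best$n_starts_used,
              singular_information = res$singular)
  class(out) <- c("joint_fit", "interval_fit")
  out
}

# Warm-start rows for joint fits: replicate a pooled fit's (or a crude
# moment guess's) constant values across each parameter's anchors.
.joint_heuristic <- function(records, structure, ncoef, init_fit = NULL) {
  pnames <- .law_param_names(structure)
  base <- NULL
  if (!is.null(init_fit) && isTRUE(init_fit$converged) &&
      inherits(init_fit$model, "initiation_model")) {
    m <- init_fit$model
    v <- c(if (structure$switching) c(1 / m$k_on, 1 / m$k_off),
           1 / m$seq_rates)
    base <- log(v)
  }
  mids <- ifelse(is.finite(records$ub_s),
                 (records$lb_s + records$ub_s) / 2, records$lb_s)
  mhat <- max(mean(mids), 1)
  crude <- log(c(if (structure$switching) c(mhat, mhat / 4),
                 rep(mhat / structure$n_steps, structure$n_steps)))
  rows <- list(crude, crude + log(2))
  if (!is.null(base)) rows <- c(list(base), rows)
  do.call(rbind, lapply(rows, function(r) rep(r, times = ncoef)))
}

#' Select the temperature-dependence structure by BIC
#'
#' Enumerates candidate order specifications (by default: all parameters
#' constant, plus one parameter at a time linear or quadratic), fits each
#' jointly across temperatures, and ranks by BIC with the Delta-BIC lower
#' bound.  The restricted lattice matches the comparisons of interest
#' while bounding compute; `lattice = "full"` fits all order
#' combinations.
#'
#' @inheritParams fit_joint_temperature
#' @param lattice `"one-at-a-time"` or `"full"`.
#' @param params parameters allowed to vary (default: all).
#' @return a `model_comparison` over order specifications.
#' @export
select_temperature_model <- function(records, structure,
                                     lattice = c("one-at-a-time", "full"),
                                     params = NULL, n_starts = 8L, seed = 1L,
                                     maxit = 500L) {
  lattice <- match.arg(lattice)
  pnames <- .law_param_names(structure)
  if (is.null(params)) params <- pnames
  specs <- list(stats::setNames(integer(0), character(0)))
  labels <- "all constant"
  if (lattice == "one-at-a-time") {
    for (pp in params) for (o in 1:2) {
      specs[[length(specs) + 1L]] <- stats::setNames(o, pp)
      labels <- c(labels, paste0(pp, ": ", c("linear", "quadratic")[o]))
    }
  } else {
    grid <- expand.grid(rep(list(0:2), length(pnames)))
    names(grid) <- pnames
    grid <- grid[rowSums(grid) > 0, , drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      sp <- unlist(grid[i, , drop = TRUE])
      specs[[length(specs) + 1L]] <- sp[sp > 0]
      labels <- c(labels, paste(paste0(names(sp)[sp > 0], ":",
                                       c("lin", "quad")[sp[sp > 0]]),
                                collapse = ","))
    }
  }
  pooled <- fit_model(records, structure, n_starts = max(n_starts, 8L),
                      seed = seed, maxit = maxit)
  fits <- lapply(seq_along(specs), function(i)
    fit_joint_temperature(records, structure, order_spec = specs[[i]],
                          n_starts = n_starts, seed = seed + i,
                          maxit = maxit, init_fit = pooled))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(ok))
    warning("non-convergent specs excluded: ",
            paste(labels[!ok], collapse = "; "), call. = FALSE)
  rank_comparison(fits[ok], labels[ok])
}

#' Shared shape-up-to-scale fit of the first-step law across schemes
#'
#' Tests whether one temperature response drives all induction schemes:
#' the first-step inverse rate is constrained to
#' \eqn{k_1^{-1}(T, s) = c_s\, g(T)} with a single quadratic shape g(T)
#' shared by all schemes and one positive scale per scheme (the reference
#' scheme's scale fixed to 1 for identifiability); all other parameters
#' are per-scheme constants.
#'
#' @param records interval records with `temperature_C` and `scheme`
#'   columns.
#' @param structure a [model_structure()].
#' @param reference reference scheme (scale 1); default `"Full"` if
#'   present, else the first scheme.
#' @param n_starts,seed,maxit optimizer controls.
#' @param init_fit optional pooled warm start.
#' @return an `interval_fit` with extra fields `shape_coefficients`
#'   (quadratic A, B, C of g), `scales` (named, reference = 1), and
#'   `schemes`.
#' @export
fit_shared_shape <- function(records, structure, reference = NULL,
                             n_starts = 10L, seed = 1L, maxit = 600L,
                             init_fit = NULL) {
  .require_cols(records, c("lb_s", "ub_s", "temperature_C", "scheme"))
  schemes <- unique(records$scheme)
  if (length(schemes) < 1) stop("no schemes present", call. = FALSE)
  if (length(schemes) == 1)
    return(fit_joint_temperature(records, structure,
                                 order_spec = stats::setNames(2L, "k1"),
                                 n_starts = n_starts, seed = seed,
                                 maxit = maxit, init_fit = init_fit))
  if (is.null(reference))
    reference <- if ("Full" %in% schemes) "Full" else schemes[1]
  if (!reference %in% schemes) stop("reference scheme not present", call. = FALSE)
  schemes <- c(reference, setdiff(schemes, reference))
  pnames <- .law_param_names(structure)
  other <- setdiff(pnames, "k1")
  groups <- unique(records[, c("scheme", "temperature_C")])
  groups <- groups[order(match(groups$scheme, schemes), groups$temperature_C), ]
  agg_list <- lapply(seq_len(nrow(groups)), function(i)
    .aggregate_records(records[records$scheme == groups$scheme[i] &
                               records$temperature_C == groups$temperature_C[i],
                               , drop = FALSE]))
  S <- length(schemes)
  p <- 3L + (S - 1L) + S * length(other)
  # theta: [log g anchors (3)] [log c_s, s != ref] [per-scheme log inv other]
  idx_scales <- 3L + seq_len(S - 1L)
  idx_other <- function(s_i, o_i) 3L + (S - 1L) + (s_i - 1L) * length(other) + o_i
  theta_to_models <- function(theta) {
    g <- .inv_rate_at(theta[1:3], 2L, groups$temperature_C)
    if (any(g <= 0)) return(NULL)
    sc <- c(1, exp(theta[idx_scales]))
    names(sc) <- schemes
    lapply(seq_len(nrow(groups)), function(i) {
      s_i <- match(groups$scheme[i], schemes)
      inv1 <- unname(sc[s_i]) * g[i]
      k <- c(k1 = 1 / inv1)
      for (o_i in seq_along(other))
        k[other[o_i]] <- exp(-theta[idx_other(s_i, o_i)])
      seqk <- k[intersect(c("k1", "k2", "k3"), names(k))]
      if (structure$switching)
        initiation_model(seq_rates = seqk, k_on = k[["k_on"]],
                         k_off = k[["k_off"]])
      else initiation_model(seq_rates = seqk)
    })
  }
  mids <- ifelse(is.finite(records$ub_s),
                 (records$lb_s + records$ub_s) / 2, records$lb_s)
  mhat <- max(mean(mids), 1)
  base_other <- log(c(k_on = mhat, k_off = mhat / 4, k2 = mhat / 2,
                      k3 = mhat / 2)[other])
  if (!is.null(init_fit) && isTRUE(init_fit$converged) &&
      inherits(init_fit$model, "initiation_model")) {
    m <- init_fit$model
    iv <- c(k_on = if (structure$switching) 1 / m$k_on else NA,
            k_off = if (structure$switching) 1 / m$k_off else NA,
            k2 = if (structure$n_steps >= 2) 1 / m$seq_rates[2] else NA,
            k3 = if (structure$n_steps >= 3) 1 / m$seq_rates[3] else NA)
    base_other <- log(iv[other])
    ganch <- rep(log(1 / m$seq_rates[1]), 3)
  } else {
    ganch <- rep(log(mhat / structure$n_steps), 3)
  }
  heur <- rbind(c(ganch, rep(0, S - 1L), rep(base_other, S)),
                c(ganch + log(1.5), rep(log(1.2), S - 1L),
                  rep(base_other, S) + log(0.8)))
  lower <- c(rep(.log_inv_bounds[["lower"]], 3), rep(log(1e-3), S - 1L),
             rep(.log_inv_bounds[["lower"]], S * length(other)))
  upper <- c(rep(.log_inv_bounds[["upper"]], 3), rep(log(1e3), S - 1L),
             rep(.log_inv_bounds[["upper"]], S * length(other)))
  res <- .fit_grouped(agg_list, theta_to_models, p, n_starts, seed, heur,
                      lower = lower, upper = upper, maxit = maxit)
  theta <- res$best$par
  other_names <- if (length(other))
    unlist(lapply(schemes, function(s) paste0("log_inv_", other, "_", s)))
  else character(0)
  names(theta) <- c(paste0("log_g_a", 1:3),
                    paste0("log_scale_", schemes[-1]), other_names)
  agg_all <- .aggregate_records(records)
  sc <- c(1, exp(theta[idx_scales])); names(sc) <- schemes
  out <- list(model_spec = list(structure = structure, kind = "shared_shape"),
              estimates = theta,
              shape_coefficients =
                if (all(is.finite(theta[1:3])))
                  .poly_from_anchors(exp(theta[1:3]), 2L),
              scales = sc, schemes = schemes,
              loglik = -res$best$value, covariance = res$cov, df = p,
              n_exact = agg_all$n_exact, n_censored = agg_all$n_censored,
              converged = res$best$convergence == 0L && all(is.finite(theta)),
              n_starts_used = res$best$n_starts_used,
              singular_information = res$singular)
  class(out) <- c("joint_fit", "interval_fit")
  out
}

#' Relative RNA-polymerase abundance profile
#'
#' Western-blot derived relative RpoC abundance versus temperature
#' (RpoC limits holoenzyme assembly, so it proxies the active RNA
#' polymerase concentration R).  Between measured temperatures R(T) is
#' piecewise-linear; extrapolation outside the measured hull is refused.
#'
#' @param temperature_C measured temperatures (degrees C).
#' @param relative_abundance relative abundances (reference = 1).
#' @return object of class `rnap_profile`.
#' @export
rnap_profile <- function(temperature_C, relative_abundance) {
  if (length(temperature_C) != length(relative_abundance) ||
      length(temperature_C) < 1)
    stop("temperatures and abundances must match in length", call. = FALSE)
  if (any(relative_abundance <= 0))
    stop("relative abundances must be positive", call. = FALSE)
  if (!any(abs(relative_abundance - 1) < 1e-12))
    stop("profile must contain a reference temperature with abundance 1",
         call. = FALSE)
  ord <- order(temperature_C)
  out <- list(temperature_C = temperature_C[ord],
              relative_abundance = relative_abundance[ord])
  class(out) <- "rnap_profile"
  out
}

#' Evaluate a relative-abundance profile
#' @param profile an [rnap_profile()].
#' @param T temperatures (degrees C); must lie within the measured hull.
#' @return interpolated relative abundance R(T).
#' @export
eval_rnap <- function(profile, T) {
  stopifnot(inherits(profile, "rnap_profile"))
  if (any(T < min(profile$temperature_C) | T > max(profile$temperature_C)))
    stop("temperature outside the measured RNAP profile hull", call. = FALSE)
  stats::approx(profile$temperature_C, profile$relative_abundance,
                xout = T, rule = 1)$y
}

#' RNA-polymerase-constrained joint fit
#'
#' Tests whether the first step's temperature response is explained
#' solely by RNA polymerase abundance: constrains
#' \eqn{k_1(T) = \tilde k_1 R(T)} with a single free constant
#' \eqn{\tilde k_1} and R(T) from the measured profile; all other
#' parameters are temperature-constant.
#'
#' @param records interval records with a `temperature_C` column.
#' @param structure a [model_structure()].
#' @param profile an [rnap_profile()].
#' @param n_starts,seed,maxit optimizer controls.
#' @param init_fit optional pooled warm start.
#' @return an `interval_fit` with extra field `k1_tilde` (1/s per unit
#'   relative abundance).
#' @export
fit_rnap_constrained <- function(records, structure, profile,
                                 n_starts = 10L, seed = 1L, maxit = 500L,
                                 init_fit = NULL) {
  .require_cols(records, c("lb_s", "ub_s", "temperature_C"))
  stopifnot(inherits(profile, "rnap_profile"))
  temps <- sort(unique(records$temperature_C))
  R <- eval_rnap(profile, temps)
  pnames <- .law_param_names(structure)
  other <- setdiff(pnames, "k1")
  agg_list <- lapply(temps, function(Tc)
    .aggregate_records(records[records$temperature_C == Tc, , drop = FALSE]))
  p <- 1L + length(other)
  theta_to_models <- function(theta) {
    k1t <- exp(theta[1])
    ko <- exp(-theta[-1])  # theta holds log inverse rates for the others
    names(ko) <- other
    lapply(seq_along(temps), function(g) {
      k <- c(k1 = k1t * R[g], ko)
      seqk <- k[intersect(c("k1", "k2", "k3"), names(k))]
      if (structure$switching)
        initiation_model(seq_rates = seqk, k_on = k[["k_on"]],
                         k_off = k[["k_off"]])
      else initiation_model(seq_rates = seqk)
    })
  }
  mids <- ifelse(is.finite(records$ub_s),
                 (records$lb_s + records$ub_s) / 2, records$lb_s)
  mhat <- max(mean(mids), 1)
  base_other <- log(c(k_on = mhat, k_off = mhat / 4, k2 = mhat / 2,
                      k3 = mhat / 2)[other])
  k1g <- log(structure$n_steps / mhat)
  if (!is.null(init_fit) && isTRUE(init_fit$converged) &&
      inherits(init_fit$model, "initiation_model")) {
    m <- init_fit$model
    k1g <- log(m$seq_rates[1])
    iv <- c(k_on = if (structure$switching) 1 / m$k_on else NA,
            k_off = if (structure$switching) 1 / m$k_off else NA,
            k2 = if (structure$n_steps >= 2) 1 / m$seq_rates[2] else NA,
            k3 = if (structure$n_steps >= 3) 1 / m$seq_rates[3] else NA)
    base_other <- log(iv[other])
  }
  heur <- rbind(c(k1g, base_other), c(k1g + log(2), base_other + log(0.8)))
  lower <- c(log(1e-7), rep(.log_inv_bounds[["lower"]], length(other)))
  upper <- c(log(10), rep(.log_inv_bounds[["upper"]], length(other)))
  res <- .fit_grouped(agg_list, theta_to_models, p, n_starts, seed, heur,
                      lower = lower, upper = upper, maxit = maxit)
  theta <- res$best$par
  names(theta) <- c("log_k1_tilde",
                    if (length(other)) paste0("log_inv_", other))
  agg_all <- .aggregate_records(records)
  out <- list(model_spec = list(structure = structure, kind = "rnap_constrained"),
              estimates = theta,
              k1_tilde = exp(theta[[1]]), temperatures = temps,
              loglik = -res$best$value, covariance = res$cov, df = p,
              n_exact = agg_all$n_exact, n_censored = agg_all$n_censored,
              converged = res$best$convergence == 0L && all(is.finite(theta)),
              n_starts_used = res$best$n_starts_used,
              singular_information = res$singular)
  class(out) <- c("joint_fit", "interval_fit")
  out
}
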