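#' Bayesian information criterion with censored-sample weighting
#'
#' BIC = -2 loglik + p log(n_eff), where the effective sample size counts
#' each right-censored record as `censored_weight` exact samples
#' (default 0.5: a censored interval carries roughly half the information
#' of an exactly observed one; the true worth depends on how badly the
#' sample is censored, which motivates the lower bound of
#' [delta_bic_with_lb()]).
#'
#' @param fit an `interval_fit` (needs `loglik`, `df`, `n_exact`,
#'   `n_censored`).
#' @param censored_weight worth of one censored sample, in \[0, 1\].
#' @return the BIC value.
#' @export
bic <- function(fit, censored_weight = 0.5) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged))
    stop("BIC requires a converged fit", call. = FALSE)
  n_eff <- fit$n_exact + censored_weight * fit$n_censored
  if (n_eff < 1) stop("effective sample size below 1", call. = FALSE)
  -2 * fit$loglik + fit$df * log(n_eff)
}

#' Delta-BIC between two fits with its censoring-worth lower bound
#'
#' The headline Delta-BIC uses censored weight 0.5.  Because the worth of
#' a censored sample is itself uncertain, the lower bound takes the worst
#' case over the weight w in \[0, 1\]: with the better model (at w = 0.5)
#' held fixed as reference, Delta-BIC(w) is monotone in w, so the minimum
#' is attained at an endpoint.
#'
#' @param fit_a,fit_b two `interval_fit`s of the same data.
#' @return list: `delta_bic`, `delta_bic_lb`, `better` (`"a"` or `"b"`).
#' @export
delta_bic_with_lb <- function(fit_a, fit_b) {
  if (fit_a$n_exact != fit_b$n_exact || fit_a$n_censored != fit_b$n_censored)
    stop("fits are not of the same data (sample counts differ)", call. = FALSE)
  d_half <- bic(fit_b, 0.5) - bic(fit_a, 0.5)
  if (d_half >= 0) { better <- fit_a; worse <- fit_b; lab <- "a" }
  else { better <- fit_b; worse <- fit_a; lab <- "b" }
  dd <- function(w) bic(worse, w) - bic(better, w)
  list(delta_bic = dd(0.5), delta_bic_lb = min(dd(0), dd(1)), better = lab)
}

.evidence_grade <- function(delta) {
  if (!is.finite(delta)) return(NA_character_)
  if (delta < 2) "weak" else if (delta < 6) "positive" else "strong"
}

#' Exhaustive structure selection over the candidate model lattice
#'
#' Fits every candidate structure (by default, with/without on/off
#' switching crossed with 1-3 sequential steps), ranks by BIC (censored
#' weight 0.5), and grades the evidence for the winner against the
#' second-best by Delta-BIC: 0-2 weak, 2-6 positive, >= 6 strong.
#' BIC ties below 1e-6 break toward fewer parameters.  Non-convergent
#' candidates are excluded with a warning.
#'
#' @param records interval records.
#' @param candidates list of [model_structure()]s.
#' @param n_starts,seed,maxit passed to [fit_model()].
#' @return object of class `model_comparison`: `candidates` (list of
#'   fits), `table` (data.frame: structure, df, loglik, bic, delta_bic,
#'   delta_bic_lb, evidence), `best` (index into `candidates`),
#'   `delta_bic_second_best`, `delta_bic_lb`, `evidence_grade`.
#' @export
select_structure <- function(records,
                             candidates = default_candidates(),
                             n_starts = 12L, seed = 1L, maxit = 400L) {
  # fit in order of increasing complexity, warm-starting each candidate
  # from already-fitted nested structures (tempers multimodality and lets
  # small n_starts suffice)
  ord <- order(vapply(candidates, n_free_rates, integer(1)))
  fits <- vector("list", length(candidates))
  for (i in ord) {
    st <- candidates[[i]]
    warm <- list()
    for (j in ord) {
      fj <- fits[[j]]
      if (is.null(fj) || !isTRUE(fj$converged)) next
      w <- .promote_theta(fj$estimates, candidates[[j]], st)
      if (!is.null(w)) warm[[length(warm) + 1L]] <- w
    }
    fits[[i]] <- fit_model(records, st, n_starts = n_starts,
                           seed = seed + i, maxit = maxit,
                           extra_starts = if (length(warm))
                             do.call(rbind, warm))
  }
  labels <- vapply(candidates, format, character(1))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(ok))
    warning("non-convergent candidates excluded: ",
            paste(labels[!ok], collapse = ", "), call. = FALSE)
  if (!any(ok)) stop("no candidate converged", call. = FALSE)
  rank_comparison(fits[ok], labels[ok])
}

# Map a fitted theta from one structure into a start point for a larger
# structure: added steps start fast (weakly rate-limiting), added
# switching starts with a high duty cycle (nearly always on).  Returns
# NULL when `from` does not nest in `to`.
.promote_theta <- function(theta, from, to) {
  if (from$n_steps > to$n_steps) return(NULL)
  if (from$switching && !to$switching) return(NULL)
  up <- log(.rate_bounds[["upper"]])
  seq_from <- if (from$switching) theta[-(1:2)] else theta
  sw_from <- if (from$switching) theta[1:2]
  # added steps start at the fast bound (negligible duration), so the
  # warm start reproduces the nested optimum and dominance is preserved
  n_add <- to$n_steps - from$n_steps
  seq_to <- c(seq_from, up - 0.02 - 0.05 * seq_len(n_add))
  sw_to <- if (to$switching) {
    if (from$switching) sw_from
    else c(up - 0.02, log(.rate_bounds[["lower"]]) + 0.02)  # switch ~always on
  }
  pmin(pmax(c(sw_to, seq_to), log(.rate_bounds[["lower"]]) + 0.01),
       up - 0.01)
}

#' Default candidate lattice: {no switching, switching} x {1, 2, 3 steps}
#' @return list of [model_structure()]s.
#' @export
default_candidates <- function() {
  out <- list()
  for (sw in c(FALSE, TRUE)) for (m in 1:3)
    out[[length(out) + 1L]] <- model_structure(sw, m)
  out
}

#' Rank a set of converged fits of the same data by BIC
#'
#' @param fits list of `interval_fit`s of the same records.
#' @param labels character labels, one per fit.
#' @return a `model_comparison` (see [select_structure()]).
#' @export
rank_comparison <- function(fits, labels = NULL) {
  if (is.null(labels))
    labels <- vapply(seq_along(fits), function(i) {
      ms <- fits[[i]]$model_spec
      if (inherits(ms, "model_structure")) format(ms)
      else if (is.character(ms)) ms else paste0("model", i)
    }, character(1))
  bics <- vapply(fits, bic, numeric(1))
  dfs <- vapply(fits, function(f) f$df, numeric(1))
  # ties below 1e-6 break toward fewer parameters
  ord <- order(round(bics / 1e-6) * 1e-6, dfs)
  best <- ord[1]
  if (length(fits) > 1) {
    second <- ord[2]
    cmp2 <- delta_bic_with_lb(fits[[best]], fits[[second]])
    d2 <- cmp2$delta_bic
    dlb <- cmp2$delta_bic_lb
  } else {
    d2 <- NA_real_; dlb <- NA_real_
  }
  tab <- data.frame(structure = labels, df = dfs,
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    bic = bics,
                    delta_bic = bics - bics[best],
                    stringsAsFactors = FALSE)
  tab$delta_bic_lb <- vapply(seq_along(fits), function(i) {
    if (i == best) return(0)
    delta_bic_with_lb(fits[[best]], fits[[i]])$delta_bic_lb
  }, numeric(1))
  tab$evidence <- vapply(tab$delta_bic, function(d)
    if (d == 0) NA_character_ else .evidence_grade(d), character(1))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(candidates = fits, labels = labels, table = tab, best = best,
              delta_bic_second_best = d2, delta_bic_lb = dlb,
              evidence_grade = .evidence_grade(d2))
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (BIC, censored weight 0.5)\n")
  print(transform(x$table,
                  loglik = round(loglik, 3), bic = round(bic, 3),
                  delta_bic = round(delta_bic, 3),
                  delta_bic_lb = round(delta_bic_lb, 3)))
  cat(sprintf("best: %s", x$labels[x$best]))
  if (is.finite(x$delta_bic_second_best %||% NA))
    cat(sprintf(" (Delta-BIC %.3g vs second best, LB %.3g, %s evidence)",
                x$delta_bic_second_best, x$delta_bic_lb, x$evidence_grade))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a selection report table to CSV
#' @param comparison a `model_comparison`.
#' @param path output CSV path.
#' @return the report data.frame, invisibly.
#' @export
write_selection_report <- function(comparison, path) {
  stopifnot(inherits(comparison, "model_comparison"))
  utils::write.csv(comparison$table, path, row.names = FALSE)
  invisible(comparison$table)
}
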