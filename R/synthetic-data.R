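#' Observation design of a time-lapse microscopy study
#'
#' Describes how RNA production events are observed: movies of fixed
#' length sampled on a regular grid, with each cell contributing an
#' observation window that may be shorter than the movie (division-limited
#' lifetimes).  Defaults reproduce the study design: 120-minute movies at a
#' 60 s sampling interval.
#'
#' @param movie_length movie duration (s).
#' @param sampling_interval time between frames (s).
#' @param n_cells number of cells observed per condition.
#' @param cell_lifetime_model `"constant"` (window = movie length) or
#'   `"lognormal"` (division-limited windows; median 3600 s, sdlog 0.3,
#'   truncated to the movie length).
#' @return list of class `observation_design`.
#' @export
observation_design <- function(movie_length = 7200, sampling_interval = 60,
                               n_cells = 100,
                               cell_lifetime_model = c("constant", "lognormal")) {
  if (sampling_interval <= 0) stop("`sampling_interval` must be > 0", call. = FALSE)
  if (movie_length < sampling_interval)
    stop("`movie_length` must be >= `sampling_interval`", call. = FALSE)
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  structure(list(movie_length = movie_length,
                 sampling_interval = sampling_interval,
                 n_cells = as.integer(n_cells),
                 cell_lifetime_model = match.arg(cell_lifetime_model)),
            class = "observation_design")
}

.draw_lifetimes <- function(design, n) {
  switch(design$cell_lifetime_model,
         constant = rep(design$movie_length, n),
         lognormal = pmin(design$movie_length,
                          stats::rlnorm(n, meanlog = log(3600), sdlog = 0.3)))
}

#' Draw inter-production intervals from an initiation model
#'
#' Exact sampler for the phase-type interval law.  With switching, the
#' pre-commit duration is the time for the first forward step to win the
#' race against deactivation: with `N ~ Geom(k1/(k1+k_off))` off-visits it
#' equals a Gamma(N+1, k1+k_off) sojourn in the on state plus a
#' Gamma(N, k_on) total off time (exponential races, no time-stepping
#' approximation).  Post-commit steps add independent exponentials.
#'
#' @param model an `initiation_model`.
#' @param n number of intervals.
#' @return numeric vector of interval durations (s).
#' @export
sample_intervals <- function(model, n) {
  stopifnot(inherits(model, "initiation_model"))
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  k <- model$seq_rates
  if (model$has_switching) {
    p <- k[1] / (k[1] + model$k_off)
    nvis <- stats::rgeom(n, p)
    w <- stats::rgamma(n, shape = nvis + 1, rate = k[1] + model$k_off)
    off <- ifelse(nvis > 0,
                  stats::rgamma(n, shape = pmax(nvis, 1), rate = model$k_on), 0)
    w <- w + off
  } else {
    w <- stats::rexp(n, k[1])
  }
  if (length(k) > 1) for (j in 2:length(k)) w <- w + stats::rexp(n, k[j])
  w
}

# closed-form mean interval (avoids the median search of interval_moments)
.model_mean <- function(model) {
  k <- model$seq_rates
  if (model$has_switching)
    (1 + model$k_off / model$k_on) / k[1] + sum(1 / k[-1])
  else sum(1 / k)
}

#' Simulate many cells and return their interval records
#'
#' Draws exact inter-production intervals for `n_cells` observation
#' windows (each window starting at a production-renewal point, i.e. in
#' the on state) and applies grid censoring interval by interval: an
#' interval of true duration W is recorded with bounds
#' (Delta ceil(W/Delta) - Delta, Delta ceil(W/Delta)\]; the interval
#' still open when the window ends is right-censored with a grid-aligned
#' lower bound.  This observation model is exactly the one the censored
#' likelihood assumes (the sampling grid re-anchored at each production),
#' which makes it the generator of choice for estimator-validation
#' studies; [censor_to_records()] instead models a fixed frame grid whose
#' sub-frame phase carries over between consecutive intervals.
#'
#' @param model an `initiation_model`.
#' @param design an [observation_design()].
#' @param condition_id condition identifier stamped on the records.
#' @param windows optional per-cell window lengths (s); defaults drawn
#'   from the design's lifetime model.
#' @return data.frame of interval records (see [censor_to_records()]).
#' @export
simulate_records <- function(model, design, condition_id = "C1",
                             windows = NULL) {
  stopifnot(inherits(design, "observation_design"))
  n_cells <- design$n_cells
  if (is.null(windows)) windows <- .draw_lifetimes(design, n_cells)
  delta <- design$sampling_interval
  mu <- .model_mean(model)
  wmax <- max(windows)
  m_per <- max(4L, ceiling(wmax / mu * 2 + 8))
  draws <- matrix(sample_intervals(model, n_cells * m_per), nrow = n_cells)
  lb_l <- vector("list", n_cells); ub_l <- lb_l; cell_l <- lb_l
  for (i in seq_len(n_cells)) {
    w <- windows[i]
    ww <- draws[i, ]
    tt <- cumsum(ww)
    while (tt[length(tt)] <= w) {   # rare top-up
      extra <- sample_intervals(model, m_per)
      ww <- c(ww, extra)
      tt <- c(tt, tt[length(tt)] + cumsum(extra))
    }
    n_complete <- sum(tt <= w)
    if (n_complete > 0) {
      d <- delta * ceiling(ww[seq_len(n_complete)] / delta)
      lb <- pmax(d - delta, 0); ub <- pmax(d, delta)
      t_last <- tt[n_complete]
    } else { lb <- numeric(0); ub <- numeric(0); t_last <- 0 }
    lb_l[[i]] <- c(lb, delta * floor((w - t_last) / delta))
    ub_l[[i]] <- c(ub, Inf)
    cell_l[[i]] <- rep.int(i, n_complete + 1L)
  }
  lb <- unlist(lb_l); ub <- unlist(ub_l); cell <- unlist(cell_l)
  idx <- sequence(vapply(cell_l[lengths(cell_l) > 0], length, integer(1)))
  ids <- sprintf("%s.cell%04d.i%02d", condition_id, cell, idx)
  prev <- c(NA_character_, ids[-length(ids)])
  if (length(prev)) prev[idx == 1L] <- NA_character_
  data.frame(interval_id = ids, condition_id = condition_id,
             lb_s = lb, ub_s = ub, prev_interval_id = prev,
             stringsAsFactors = FALSE)
}

#' Simulate RNA production times in one observation window
#'
#' Event-by-event exact simulation of the initiation scheme starting in
#' the on state at time 0; after each production the chain restarts in the
#' on state of the first step.
#'
#' @param model an `initiation_model`.
#' @param window observation window length (s), > 0.
#' @param seed optional integer seed.
#' @return increasing vector of production times in (0, window].
#' @export
simulate_event_times <- function(model, window, seed = NULL) {
  stopifnot(inherits(model, "initiation_model"))
  if (!is.finite(window) || window <= 0) stop("`window` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- .model_mean(model)
  times <- numeric(0)
  t_last <- 0
  repeat {
    batch <- max(16L, ceiling(1.5 * (window - t_last) / mu))
    w <- sample_intervals(model, batch)
    tt <- t_last + cumsum(w)
    times <- c(times, tt[tt <= window])
    if (tt[length(tt)] > window) break
    t_last <- tt[length(tt)]
  }
  times
}

#' Apply the observation operator to event times
#'
#' Converts true production times in one cell into the bounded/censored
#' interval records of the study schema.  A production at true time t is
#' detected at the first sample time >= t (samples at multiples of the
#' sampling interval, up to the cell's window).  Consecutive detections
#' d1 < d2 give a grid-censored record with bounds (d2-d1-Delta, d2-d1];
#' two productions detected in the same frame give (0, Delta].  The
#' interval still open at the window end gives a right-censored record
#' with `lb` = grid-aligned elapsed time since the last detection and
#' `ub` = Inf.  The interval from window start to first detection is not a
#' production interval and is discarded unless `keep_first = TRUE`.
#'
#' @param event_times increasing production times (s) within the window.
#' @param design an [observation_design()].
#' @param condition_id condition identifier stamped on the records.
#' @param cell_id cell identifier (used to build interval ids and chains).
#' @param window this cell's observation window (s); defaults to the movie
#'   length.
#' @param keep_first include the (window-start, first-detection) interval?
#' @return data.frame of interval records: `interval_id`, `condition_id`,
#'   `lb_s`, `ub_s` (Inf when right-censored), `prev_interval_id`.
#' @export
censor_to_records <- function(event_times, design, condition_id = "C1",
                              cell_id = 1L, window = NULL,
                              keep_first = FALSE) {
  stopifnot(inherits(design, "observation_design"))
  delta <- design$sampling_interval
  if (is.null(window)) window <- design$movie_length
  if (length(event_times) && any(event_times > window | event_times < 0))
    stop("event times outside the observation window", call. = FALSE)
  last_sample <- delta * floor(window / delta)
  empty <- data.frame(interval_id = character(0), condition_id = character(0),
                      lb_s = numeric(0), ub_s = numeric(0),
                      prev_interval_id = character(0),
                      stringsAsFactors = FALSE)
  if (!length(event_times)) return(empty)
  det <- delta * ceiling(event_times / delta)
  det <- det[det <= last_sample]          # events after the last frame unseen
  if (!length(det)) return(empty)
  lb <- ub <- numeric(0)
  if (keep_first) {
    lb <- max(det[1] - delta, 0); ub <- det[1]
  }
  if (length(det) > 1) {
    d <- diff(det)
    lb <- c(lb, pmax(d - delta, 0))
    ub <- c(ub, pmax(d, delta))
  }
  # open interval at window end
  lb <- c(lb, last_sample - det[length(det)])
  ub <- c(ub, Inf)
  ids <- sprintf("%s.cell%03d.i%02d", condition_id, as.integer(cell_id),
                 seq_along(lb))
  prev <- c(NA_character_, ids[-length(ids)])
  data.frame(interval_id = ids, condition_id = condition_id,
             lb_s = lb, ub_s = ub, prev_interval_id = prev,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic interval study
#'
#' For every scheme x temperature combination, instantiates the initiation
#' model from the temperature law, simulates `n_cells` observation
#' windows, applies the observation operator, and assembles condition and
#' interval tables in the study schema.  Fully reproducible from `seed`.
#'
#' @param design an [observation_design()].
#' @param temperature_law a [temperature_law()] giving each model
#'   parameter's inverse rate as a polynomial in temperature; used for any
#'   scheme that does not carry its own `law`.
#' @param schemes list of scheme descriptors; each a list with fields
#'   `name`, and optionally `promoter`, `iptg_mM`, `ara_pct`, `atc_ng_ml`
#'   and a scheme-specific `law`.
#' @param temperatures numeric vector of temperatures (degrees C).
#' @param seed integer seed.
#' @return list of class `study_dataset` with data.frames `conditions`
#'   and `intervals`, plus `provenance`.
#' @export
generate_study <- function(design, temperature_law = NULL, schemes,
                           temperatures, seed = 1L) {
  stopifnot(inherits(design, "observation_design"))
  set.seed(seed)
  conds <- list(); ivals <- list(); cid <- 0L
  for (s in schemes) {
    law <- if (!is.null(s$law)) s$law else temperature_law
    if (is.null(law)) stop("no temperature law for scheme ", s$name, call. = FALSE)
    for (Tc in temperatures) {
      cid <- cid + 1L
      id <- sprintf("C%03d", cid)
      model <- model_at_temperature(law, Tc)
      conds[[cid]] <- data.frame(
        condition_id = id,
        promoter = if (is.null(s$promoter)) s$name else s$promoter,
        iptg_mM = if (is.null(s$iptg_mM)) 0 else s$iptg_mM,
        ara_pct = if (is.null(s$ara_pct)) 0 else s$ara_pct,
        atc_ng_ml = if (is.null(s$atc_ng_ml)) 0 else s$atc_ng_ml,
        temperature_C = Tc, scheme = s$name,
        stringsAsFactors = FALSE)
      ivals[[cid]] <- simulate_records(model, design, condition_id = id)
    }
  }
  structure(list(conditions = do.call(rbind, conds),
                 intervals = do.call(rbind, ivals),
                 provenance = list(generator = "txinit::generate_study",
                                   seed = seed, schema_version = "1")),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study dataset: %d conditions, %d interval records (%d right-censored)\n",
              nrow(x$conditions), nrow(x$intervals),
              sum(!is.finite(x$intervals$ub_s))))
  invisible(x)
}
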