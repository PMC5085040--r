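#' Read a study dataset from the condition/interval CSV schemas
#'
#' The conditions table carries one row per measurement condition
#' (promoter, inducer concentrations, temperature); the intervals table
#' one row per observed inter-production interval with lower/upper bounds
#' in seconds.  An empty upper-bound field encodes a right-censored
#' interval (`Inf`).  Row order carries no meaning.
#'
#' @param conditions_path CSV with header
#'   `Condition ID, Promoter, IPTG, Ara, aTc, Temperature` (an optional
#'   `Scheme` column is preserved).
#' @param intervals_path CSV with header
#'   `Interval ID, Condition ID, Interval LB, Interval UB,
#'   Previous Interval ID`.
#' @return a `study_dataset` (see [generate_study()]).
#' @export
read_study <- function(conditions_path, intervals_path) {
  cond_raw <- utils::read.csv(conditions_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  int_raw <- utils::read.csv(intervals_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  need_c <- c("Condition ID", "Promoter", "IPTG", "Ara", "aTc", "Temperature")
  need_i <- c("Interval ID", "Condition ID", "Interval LB", "Interval UB",
              "Previous Interval ID")
  if (!all(need_c %in% names(cond_raw)))
    stop("conditions file lacks columns: ",
         paste(setdiff(need_c, names(cond_raw)), collapse = ", "), call. = FALSE)
  if (!all(need_i %in% names(int_raw)))
    stop("intervals file lacks columns: ",
         paste(setdiff(need_i, names(int_raw)), collapse = ", "), call. = FALSE)
  conditions <- data.frame(
    condition_id = as.character(cond_raw[["Condition ID"]]),
    promoter = as.character(cond_raw[["Promoter"]]),
    iptg_mM = as.numeric(cond_raw[["IPTG"]]),
    ara_pct = as.numeric(cond_raw[["Ara"]]),
    atc_ng_ml = as.numeric(cond_raw[["aTc"]]),
    temperature_C = as.numeric(cond_raw[["Temperature"]]),
    stringsAsFactors = FALSE)
  if ("Scheme" %in% names(cond_raw))
    conditions$scheme <- as.character(cond_raw[["Scheme"]])
  if (anyDuplicated(conditions$condition_id))
    stop("duplicate condition ids", call. = FALSE)
  ub_raw <- int_raw[["Interval UB"]]
  ub <- suppressWarnings(as.numeric(ub_raw))
  ub[is.na(ub) | (is.character(ub_raw) & !nzchar(trimws(as.character(ub_raw))))] <- Inf
  prev <- as.character(int_raw[["Previous Interval ID"]])
  prev[!nzchar(trimws(prev)) | is.na(prev)] <- NA_character_
  intervals <- data.frame(
    interval_id = as.character(int_raw[["Interval ID"]]),
    condition_id = as.character(int_raw[["Condition ID"]]),
    lb_s = as.numeric(int_raw[["Interval LB"]]),
    ub_s = ub, prev_interval_id = prev,
    stringsAsFactors = FALSE)
  dangling <- which(!intervals$condition_id %in% conditions$condition_id)
  if (length(dangling))
    stop("interval rows reference unknown conditions (rows ",
         paste(utils::head(dangling, 5), collapse = ", "), ")", call. = FALSE)
  bad <- which(!(intervals$lb_s >= 0 & intervals$lb_s < intervals$ub_s))
  if (length(bad))
    stop("malformed interval bounds (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  out <- list(conditions = conditions, intervals = intervals,
              provenance = list(source = c(conditions = conditions_path,
                                           intervals = intervals_path),
                                schema_version = "1"))
  class(out) <- "study_dataset"
  out
}

#' Write a study dataset in the condition/interval CSV schemas
#'
#' Inverse of [read_study()]: `Inf` upper bounds become empty fields.
#'
#' @param study a `study_dataset`.
#' @param conditions_path,intervals_path output CSV paths.
#' @return `study`, invisibly.
#' @export
write_study <- function(study, conditions_path, intervals_path) {
  stopifnot(inherits(study, "study_dataset"))
  co <- study$conditions
  out_c <- data.frame(
    `Condition ID` = co$condition_id, Promoter = co$promoter,
    IPTG = co$iptg_mM, Ara = co$ara_pct, aTc = co$atc_ng_ml,
    Temperature = co$temperature_C, check.names = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(co$scheme)) out_c$Scheme <- co$scheme
  iv <- study$intervals
  out_i <- data.frame(
    `Interval ID` = iv$interval_id, `Condition ID` = iv$condition_id,
    `Interval LB` = iv$lb_s,
    `Interval UB` = ifelse(is.finite(iv$ub_s), as.character(iv$ub_s), ""),
    `Previous Interval ID` = ifelse(is.na(iv$prev_interval_id), "",
                                    iv$prev_interval_id),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out_c, conditions_path, row.names = FALSE, na = "")
  utils::write.csv(out_i, intervals_path, row.names = FALSE, na = "")
  invisible(study)
}

#' Read activity-vs-RNAP measurements for the commit split
#' @param path CSV with columns `condition`, `relative_rnap`,
#'   `relative_activity` (one row per replicate).
#' @return data.frame.
#' @export
read_activity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "relative_rnap", "relative_activity")
  if (!all(need %in% names(df)))
    stop("activity file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a relative RNA-polymerase abundance profile
#' @param path 2-column CSV: `temperature_C`, `relative_abundance`.
#' @return an [rnap_profile()].
#' @export
read_rnap_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "relative_abundance")
  if (!all(need %in% names(df)))
    stop("RNAP profile file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rnap_profile(df$temperature_C, df$relative_abundance)
}

#' Interval records of a study joined with their condition metadata
#' @param study a `study_dataset`.
#' @return data.frame of interval records with `temperature_C`,
#'   `promoter` (and `scheme` when present) attached.
#' @export
attach_conditions <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  merge(study$intervals, study$conditions, by = "condition_id", sort = FALSE)
}
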