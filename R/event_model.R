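#' The illness-death state space
#'
#' Three states — 1 Diagnosis, 2 Transplant, 3 Death — and the three
#' permitted transitions 1->2 (numbered 1), 1->3 (2) and 2->3 (3).  Death is
#' absorbing; there are no backward transitions.
#'
#' @return A list with `states` (named integer vector) and `transitions`
#'   (data frame with columns `trans`, `from`, `to`).
#' @export
state_space <- function() {
  list(
    states = c(Diagnosis = 1L, Transplant = 2L, Death = 3L),
    transitions = data.frame(
      trans = 1:3,
      from = c(1L, 1L, 2L),
      to = c(2L, 3L, 3L))
  )
}

DAYS_PER_YEAR <- 365.25

#' Convert between days and years
#'
#' Times are handled internally in days since diagnosis; figures and
#' summaries report years using 365.25 days per year.
#'
#' @param x numeric vector.
#' @return the converted vector.
#' @export
days_to_years <- function(x) x / DAYS_PER_YEAR

#' @rdname days_to_years
#' @export
years_to_days <- function(x) x * DAYS_PER_YEAR

registry_columns <- c("id", "cohort", "t_tx_days", "t_end_days", "dead",
                      "r_trunc_days", "age_gt60", "raebt", "cyto_abnormal",
                      "year_dx")

#' Validate registry subject records
#'
#' Checks a per-patient event table (one row per subject, times in days
#' since diagnosis) against the registry invariants, resolves same-day
#' transplant-and-death ties, and reports every adjustment or rejection.
#'
#' Rules enforced:
#' * `id` unique, times numeric — violations are errors, not reports;
#' * `t_end_days > 0`; transplant-registry rows carry `t_tx_days` with
#'   `0 < t_tx_days <= t_end_days` and, when a right-truncation limit is
#'   present, `t_tx_days <= r_trunc_days` — violations are errors where
#'   structural (negative time, missing transplant time in the transplant
#'   registry) and rejections otherwise;
#' * non-transplant-registry rows must not carry a transplant time
#'   (rejected with reason `"transplant in non-transplant registry"`);
#' * `t_tx_days == t_end_days` (same-day transplant and death/censoring):
#'   `t_end_days` is moved 0.5 day later so every at-risk interval has
#'   positive length, and the record is flagged.
#'
#' @param records data frame in the registry schema (see
#'   [read_registry_csv] for the column list).
#' @param year_range plausible calendar-year range for `year_dx`.
#' @return A list with `records` (the cleaned table) and `issues`
#'   (data frame `id`, `action` in `{"adjusted","rejected"}`, `reason`).
#' @export
validate_records <- function(records, year_range = c(1950L, 2030L)) {
  records <- as.data.frame(records)
  miss <- setdiff(c("id", "cohort", "t_end_days", "dead"), names(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(registry_columns, names(records)))
    records[[col]] <- NA
  if (anyDuplicated(records$id))
    stop("duplicate subject id: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  for (col in c("t_tx_days", "t_end_days", "r_trunc_days")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
    if (any(records[[col]] < 0, na.rm = TRUE))
      stop("negative time in column ", col)
  }
  if (any(is.na(records$t_end_days)))
    stop("t_end_days missing or non-numeric")
  bad_cohort <- !records$cohort %in% c("tx_registry", "non_tx_registry", "complete")
  if (any(bad_cohort))
    stop("unknown cohort label: ",
         paste(unique(records$cohort[bad_cohort]), collapse = ", "))
  if (any(records$cohort == "tx_registry" & is.na(records$t_tx_days)))
    stop("transplant-registry record lacking t_tx_days: ",
         paste(records$id[records$cohort == "tx_registry" &
                            is.na(records$t_tx_days)], collapse = ", "))
  for (col in c("age_gt60", "raebt", "cyto_abnormal", "dead")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
    if (any(!records[[col]] %in% c(0, 1) & !is.na(records[[col]])))
      stop("non-binary value in column ", col)
  }

  issues <- data.frame(id = character(), action = character(),
                       reason = character(), stringsAsFactors = FALSE)
  note <- function(id, action, reason)
    rbind(issues, data.frame(id = as.character(id), action = action,
                             reason = reason, stringsAsFactors = FALSE))

  # Same-day transplant and end of follow-up: shift t_end by half a day so
  # the (entry, exit] at-risk interval has positive length.
  tie <- !is.na(records$t_tx_days) & records$t_tx_days == records$t_end_days
  if (any(tie)) {
    records$t_end_days[tie] <- records$t_end_days[tie] + 0.5
    for (id in records$id[tie])
      issues <- note(id, "adjusted", "same-day transplant/death")
  }

  drop <- rep(FALSE, nrow(records))
  reject <- function(mask, reason) {
    for (id in records$id[mask & !drop]) issues <<- note(id, "rejected", reason)
    drop <<- drop | mask
  }
  reject(records$t_end_days <= 0, "non-positive follow-up time")
  reject(records$cohort == "non_tx_registry" & !is.na(records$t_tx_days),
         "transplant in non-transplant registry")
  reject(!is.na(records$t_tx_days) &
           (records$t_tx_days <= 0 | records$t_tx_days > records$t_end_days),
         "transplant time outside (0, t_end]")
  reject(records$cohort == "tx_registry" & !is.na(records$r_trunc_days) &
           records$t_tx_days > records$r_trunc_days,
         "transplant after right-truncation limit")
  yr <- suppressWarnings(as.numeric(records$year_dx))
  reject(!is.na(yr) & (yr < year_range[1] | yr > year_range[2]),
         "year of diagnosis outside plausible range")

  list(records = records[!drop, , drop = FALSE], issues = issues)
}

#' Assemble registry tables into transition-specific counting-process data
#'
#' Maps the two registries onto the estimable pieces of the illness-death
#' model:
#'
#' * transition 2 (Diagnosis -> Death) rows come only from the
#'   non-transplant registry: `(entry = 0, exit = t_end, status = dead)`;
#' * transition 3 (Transplant -> Death) rows come only from the transplant
#'   registry; with `clock = "forward"` the subject enters the risk set at
#'   transplant on the diagnosis time scale (left truncation,
#'   `entry = t_tx, exit = t_end`), with `clock = "reset"` time is measured
#'   from transplant (`entry = 0, exit = t_end - t_tx`);
#' * transition 1 (Diagnosis -> Transplant) is never emitted as
#'   counting-process rows — the transplant registry holds no one who died
#'   while waiting, so that risk set is unobservable.  Instead the waiting
#'   times are returned as a right-truncated sample `(T = t_tx,
#'   R = r_trunc)`, `R` defaulting to the largest observed waiting time;
#' * for the pooled treatment comparison (`clock = "forward"` only), one
#'   row per subject on the diagnosis time scale: non-transplant subjects
#'   span `(0, t_end]` with `tx_state = 0`, transplant subjects enter at
#'   `t_tx` with `tx_state = 1`.
#'
#' @param non_tx,tx validated registry tables ([validate_records]).
#' @param clock time scale for the post-transplant hazard, `"forward"`
#'   (days since diagnosis, the Markov clock) or `"reset"` (days since
#'   transplant).
#' @return A list with `rows` (counting-process data: `id`, `trans`,
#'   `entry`, `exit`, `status`, `tx_state`, covariates), `comparison`
#'   (the pooled comparison rows, `NULL` when `clock = "reset"` is
#'   requested they are refused), `waiting` (data frame `id`, `T`, `R`)
#'   and `clock`.
#' @export
assemble_multistate_dataset <- function(non_tx, tx,
                                        clock = c("forward", "reset")) {
  clock <- match.arg(clock)
  non_tx <- as.data.frame(non_tx); tx <- as.data.frame(tx)
  if (!nrow(non_tx)) stop("empty non-transplant cohort")
  if (!nrow(tx)) stop("empty transplant cohort")
  if (length(intersect(non_tx$id, tx$id)))
    stop("subject appears in both registries: ",
         paste(intersect(non_tx$id, tx$id), collapse = ", "))
  covs <- c("age_gt60", "raebt", "cyto_abnormal", "year_dx")
  for (col in covs) {
    if (is.null(non_tx[[col]])) non_tx[[col]] <- NA
    if (is.null(tx[[col]])) tx[[col]] <- NA
  }

  cp_row <- function(d, trans, entry, exit, status, tx_state) {
    cbind(data.frame(id = d$id, trans = trans, entry = entry, exit = exit,
                     status = as.integer(status), tx_state = tx_state),
          d[, covs, drop = FALSE])
  }
  rows2 <- cp_row(non_tx, 2L, 0, non_tx$t_end_days, non_tx$dead, 0L)
  if (clock == "forward") {
    rows3 <- cp_row(tx, 3L, tx$t_tx_days, tx$t_end_days, tx$dead, 1L)
  } else {
    rows3 <- cp_row(tx, 3L, 0, tx$t_end_days - tx$t_tx_days, tx$dead, 1L)
  }
  # waiting-time interval, a covariate only meaningful for transition 3
  rows3$wait_days <- tx$t_tx_days
  rows2$wait_days <- NA_real_
  rows <- rbind(rows2, rows3)
  if (any(rows$entry >= rows$exit))
    stop("at-risk interval with entry >= exit (run validate_records first)")

  R <- tx$r_trunc_days
  if (all(is.na(R))) R <- rep(max(tx$t_tx_days), nrow(tx))
  if (any(is.na(R))) R[is.na(R)] <- max(tx$t_tx_days, R, na.rm = TRUE)
  waiting <- data.frame(id = tx$id, T = tx$t_tx_days, R = R)
  if (any(waiting$T > waiting$R))
    stop("waiting time exceeds its right-truncation limit")

  comparison <- NULL
  if (clock == "forward") {
    comparison <- rbind(
      cp_row(non_tx, NA_integer_, 0, non_tx$t_end_days, non_tx$dead, 0L),
      cp_row(tx, NA_integer_, tx$t_tx_days, tx$t_end_days, tx$dead, 1L))
  }
  list(rows = rows, comparison = comparison, waiting = waiting, clock = clock)
}

#' Read / write registry tables
#'
#' The registry exchange format is a plain CSV with columns `id, cohort,
#' t_tx_days, t_end_days, dead, r_trunc_days, age_gt60, raebt,
#' cyto_abnormal, year_dx`; missing values are empty fields.
#'
#' @param file path to a CSV file.
#' @return `read_registry_csv`: a data frame in the registry schema.
#' @export
read_registry_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  miss <- setdiff(registry_columns, names(df))
  if (length(miss))
    stop("registry CSV lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_registry_csv
#' @param records registry data frame.
#' @export
write_registry_csv <- function(records, file) {
  out <- as.data.frame(records)[, registry_columns]
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE, na = "",
                   eol = "\n")
  invisible(file)
}

#' Write counting-process rows to CSV
#'
#' Long-format export of the assembled dataset — the exchange format for
#' every downstream module.
#'
#' @param rows counting-process data frame from
#'   [assemble_multistate_dataset].
#' @param file path.
#' @export
write_counting_csv <- function(rows, file) {
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE, na = "",
                   eol = "\n")
  invisible(file)
}
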