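#' Run naive and corrected analyses on one pair of registries
#'
#' Computes, on identical data, the five estimates whose comparison is
#' the point of this package:
#'
#' * `km_from_tx` — Kaplan-Meier of the transplant registry from the
#'   *transplant* date (wrong time origin for a from-diagnosis
#'   comparison);
#' * `km_from_dx_no_trunc` — Kaplan-Meier of the transplant registry
#'   from diagnosis ignoring delayed entry: every subject is treated as
#'   at risk from `t = 0`, although no one who died before transplant
#'   can be in this registry (immortal-time bias);
#' * `km_from_dx_left_trunc` — Kaplan-Meier from diagnosis with entry at
#'   transplant (left truncation handled; still a counterfactual
#'   "everyone already transplanted" curve);
#' * `multistate_reconstruction` — the from-diagnosis transplant-strategy
#'   curve of [reconstruct_strategy_survival];
#' * `cox_avg_hr` — the pooled average hazard ratio of
#'   [fit_treatment_comparison].
#'
#' @param tx_registry,non_tx_registry registry-schema data frames.
#' @param truth optional `complete_cohort` (the latent strategy cohort);
#'   when given, per-method errors at the horizons are attached.  The
#'   reference is the empirical survival of the latent, uncensored
#'   cohort — valid under frailty too.
#' @param horizons evaluation horizons in days (default 1, 2, 5 years).
#' @return A data frame with one row per method x horizon: `method`,
#'   `horizon_days`, `estimate` (survival, or the hazard ratio for
#'   `cox_avg_hr` with `horizon_days = NA`), `lower`, `upper` (where the
#'   method carries an analytic interval), `truth`, `error`.
#' @export
run_naive_comparison <- function(tx_registry, non_tx_registry, truth = NULL,
                                 horizons = years_to_days(c(1, 2, 5))) {
  tx <- as.data.frame(tx_registry)
  dataset <- assemble_multistate_dataset(non_tx_registry, tx, clock = "forward")

  km_list <- list(
    km_from_tx = kaplan_meier(data.frame(
      entry = 0, exit = tx$t_end_days - tx$t_tx_days, status = tx$dead)),
    km_from_dx_no_trunc = kaplan_meier(data.frame(
      entry = 0, exit = tx$t_end_days, status = tx$dead)),
    km_from_dx_left_trunc = kaplan_meier(data.frame(
      entry = tx$t_tx_days, exit = tx$t_end_days, status = tx$dead)))
  sc <- reconstruct_strategy_survival(dataset)

  truth_at <- rep(NA_real_, length(horizons))
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "complete_cohort"))
    truth_at <- vapply(horizons,
                       function(h) mean(truth$truth$t_death > h), 0)
  }
  one <- function(method, sf) {
    est <- step_eval(sf, horizons)
    data.frame(method = method, horizon_days = horizons, estimate = est,
               lower = approx_bound(sf, horizons, "lower"),
               upper = approx_bound(sf, horizons, "upper"),
               truth = truth_at, error = est - truth_at)
  }
  out <- rbind(
    one("km_from_tx", km_list$km_from_tx),
    one("km_from_dx_no_trunc", km_list$km_from_dx_no_trunc),
    one("km_from_dx_left_trunc", km_list$km_from_dx_left_trunc),
    one("multistate_reconstruction", sc$tx))
  cox <- fit_treatment_comparison(dataset)
  out <- rbind(out, data.frame(
    method = "cox_avg_hr", horizon_days = NA_real_,
    estimate = unname(cox$hr["tx_state"]),
    lower = unname(cox$ci["tx_state", "lower"]),
    upper = unname(cox$ci["tx_state", "upper"]),
    truth = NA_real_, error = NA_real_))
  rownames(out) <- NULL
  out
}

# evaluate a step function's CI bound at times (step-wise, like the estimate)
approx_bound <- function(sf, t, which = "lower") {
  vals <- sf[[which]]
  if (!length(sf$time) || all(is.na(vals))) return(rep(NA_real_, length(t)))
  base <- if (sf$kind == "survival") 1 else 0
  idx <- findInterval(t, sf$time)
  c(base, vals)[idx + 1L]
}

#' Replicated bias study over scenarios
#'
#' The replication engine: for each scenario, repeatedly simulate the
#' two-registry study ([simulate_registries]), run all five methods
#' ([run_naive_comparison]) against the latent truth, and aggregate
#' into a bias table.  Replicates whose registries are degenerate (e.g.
#' an empty transplant registry) are dropped and counted; a scenario
#' failing in more than half its replicates is flagged.
#'
#' @param scenarios named list of [scenario] objects.
#' @param n_reps replicates per scenario (>= 2).
#' @param seed master seed; replicate `r` of scenario `s` runs under a
#'   seed derived deterministically from `(seed, s, r)`.
#' @param horizons evaluation horizons in days.
#' @return A `bias_table` data frame: one row per scenario x method x
#'   horizon with `truth` (mean latent truth), `mean_estimate`, `bias`,
#'   `mc_se` (Monte-Carlo standard error of the mean estimate),
#'   `coverage` (empirical coverage of the method's nominal 95% interval,
#'   `NA` where none is defined), `n_reps` (completed replicates),
#'   `n_failed`, `flagged`, `seed`.
#' @export
run_bias_study <- function(scenarios, n_reps = 100L, seed = 1L,
                           horizons = years_to_days(c(1, 2, 5))) {
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios))))
    stop("scenarios must be a named list")
  out <- list()
  for (sname in names(scenarios)) {
    sc <- scenarios[[sname]]
    stopifnot(inherits(sc, "scenario"))
    reps <- vector("list", n_reps)
    failed <- 0L
    for (r in seq_len(n_reps)) {
      p <- sc
      p$seed <- as.integer((sc$seed + 1000003 * (r - 1) +
                              7919 * match(sname, names(scenarios))) %%
                             2147483629)
      res <- tryCatch({
        regs <- simulate_registries(p)
        if (nrow(regs$tx_registry) < 2 || nrow(regs$non_tx_registry) < 2)
          stop("degenerate registries")
        run_naive_comparison(regs$tx_registry, regs$non_tx_registry,
                             truth = regs$strategy, horizons = horizons)
      }, error = function(e) NULL)
      if (is.null(res)) failed <- failed + 1L else reps[[r]] <- res
    }
    reps <- reps[!vapply(reps, is.null, TRUE)]
    flagged <- failed > n_reps / 2
    if (!length(reps)) {
      warning("scenario ", sname, " failed in every replicate")
      next
    }
    all_reps <- do.call(rbind, reps)
    key <- paste(all_reps$method,
                 ifelse(is.na(all_reps$horizon_days), "hr",
                        all_reps$horizon_days))
    agg <- do.call(rbind, lapply(split(all_reps, key), function(d) {
      covered <- !is.na(d$lower) & !is.na(d$truth) &
        d$lower <= d$truth & d$truth <= d$upper
      data.frame(
        scenario = sname, method = d$method[1],
        horizon_days = d$horizon_days[1],
        truth = mean(d$truth),
        mean_estimate = mean(d$estimate, na.rm = TRUE),
        bias = mean(d$error, na.rm = TRUE),
        mc_se = stats::sd(d$estimate, na.rm = TRUE) /
          sqrt(sum(!is.na(d$estimate))),
        coverage = if (all(is.na(d$lower)) || all(is.na(d$truth)))
          NA_real_ else mean(covered),
        n_reps = nrow(d), n_failed = failed, flagged = flagged,
        seed = seed)
    }))
    out[[sname]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bias_table", "data.frame")
  res
}

#' Write a bias table as CSV and JSON
#'
#' @param tab a `bias_table` from [run_bias_study].
#' @param csv_file,json_file output paths (either may be `NULL`).
#' @export
write_bias_table <- function(tab, csv_file = NULL, json_file = NULL) {
  if (!is.null(csv_file))
    utils::write.csv(as.data.frame(tab), csv_file, row.names = FALSE,
                     quote = FALSE, na = "", eol = "\n")
  if (!is.null(json_file))
    jsonlite::write_json(as.data.frame(tab), json_file, auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(tab)
}
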