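#' Risk-set counts for counting-process data
#'
#' With half-open at-risk intervals `(entry, exit]`, the risk set at time
#' `t` is `Y(t) = #\{i : entry_i < t <= exit_i\}` — delayed entry (left
#' truncation) is honoured by construction.  Events tied at one time are
#' aggregated; subjects censored at an event time are still in the risk
#' set there (event-before-censoring convention).
#'
#' @param entry,exit,status numeric vectors defining the rows.
#' @return A data frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`.
#' @export
risk_sets <- function(entry, exit, status) {
  stopifnot(length(entry) == length(exit), length(exit) == length(status))
  if (any(entry >= exit)) stop("at-risk interval with entry >= exit")
  times <- sort(unique(exit[status == 1]))
  if (!length(times))
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer()))
  y <- vapply(times, function(t) sum(entry < t & exit >= t), 0L)
  d <- as.integer(rowsum(status[status == 1],
                         group = exit[status == 1])[, 1])
  data.frame(time = times, n_risk = as.integer(y), n_event = d)
}

# Internal fast version used by the estimators (O(n log n) not O(n K)).
risk_sets_fast <- function(entry, exit, status) {
  times <- sort(unique(exit[status == 1]))
  if (!length(times))
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer()))
  n <- length(exit)
  se <- sort(exit); sn <- sort(entry)
  # #{exit >= t}: exits strictly below t via findInterval on t - eps is
  # fragile for doubles; instead count exit < t exactly with left-open
  # intervals: findInterval(t, se, left.open = TRUE) counts se < t.
  n_exit_ge <- n - findInterval(times, se, left.open = TRUE)
  n_entry_ge <- n - findInterval(times, sn, left.open = TRUE)
  # entry >= t implies exit > entry >= t, so subtraction yields entry < t <= exit
  y <- n_exit_ge - n_entry_ge
  d <- as.integer(rowsum(status[status == 1],
                         group = exit[status == 1])[, 1])
  data.frame(time = times, n_risk = as.integer(y), n_event = d)
}

check_rows <- function(rows) {
  rows <- as.data.frame(rows)
  stopifnot(all(c("entry", "exit", "status") %in% names(rows)))
  if (any(rows$entry >= rows$exit)) stop("at-risk interval with entry >= exit")
  if (any(rows$entry < 0)) stop("negative entry time")
  if (!all(rows$status %in% 0:1)) stop("status must be 0/1")
  rows
}

#' Nelson-Aalen cumulative hazard with delayed entry
#'
#' Increments `d(t)/Y(t)` at each distinct event time over half-open
#' at-risk intervals; the variance is the usual sum of `d(t)/Y(t)^2`.
#' An event time with an empty risk set — possible with left-truncated
#' data when the earliest event precedes every entry — is an error, since
#' the hazard is not estimable across such a gap.
#'
#' @param rows data frame with columns `entry`, `exit`, `status`.
#' @param ci_level confidence level (log-transformed interval).
#' @return an [msm_step] of kind `"cumhaz"`.
#' @export
nelson_aalen <- function(rows, ci_level = 0.95) {
  rows <- check_rows(rows)
  rs <- risk_sets_fast(rows$entry, rows$exit, rows$status)
  if (any(rs$n_risk < rs$n_event) || any(rs$n_risk == 0))
    stop("empty risk set (left-truncation gap) at t = ",
         rs$time[which(rs$n_risk < pmax(rs$n_event, 1))[1]])
  inc <- rs$n_event / rs$n_risk
  msm_step(rs$time, cumsum(inc), cumsum(rs$n_event / rs$n_risk^2),
           kind = "cumhaz", n = nrow(rows), n_events = sum(rows$status),
           ci_level = ci_level)
}

#' Kaplan-Meier survival with delayed entry
#'
#' Product-limit estimator over half-open at-risk intervals with Greenwood
#' variance and log(-log)-transformed confidence limits.
#'
#' @inheritParams nelson_aalen
#' @return an [msm_step] of kind `"survival"`; attributes `median` (first
#'   time the estimate drops to 0.5 or below, `NA` if never reached) and
#'   `median_ci`.
#' @export
kaplan_meier <- function(rows, ci_level = 0.95) {
  rows <- check_rows(rows)
  rs <- risk_sets_fast(rows$entry, rows$exit, rows$status)
  if (any(rs$n_risk < rs$n_event) || any(rs$n_risk == 0))
    stop("empty risk set (left-truncation gap) at t = ",
         rs$time[which(rs$n_risk < pmax(rs$n_event, 1))[1]])
  surv <- cumprod(1 - rs$n_event / rs$n_risk)
  gw <- cumsum(rs$n_event / (rs$n_risk * pmax(rs$n_risk - rs$n_event, 1)))
  gw[rs$n_risk == rs$n_event] <- Inf
  var <- surv^2 * cummax(gw)
  var[!is.finite(var) | surv == 0] <- NA_real_
  sf <- msm_step(rs$time, surv, var, kind = "survival", n = nrow(rows),
                 n_events = sum(rows$status), ci_level = ci_level)
  attr(sf, "median") <- step_quantile(sf, 0.5)
  attr(sf, "median_ci") <- c(
    lower = quantile_from_curve(sf$time, sf$upper, 0.5),
    upper = quantile_from_curve(sf$time, sf$lower, 0.5))
  sf
}

# first knot where a non-increasing curve reaches <= 1 - p
quantile_from_curve <- function(time, values, p) {
  ok <- which(!is.na(values) & values <= 1 - p + 1e-12)
  if (!length(ok)) NA_real_ else time[min(ok)]
}

#' Survival quantile of a step estimate
#'
#' @param sf a survival-kind [msm_step].
#' @param p probability of the event, e.g. 0.5 for the median.
#' @return first time at which survival drops to `1 - p` or below, `NA`
#'   ("not reached") if it never does.
#' @export
step_quantile <- function(sf, p = 0.5) {
  stopifnot(inherits(sf, "msm_step"), sf$kind == "survival")
  quantile_from_curve(sf$time, sf$est, p)
}

#' Conditional CDF of a right-truncated waiting time
#'
#' Diagnosis-to-transplant times in a transplant registry are observed
#' only when the transplant happened before the registry's collection
#' window closed: `T` is seen only if `T <= R`.  Reversing time about
#' `tau = max(R)` turns right truncation into left truncation, where the
#' product-limit estimator applies; mapped back this yields
#' `F(t | T <= tau)`, the waiting-time CDF conditional on being observed
#' by `tau`.  Equivalently, in forward time,
#' `F_hat(t) = prod over event times s > t of (1 - d(s)/Y*(s))` with
#' `Y*(s) = #\{i : T_i <= s <= R_i\}`.
#'
#' @param waiting data frame with columns `T` (observed waiting time,
#'   days) and `R` (right-truncation limit, days).
#' @param tau conditioning horizon; defaults to `max(R)`.
#' @param ci_level confidence level.
#' @return an [msm_step] of kind `"cif"` carrying `F_hat(t | T <= tau)`;
#'   attribute `tau` records the horizon.
#' @export
right_truncated_cdf <- function(waiting, tau = NULL, ci_level = 0.95) {
  waiting <- as.data.frame(waiting)
  stopifnot(all(c("T", "R") %in% names(waiting)))
  if (any(waiting$T > waiting$R))
    stop("waiting time exceeds its right-truncation limit")
  if (any(waiting$T <= 0)) stop("non-positive waiting time")
  if (is.null(tau)) tau <- max(waiting$R)
  times <- sort(unique(waiting$T))
  d <- as.integer(rowsum(rep(1L, nrow(waiting)), group = waiting$T)[, 1])
  # reversed-time risk set: subjects with T <= s <= R
  y <- vapply(times, function(s) sum(waiting$T <= s & waiting$R >= s), 0L)
  # F(t)/F(tau) = prod_{s > t} (1 - d/Y*); build from the right
  frac <- 1 - d / y
  revprod <- rev(cumprod(rev(frac)))          # prod over s >= t_j
  Fhat <- c(revprod[-1], 1)                   # prod over s > t_j
  # Greenwood-type variance on the reversed scale
  gvar <- d / (y * pmax(y - d, 1))
  gvar[y == d] <- 0
  cumg <- rev(cumsum(rev(gvar)))              # sum over s >= t_j
  vhat <- Fhat^2 * c(cumg[-1], 0)
  sf <- msm_step(times, Fhat, vhat, kind = "cif", n = nrow(waiting),
                 n_events = nrow(waiting), ci_level = ci_level)
  attr(sf, "tau") <- tau
  sf
}

#' Cumulative transition rate implied by a waiting-time CDF
#'
#' The hazard-scale transform of a conditional waiting-time distribution:
#' increments `dF(t) / (1 - F(t-))`, the display used for cumulative
#' diagnosis-to-transplant rates.  Note this is the hazard of the
#' conditional waiting-time distribution, not yet the illness-death
#' transition intensity; see [reconstruct_strategy_survival] for the
#' conversion used in reconstruction.
#'
#' @param cdf an [msm_step] of kind `"cif"` from [right_truncated_cdf].
#' @return an [msm_step] of kind `"cumhaz"`.
#' @export
waiting_time_cumhaz <- function(cdf) {
  stopifnot(inherits(cdf, "msm_step"), cdf$kind == "cif")
  Fm <- c(0, cdf$est[-length(cdf$est)])
  dF <- diff(c(0, cdf$est))
  inc <- ifelse(1 - Fm > 0, dF / (1 - Fm), 0)
  msm_step(cdf$time, cumsum(inc), kind = "cumhaz", n = cdf$n,
           n_events = cdf$n_events, ci_level = cdf$ci_level)
}

#' Competing-risks cumulative incidence with delayed entry
#'
#' Aalen-Johansen form of the cumulative incidence function:
#' `CIF_k(t) = sum over event times u <= t of S(u-) d_k(u) / Y(u)` where
#' `S` is the all-cause Kaplan-Meier.  At every knot the cause-specific
#' CIFs and the event-free probability sum to one.
#'
#' @param rows data frame with `entry`, `exit`, `status` and, for rows
#'   with `status = 1`, a `cause` column (e.g. `"relapse"`, `"NRM"`).
#'   At most one event row per subject (`id` column, if present, is
#'   checked).
#' @param ci_level confidence level.
#' @return named list of [msm_step] objects of kind `"cif"`, one per
#'   cause, each on the pooled event-time grid.
#' @export
competing_risks_cif <- function(rows, ci_level = 0.95) {
  rows <- check_rows(rows)
  if (!"cause" %in% names(rows)) stop("rows must carry a cause column")
  if ("id" %in% names(rows)) {
    ev <- rows[rows$status == 1, ]
    if (anyDuplicated(ev$id))
      stop("overlapping causes: subject with more than one event row")
  }
  causes <- sort(unique(rows$cause[rows$status == 1]))
  if (!length(causes)) stop("no events")
  rs_all <- risk_sets_fast(rows$entry, rows$exit, rows$status)
  if (any(rs_all$n_risk == 0)) stop("empty risk set (left-truncation gap)")
  surv_minus <- c(1, cumprod(1 - rs_all$n_event / rs_all$n_risk))
  surv_minus <- surv_minus[-length(surv_minus)]   # S(u-)
  out <- list()
  for (k in causes) {
    dk <- vapply(rs_all$time, function(t)
      sum(rows$exit == t & rows$status == 1 & rows$cause == k), 0L)
    inc <- surv_minus * dk / rs_all$n_risk
    cif <- cumsum(inc)
    # Aalen (1978) variance via the delta method, simple Greenwood-style
    # approximation adequate for descriptive use
    vr <- cumsum(surv_minus^2 * dk / rs_all$n_risk^2)
    out[[k]] <- msm_step(rs_all$time, cif, vr, kind = "cif",
                         n = nrow(rows), n_events = sum(dk),
                         ci_level = ci_level)
  }
  out
}
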