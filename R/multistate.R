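#' Aalen-Johansen transition probabilities for the illness-death model
#'
#' Product integral `P(s, t] = prod over u in (s, t] of (I + dA(u))` on
#' the pooled knot grid of the three cumulative transition hazards
#' (Diagnosis->Transplant, Diagnosis->Death, Transplant->Death), all on
#' the diagnosis time scale (clock-forward Markov).  The transition
#' structure is upper-triangular — no recovery from Death, no reverse
#' transplant — so the product reduces to two scalar recursions.
#'
#' @param cumhaz_12,cumhaz_13,cumhaz_23 [msm_step] objects of kind
#'   `"cumhaz"` on the diagnosis time scale.
#' @param s start time (days); subjects are in Diagnosis at `s`.
#' @return A `tpmatrix` object: `time` (evaluation knots > `s`), `P` (an
#'   array `length(time) x 3 x 3`), `s`.  Rows sum to one; `P[, 1, 1]`
#'   is the probability of still awaiting transplant, `P[, 1, 3]` the
#'   probability of having died.
#' @export
aalen_johansen <- function(cumhaz_12, cumhaz_13, cumhaz_23, s = 0) {
  for (h in list(cumhaz_12, cumhaz_13, cumhaz_23))
    stopifnot(inherits(h, "msm_step"), h$kind == "cumhaz")
  times <- sort(unique(c(cumhaz_12$time, cumhaz_13$time, cumhaz_23$time)))
  times <- times[times > s]
  K <- length(times)
  dA12 <- step_increments(cumhaz_12, times, s)
  dA13 <- step_increments(cumhaz_13, times, s)
  dA23 <- step_increments(cumhaz_23, times, s)
  if (any(dA12 + dA13 > 1 + 1e-12) || any(dA23 > 1 + 1e-12))
    stop("hazard increment > 1: row of I + dA would go negative")
  P <- array(0, c(K, 3, 3))
  p11 <- 1; p12 <- 0; p13 <- 0
  p22 <- 1; p23 <- 0
  for (k in seq_len(K)) {
    # state 1 occupation splits into stay / to transplant / to death
    new12 <- p12 * (1 - dA23[k]) + p11 * dA12[k]
    new13 <- p13 + p12 * dA23[k] + p11 * dA13[k]
    p11 <- p11 * (1 - dA12[k] - dA13[k])
    p12 <- new12; p13 <- new13
    new23 <- p23 + p22 * dA23[k]
    p22 <- p22 * (1 - dA23[k])
    p23 <- new23
    P[k, 1, ] <- c(p11, p12, p13)
    P[k, 2, ] <- c(0, p22, p23)
    P[k, 3, ] <- c(0, 0, 1)
  }
  structure(list(time = times, P = P, s = s), class = "tpmatrix")
}

# increments of a cumulative-hazard step function on a superset grid
step_increments <- function(sf, times, s = 0) {
  vals <- step_eval(sf, times)
  diff(c(step_eval(sf, s), vals))
}

#' @export
print.tpmatrix <- function(x, ...) {
  cat(sprintf("Aalen-Johansen transition probabilities from s = %g: %d knots\n",
              x$s, length(x$time)))
  if (length(x$time)) {
    k <- length(x$time)
    cat(sprintf("P(s, %g) =\n", x$time[k]))
    print(round(x$P[k, , ], 4))
  }
  invisible(x)
}

#' Evaluate transition probabilities at arbitrary times
#'
#' @param tp a `tpmatrix` from [aalen_johansen].
#' @param t evaluation times.
#' @param from,to state indices (1 Diagnosis, 2 Transplant, 3 Death).
#' @return numeric vector `P_{from,to}(s, t)`.
#' @export
tp_eval <- function(tp, t, from = 1, to = 3) {
  stopifnot(inherits(tp, "tpmatrix"))
  idx <- findInterval(t, tp$time)
  base <- as.numeric(from == to)
  out <- ifelse(idx == 0, base, tp$P[pmax(idx, 1), from, to])
  out[t < tp$s] <- NA_real_
  out
}

#' Reconstruct from-diagnosis survival for both treatment strategies
#'
#' The package's central product.  The three estimable inputs are
#' combined under the Markov assumption — the pre-transplant death
#' hazard of transplant candidates equals the non-transplant cohort's
#' death hazard — into the from-diagnosis survival curve of the
#' transplant strategy:
#'
#' * `A13(t)`: Nelson-Aalen Diagnosis->Death hazard from the
#'   non-transplant registry;
#' * `A23(t)`: Nelson-Aalen Transplant->Death hazard from the transplant
#'   registry with delayed entry at transplant (clock-forward);
#' * `A12(t)`: the Diagnosis->Transplant intensity recovered from the
#'   right-truncated waiting-time CDF `F*`.  Because `F*` is the
#'   waiting-time distribution *among patients who reach transplant*, its
#'   hazard transform `dF*(t) / (1 - F*(t-))` estimates the rate of
#'   leaving Diagnosis by either route; the transplant intensity is
#'   obtained by subtracting the death hazard,
#'   `dA12(t) = dF*(t)/(1 - F*(t-)) - dA13(t)` (floored at zero).  This
#'   identity is exact when the ratio of the two Diagnosis exit hazards
#'   is constant over time and the truncation horizon is long; it is the
#'   package's identifiability assumption for the unobservable
#'   Diagnosis->Transplant risk set.
#'
#' The transplant-strategy curve is `1 - P13(0, t)` from
#' [aalen_johansen]; the non-transplant curve is the plain Kaplan-Meier
#' of the non-transplant registry.  Both start at diagnosis.
#'
#' @param dataset result of [assemble_multistate_dataset] with
#'   `clock = "forward"`.
#' @param boot number of bootstrap resamples for pointwise percentile
#'   confidence bands (0 = none).  Resampling is subject-level,
#'   stratified by registry.
#' @param seed optional seed for the bootstrap.
#' @param ci_level confidence level for the bands.
#' @return A `strategy_curves` object: `tx` and `non_tx` ([msm_step]
#'   survival curves), `medians` (days), `tau` (the waiting-time
#'   truncation horizon beyond which the transplant curve is not
#'   identified), `aj` (the underlying `tpmatrix`), and the three
#'   cumulative hazards.
#' @export
reconstruct_strategy_survival <- function(dataset, boot = 0L, seed = NULL,
                                          ci_level = 0.95) {
  if (dataset$clock != "forward")
    stop("reconstruction requires clock = \"forward\" (Markov time scale)")
  curves <- strategy_curves_once(dataset, ci_level)
  if (boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    rows <- dataset$rows
    non_ids <- unique(rows$id[rows$trans == 2])
    tx_ids <- unique(rows$id[rows$trans == 3])
    grid_tx <- curves$tx$time
    grid_non <- curves$non_tx$time
    bs_tx <- matrix(NA_real_, boot, length(grid_tx))
    bs_non <- matrix(NA_real_, boot, length(grid_non))
    for (b in seq_len(boot)) {
      bn <- sample(non_ids, replace = TRUE)
      bt <- sample(tx_ids, replace = TRUE)
      d <- resample_dataset(dataset, bn, bt)
      cb <- tryCatch(suppressWarnings(strategy_curves_once(d, ci_level)),
                     error = function(e) NULL)
      if (is.null(cb)) next
      bs_tx[b, ] <- step_eval(cb$tx, grid_tx)
      bs_non[b, ] <- step_eval(cb$non_tx, grid_non)
    }
    a <- (1 - ci_level) / 2
    band <- function(m) apply(m, 2, stats::quantile,
                              probs = c(a, 1 - a), na.rm = TRUE)
    btx <- band(bs_tx); bnon <- band(bs_non)
    curves$tx$lower <- pmin(btx[1, ], curves$tx$est)
    curves$tx$upper <- pmax(btx[2, ], curves$tx$est)
    curves$non_tx$lower <- pmin(bnon[1, ], curves$non_tx$est)
    curves$non_tx$upper <- pmax(bnon[2, ], curves$non_tx$est)
    curves$boot <- boot
  }
  curves
}

strategy_curves_once <- function(dataset, ci_level = 0.95) {
  rows <- dataset$rows
  non_rows <- rows[rows$trans == 2, ]
  tx_rows <- rows[rows$trans == 3, ]
  if (!nrow(non_rows) || !nrow(tx_rows)) stop("a registry is empty")
  A13 <- nelson_aalen(non_rows, ci_level)
  A23 <- nelson_aalen(tx_rows, ci_level)
  Fstar <- right_truncated_cdf(dataset$waiting, ci_level = ci_level)
  tau <- attr(Fstar, "tau")
  # exit hazard of state 1 from the conditional waiting-time CDF, minus
  # the death hazard accumulated since the previous waiting-time knot
  # (Markov assumption), floored at zero.  Both measures are pure jumps
  # on different grids, so the subtraction is interval-wise on the
  # waiting-time event grid.
  grid <- Fstar$time
  dExit <- step_increments(waiting_time_cumhaz(Fstar), grid)
  d13_acc <- step_increments(A13, grid)
  d12 <- pmax(dExit - d13_acc, 0)
  d12 <- pmin(d12, 1)   # a single increment cannot exceed total exit mass
  A12 <- msm_step(grid, cumsum(d12), kind = "cumhaz",
                  n = Fstar$n, n_events = Fstar$n_events)
  aj <- aalen_johansen(A12, A13, A23, s = 0)
  keep <- aj$time <= tau
  if (!all(keep))
    warning("waiting-time CDF undefined beyond tau = ", signif(tau, 6),
            " days; strategy curve truncated there")
  surv_tx <- 1 - aj$P[, 1, 3]
  tx_curve <- msm_step(aj$time[keep], pmin(cummin(surv_tx[keep]), 1),
                       kind = "survival", n = nrow(dataset$waiting),
                       n_events = sum(tx_rows$status))
  attr(tx_curve, "median") <- step_quantile(tx_curve, 0.5)
  non_curve <- kaplan_meier(non_rows, ci_level)
  structure(list(
    tx = tx_curve, non_tx = non_curve,
    medians = c(tx = step_quantile(tx_curve, 0.5),
                non_tx = step_quantile(non_curve, 0.5)),
    tau = tau, aj = aj,
    cumhaz = list(A12 = A12, A13 = A13, A23 = A23)),
    class = "strategy_curves")
}

resample_dataset <- function(dataset, non_ids, tx_ids) {
  rows <- dataset$rows
  pick <- function(tab, ids, key) {
    idx <- match(ids, tab[[key]])
    out <- tab[idx, , drop = FALSE]
    out$id <- paste0("b", seq_along(idx))
    out
  }
  non_rows <- rows[rows$trans == 2, ]
  tx_rows <- rows[rows$trans == 3, ]
  list(rows = rbind(pick(non_rows, non_ids, "id"), pick(tx_rows, tx_ids, "id")),
       waiting = pick(dataset$waiting, tx_ids, "id"),
       comparison = NULL, clock = dataset$clock)
}

#' @export
print.strategy_curves <- function(x, ...) {
  cat("From-diagnosis survival by treatment strategy\n")
  cat(sprintf("  transplant strategy : %d knots, median %s days\n",
              length(x$tx$time),
              ifelse(is.na(x$medians["tx"]), "not reached",
                     format(x$medians["tx"]))))
  cat(sprintf("  non-transplant      : %d knots, median %s days\n",
              length(x$non_tx$time),
              ifelse(is.na(x$medians["non_tx"]), "not reached",
                     format(x$medians["non_tx"]))))
  cat(sprintf("  identified up to tau = %g days (%.1f years)\n",
              x$tau, days_to_years(x$tau)))
  invisible(x)
}

#' State-occupation probabilities over time
#'
#' Presentation layer over [aalen_johansen]: the probability of being in
#' Diagnosis (alive, untransplanted), Transplant (alive, transplanted)
#' and Death at each knot, starting from Diagnosis at time 0.  The three
#' curves sum to one everywhere.
#'
#' @param dataset result of [assemble_multistate_dataset]
#'   (`clock = "forward"`).
#' @return A data frame `time_days`, `diagnosis`, `transplant`, `death`.
#' @export
state_occupation <- function(dataset) {
  sc <- strategy_curves_once(dataset)
  aj <- sc$aj
  keep <- aj$time <= sc$tau
  data.frame(time_days = aj$time[keep],
             diagnosis = aj$P[keep, 1, 1],
             transplant = aj$P[keep, 1, 2],
             death = aj$P[keep, 1, 3])
}
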