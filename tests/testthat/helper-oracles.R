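# Independent oracles and small fixture builders shared across tests.
# Every oracle here recomputes its quantity by direct enumeration, never
# through the package's own code paths.

# Breslow partial log-likelihood by direct risk-set enumeration (O(K n)),
# for a single numeric covariate; used for grid-search argmax checks.
oracle_partial_loglik <- function(beta, entry, exit, status, x) {
  ev_times <- sort(unique(exit[status == 1]))
  ll <- 0
  for (t in ev_times) {
    risk <- which(entry < t & exit >= t)
    dead <- which(exit == t & status == 1)
    ll <- ll + sum(beta * x[dead]) - length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_grid_argmax <- function(entry, exit, status, x,
                               grid = seq(-5, 5, by = 1e-4)) {
  # vectorised over the grid: S0(t, beta) enumerated per event time
  ev_times <- sort(unique(exit[status == 1]))
  ll <- numeric(length(grid))
  sum_x_dead <- 0
  for (t in ev_times) {
    risk <- which(entry < t & exit >= t)
    dead <- which(exit == t & status == 1)
    sum_x_dead <- sum_x_dead + sum(x[dead])
    ll <- ll - length(dead) *
      log(colSums(exp(outer(x[risk], grid))))
  }
  grid[which.max(sum_x_dead * grid + ll)]
}

# Reverse-time product-limit for right-truncated data, written as an
# explicit left-truncated Kaplan-Meier in reversed time.
oracle_right_trunc_cdf <- function(T, R, eval_times) {
  tau <- max(R)
  # reversed time: subject enters at tau - R, "fails" at tau - T
  entry <- tau - R; fail <- tau - T
  ev <- sort(unique(fail))
  surv <- 1
  km <- data.frame(time = ev, surv = NA_real_)
  for (i in seq_along(ev)) {
    t <- ev[i]
    y <- sum(entry <= t & fail >= t)   # closed on both sides in reversed time
    d <- sum(fail == t)
    surv <- surv * (1 - d / y)
    km$surv[i] <- surv
  }
  # F(t) = P(T <= t | T <= tau): the mass at t itself is included, so in
  # reversed time the product runs over failures strictly before tau - t
  vapply(eval_times, function(t) {
    past <- km$time[km$time < tau - t]
    if (!length(past)) 1 else km$surv[match(max(past), km$time)]
  }, 0)
}

# Cumulative incidence by direct enumeration of the CIF sum.
oracle_cif <- function(entry, exit, status, cause, which_cause, eval_times) {
  ev <- sort(unique(exit[status == 1]))
  surv_minus <- 1; cif <- 0
  steps <- data.frame(time = ev, cif = NA_real_)
  for (i in seq_along(ev)) {
    t <- ev[i]
    y <- sum(entry < t & exit >= t)
    d_all <- sum(exit == t & status == 1)
    d_k <- sum(exit == t & status == 1 & cause == which_cause)
    cif <- cif + surv_minus * d_k / y
    surv_minus <- surv_minus * (1 - d_all / y)
    steps$cif[i] <- cif
  }
  vapply(eval_times, function(t) {
    past <- steps$time[steps$time <= t]
    if (!length(past)) 0 else steps$cif[match(max(past), steps$time)]
  }, 0)
}

# closed-form alive probability of the constant-hazard illness-death
# model (rates per year, t in years)
closed_form_alive <- function(t, l12, l13, l23) {
  exp(-(l12 + l13) * t) +
    l12 / (l12 + l13 - l23) * (exp(-l23 * t) - exp(-(l12 + l13) * t))
}

# small well-formed registry tables
make_tx_records <- function(t_tx, t_end, dead, r_trunc = NA, ids = NULL) {
  n <- length(t_tx)
  data.frame(id = ids %||% paste0("tx", seq_len(n)), cohort = "tx_registry",
             t_tx_days = t_tx, t_end_days = t_end, dead = dead,
             r_trunc_days = r_trunc, age_gt60 = 0, raebt = 0,
             cyto_abnormal = 0, year_dx = 2000L)
}

make_non_tx_records <- function(t_end, dead, ids = NULL) {
  n <- length(t_end)
  data.frame(id = ids %||% paste0("nt", seq_len(n)),
             cohort = "non_tx_registry",
             t_tx_days = NA_real_, t_end_days = t_end, dead = dead,
             r_trunc_days = NA_real_, age_gt60 = 0, raebt = 0,
             cyto_abnormal = 0, year_dx = 2000L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sample exponential counting-process fixture
make_two_sample <- function(n, log_hr, censor_rate = 0.3) {
  x <- stats::rbinom(n, 1, 0.5)
  t <- stats::rexp(n, exp(log_hr * x))
  c <- stats::rexp(n, censor_rate)
  data.frame(entry = 0, exit = pmin(t, c), status = as.integer(t <= c), x = x)
}
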