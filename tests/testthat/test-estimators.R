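test_that("Nelson-Aalen matches hand risk-set counting", {
  # all censored: flat zero
  flat <- nelson_aalen(data.frame(entry = 0, exit = c(1, 2, 5), status = 0))
  expect_length(flat$time, 0)
  expect_equal(step_eval(flat, c(1, 10)), c(0, 0))
  # entries 0, exits 1,2,3 all events: 1/3 + 1/2 + 1
  na1 <- nelson_aalen(data.frame(entry = 0, exit = 1:3, status = 1))
  expect_equal(step_eval(na1, 3), 1/3 + 1/2 + 1)
  # delayed entry: (0,2] event, (1,3] event -> 1/2 at t=2, 1 at t=3
  na2 <- nelson_aalen(data.frame(entry = c(0, 1), exit = c(2, 3), status = 1))
  expect_equal(na2$est, c(0.5, 1.5))
  expect_equal(na2$var, c(1/4, 1/4 + 1))
})

test_that("Kaplan-Meier matches the hand product-limit and reports medians", {
  km <- kaplan_meier(data.frame(entry = 0, exit = c(1, 2), status = 1))
  expect_equal(km$est, c(0.5, 0))
  expect_equal(attr(km, "median"), 1)
  allc <- kaplan_meier(data.frame(entry = 0, exit = c(3, 4), status = 0))
  expect_equal(step_eval(allc, 10), 1)
  expect_true(is.na(attr(allc, "median")))   # median not reached
})

test_that("KM and Nelson-Aalen agree with survival::survfit under delayed entry", {
  skip_if_not_installed("survival")
  set.seed(42)
  n <- 150
  entry <- runif(n, 0, 1)
  exit <- entry + rexp(n, 1)
  status <- rbinom(n, 1, 0.6)
  rows <- data.frame(entry = entry, exit = exit, status = status)
  mine_km <- kaplan_meier(rows)
  mine_na <- nelson_aalen(rows)
  sf <- survival::survfit(survival::Surv(entry, exit, status) ~ 1,
                          data = rows, ctype = 1)
  ev <- sf$time[sf$n.event > 0]
  expect_equal(step_eval(mine_km, ev), sf$surv[sf$n.event > 0],
               tolerance = 1e-12)
  expect_equal(step_eval(mine_na, ev), sf$cumhaz[sf$n.event > 0],
               tolerance = 1e-12)
  # Greenwood variance agrees too
  expect_equal(sqrt(mine_km$var), sf$std.err[sf$n.event > 0] *
                 sf$surv[sf$n.event > 0], tolerance = 1e-10)
})

test_that("malformed at-risk intervals are rejected", {
  expect_silent(nelson_aalen(data.frame(entry = c(0, 5), exit = c(1, 8),
                                        status = 1)))
  expect_error(nelson_aalen(data.frame(entry = 2, exit = 1, status = 1)),
               "entry >= exit")
  expect_error(kaplan_meier(data.frame(entry = -1, exit = 1, status = 1)),
               "negative entry")
})

test_that("right-truncated CDF reduces to the empirical CDF without truncation", {
  w <- data.frame(T = c(3, 1, 4, 1, 5), R = 10)
  cdf <- right_truncated_cdf(w)
  expect_equal(step_eval(cdf, c(1, 3, 4, 5)), c(0.4, 0.6, 0.8, 1))
  # all waiting times equal: degenerate single-step CDF is allowed
  deg <- right_truncated_cdf(data.frame(T = c(2, 2, 2), R = 5))
  expect_equal(deg$est, 1)
  expect_error(right_truncated_cdf(data.frame(T = 5, R = 3)),
               "exceeds its right-truncation limit")
})

test_that("right-truncated CDF equals the reverse-time product-limit oracle", {
  w <- data.frame(T = c(2, 1, 3, 2), R = c(3, 2, 4, 4))
  cdf <- right_truncated_cdf(w)
  # hand enumeration: Y*(1)=1, Y*(2)=3, Y*(3)=3 -> F = 2/9, 2/3, 1
  expect_equal(step_eval(cdf, c(0.5, 1, 2, 3)), c(0, 2/9, 2/3, 1))
  expect_equal(step_eval(cdf, c(1, 2, 3)),
               oracle_right_trunc_cdf(w$T, w$R, c(1, 2, 3)))
  # random staggered instances agree with the oracle everywhere
  set.seed(8)
  for (rep in 1:20) {
    T <- sample(1:15, 8, replace = TRUE)
    R <- T + sample(0:10, 8, replace = TRUE)
    ev <- sort(unique(T))
    expect_equal(step_eval(right_truncated_cdf(data.frame(T = T, R = R)), ev),
                 oracle_right_trunc_cdf(T, R, ev), tolerance = 1e-12)
  }
})

test_that("competing-risks CIF reduces to 1 - KM and conserves probability", {
  set.seed(5)
  n <- 60
  rows <- data.frame(id = seq_len(n), entry = 0, exit = rexp(n),
                     status = rbinom(n, 1, 0.7))
  rows$cause <- ifelse(rows$status == 1, "relapse", NA)
  cif <- competing_risks_cif(rows)$relapse
  km <- kaplan_meier(rows)
  expect_equal(cif$est, 1 - km$est, tolerance = 1e-12)

  rows$cause[rows$status == 1] <- sample(c("relapse", "NRM"),
                                         sum(rows$status), replace = TRUE)
  cifs <- competing_risks_cif(rows)
  ev <- sort(unique(rows$exit[rows$status == 1]))
  total <- step_eval(cifs$relapse, ev) + step_eval(cifs$NRM, ev) +
    step_eval(km, ev)
  expect_equal(total, rep(1, length(ev)), tolerance = 1e-12)
})

test_that("CIF matches the direct-sum oracle on a toy delayed-entry table", {
  rows <- data.frame(id = 1:4, entry = c(0, 0, 1, 2),
                     exit = c(2, 3, 4, 6), status = c(1, 1, 0, 1),
                     cause = c("relapse", "NRM", NA, "relapse"))
  cifs <- competing_risks_cif(rows)
  ev <- c(2, 3, 6)
  expect_equal(step_eval(cifs$relapse, ev),
               oracle_cif(rows$entry, rows$exit, rows$status, rows$cause,
                          "relapse", ev))
  expect_equal(step_eval(cifs$NRM, ev),
               oracle_cif(rows$entry, rows$exit, rows$status, rows$cause,
                          "NRM", ev))
  dup <- rbind(rows, data.frame(id = 1, entry = 0, exit = 5, status = 1,
                                cause = "NRM"))
  expect_error(competing_risks_cif(dup), "more than one event")
})

test_that("ignoring delayed entry biases the early cumulative hazard downward", {
  # immortal-time direction: treating left-truncated subjects as at risk
  # from t = 0 dilutes early risk sets
  ps <- scenario_presets(n = 1500, seed = 314)
  regs <- simulate_registries(ps[["s1-markov"]])
  tx <- regs$tx_registry
  with_entry <- nelson_aalen(data.frame(entry = tx$t_tx_days,
                                        exit = tx$t_end_days,
                                        status = tx$dead))
  no_entry <- nelson_aalen(data.frame(entry = 0, exit = tx$t_end_days,
                                      status = tx$dead))
  at <- years_to_days(c(0.5, 1))
  expect_true(all(step_eval(no_entry, at) < step_eval(with_entry, at)))
})

test_that("Nelson-Aalen is linear in t for constant hazards", {
  set.seed(99)
  n <- 2000; lam <- 0.7
  rows <- data.frame(entry = 0, exit = pmin(rexp(n, lam), 2),
                     status = NA)
  rows$status <- as.integer(rows$exit < 2)
  na <- nelson_aalen(rows)
  t_star <- max(na$time[na$time <= 1.5])
  slope <- step_eval(na, t_star) / t_star
  se <- sqrt(na$var[match(t_star, na$time)]) / t_star
  expect_lt(abs(slope - lam), 3 * se)
})

test_that("KM tracks exp(-Nelson-Aalen) within the summed squared increments", {
  set.seed(12)
  rows <- data.frame(entry = 0, exit = rexp(400), status = rbinom(400, 1, .8))
  km <- kaplan_meier(rows)
  na <- nelson_aalen(rows)
  inc <- diff(c(0, na$est))
  gap <- abs(km$est - exp(-na$est))
  expect_true(all(gap <= cumsum(inc^2) + 1e-12))
})
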