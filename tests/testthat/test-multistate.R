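mk_cumhaz <- function(times, values) msm_step(times, values, kind = "cumhaz")

test_that("zero hazards give the identity transition matrix", {
  z <- mk_cumhaz(c(10, 50), c(0, 0))
  aj <- aalen_johansen(z, z, z)
  for (k in seq_along(aj$time))
    expect_equal(aj$P[k, , ], diag(3))
  expect_equal(tp_eval(aj, 30, 1, 1), 1)
})

test_that("with only Diagnosis->Death the model collapses to Kaplan-Meier", {
  set.seed(10)
  n <- 50
  rows <- data.frame(entry = 0, exit = rexp(n), status = rbinom(n, 1, 0.8))
  km <- kaplan_meier(rows)
  na13 <- nelson_aalen(rows)
  zero <- mk_cumhaz(numeric(0), numeric(0))
  aj <- aalen_johansen(zero, na13, zero)
  expect_equal(aj$P[, 1, 1], step_eval(km, aj$time), tolerance = 1e-12)
  expect_equal(1 - aj$P[, 1, 3], step_eval(km, aj$time), tolerance = 1e-12)
})

test_that("product integral matches the constant-hazard closed form", {
  gy <- seq(0.001, 5, by = 0.001)
  gd <- years_to_days(gy)
  aj <- aalen_johansen(mk_cumhaz(gd, 1.0 * gy), mk_cumhaz(gd, 0.3 * gy),
                       mk_cumhaz(gd, 0.5 * gy))
  alive <- closed_form_alive(gy, 1.0, 0.3, 0.5)
  expect_lt(max(abs((1 - aj$P[, 1, 3]) - alive)), 1e-3)
  expect_lt(max(abs(aj$P[, 1, 1] - exp(-1.3 * gy))), 1e-3)
  p12 <- 1.0 / (1.3 - 0.5) * (exp(-0.5 * gy) - exp(-1.3 * gy))
  expect_lt(max(abs(aj$P[, 1, 2] - p12)), 1e-3)
  # structural invariants on the whole path
  rs <- apply(aj$P, 1, function(m) rowSums(matrix(m, 3, 3)))
  expect_lt(max(abs(rs - 1)), 1e-10)
  expect_true(all(aj$P >= 0 & aj$P <= 1 + 1e-12))
  expect_true(all(diff(aj$P[, 1, 3]) >= -1e-12))   # death non-decreasing
  expect_true(all(aj$P[, 3, 3] == 1))              # death absorbing
})

test_that("oversized hazard increments are refused", {
  big <- mk_cumhaz(c(5, 10), c(0.8, 1.9))
  z <- mk_cumhaz(numeric(0), numeric(0))
  expect_error(aalen_johansen(big, mk_cumhaz(5, 0.5), z), "increment > 1")
})

test_that("strategy curves coincide when transplant never happens to matter", {
  # equal death hazards before and after transplant: the transplant
  # strategy curve equals the supportive-care curve by construction
  sc <- scenario(1.0, 0.35, 0.35, n = 5000, seed = 61)
  regs <- simulate_registries(sc)
  ds <- assemble_multistate_dataset(regs$non_tx_registry, regs$tx_registry)
  curves <- reconstruct_strategy_survival(ds)
  grid <- years_to_days(seq(0.1, 4, by = 0.1))
  gap <- abs(step_eval(curves$tx, grid) - step_eval(curves$non_tx, grid))
  expect_lt(max(gap), 0.02)
})

test_that("reconstruction recaptures the complete-cohort truth", {
  ps <- scenario_presets(n = 5000, seed = 303)
  regs <- simulate_registries(ps[["s1-markov"]])
  ds <- assemble_multistate_dataset(regs$non_tx_registry, regs$tx_registry)
  curves <- reconstruct_strategy_survival(ds)
  grid <- years_to_days(seq(0.1, 5, by = 0.1))
  truth <- vapply(grid, function(h) mean(regs$strategy$truth$t_death > h), 0)
  expect_lt(max(abs(step_eval(curves$tx, grid) - truth)), 0.03)
})

test_that("reconstruction is refused on the clock-reset scale", {
  sc <- scenario(1.0, 0.3, 0.5, n = 200, seed = 3)
  regs <- simulate_registries(sc)
  ds <- assemble_multistate_dataset(regs$non_tx_registry, regs$tx_registry,
                                    clock = "reset")
  expect_error(reconstruct_strategy_survival(ds), "forward")
})

test_that("state occupation probabilities conserve mass and peak in transit", {
  sc <- scenario(1.0, 0.3, 0.5, n = 3000, seed = 17)
  regs <- simulate_registries(sc)
  ds <- assemble_multistate_dataset(regs$non_tx_registry, regs$tx_registry)
  occ <- state_occupation(ds)
  expect_equal(occ$time_days[1] >= 0, TRUE)
  expect_lt(max(abs(occ$diagnosis + occ$transplant + occ$death - 1)), 1e-10)
  expect_true(all(diff(occ$death) >= -1e-12))
  # closed form: transplant occupation rises then falls
  gy <- days_to_years(occ$time_days)
  p12 <- 1.0 / (1.3 - 0.5) * (exp(-0.5 * gy) - exp(-1.3 * gy))
  expect_lt(max(abs(occ$transplant - p12)), 0.04)
  peak <- which.max(occ$transplant)
  expect_true(peak > 1 && peak < nrow(occ))
})

test_that("the strategy curve spreads the early post-transplant drop", {
  # with a TRM spike, the from-transplant KM falls steeply right after
  # its origin; the from-diagnosis reconstruction disperses that drop
  # over the waiting-time distribution
  ps <- scenario_presets(n = 3000, seed = 42)
  regs <- simulate_registries(ps[["s1-trm"]])
  tx <- regs$tx_registry
  ds <- assemble_multistate_dataset(regs$non_tx_registry, tx)
  curves <- reconstruct_strategy_survival(ds)
  km_from_tx <- kaplan_meier(data.frame(entry = 0,
                                        exit = tx$t_end_days - tx$t_tx_days,
                                        status = tx$dead))
  half_year <- years_to_days(0.5)
  drop_strategy <- 1 - step_eval(curves$tx, half_year)
  drop_from_tx <- 1 - step_eval(km_from_tx, half_year)
  expect_lt(drop_strategy, drop_from_tx)
})

test_that("bootstrap bands bracket the point estimate", {
  sc <- scenario(1.0, 0.3, 0.5, n = 400, seed = 15)
  regs <- simulate_registries(sc)
  ds <- assemble_multistate_dataset(regs$non_tx_registry, regs$tx_registry)
  curves <- reconstruct_strategy_survival(ds, boot = 25, seed = 1)
  expect_true(all(curves$tx$lower <= curves$tx$est + 1e-12))
  expect_true(all(curves$tx$upper >= curves$tx$est - 1e-12))
  expect_equal(curves$boot, 25)
})
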