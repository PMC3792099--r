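test_that("Newton estimate equals the grid-search partial-likelihood argmax", {
  set.seed(4)
  fixtures <- list(
    # 12 rows, binary covariate, some censoring
    data.frame(entry = 0, exit = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
               status = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1),
               x = rep(c(0, 1), 6)),
    # 30 rows with delayed entry and ties
    {
      n <- 30
      d <- data.frame(entry = round(runif(n, 0, 2), 1), x = rbinom(n, 1, .5))
      d$exit <- d$entry + ceiling(rexp(n, exp(0.6 * d$x)) * 4) / 4
      d$status <- rbinom(n, 1, 0.8)
      d
    },
    # 40 rows, continuous covariate (coarse so grid argmax is meaningful)
    {
      n <- 40
      d <- data.frame(entry = 0, x = round(rnorm(n), 1))
      d$exit <- rexp(n, exp(-0.4 * d$x))
      d$status <- 1
      d
    })
  for (d in fixtures) {
    fit <- fit_cox(d, "x")
    bstar <- oracle_grid_argmax(d$entry, d$exit, d$status, d$x)
    expect_lt(abs(unname(fit$beta) - bstar), 1e-4)
    expect_lt(max(abs(fit$gradient)), 1e-6)
    # reported optimum dominates the whole oracle grid
    expect_gte(fit$loglik["optimum"] + 1e-10,
               oracle_partial_loglik(bstar, d$entry, d$exit, d$status, d$x))
  }
})

test_that("fit matches survival::coxph with Breslow ties, incl. baseline", {
  skip_if_not_installed("survival")
  set.seed(16)
  n <- 250
  d <- data.frame(entry = runif(n, 0, 1), x1 = rbinom(n, 1, .5),
                  x2 = rnorm(n))
  d$exit <- d$entry + round(rexp(n, exp(0.5 * d$x1 - 0.3 * d$x2)), 1) + 0.05
  d$status <- rbinom(n, 1, 0.7)
  mine <- fit_cox(d, c("x1", "x2"))
  ref <- survival::coxph(survival::Surv(entry, exit, status) ~ x1 + x2,
                         data = d, ties = "breslow")
  expect_equal(unname(mine$beta), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(mine$vcov), unname(vcov(ref)), tolerance = 1e-6)
  expect_equal(unname(mine$loglik), unname(rev(ref$loglik)), tolerance = 1e-8)
  bh <- survival::basehaz(ref, centered = FALSE)
  at <- bh$time[bh$time %in% mine$baseline$time]
  expect_equal(step_eval(mine$baseline, at),
               bh$hazard[match(at, bh$time)], tolerance = 1e-7)
})

test_that("parameter recovery: two-sample exponential with log HR = log 2", {
  set.seed(1001)
  d <- make_two_sample(1000, log(2))
  fit <- fit_cox(d, "x")
  expect_lt(abs(fit$beta - log(2)), 3 * fit$se)
  # invariants of the fit object
  expect_gte(fit$loglik["optimum"], fit$loglik["null"])
  expect_equal(unname(fit$hr), exp(unname(fit$beta)))
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("degenerate inputs raise informative errors", {
  d <- data.frame(entry = 0, exit = 1:10, status = 1, x = 1)
  expect_error(fit_cox(d, "x"), "unidentifiable")
  d$x <- rep(0:1, 5)
  d$status <- 0
  expect_error(fit_cox(d, "x"), "no events")
  # perfect separation: all early deaths in one arm, likelihood is monotone
  sep <- data.frame(entry = 0, exit = c(1:10, 101:110),
                    status = c(rep(1, 10), rep(0, 10)),
                    x = c(rep(1, 10), rep(0, 10)))
  expect_error(fit_cox(sep, "x"), "monotone|diverging")
})

test_that("treatment comparison is null when transplant changes nothing", {
  # equal death hazards before and after transplant: HR(tx) = 1
  sc <- scenario(1.0, 0.3, 0.3, n = 2000, seed = 404)
  regs <- simulate_registries(sc)
  ds <- assemble_multistate_dataset(regs$non_tx_registry, regs$tx_registry)
  fit <- fit_treatment_comparison(ds)
  expect_lt(abs(fit$beta["tx_state"]), 3 * fit$se["tx_state"])
  # adjustment covariates pass through
  fit2 <- fit_treatment_comparison(ds, adjust = c("age_gt60", "raebt"))
  expect_setequal(names(fit2$beta), c("tx_state", "age_gt60", "raebt"))
})

test_that("the average HR lies between the early and late true hazard ratios", {
  ps <- scenario_presets(n = 3000, seed = 2024)
  regs <- simulate_registries(ps[["tv-effect"]])
  ds <- assemble_multistate_dataset(regs$non_tx_registry, regs$tx_registry)
  fit <- fit_treatment_comparison(ds)
  expect_gt(unname(fit$hr["tx_state"]), 1.0)
  expect_lt(unname(fit$hr["tx_state"]), 5.8)
})

test_that("piecewise effect with no cutpoints reduces to the pooled fit", {
  sc <- scenario(1.0, 0.3, 0.5, n = 400, seed = 77)
  regs <- simulate_registries(sc)
  ds <- assemble_multistate_dataset(regs$non_tx_registry, regs$tx_registry)
  tv <- fit_time_varying_effect(ds, cutpoints = numeric(0))
  pooled <- fit_treatment_comparison(ds)
  expect_lt(abs(tv$intervals$loghr - pooled$beta["tx_state"]), 1e-10)
})

test_that("piecewise estimates are invariant to the time unit", {
  sc <- scenario(1.0, 0.3, 0.5, n = 500, seed = 88)
  regs <- simulate_registries(sc)
  ds <- assemble_multistate_dataset(regs$non_tx_registry, regs$tx_registry)
  tv_days <- fit_time_varying_effect(ds, cutpoints = c(91, 365))
  ds_y <- ds
  ds_y$comparison$entry <- days_to_years(ds$comparison$entry)
  ds_y$comparison$exit <- days_to_years(ds$comparison$exit)
  tv_years <- fit_time_varying_effect(ds_y, cutpoints = days_to_years(c(91, 365)))
  expect_equal(tv_days$intervals$loghr, tv_years$intervals$loghr,
               tolerance = 1e-8)
})

test_that("episode splitting preserves the partial likelihood", {
  # splitting at-risk intervals must not change a time-fixed fit
  set.seed(3)
  d <- make_two_sample(120, 0.5)
  split <- txmsm:::split_at_cutpoints(d, cutpoints = c(0.3, 1.1))
  expect_equal(sum(split$status), sum(d$status))
  f1 <- fit_cox(d, "x")
  f2 <- fit_cox(split, "x")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(unname(f1$loglik), unname(f2$loglik), tolerance = 1e-10)
})

test_that("PH test behaves like a score test on scaled Schoenfeld residuals", {
  skip_if_not_installed("survival")
  set.seed(6)
  d <- make_two_sample(300, 0.4)
  fit <- fit_cox(d, "x")
  mine <- test_proportional_hazards(fit)
  expect_true(mine$global_p >= 0 && mine$global_p <= 1)
  ref <- survival::cox.zph(
    survival::coxph(survival::Surv(exit, status) ~ x, data = d,
                    ties = "breslow"), transform = "km")
  # same order of magnitude as the reference implementation's statistic
  expect_lt(abs(mine$table$chisq[1] - ref$table["x", "chisq"]),
            2 + 0.5 * ref$table["x", "chisq"])
  expect_error(test_proportional_hazards(
    fit_cox(data.frame(entry = 0, exit = c(1, 2), status = c(1, 0),
                       x = c(0, 1)), "x")), "two events")
})

test_that("a null year-by-cohort interaction gives uniform Wald p-values", {
  set.seed(55)
  pvals <- replicate(150, {
    n <- 240
    year <- sample(0:7, n, replace = TRUE)
    grp <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.5)
    cns <- runif(n, 0.5, 4)
    d <- data.frame(entry = 0, exit = pmin(t, cns),
                    status = as.integer(t <= cns),
                    grp = grp, year = year, inter = grp * year)
    fit_cox(d, c("grp", "year", "inter"))$p["inter"]
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
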