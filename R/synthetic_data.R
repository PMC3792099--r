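#' Piecewise-constant hazard
#'
#' @param rates hazard rates on successive intervals.
#' @param breaks strictly increasing interior breakpoints (one fewer than
#'   `rates`); the last rate extends to infinity.
#' @param unit `"year"` (rates per year, breaks in years — the natural
#'   scale for scenario definitions) or `"day"`.  Stored internally per
#'   day with breakpoints in days.
#' @return an object of class `"pw_hazard"` with `rates` (per day) and
#'   `breaks` (days).
#' @export
pw_hazard <- function(rates, breaks = numeric(0), unit = c("year", "day")) {
  unit <- match.arg(unit)
  rates <- as.numeric(rates); breaks <- as.numeric(breaks)
  if (length(rates) != length(breaks) + 1)
    stop("need one more rate than breakpoints")
  if (any(rates < 0)) stop("negative hazard rate")
  if (length(breaks) && (any(diff(breaks) <= 0) || any(breaks <= 0)))
    stop("breakpoints must be positive and strictly increasing")
  if (unit == "year") {
    rates <- rates / DAYS_PER_YEAR
    breaks <- breaks * DAYS_PER_YEAR
  }
  structure(list(rates = rates, breaks = breaks), class = "pw_hazard")
}

# cumulative hazard of a pw_hazard at times t (days)
pw_cumhaz <- function(h, t) {
  edges <- c(0, h$breaks)
  widths <- diff(c(edges, Inf))
  base <- c(0, cumsum(h$rates * widths)[-length(h$rates)])
  j <- findInterval(t, edges)
  base[j] + h$rates[j] * (t - edges[j])
}

# smallest t with cumulative hazard >= target (Inf if never reached);
# exact inversion piece by piece
pw_invert <- function(h, target) {
  edges <- c(0, h$breaks)
  cums <- c(0, cumsum(h$rates * diff(c(edges, Inf)))[-length(h$rates)])
  out <- rep(Inf, length(target))
  for (j in seq_along(h$rates)) {
    hi <- if (j < length(h$rates)) cums[j] + h$rates[j] * (edges[j + 1] - edges[j]) else Inf
    sel <- is.infinite(out) & target >= cums[j] &
      (target < hi | (j == length(h$rates) & h$rates[j] > 0))
    if (any(sel) && h$rates[j] > 0)
      out[sel] <- edges[j] + (target[sel] - cums[j]) / h$rates[j]
  }
  out[target <= 0] <- 0
  out
}

#' Scenario parameters for the illness-death simulator
#'
#' Full generative specification of a transplant-strategy cohort: a
#' three-state process Diagnosis -> Transplant -> Death with
#' piecewise-constant transition hazards, binary baseline covariates with
#' per-transition log hazard ratios, an optional shared lognormal frailty
#' acting on both death transitions (its standard deviation 0 recovers
#' the Markov case), a selection mechanism routing high-frailty patients
#' towards or away from transplant, and administrative censoring uniform
#' over a calendar window (staggered registry entry).
#'
#' @param hazard_12,hazard_13,hazard_23 [pw_hazard] objects (or a single
#'   rate per year) for Diagnosis->Transplant, Diagnosis->Death,
#'   Transplant->Death.
#' @param clock_23 `"forward"`: `hazard_23` is indexed by days since
#'   diagnosis (Markov); `"reset"`: by days since transplant.
#' @param covariate_effects list with entries `trans12`, `trans13`,
#'   `trans23`, each a named numeric vector of log hazard ratios for
#'   `age_gt60`, `raebt`, `cyto_abnormal`.
#' @param covariate_prevalences named numeric vector of Bernoulli
#'   prevalences for the three binary covariates, plus `cyto_missing`,
#'   the probability that cytogenetics is unrecorded.
#' @param year_range calendar-year range for the year of diagnosis
#'   (uniform integer draw).
#' @param frailty_sd standard deviation of log-frailty; the frailty
#'   multiplies hazards 13 and 23 and is normalised to mean 1.
#' @param selection_gamma hazard 12 is scaled by
#'   `exp(selection_gamma * log(frailty))`: positive values route
#'   high-risk patients preferentially to transplant.
#' @param admin_censor days from diagnosis to the data-collection
#'   cutoff, `c(lo, hi)` of a uniform window.
#' @param n cohort size.
#' @param seed master seed; per-subject substreams are spawned from it
#'   so earlier subjects are unchanged when `n` grows.
#' @return an object of class `"scenario"`.
#' @export
scenario <- function(hazard_12, hazard_13, hazard_23,
                     clock_23 = c("forward", "reset"),
                     covariate_effects = NULL,
                     covariate_prevalences = c(age_gt60 = 0.4, raebt = 0.3,
                                               cyto_abnormal = 0.5,
                                               cyto_missing = 0),
                     year_range = c(1998L, 2005L),
                     frailty_sd = 0, selection_gamma = 0,
                     admin_censor = years_to_days(c(4, 8)),
                     n = 1000L, seed = 1L) {
  as_pw <- function(h) if (inherits(h, "pw_hazard")) h else pw_hazard(h)
  clock_23 <- match.arg(clock_23)
  eff0 <- c(age_gt60 = 0, raebt = 0, cyto_abnormal = 0)
  eff <- list(trans12 = eff0, trans13 = eff0, trans23 = eff0)
  for (nm in names(covariate_effects)) {
    v <- covariate_effects[[nm]]
    eff[[nm]][names(v)] <- v
  }
  if (frailty_sd < 0) stop("frailty_sd must be non-negative")
  if (n < 1) stop("n must be at least 1")
  if (length(admin_censor) != 2 || diff(admin_censor) < 0 ||
      admin_censor[1] < 0)
    stop("admin_censor must be c(lo, hi) days with 0 <= lo <= hi")
  s <- structure(list(
    hazard_12 = as_pw(hazard_12), hazard_13 = as_pw(hazard_13),
    hazard_23 = as_pw(hazard_23), clock_23 = clock_23,
    covariate_effects = eff,
    covariate_prevalences = covariate_prevalences,
    year_range = as.integer(year_range),
    frailty_sd = frailty_sd, selection_gamma = selection_gamma,
    admin_censor = as.numeric(admin_censor),
    n = as.integer(n), seed = as.integer(seed)), class = "scenario")
  if (all(s$hazard_12$rates == 0) && all(s$hazard_13$rates == 0) &&
      all(s$hazard_23$rates == 0))
    stop("degenerate scenario: all hazards zero")
  s
}

#' @export
print.scenario <- function(x, ...) {
  fmt <- function(h) paste0(
    paste(signif(h$rates * DAYS_PER_YEAR, 3), collapse = "/"), " per year",
    if (length(h$breaks))
      paste0(" (breaks ", paste(signif(days_to_years(h$breaks), 3),
                                collapse = ", "), " y)"))
  cat("Illness-death scenario\n")
  cat("  Dx->Tx   :", fmt(x$hazard_12), "\n")
  cat("  Dx->Death:", fmt(x$hazard_13), "\n")
  cat("  Tx->Death:", fmt(x$hazard_23), sprintf("[clock %s]\n", x$clock_23))
  cat(sprintf("  frailty sd %g, selection gamma %g, censor U(%.2f, %.2f) y, n = %d, seed = %d\n",
              x$frailty_sd, x$selection_gamma,
              days_to_years(x$admin_censor[1]),
              days_to_years(x$admin_censor[2]), x$n, x$seed))
  invisible(x)
}

#' Simulate a complete illness-death cohort
#'
#' For each subject: draw covariates and frailty; latent competing
#' piecewise-exponential times from Diagnosis to Transplant and to
#' Death (inversion on each constant piece, exact); if transplant comes
#' first, a post-transplant death time under the scenario's clock;
#' administrative censoring.  One master seed spawns per-subject
#' substreams, so increasing `n` extends the cohort without reshuffling
#' earlier subjects.
#'
#' @param params a [scenario].
#' @return A `complete_cohort` list: `records` (registry-schema data
#'   frame, `cohort = "complete"`, with the *observed* transplant time
#'   and follow-up), `truth` (latent times pre-censoring: `u_tx` latent
#'   transplant time, `v_death_dx` latent death-from-diagnosis time,
#'   `t_death` realised latent death time, `transplanted` (latent
#'   pathway), `censor`, `frailty`), and `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "scenario"))
  n <- params$n
  set.seed(params$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
  prev <- params$covariate_prevalences
  eff <- params$covariate_effects
  out <- matrix(NA_real_, n, 12)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    x_age <- stats::rbinom(1, 1, prev[["age_gt60"]])
    x_raebt <- stats::rbinom(1, 1, prev[["raebt"]])
    x_cyto <- stats::rbinom(1, 1, prev[["cyto_abnormal"]])
    cyto_miss <- stats::rbinom(1, 1, prev[["cyto_missing"]])
    year <- sample(seq(params$year_range[1], params$year_range[2]), 1)
    logz <- if (params$frailty_sd > 0)
      stats::rnorm(1, -params$frailty_sd^2 / 2, params$frailty_sd) else 0
    x <- c(x_age, x_raebt, x_cyto)
    m12 <- exp(params$selection_gamma * logz + sum(eff$trans12 * x))
    m13 <- exp(logz + sum(eff$trans13 * x))
    m23 <- exp(logz + sum(eff$trans23 * x))
    u <- pw_invert(params$hazard_12, stats::rexp(1) / m12)
    v <- pw_invert(params$hazard_13, stats::rexp(1) / m13)
    cens <- stats::runif(1, params$admin_censor[1], params$admin_censor[2])
    transplanted <- u < v
    if (transplanted) {
      e23 <- stats::rexp(1) / m23
      if (params$clock_23 == "forward") {
        t_death <- pw_invert(params$hazard_23, pw_cumhaz(params$hazard_23, u) + e23)
      } else {
        t_death <- u + pw_invert(params$hazard_23, e23)
      }
    } else {
      t_death <- v
    }
    out[i, ] <- c(x_age, x_raebt, if (cyto_miss) NA_real_ else x_cyto, year,
                  exp(logz), u, v, t_death, as.numeric(transplanted), cens,
                  NA, NA)
  }
  u <- out[, 6]; v <- out[, 7]; t_death <- out[, 8]; cens <- out[, 10]
  obs_tx <- out[, 9] == 1 & u <= cens
  t_end <- pmin(t_death, cens)
  dead <- as.integer(t_death <= cens)
  records <- data.frame(
    id = paste0("s", seq_len(n)),
    cohort = "complete",
    t_tx_days = ifelse(obs_tx, u, NA_real_),
    t_end_days = t_end,
    dead = dead,
    r_trunc_days = cens,
    age_gt60 = out[, 1], raebt = out[, 2], cyto_abnormal = out[, 3],
    year_dx = as.integer(out[, 4]))
  truth <- data.frame(
    id = records$id, frailty = out[, 5], u_tx = u, v_death_dx = v,
    t_death = t_death, transplanted = out[, 9] == 1, censor = cens)
  structure(list(records = records, truth = truth, params = params),
            class = "complete_cohort")
}

#' Split a complete cohort into the two registry samples
#'
#' The transplant registry observes exactly the subjects whose transplant
#' happened during follow-up (before death and before the administrative
#' cutoff), carrying the cutoff as the right-truncation limit `r_trunc` —
#' by construction it holds no one who died while waiting.  The
#' non-transplant registry holds the subjects never transplanted during
#' their lifetime; subjects whose (latent) transplant falls after their
#' data-collection window belong to neither registry.
#'
#' @param cohort a `complete_cohort` from [simulate_cohort].
#' @return list with `tx_registry` and `non_tx_registry` registry-schema
#'   data frames.
#' @export
apply_registry_sampling <- function(cohort) {
  stopifnot(inherits(cohort, "complete_cohort"))
  rec <- cohort$records; tru <- cohort$truth
  in_tx <- !is.na(rec$t_tx_days)
  # latent transplant after the registry window (but before death):
  # absent from both registries
  late <- tru$transplanted & !in_tx
  tx <- rec[in_tx, , drop = FALSE]
  tx$cohort <- rep("tx_registry", nrow(tx))
  non <- rec[!in_tx & !late, , drop = FALSE]
  non$cohort <- rep("non_tx_registry", nrow(non))
  non$t_tx_days <- rep(NA_real_, nrow(non))
  non$r_trunc_days <- rep(NA_real_, nrow(non))
  list(tx_registry = tx, non_tx_registry = non)
}

#' Simulate the two-registry study
#'
#' The study conditions this package emulates: two separately obtained
#' cohorts.  The transplant registry is sampled from a strategy cohort
#' generated under `params`; the non-transplant registry is an
#' independent supportive-care cohort generated under the same
#' parameters with the transplant intensity switched off — so both
#' populations share the pre-transplant death hazard (the Markov
#' assumption holds across registries by construction, and fails exactly
#' when frailty-driven selection makes the transplant registry's source
#' population differ).
#'
#' @param params a [scenario] for the transplant-strategy cohort.
#' @param n_non size of the supportive-care cohort (default `params$n`).
#' @return list with `tx_registry`, `non_tx_registry`, and the two
#'   underlying `complete_cohort` objects (`strategy`, `supportive`).
#' @export
simulate_registries <- function(params, n_non = params$n) {
  stopifnot(inherits(params, "scenario"))
  strategy <- simulate_cohort(params)
  p_non <- params
  p_non$hazard_12 <- pw_hazard(0, unit = "day")
  p_non$selection_gamma <- 0
  p_non$n <- as.integer(n_non)
  p_non$seed <- as.integer((params$seed * 69069 + 12345) %% 2147483647)
  supportive <- simulate_cohort(p_non)
  reg_tx <- apply_registry_sampling(strategy)$tx_registry
  reg_non <- apply_registry_sampling(supportive)$non_tx_registry
  reg_non$id <- paste0("n_", reg_non$id)
  reg_tx$id <- paste0("t_", reg_tx$id)
  list(tx_registry = reg_tx, non_tx_registry = reg_non,
       strategy = strategy, supportive = supportive)
}

#' Named scenario presets
#'
#' * `"s1-markov"` — constant hazards (1.0, 0.3, 0.5 per year), no
#'   frailty: the equal-pre-transplant-mortality assumption holds.
#' * `"s1-trm"` — as above with an early treatment-related-mortality
#'   spike: the post-transplant hazard is elevated during the first
#'   quarter year after transplant (clock reset).
#' * `"frailty-selection"` — shared frailty (sd 0.8) on both death
#'   hazards with strong routing of high-risk patients to transplant
#'   (gamma 1.5): the assumption is violated and every registry-based
#'   method inherits a selection bias.
#' * `"tv-effect"` — calibrated so the transplant-vs-none hazard ratio
#'   on the diagnosis time scale is 5.8 in the first 3 months, an
#'   interpolated 2.41 between 3 and 12 months, and exactly 1 after a
#'   year (an early-harm/late-equivalence shape).
#'
#' @param n cohort size stored in each preset.
#' @param seed master seed stored in each preset.
#' @return named list of [scenario] objects.
#' @export
scenario_presets <- function(n = 2000L, seed = 20130) {
  base13 <- 0.3
  list(
    "s1-markov" = scenario(
      hazard_12 = pw_hazard(1.0), hazard_13 = pw_hazard(base13),
      hazard_23 = pw_hazard(0.5), n = n, seed = seed),
    "s1-trm" = scenario(
      hazard_12 = pw_hazard(1.0), hazard_13 = pw_hazard(base13),
      hazard_23 = pw_hazard(c(2.0, 0.35), breaks = 0.25),
      clock_23 = "reset", n = n, seed = seed),
    "frailty-selection" = scenario(
      hazard_12 = pw_hazard(1.0), hazard_13 = pw_hazard(base13),
      hazard_23 = pw_hazard(0.5), frailty_sd = 0.8,
      selection_gamma = 1.5, n = n, seed = seed),
    "tv-effect" = scenario(
      hazard_12 = pw_hazard(1.0), hazard_13 = pw_hazard(base13),
      hazard_23 = pw_hazard(base13 * c(5.8, exp(mean(log(c(5.8, 1)))), 1) /
                              DAYS_PER_YEAR,
                            breaks = c(91, 365), unit = "day"),
      clock_23 = "forward", n = n, seed = seed))
}

#' Serialize scenarios to and from YAML
#'
#' Flat YAML representation of a [scenario]; round-trips exactly.
#'
#' @param params a [scenario].
#' @param file optional path; when omitted the YAML text is returned.
#' @export
scenario_to_yaml <- function(params, file = NULL) {
  stopifnot(inherits(params, "scenario"))
  x <- list(
    hazard_12_rates = params$hazard_12$rates,
    hazard_12_breaks = params$hazard_12$breaks,
    hazard_13_rates = params$hazard_13$rates,
    hazard_13_breaks = params$hazard_13$breaks,
    hazard_23_rates = params$hazard_23$rates,
    hazard_23_breaks = params$hazard_23$breaks,
    clock_23 = params$clock_23,
    covariate_effects = lapply(params$covariate_effects, as.list),
    covariate_prevalences = as.list(params$covariate_prevalences),
    year_range = params$year_range,
    frailty_sd = params$frailty_sd,
    selection_gamma = params$selection_gamma,
    admin_censor = params$admin_censor,
    n = params$n, seed = params$seed)
  txt <- yaml::as.yaml(x, precision = 15L)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' @rdname scenario_to_yaml
#' @param text YAML text (alternative to `file`).
#' @export
scenario_from_yaml <- function(file = NULL, text = NULL) {
  x <- if (is.null(text)) yaml::read_yaml(file) else yaml::yaml.load(text)
  pw <- function(r, b) pw_hazard(r, if (is.null(b)) numeric(0) else b,
                                 unit = "day")
  scenario(
    hazard_12 = pw(x$hazard_12_rates, x$hazard_12_breaks),
    hazard_13 = pw(x$hazard_13_rates, x$hazard_13_breaks),
    hazard_23 = pw(x$hazard_23_rates, x$hazard_23_breaks),
    clock_23 = x$clock_23,
    covariate_effects = lapply(x$covariate_effects, unlist),
    covariate_prevalences = unlist(x$covariate_prevalences),
    year_range = unlist(x$year_range),
    frailty_sd = x$frailty_sd,
    selection_gamma = x$selection_gamma,
    admin_censor = unlist(x$admin_censor),
    n = x$n, seed = x$seed)
}
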