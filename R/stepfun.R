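#' Right-continuous step-function estimates
#'
#' All nonparametric estimators in this package (Kaplan-Meier, Nelson-Aalen,
#' right-truncated waiting-time CDF, cumulative incidence, transition
#' probabilities) return objects of class `"msm_step"`: a right-continuous
#' step function with knots in days, the estimate immediately after each
#' knot, a pointwise variance and a range-respecting confidence interval.
#'
#' @param time strictly increasing knot times in days (the value at `t = 0`
#'   is implied by `kind`: 1 for survival, 0 for cumulative hazards and CIFs).
#' @param est estimate immediately after each knot.
#' @param var pointwise variance at each knot (may be `NA`).
#' @param kind one of `"survival"`, `"cumhaz"`, `"cif"`, `"prob"`.
#' @param n number of subjects contributing.
#' @param n_events number of events observed.
#' @param ci_level two-sided confidence level, default 0.95.
#'
#' @return An object of class `"msm_step"` with components `time`, `est`,
#'   `var`, `lower`, `upper`, `kind`, `n`, `n_events`, `ci_level`.
#' @export
msm_step <- function(time, est, var = rep(NA_real_, length(time)),
                     kind = c("survival", "cumhaz", "cif", "prob"),
                     n = NA_integer_, n_events = NA_integer_,
                     ci_level = 0.95) {
  kind <- match.arg(kind)
  time <- as.numeric(time); est <- as.numeric(est); var <- as.numeric(var)
  if (length(est) != length(time) || length(var) != length(time))
    stop("time, est and var must have equal length")
  if (length(time) && any(diff(time) <= 0))
    stop("knot times must be strictly increasing")
  if (length(time) && any(time < 0)) stop("negative knot time")
  if (kind == "survival" && length(est) &&
      (any(est < -1e-12 | est > 1 + 1e-12) || any(diff(est) > 1e-12)))
    stop("survival estimate must be non-increasing within [0, 1]")
  if (kind %in% c("cumhaz", "cif") && length(est) &&
      (any(est < -1e-12) || any(diff(est) < -1e-12)))
    stop(sprintf("%s estimate must be non-decreasing and non-negative", kind))
  if (kind == "cif" && length(est) && any(est > 1 + 1e-12))
    stop("cumulative incidence cannot exceed 1")
  ci <- step_ci(est, var, kind, ci_level)
  structure(
    list(time = time, est = est, var = var,
         lower = ci$lower, upper = ci$upper, kind = kind,
         n = as.integer(n), n_events = as.integer(n_events),
         ci_level = ci_level),
    class = "msm_step")
}

# Range-respecting pointwise CIs: log(-log) for survival-type quantities,
# log for cumulative hazards.
step_ci <- function(est, var, kind, ci_level) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  lower <- upper <- rep(NA_real_, length(est))
  ok <- is.finite(var) & var >= 0
  if (kind %in% c("survival")) {
    i <- ok & est > 0 & est < 1
    se_ll <- sqrt(var[i]) / (est[i] * abs(log(est[i])))
    lower[i] <- est[i]^exp(z * se_ll)
    upper[i] <- est[i]^exp(-z * se_ll)
    lower[ok & est == 0] <- 0; upper[ok & est == 0] <- 0
    lower[ok & est == 1] <- 1; upper[ok & est == 1] <- 1
  } else if (kind == "cumhaz") {
    i <- ok & est > 0
    se_l <- sqrt(var[i]) / est[i]
    lower[i] <- est[i] * exp(-z * se_l)
    upper[i] <- est[i] * exp(z * se_l)
    lower[ok & est == 0] <- 0; upper[ok & est == 0] <- 0
  } else { # cif / prob: complementary log(-log) via the survivor scale
    s <- 1 - est
    i <- ok & s > 0 & s < 1
    se_ll <- sqrt(var[i]) / (s[i] * abs(log(s[i])))
    lower[i] <- 1 - s[i]^exp(-z * se_ll)
    upper[i] <- 1 - s[i]^exp(z * se_ll)
    lower[ok & i == FALSE] <- est[ok & i == FALSE]
    upper[ok & i == FALSE] <- est[ok & i == FALSE]
  }
  list(lower = lower, upper = upper)
}

#' Evaluate a step function
#'
#' Right-continuous evaluation: returns the estimate at the largest knot
#' `<= t`, and the implied value at `t = 0` (1 for survival, 0 otherwise)
#' before the first knot.
#'
#' @param sf an [msm_step] object.
#' @param t numeric vector of evaluation times (days).
#' @return numeric vector of the same length as `t`.
#' @export
step_eval <- function(sf, t) {
  stopifnot(inherits(sf, "msm_step"))
  base <- if (sf$kind == "survival") 1 else 0
  if (!length(sf$time)) return(rep(base, length(t)))
  idx <- findInterval(t, sf$time)
  out <- c(base, sf$est)[idx + 1L]
  out[t < 0] <- NA_real_
  out
}

#' @export
print.msm_step <- function(x, ...) {
  cat(sprintf("Step-function estimate (%s): %d knots, n = %s, events = %s\n",
              x$kind, length(x$time),
              ifelse(is.na(x$n), "?", x$n),
              ifelse(is.na(x$n_events), "?", x$n_events)))
  if (length(x$time)) {
    show <- unique(round(seq(1, length(x$time), length.out = min(6, length(x$time)))))
    print(data.frame(time_days = x$time[show], estimate = x$est[show],
                     lower = x$lower[show], upper = x$upper[show],
                     row.names = NULL), digits = 4)
  }
  invisible(x)
}

#' @export
plot.msm_step <- function(x, xlab = "Days since origin", ylab = NULL,
                          conf_int = TRUE, xscale = 1, ...) {
  if (is.null(ylab))
    ylab <- switch(x$kind, survival = "Survival probability",
                   cumhaz = "Cumulative hazard",
                   cif = "Cumulative incidence", prob = "Probability")
  base <- if (x$kind == "survival") 1 else 0
  tt <- c(0, x$time) / xscale
  ee <- c(base, x$est)
  plot(tt, ee, type = "s", xlab = xlab, ylab = ylab,
       ylim = if (x$kind == "cumhaz") NULL else c(0, 1), ...)
  if (conf_int && any(is.finite(x$lower))) {
    graphics::lines(c(0, x$time) / xscale, c(base, x$lower), type = "s", lty = 2)
    graphics::lines(c(0, x$time) / xscale, c(base, x$upper), type = "s", lty = 2)
  }
  invisible(x)
}

#' Serialize a step function to CSV plus JSON metadata
#'
#' Writes `(time_days, estimate, var, lo, hi)` rows to `file` and, when
#' `meta_file` is given, a JSON header with the kind, sample size, event
#' count and confidence level — the exchange format used by the
#' command-line pipeline.
#'
#' @param sf an [msm_step] object.
#' @param file CSV path.
#' @param meta_file optional JSON path.
#' @return `file`, invisibly.
#' @export
write_stepfun_csv <- function(sf, file, meta_file = NULL) {
  stopifnot(inherits(sf, "msm_step"))
  df <- data.frame(time_days = sf$time, estimate = sf$est, var = sf$var,
                   lo = sf$lower, hi = sf$upper)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, eol = "\n")
  if (!is.null(meta_file)) {
    jsonlite::write_json(
      list(kind = sf$kind, n = sf$n, events = sf$n_events,
           ci_level = sf$ci_level),
      meta_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read a step function written by [write_stepfun_csv]
#'
#' @param file CSV path.
#' @param kind the estimate kind (not stored in the CSV body).
#' @return an [msm_step] object.
#' @export
read_stepfun_csv <- function(file, kind = "survival") {
  df <- utils::read.csv(file)
  msm_step(df$time_days, df$estimate, df$var, kind = kind)
}
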