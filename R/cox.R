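#' Cox regression on counting-process data
#'
#' Maximises the Breslow partial likelihood over delayed-entry risk sets
#' `\{i : entry_i < t <= exit_i\}` by Newton-Raphson with step-halving
#' (maximum 50 iterations, convergence when the gradient's Euclidean norm
#' drops below `tol`).  Ties are handled by Breslow's method — events tied
#' at one time share the same denominator — which is exact for
#' counting-process input and the simplest form to reason about; note it
#' is a known source of small differences versus software defaulting to
#' the Efron correction.
#'
#' @param rows data frame with `entry`, `exit`, `status` and the model
#'   covariates as columns.  Rows with a missing covariate value are
#'   dropped (complete-case analysis) with a message.
#' @param covariates character vector of covariate column names.
#' @param strata optional column name; when given, risk sets are formed
#'   within strata (used for transition-stratified fits).
#' @param init starting coefficient values.
#' @param tol convergence tolerance on the gradient norm.
#' @param max_iter Newton iteration cap.
#' @param ci_level confidence level for the reported hazard-ratio CIs.
#' @return A `cox_fit` object: `beta` (named log hazard ratios), `vcov`,
#'   `se`, `hr`, `ci`, `p` (Wald), `loglik` (at optimum and at zero),
#'   `n`, `n_events`, `ties = "breslow"`, `baseline` (Breslow cumulative
#'   baseline hazard at covariate value zero, an [msm_step]; per stratum
#'   when stratified), `gradient`, `iter`, and the data slots used by
#'   [test_proportional_hazards].
#' @export
fit_cox <- function(rows, covariates, strata = NULL, init = NULL,
                    tol = 1e-8, max_iter = 50L, ci_level = 0.95) {
  rows <- check_rows(rows)
  if (!length(covariates)) stop("no covariates given")
  miss <- setdiff(covariates, names(rows))
  if (length(miss)) stop("unknown covariates: ", paste(miss, collapse = ", "))
  X <- as.matrix(rows[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    message(sum(!keep), " rows dropped (missing covariate values)")
    rows <- rows[keep, , drop = FALSE]; X <- X[keep, , drop = FALSE]
  }
  if (sum(rows$status) < 1) stop("no events in the analysis set")
  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const))
    stop("unidentifiable: constant covariate(s) ",
         paste(covariates[const], collapse = ", "))
  st <- if (is.null(strata)) rep(1L, nrow(rows)) else as.integer(factor(rows[[strata]]))

  p <- ncol(X)
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  ll0 <- cox_loglik(beta * 0, X, rows$entry, rows$exit, rows$status, st)$loglik
  cur <- cox_loglik(beta, X, rows$entry, rows$exit, rows$status, st)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (sqrt(sum(cur$grad^2)) < tol) break
    if (iter > max_iter)
      stop("Newton did not converge in ", max_iter, " iterations")
    step <- tryCatch(solve(cur$info, cur$grad),
                     error = function(e) stop("singular information matrix"))
    halve <- 0L
    repeat {
      cand <- beta + step / 2^halve
      new <- cox_loglik(cand, X, rows$entry, rows$exit, rows$status, st)
      if (is.finite(new$loglik) && new$loglik >= cur$loglik - 1e-12) break
      halve <- halve + 1L
      if (halve > 30L) stop("step-halving failed (likelihood not improvable)")
    }
    beta <- cand; cur <- new
    if (max(abs(beta)) > 20)
      stop("monotone partial likelihood: |beta| diverging for ",
           paste(covariates[abs(beta) > 20], collapse = ", "),
           " (groups may be perfectly separated)")
  }
  vc <- solve(cur$info)
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(covariates, covariates)
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  names(beta) <- covariates
  fit <- structure(list(
    beta = beta, vcov = vc, se = stats::setNames(se, covariates),
    hr = exp(beta),
    ci = cbind(lower = exp(beta - z * se), upper = exp(beta + z * se)),
    p = stats::setNames(2 * stats::pnorm(-abs(beta / se)), covariates),
    loglik = c(optimum = cur$loglik, null = ll0),
    n = nrow(rows), n_events = sum(rows$status), ties = "breslow",
    gradient = cur$grad, iter = iter, ci_level = ci_level,
    covariates = covariates,
    data = list(entry = rows$entry, exit = rows$exit,
                status = rows$status, X = X, strata = st)),
    class = "cox_fit")
  fit$baseline <- breslow_baseline(fit)
  fit
}

# Breslow partial log-likelihood, score and information for one beta.
# Risk-set sums S0/S1/S2 at the event times are accumulated with reverse
# cumulative sums over exit- and entry-sorted copies, so each call is
# O(n log n + n p^2) rather than O(n^2).
cox_loglik <- function(beta, X, entry, exit, status, strata) {
  p <- ncol(X); n <- nrow(X)
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)                    # numerical centring only
  w <- exp(eta)
  loglik <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    ev <- idx[status[idx] == 1]
    if (!length(ev)) next
    times <- sort(unique(exit[ev]))
    K <- length(times)
    sums <- risk_sums(times, entry[idx], exit[idx], w[idx], X[idx, , drop = FALSE])
    if (any(sums$S0 <= 0)) stop("empty risk set at an event time")
    agg <- rowsum(cbind(1, eta[ev], X[ev, , drop = FALSE]), group = exit[ev])
    d <- agg[, 1]; sum_eta <- agg[, 2]
    sum_x <- agg[, 3:(2 + p), drop = FALSE]
    loglik <- loglik + sum(sum_eta) - sum(d * log(sums$S0))
    xbar <- sums$S1 / sums$S0               # K x p
    grad <- grad + colSums(sum_x) - colSums(d * xbar)
    for (a in seq_len(p)) for (b in a:p) {
      v <- sum(d * (sums$S2[, a, b] / sums$S0 - xbar[, a] * xbar[, b]))
      info[a, b] <- info[a, b] + v
      if (b > a) info[b, a] <- info[b, a] + v
    }
  }
  list(loglik = loglik, grad = grad, info = info)
}

# S0(t) = sum_{entry < t <= exit} w, S1 = sum w x, S2 = sum w x x'
risk_sums <- function(times, entry, exit, w, X) {
  p <- ncol(X); K <- length(times)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  Q <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  M <- cbind(w, w * X, w * Q)               # n x (1 + p + p(p+1)/2)
  oe <- order(exit); on_ <- order(entry)
  cum_exit <- apply(M[oe, , drop = FALSE], 2, function(v) rev(cumsum(rev(v))))
  cum_entry <- apply(M[on_, , drop = FALSE], 2, function(v) rev(cumsum(rev(v))))
  cum_exit <- rbind(cum_exit, 0); cum_entry <- rbind(cum_entry, 0)
  se <- exit[oe]; sn <- entry[on_]
  i_exit <- findInterval(times, se, left.open = TRUE) + 1L   # first exit >= t
  i_entry <- findInterval(times, sn, left.open = TRUE) + 1L  # first entry >= t
  tot <- cum_exit[i_exit, , drop = FALSE] - cum_entry[i_entry, , drop = FALSE]
  S0 <- tot[, 1]
  S1 <- tot[, 2:(1 + p), drop = FALSE]
  S2 <- array(0, c(K, p, p))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    S2[, a, b] <- tot[, 1 + p + k]
    S2[, b, a] <- tot[, 1 + p + k]
  }
  list(S0 = S0, S1 = S1, S2 = S2)
}

# Breslow baseline cumulative hazard at X = 0 (per stratum).
breslow_baseline <- function(fit) {
  d <- fit$data
  w <- exp(drop(d$X %*% fit$beta))
  out <- list()
  for (s in unique(d$strata)) {
    idx <- which(d$strata == s)
    ev <- idx[d$status[idx] == 1]
    if (!length(ev)) next
    times <- sort(unique(d$exit[ev]))
    sums <- risk_sums(times, d$entry[idx], d$exit[idx], w[idx],
                      d$X[idx, , drop = FALSE])
    dd <- as.numeric(rowsum(rep(1, length(ev)), group = d$exit[ev])[, 1])
    out[[as.character(s)]] <- msm_step(
      times, cumsum(dd / sums$S0), cumsum(dd / sums$S0^2),
      kind = "cumhaz", n = length(idx), n_events = length(ev))
  }
  if (length(out) == 1L) out[[1]] else out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (Breslow ties), n = %d, events = %d, iter = %d\n",
              x$n, x$n_events, x$iter))
  tab <- data.frame(coef = x$beta, HR = x$hr, se = x$se,
                    lower = x$ci[, "lower"], upper = x$ci[, "upper"],
                    p = x$p)
  print(tab, digits = 4)
  cat(sprintf("log-likelihood: %.4f (null %.4f)\n",
              x$loglik["optimum"], x$loglik["null"]))
  invisible(x)
}

#' Summarise a Cox fit as a plain list (JSON-ready)
#'
#' @param fit a `cox_fit`.
#' @param file optional path; when given the summary is written as JSON.
#' @return the summary list, invisibly when written to file.
#' @export
cox_fit_json <- function(fit, file = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  out <- list(
    coefficients = as.list(fit$beta),
    se = as.list(fit$se),
    hr = as.list(fit$hr),
    ci_lower = as.list(fit$ci[, "lower"]),
    ci_upper = as.list(fit$ci[, "upper"]),
    p = as.list(fit$p),
    loglik = as.list(fit$loglik),
    n = fit$n, events = fit$n_events, ties = fit$ties)
  if (!is.null(file)) {
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Pooled treatment comparison with transplant as a time-dependent state
#'
#' Fits, on the diagnosis time scale, the Cox model in which transplanted
#' subjects enter the risk set at their transplant time with
#' `tx_state = 1` (delayed entry) and non-transplant subjects are at risk
#' over `(0, t_end]` with `tx_state = 0`.  The `tx_state` coefficient is
#' the overall "average" hazard ratio of transplant versus no transplant —
#' a single number that is misleading whenever the true effect varies
#' with time (see [fit_time_varying_effect] and
#' [test_proportional_hazards]).
#'
#' @param dataset result of [assemble_multistate_dataset] with
#'   `clock = "forward"` (the comparison is defined on the diagnosis time
#'   scale only).
#' @param adjust optional adjustment covariates among `age_gt60`,
#'   `raebt`, `cyto_abnormal`, `year_dx`.
#' @param ... passed to [fit_cox].
#' @return a `cox_fit`; the treatment coefficient is named `tx_state`.
#' @export
fit_treatment_comparison <- function(dataset, adjust = character(), ...) {
  if (is.null(dataset$comparison))
    stop("comparison rows are only defined for clock = \"forward\"")
  fit_cox(dataset$comparison, covariates = c("tx_state", adjust), ...)
}

#' Piecewise and smoothed time-varying treatment effect
#'
#' Splits every at-risk interval at the supplied cutpoints and fits one
#' Cox model with an interval-specific `tx_state` coefficient per piece,
#' giving a step-shaped log hazard-ratio curve; defaults cut at 3 months
#' and 1 year (91 and 365 days).  Additionally produces a smooth
#' `logHR(t)` estimate with pointwise confidence band by local-linear
#' kernel smoothing of the scaled Schoenfeld residuals of the
#' single-coefficient fit on a log-time grid.
#'
#' @param dataset result of [assemble_multistate_dataset]
#'   (`clock = "forward"`).
#' @param cutpoints interior cutpoints in days; `numeric(0)` reduces to
#'   the single-coefficient comparison.
#' @param adjust optional adjustment covariates.
#' @param bandwidth kernel bandwidth as a fraction of the log-time range.
#' @param grid_size number of grid points for the smooth curve.
#' @param ci_level confidence level.
#' @return A `tv_effect` object: `cutpoints`, `intervals` (data frame
#'   with per-interval log HR, se, HR, CI), `vcov`, `fit` (the underlying
#'   `cox_fit`), and `smooth` (data frame `time_days`, `loghr`, `lo`,
#'   `hi`).
#' @export
fit_time_varying_effect <- function(dataset, cutpoints = c(91, 365),
                                    adjust = character(), bandwidth = 0.4,
                                    grid_size = 51L, ci_level = 0.95) {
  if (is.null(dataset$comparison))
    stop("comparison rows are only defined for clock = \"forward\"")
  rows <- dataset$comparison
  cutpoints <- sort(unique(as.numeric(cutpoints)))
  if (!length(cutpoints)) {
    fit <- fit_cox(rows, covariates = c("tx_state", adjust),
                   ci_level = ci_level)
    intervals <- data.frame(start = 0, end = Inf,
                            loghr = fit$beta["tx_state"],
                            se = fit$se["tx_state"],
                            hr = fit$hr["tx_state"],
                            lower = fit$ci["tx_state", "lower"],
                            upper = fit$ci["tx_state", "upper"],
                            row.names = NULL)
    sm <- smooth_schoenfeld(fit, "tx_state", bandwidth, grid_size, ci_level)
    return(structure(list(cutpoints = cutpoints, intervals = intervals,
                          vcov = fit$vcov, fit = fit, smooth = sm,
                          ci_level = ci_level), class = "tv_effect"))
  }
  split <- split_at_cutpoints(rows, cutpoints)
  bounds <- c(0, cutpoints, Inf)
  nm <- sprintf("tx_state_%d", seq_len(length(bounds) - 1))
  for (j in seq_along(nm))
    split[[nm[j]]] <- split$tx_state *
      as.integer(split$exit > bounds[j] & split$exit <= bounds[j + 1])
  # every interval needs events from both arms, else the piece is unidentified
  for (j in seq_along(nm)) {
    in_j <- split$status == 1 & split$exit > bounds[j] & split$exit <= bounds[j + 1]
    if (!any(in_j & split$tx_state == 1) || !any(in_j & split$tx_state == 0))
      stop(sprintf("interval (%g, %g] days has no events in one group",
                   bounds[j], bounds[j + 1]))
  }
  fit <- fit_cox(split, covariates = c(nm, adjust), ci_level = ci_level)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  intervals <- data.frame(
    start = bounds[-length(bounds)], end = bounds[-1],
    loghr = unname(fit$beta[nm]), se = unname(fit$se[nm]),
    hr = unname(fit$hr[nm]),
    lower = unname(exp(fit$beta[nm] - z * fit$se[nm])),
    upper = unname(exp(fit$beta[nm] + z * fit$se[nm])))
  base_fit <- fit_cox(rows, covariates = c("tx_state", adjust),
                      ci_level = ci_level)
  sm <- smooth_schoenfeld(base_fit, "tx_state", bandwidth, grid_size, ci_level)
  structure(list(cutpoints = cutpoints, intervals = intervals,
                 vcov = fit$vcov[nm, nm], fit = fit, smooth = sm,
                 ci_level = ci_level), class = "tv_effect")
}

#' @export
print.tv_effect <- function(x, ...) {
  cat("Time-varying treatment effect (piecewise log HR)\n")
  tab <- x$intervals
  tab$start <- round(days_to_years(tab$start), 2)
  tab$end <- round(days_to_years(tab$end), 2)
  names(tab)[1:2] <- c("start_y", "end_y")
  print(tab, digits = 3)
  invisible(x)
}

# Episode splitting: cut each (entry, exit] row at interior cutpoints.
split_at_cutpoints <- function(rows, cutpoints) {
  pieces <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, , drop = FALSE]
    cuts <- cutpoints[cutpoints > r$entry & cutpoints < r$exit]
    lo <- c(r$entry, cuts); hi <- c(cuts, r$exit)
    out <- r[rep(1, length(lo)), , drop = FALSE]
    out$entry <- lo; out$exit <- hi
    out$status <- c(rep(0L, length(lo) - 1), r$status)
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Schoenfeld residuals (per distinct event time, Breslow-aggregated):
# for each event time, sum over tied events of (x_i - xbar(t)).
schoenfeld_residuals <- function(fit) {
  d <- fit$data
  if (length(unique(d$strata)) > 1)
    stop("Schoenfeld residuals implemented for unstratified fits")
  w <- exp(drop(d$X %*% fit$beta))
  ev <- which(d$status == 1)
  times <- sort(unique(d$exit[ev]))
  sums <- risk_sums(times, d$entry, d$exit, w, d$X)
  xbar <- sums$S1 / sums$S0
  agg <- rowsum(cbind(1, d$X[ev, , drop = FALSE]), group = d$exit[ev])
  dd <- agg[, 1]
  sum_x <- agg[, -1, drop = FALSE]
  resid <- sum_x - dd * xbar
  colnames(resid) <- fit$covariates
  list(time = times, resid = resid, d = dd, xbar = xbar)
}

# Local-linear Gaussian-kernel smooth of scaled Schoenfeld residuals on
# log time; pointwise variance from the weighted residual variance.
smooth_schoenfeld <- function(fit, covariate, bandwidth = 0.4,
                              grid_size = 51L, ci_level = 0.95) {
  sr <- schoenfeld_residuals(fit)
  j <- match(covariate, fit$covariates)
  m <- sum(sr$d)
  # Grambsch-Therneau scaling: beta(t) ~ beta + m * V * r(t)
  rstar <- fit$beta[j] + m * drop(sr$resid %*% fit$vcov[, j])
  # replicate per tied event so weights follow the event counts
  u <- log(rep(sr$time, sr$d))
  y <- rep(rstar, sr$d)
  h <- bandwidth * (max(u) - min(u))
  if (h <= 0) h <- 1
  grid <- seq(min(u), max(u), length.out = grid_size)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  est <- se <- numeric(grid_size)
  for (g in seq_len(grid_size)) {
    wk <- stats::dnorm((u - grid[g]) / h)
    wk <- wk / sum(wk)
    X <- cbind(1, u - grid[g])
    W <- wk
    XtWX <- crossprod(X, X * W)
    bhat <- solve(XtWX, crossprod(X, W * y))
    res <- y - X %*% bhat
    sigma2 <- sum(W * res^2) / (1 - sum(W^2) / sum(W)^2)
    # variance of the local intercept: e1' (X'WX)^-1 X'W^2X (X'WX)^-1 e1 * sigma2
    A <- solve(XtWX, t(X * W))
    v <- sigma2 * drop(tcrossprod(A[1, , drop = FALSE]))
    est[g] <- bhat[1]; se[g] <- sqrt(v)
  }
  data.frame(time_days = exp(grid), loghr = est,
             lo = est - z * se, hi = est + z * se)
}

#' Proportional-hazards test on scaled Schoenfeld residuals
#'
#' Score test for a time-varying coefficient `beta(t) = beta +
#' theta g(t)`: regresses the scaled Schoenfeld residuals on a monotone
#' transform of event time and tests `theta = 0` (per covariate and
#' globally).  The default transform is the left-continuous Kaplan-Meier
#' of the event times, which spaces the test evenly over observed risk.
#'
#' @param fit a `cox_fit` from [fit_cox] or [fit_treatment_comparison].
#' @param transform `"km"` (default), `"identity"`, `"log"` or `"rank"`.
#' @return A `ph_test` object: `table` (per-covariate and global rows
#'   with `chisq`, `df`, `p`), `transform`, and `global_p`.
#' @export
test_proportional_hazards <- function(fit,
                                      transform = c("km", "identity",
                                                    "log", "rank")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (fit$n_events < 2) stop("at least two events required")
  sr <- schoenfeld_residuals(fit)
  times <- rep(sr$time, sr$d)
  g <- switch(transform,
              identity = times,
              log = log(times),
              rank = rank(times),
              km = {
                km <- kaplan_meier(data.frame(entry = fit$data$entry,
                                              exit = fit$data$exit,
                                              status = fit$data$status))
                # left-continuous: 1 - S(t-)
                sminus <- c(1, km$est[-length(km$est)])
                1 - sminus[match(rep(sr$time, sr$d), km$time)]
              })
  gc_ <- g - mean(g)
  # expand residuals to per-event rows (Breslow: tied events share xbar)
  p <- length(fit$covariates)
  rexp <- sr$resid / sr$d       # per-event residual within a tie group
  ridx <- rep(seq_along(sr$time), sr$d)
  revent <- rexp[ridx, , drop = FALSE]
  u <- drop(crossprod(gc_, revent))           # p-vector
  D <- sum(gc_^2)
  m <- sum(sr$d)
  V <- fit$vcov
  global <- drop(t(u) %*% V %*% u) * m / D
  if (!is.finite(global)) stop("singular covariance in PH test")
  per <- (m * drop(V %*% u))^2 / (m * diag(V) * D)
  tab <- data.frame(
    covariate = c(fit$covariates, "GLOBAL"),
    chisq = c(per, global),
    df = c(rep(1L, p), p),
    p = c(stats::pchisq(per, 1, lower.tail = FALSE),
          stats::pchisq(global, p, lower.tail = FALSE)))
  structure(list(table = tab, transform = transform,
                 global_p = tab$p[p + 1]), class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat(sprintf("Proportional-hazards score test (transform: %s)\n",
              x$transform))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
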