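#' Emit the standard figure pack for one assembled dataset
#'
#' Writes CSV step functions (and, optionally, base-graphics PDF plots)
#' for the three displays a registry comparison needs:
#'
#' 1. from-diagnosis survival of the two treatment strategies
#'    (reconstructed transplant curve vs non-transplant Kaplan-Meier);
#' 2. the three cumulative transition rates (Diagnosis->Transplant under
#'    right truncation, Diagnosis->Death, Transplant->Death);
#' 3. the smoothed time-varying log hazard ratio of transplant with its
#'    pointwise confidence band.
#'
#' @param dataset result of [assemble_multistate_dataset]
#'   (`clock = "forward"`).
#' @param out_dir output directory (created if absent).
#' @param plots also write `figures.pdf`.
#' @param cutpoints cutpoints (days) for the piecewise treatment effect.
#' @return invisibly, the list of written file paths.
#' @export
figure_pack <- function(dataset, out_dir, plots = FALSE,
                        cutpoints = c(91, 365)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- reconstruct_strategy_survival(dataset)
  tv <- fit_time_varying_effect(dataset, cutpoints = cutpoints)
  files <- c(
    survival_tx = file.path(out_dir, "survival_transplant_strategy.csv"),
    survival_non = file.path(out_dir, "survival_non_transplant.csv"),
    rate_12 = file.path(out_dir, "cumrate_dx_tx.csv"),
    rate_13 = file.path(out_dir, "cumrate_dx_death.csv"),
    rate_23 = file.path(out_dir, "cumrate_tx_death.csv"),
    loghr = file.path(out_dir, "loghr_smooth.csv"))
  write_stepfun_csv(sc$tx, files["survival_tx"])
  write_stepfun_csv(sc$non_tx, files["survival_non"])
  write_stepfun_csv(sc$cumhaz$A12, files["rate_12"])
  write_stepfun_csv(sc$cumhaz$A13, files["rate_13"])
  write_stepfun_csv(sc$cumhaz$A23, files["rate_23"])
  utils::write.csv(tv$smooth, files["loghr"], row.names = FALSE,
                   quote = FALSE, eol = "\n")
  if (plots) {
    pdf_file <- file.path(out_dir, "figures.pdf")
    grDevices::pdf(pdf_file, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(sc$tx, xscale = DAYS_PER_YEAR, xlab = "Years since diagnosis",
         conf_int = FALSE, main = "From-diagnosis survival by strategy")
    graphics::lines(c(0, sc$non_tx$time) / DAYS_PER_YEAR,
                    c(1, sc$non_tx$est), type = "s", lty = 2)
    graphics::legend("topright", c("transplant strategy", "non-transplant"),
                     lty = 1:2, bty = "n")
    plot(sc$cumhaz$A12, xscale = DAYS_PER_YEAR,
         xlab = "Years since diagnosis", conf_int = FALSE,
         main = "Cumulative transition rates")
    graphics::lines(c(0, sc$cumhaz$A13$time) / DAYS_PER_YEAR,
                    c(0, sc$cumhaz$A13$est), type = "s", lty = 2)
    graphics::lines(c(0, sc$cumhaz$A23$time) / DAYS_PER_YEAR,
                    c(0, sc$cumhaz$A23$est), type = "s", lty = 3)
    graphics::legend("topleft",
                     c("Dx->Tx (right-truncated)", "Dx->Death", "Tx->Death"),
                     lty = 1:3, bty = "n")
    graphics::plot(days_to_years(tv$smooth$time_days), tv$smooth$loghr,
                   type = "l", log = "x", xlab = "Years since diagnosis",
                   ylab = "log hazard ratio",
                   ylim = range(tv$smooth[c("lo", "hi")], finite = TRUE),
                   main = "Time-varying effect of transplant")
    graphics::lines(days_to_years(tv$smooth$time_days), tv$smooth$lo, lty = 2)
    graphics::lines(days_to_years(tv$smooth$time_days), tv$smooth$hi, lty = 2)
    graphics::abline(h = 0, col = "grey")
    files <- c(files, pdf = pdf_file)
  }
  invisible(files)
}
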