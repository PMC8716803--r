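#' Linear R2-versus-concentration calibration
#'
#' Ordinary least squares of the per-vial median R2 (s^-1) on H2-17O
#' concentration (%), restricted to vials inside the fit range
#' (inclusive). The default range [0.245, 5.5]% brackets the linear
#' regime of the transverse-rate response; the 6.5% vial lies outside
#' it. The Spearman rank correlation over the full concentration set is
#' stored alongside the line. Two in-range vials determine the line
#' exactly (an interpolating fit); fewer raise an insufficient-data
#' error.
#'
#' @param stats A `vial_stats` data frame (see [summarize_vials()]).
#' @param fit_range Length-2 ordered concentration range (%).
#' @return An object of class `calibration_model` with `slope` (s^-1
#'   per %), `intercept` (s^-1), `fit_range`, `r_spearman`, `n_points`.
#' @export
fit_calibration <- function(stats, fit_range = c(0.245, 5.5)) {
  if (length(fit_range) != 2L || fit_range[1] >= fit_range[2])
    abort_validation("fit_range must be an ordered length-2 range")
  inr <- stats$concentration >= fit_range[1] &
         stats$concentration <= fit_range[2]
  if (sum(inr) < 2L)
    abort_o17(sprintf(
      "only %d vial(s) inside the fit range; a line needs at least 2",
      sum(inr)),
      "o17_insufficient_data_error")
  sub <- stats[inr, ]
  fit <- stats::lm(median_rate ~ concentration, data = sub)
  rho <- if (nrow(stats) >= 4L && length(unique(stats$concentration)) > 1L)
    spearman_vs_concentration(stats)$rho else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit_range = fit_range,
                 r_spearman = rho,
                 n_points = nrow(sub)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> R2 = %.4g * C + %.4g (s^-1)\n",
              x$slope, x$intercept))
  cat(sprintf("  fit range: [%g, %g]%%, %d vials; Spearman rho %.3f\n",
              x$fit_range[1], x$fit_range[2], x$n_points, x$r_spearman))
  invisible(x)
}

#' Invert the calibration: concentration from R2
#'
#' `C = (R2 - intercept) / slope`, flagged as out of range when the
#' estimate falls outside the model's fit range; the function never
#' extrapolates silently.
#'
#' @param r2 Relaxation rate(s) in s^-1.
#' @param model A [fit_calibration()] model.
#' @return Data frame with columns `r2`, `concentration` (%), and
#'   `out_of_range` (logical).
#' @export
estimate_concentration <- function(r2, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope == 0)
    abort_o17("calibration slope is zero; cannot invert",
              "o17_inversion_error")
  conc <- (r2 - model$intercept) / model$slope
  tol <- 1e-8 * max(abs(model$fit_range), 1)
  data.frame(r2 = r2,
             concentration = conc,
             out_of_range = conc < model$fit_range[1] - tol |
                            conc > model$fit_range[2] + tol)
}
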