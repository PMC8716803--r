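#' Voxel-wise baseline-normalized R2 change
#'
#' `(R2_post - R2_pre) / R2_pre` on a shared grid. Voxels where either
#' map is non-converged, or where the baseline rate falls below the
#' floor, carry `NaN`.
#'
#' @param pre Baseline [parametric_map()].
#' @param post Post-injection [parametric_map()].
#' @param rate_floor Minimum baseline rate (s^-1) accepted in the
#'   denominator; default 0.1.
#' @return 3-D array of dimensionless relative change.
#' @export
relative_r2_change <- function(pre, post, rate_floor = 0.1) {
  stopifnot(inherits(pre, "parametric_map"),
            inherits(post, "parametric_map"))
  if (!all(dim(pre$time) == dim(post$time)))
    abort_validation("pre and post maps are on different grids")
  change <- (post$rate - pre$rate) / pre$rate
  bad <- !pre$converged | !post$converged | !(pre$rate >= rate_floor)
  change[bad] <- NaN
  change
}

#' Dynamic relative-change curve over a mask
#'
#' Computes, for every post-injection timepoint, the voxel-wise relative
#' R2 change map against baseline and its mean and standard deviation
#' over the mask (sentinel voxels excluded). Timepoint `i` is stamped
#' `i * series_duration_min` minutes, time 0 being the baseline
#' acquisition; 82 series of 3 min end at 246 min. A timepoint whose
#' mask is empty after sentinel exclusion is flagged, not fatal.
#'
#' @param baseline Baseline [parametric_map()].
#' @param post_maps Time-ordered list of post [parametric_map()]s
#'   (>= 1).
#' @param mask Logical 3-D array on the shared grid.
#' @param series_duration_min Duration of one dynamic series (min).
#' @param summary `"mean"` (default) or `"median"` as the curve's
#'   central summary.
#' @param rate_floor Baseline-rate floor passed to
#'   [relative_r2_change()].
#' @return An object of class `dynamics_result`: `baseline`,
#'   `relative_change_maps` (list of arrays), and `curve`, a data frame
#'   with `time_min`, `mean_change`, `sd_change`, `n_voxels`, `flagged`.
#' @export
change_time_curve <- function(baseline, post_maps, mask,
                              series_duration_min,
                              summary = c("mean", "median"),
                              rate_floor = 0.1) {
  summary <- match.arg(summary)
  if (inherits(post_maps, "parametric_map")) post_maps <- list(post_maps)
  if (!length(post_maps)) abort_validation("need at least one post map")
  if (!any(mask)) abort_o17("mask contains no voxels", "o17_empty_mask_error")
  if (!all(dim(baseline$time) == dim(mask)))
    abort_validation("mask grid does not match the baseline map")
  centre <- if (summary == "mean") mean else stats::median

  maps <- vector("list", length(post_maps))
  rows <- vector("list", length(post_maps))
  for (i in seq_along(post_maps)) {
    ch <- relative_r2_change(baseline, post_maps[[i]], rate_floor)
    maps[[i]] <- ch
    vals <- ch[mask]
    vals <- vals[is.finite(vals)]
    flagged <- length(vals) == 0L
    rows[[i]] <- data.frame(
      time_min = i * series_duration_min,
      mean_change = if (flagged) NA_real_ else centre(vals),
      sd_change = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
      n_voxels = length(vals),
      flagged = flagged)
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  structure(list(baseline = baseline,
                 relative_change_maps = maps,
                 curve = curve,
                 summary = summary),
            class = "dynamics_result")
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat(sprintf("<dynamics_result> %d timepoint(s), %s summary\n",
              nrow(x$curve), x$summary))
  cat(sprintf("  peak %s change %.3f at %g min; final %.3f at %g min\n",
              x$summary,
              max(x$curve$mean_change, na.rm = TRUE),
              x$curve$time_min[which.max(x$curve$mean_change)],
              x$curve$mean_change[nrow(x$curve)],
              x$curve$time_min[nrow(x$curve)]))
  invisible(x)
}

#' Fit the washout model to a relative-change curve
#'
#' Least-squares fit of `peak * 2^(-(t - t_arrival) / halflife)` to the
#' observed curve from the arrival timepoint onwards, used to recover
#' the bolus parameters from a measured experiment.
#'
#' @param curve The `curve` data frame of a [change_time_curve()]
#'   result.
#' @param arrival_time_min Arrival timestamp (min); default the first
#'   timepoint.
#' @return List with `peak_relative_change` and `washout_halflife_min`.
#' @export
fit_washout <- function(curve, arrival_time_min = curve$time_min[1]) {
  obs <- curve[curve$time_min >= arrival_time_min & !curve$flagged, ]
  if (nrow(obs) < 3L)
    abort_validation("need at least 3 usable timepoints to fit a washout")
  t0 <- obs$time_min - arrival_time_min
  y <- obs$mean_change
  fit <- stats::optim(
    par = c(peak = max(y), log_hl = log(max(t0[t0 > 0], 1))),
    fn = function(p) sum((p[1] * 2^(-t0 / exp(p[2])) - y)^2),
    method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-12))
  list(peak_relative_change = unname(fit$par[1]),
       washout_halflife_min = unname(exp(fit$par[2])))
}
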