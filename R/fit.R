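#' Fit configuration
#'
#' Controls the voxel-wise least-squares fits. Defaults: relaxation time
#' bounded to [1, 20000] ms, amplitude to (0, 10 x series maximum],
#' convergence at relative parameter change < 1e-8 or 200 iterations,
#' and voxels whose maximum frame intensity falls below 5% of the series
#' maximum skipped as background (marked non-converged).
#'
#' @param max_iterations Iteration cap for the damped least-squares
#'   refinement.
#' @param convergence_tol Relative parameter change declaring
#'   convergence.
#' @param time_bounds Length-2 positive ordered bounds on the relaxation
#'   time (ms).
#' @param amplitude_bounds Length-2 bounds on the amplitude, or `NULL`
#'   for model-dependent defaults: (0, 10 x max signal] for multi-echo
#'   decays, whose amplitude is the extrapolated zero-echo signal, and
#'   (0, 1000 x max signal] for the variable-flip-angle fit, whose M0
#'   far exceeds the measured steady-state signal at short TR.
#' @param min_signal_fraction Background threshold as a fraction of the
#'   series maximum, in [0, 1).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(max_iterations = 200L,
                       convergence_tol = 1e-8,
                       time_bounds = c(1, 20000),
                       amplitude_bounds = NULL,
                       min_signal_fraction = 0.05) {
  if (length(time_bounds) != 2L || any(time_bounds <= 0) ||
      time_bounds[1] >= time_bounds[2])
    abort_validation("time_bounds must be positive and ordered")
  if (!is.null(amplitude_bounds) &&
      (length(amplitude_bounds) != 2L || any(amplitude_bounds <= 0) ||
       amplitude_bounds[1] >= amplitude_bounds[2]))
    abort_validation("amplitude_bounds must be positive and ordered")
  if (min_signal_fraction < 0 || min_signal_fraction >= 1)
    abort_validation("min_signal_fraction must be in [0, 1)")
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 time_bounds = time_bounds,
                 amplitude_bounds = amplitude_bounds,
                 min_signal_fraction = min_signal_fraction),
            class = "fit_config")
}

# Vectorized damped least squares over voxels for separable
# two-parameter decay models (amplitude x basis(time)). The amplitude is
# linear in both models, so it is profiled out by linear least squares
# at every step (variable projection) and the Levenberg-Marquardt
# iteration runs on the relaxation time alone. basis(time) must return
# list(g, dg): the n x m basis values and their derivative in time.
# Bounds are enforced by projection; a voxel converges on a relative
# time change below tol, an accepted step with no measurable residual
# decrease, or damping past the point of measurable steps.
lm_refine_profiled <- function(y, t0, basis, lower_t, upper_t,
                               amp_lo, amp_hi, max_iterations, tol) {
  clamp <- function(p, lo, hi) pmin(pmax(p, lo), hi)
  tt <- clamp(t0, lower_t, upper_t)
  n <- length(tt)
  profile <- function(tt) {
    b <- basis(tt)
    k <- clamp(rowSums(y * b$g) / pmax(rowSums(b$g * b$g), 1e-300),
               amp_lo, amp_hi)
    r <- k * b$g - y
    list(k = k, g = b$g, dg = b$dg, r = r, rss = rowSums(r * r))
  }
  st <- profile(tt)
  lambda <- rep(1e-3, n)
  converged <- rep(FALSE, n)
  for (it in seq_len(max_iterations)) {
    active <- !converged
    if (!any(active)) break
    J <- st$k * st$dg
    a <- rowSums(J * J)
    grad <- rowSums(J * st$r)
    step <- -grad / pmax(a * (1 + lambda), 1e-300)
    t_new <- clamp(tt + step, lower_t, upper_t)
    st_new <- profile(t_new)
    improved <- active & is.finite(st_new$rss) &
      st_new$rss <= st$rss + 1e-12 * (1 + st$rss)
    relch <- abs(t_new - tt) / pmax(abs(tt), 1e-12)
    converged <- converged |
      (improved & (relch < tol |
                     st$rss - st_new$rss <= 1e-10 * (1 + st$rss)))
    upd <- improved
    tt[upd] <- t_new[upd]
    st$k[upd] <- st_new$k[upd]
    st$rss[upd] <- st_new$rss[upd]
    st$g[upd, ] <- st_new$g[upd, ]
    st$dg[upd, ] <- st_new$dg[upd, ]
    st$r[upd, ] <- st_new$r[upd, ]
    lambda <- ifelse(improved, pmax(lambda / 3, 1e-12), lambda * 10)
    converged <- converged | (active & !improved & lambda > 1e8)
  }
  list(amplitude = st$k, time = tt, rss = st$rss, converged = converged)
}

series_matrix <- function(series) {
  d <- dim(series$data)
  matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
}

assemble_map <- function(series, fitted_idx, p_amp, p_time, rss, conv,
                         shape) {
  nv <- prod(shape)
  time <- rep(NaN, nv); amp <- rep(NaN, nv)
  rss_all <- rep(NaN, nv); cv <- rep(FALSE, nv)
  time[fitted_idx] <- p_time
  amp[fitted_idx] <- p_amp
  rss_all[fitted_idx] <- rss
  cv[fitted_idx] <- conv
  parametric_map(array(time, shape), array(amp, shape),
                 array(rss_all, shape), array(cv, shape),
                 series$protocol$voxel_size_mm)
}

#' Voxel-wise mono-exponential transverse relaxation fit
#'
#' Fits `SI = k * exp(-TE / T)` to every foreground voxel of a
#' multi-echo series using all echoes. Starting values come from a
#' log-linear regression of the intensities on echo time; refinement
#' uses damped (Levenberg-Marquardt) least squares on the relaxation
#' time with the amplitude profiled out by linear least squares at each
#' step, and bound projection. The rate map is `1000 / T` in s^-1.
#'
#' Voxels below the background threshold, voxels with a strictly
#' increasing echo train (non-physical for a decay), and voxels with no
#' positive intensity at any echo are marked non-converged and carry
#' `NaN`.
#'
#' @param series A multi-echo [image_series()] with >= 3 echoes.
#' @param config A [fit_config()].
#' @return A [parametric_map()]; T2 or T2* depending on which sequence
#'   produced the series.
#' @export
fit_monoexp <- function(series, config = fit_config()) {
  stopifnot(inherits(series, "image_series"))
  if (series$frame_axis != "echo" || n_frames(series) < 3L)
    abort_protocol("fit_monoexp needs an echo-axis series with >= 3 echoes")
  tes <- series$protocol$echo_times_ms
  y <- series_matrix(series)
  shape <- dim(series$data)[1:3]
  maxsig <- max(y)
  if (maxsig <= 0) abort_validation("series contains no signal")
  rmax <- do.call(pmax, as.data.frame(y))
  fit_idx <- which(rmax >= config$min_signal_fraction * maxsig)
  if (!length(fit_idx))
    return(assemble_map(series, integer(), numeric(), numeric(),
                        numeric(), logical(), shape))
  yf <- y[fit_idx, , drop = FALSE]

  # exclusions: all-nonpositive, or strictly increasing echo train
  any_pos <- rowSums(yf > 0) > 0
  increasing <- rowSums(yf[, -1, drop = FALSE] >
                          yf[, -ncol(yf), drop = FALSE]) == (ncol(yf) - 1L)
  usable <- any_pos & !increasing

  amp_hi <- if (is.null(config$amplitude_bounds)) 10 * maxsig
            else config$amplitude_bounds[2]
  amp_lo <- if (is.null(config$amplitude_bounds)) maxsig * 1e-9
            else config$amplitude_bounds[1]

  # log-linear initialization on all echoes (clamped at a tiny floor)
  eps <- maxsig * 1e-9
  L <- log(pmax(yf, eps))
  te_c <- tes - mean(tes)
  sxx <- sum(te_c^2)
  slope <- as.vector(L %*% te_c) / sxx
  t0 <- ifelse(slope < 0, -1 / slope, config$time_bounds[2])

  basis <- function(tt) {
    g <- exp(outer(-1 / tt, tes))
    list(g = g, dg = g * outer(1 / tt^2, tes))
  }
  fit <- lm_refine_profiled(yf, t0, basis,
                            config$time_bounds[1], config$time_bounds[2],
                            amp_lo, amp_hi,
                            config$max_iterations, config$convergence_tol)
  conv <- fit$converged & usable
  assemble_map(series, fit_idx, fit$amplitude, fit$time, fit$rss, conv, shape)
}

#' Voxel-wise variable-flip-angle T1 fit
#'
#' Fits the SPGR steady-state equation (see [vfa_signal()]) to every
#' foreground voxel of a variable-flip-angle series. Starting values
#' come from the standard linearization (signal/sin(theta) regressed on
#' signal/tan(theta), whose slope is `exp(-TR/T1)`); refinement uses
#' damped least squares on T1 with M0 profiled out by linear least
#' squares at each step, and bound projection. The rate map is
#' `1000 / T1` in s^-1.
#'
#' Voxels whose refined T1 is pinned at a bound, and voxels whose best
#' fit still misses the data by more than 15% of the mean signal (root
#' mean square), are marked non-converged: no T1 within bounds explains
#' their angle dependence. The misfit rule covers the degenerate
#' constant-signal case, whose least-squares optimum leaves a residual
#' an order of magnitude above noise at working SNR.
#'
#' @param series A `vfa_spgr` [image_series()] with >= 2 flip angles.
#' @param config A [fit_config()].
#' @return A [parametric_map()] of T1 / R1 / M0.
#' @export
fit_t1_vfa <- function(series, config = fit_config()) {
  stopifnot(inherits(series, "image_series"))
  if (series$frame_axis != "flip_angle" || n_frames(series) < 2L)
    abort_protocol("fit_t1_vfa needs a flip-angle series with >= 2 angles")
  th <- series$protocol$flip_angles_deg * pi / 180
  tr <- series$protocol$tr_ms
  y <- series_matrix(series)
  shape <- dim(series$data)[1:3]
  maxsig <- max(y)
  if (maxsig <= 0) abort_validation("series contains no signal")
  rmax <- do.call(pmax, as.data.frame(y))
  fit_idx <- which(rmax >= config$min_signal_fraction * maxsig)
  if (!length(fit_idx))
    return(assemble_map(series, integer(), numeric(), numeric(),
                        numeric(), logical(), shape))
  yf <- y[fit_idx, , drop = FALSE]

  # at short TR the SPGR signal is a small fraction of M0 (about TR/T1
  # of it near the Ernst angle), so the default M0 cap must sit far
  # above the measured signal
  amp_hi <- if (is.null(config$amplitude_bounds)) 1000 * maxsig
            else config$amplitude_bounds[2]
  amp_lo <- if (is.null(config$amplitude_bounds)) maxsig * 1e-9
            else config$amplitude_bounds[1]

  # DESPOT1-style linearization: Y = S/sin, X = S/tan, slope = E1
  Ylin <- sweep(yf, 2, sin(th), "/")
  Xlin <- sweep(yf, 2, tan(th), "/")
  xbar <- rowMeans(Xlin); ybar <- rowMeans(Ylin)
  sxx <- rowSums((Xlin - xbar)^2)
  sxy <- rowSums((Xlin - xbar) * (Ylin - ybar))
  e1 <- sxy / pmax(sxx, 1e-300)
  valid <- is.finite(e1) & e1 > 0 & e1 < 1
  t1_0 <- rep(config$time_bounds[2], nrow(yf))
  t1_0[valid] <- -tr / log(e1[valid])

  basis <- function(t1) {
    e <- exp(-tr / t1)
    den <- 1 - outer(e, cos(th))
    g <- outer(1 - e, sin(th)) / den
    # d g / d E1, chained through dE1/dT1 = E1 * TR / T1^2
    dgde <- outer(rep(1, length(e)), sin(th)) *
      (outer(rep(1, length(e)), cos(th)) - 1) / den^2
    list(g = g, dg = dgde * (e * tr / t1^2))
  }
  fit <- lm_refine_profiled(yf, t1_0, basis,
                            config$time_bounds[1], config$time_bounds[2],
                            amp_lo, amp_hi,
                            config$max_iterations, config$convergence_tol)
  at_bound <- fit$time <= config$time_bounds[1] * (1 + 1e-9) |
              fit$time >= config$time_bounds[2] * (1 - 1e-9)
  # voxels whose angle dependence the model cannot reproduce (e.g. a
  # constant signal, whose best fit still misses by >20% of the mean)
  misfit <- sqrt(fit$rss / length(th)) > 0.15 * rowMeans(yf)
  conv <- fit$converged & !at_bound & !misfit
  assemble_map(series, fit_idx, fit$amplitude, fit$time, fit$rss, conv, shape)
}

#' Summary report of a fit
#'
#' @param map A [parametric_map()].
#' @return List with voxel counts, converged fraction and rate summary
#'   statistics, suitable for serialization as a structured-text report.
#' @export
fit_report <- function(map) {
  stopifnot(inherits(map, "parametric_map"))
  fitted <- sum(is.finite(map$rss))
  conv <- sum(map$converged)
  rates <- map$rate[map$converged]
  list(voxels_total = length(map$time),
       voxels_fitted = fitted,
       voxels_converged = conv,
       converged_fraction = if (fitted > 0) conv / fitted else 0,
       rate_median = if (length(rates)) stats::median(rates) else NA_real_,
       rate_iqr = if (length(rates)) stats::IQR(rates) else NA_real_)
}
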