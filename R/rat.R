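#' Parameters of the synthetic rat bolus experiment
#'
#' The dynamic scenario: a brain-shaped region at a constant baseline R2
#' receives an injected tracer bolus that raises R2 by a relative
#' fraction at arrival, followed by mono-exponential washout back to
#' baseline. The acquisition schedule is a baseline series followed by
#' `n_dynamic_series` consecutive series of `series_duration_min`
#' minutes each (82 x 3 min in the full experiment).
#'
#' @param baseline_r2 Baseline brain R2 (s^-1); default 13, a typical
#'   3-T brain value.
#' @param peak_relative_change Relative R2 elevation at bolus arrival
#'   (dimensionless, in [0, 1)); default 0.10.
#' @param washout_halflife_min Washout half-life (min).
#' @param n_dynamic_series Number of post-injection series (>= 1).
#' @param series_duration_min Duration of one series (min).
#' @param arrival_series_index Index of the first post series at which
#'   the bolus has arrived (1 = immediately after injection).
#' @return An object of class `rat_dynamics_params`.
#' @export
rat_dynamics_params <- function(baseline_r2 = 13,
                                peak_relative_change = 0.10,
                                washout_halflife_min = 60,
                                n_dynamic_series = 82L,
                                series_duration_min = 3,
                                arrival_series_index = 1L) {
  if (baseline_r2 <= 0) abort_validation("baseline_r2 must be positive")
  if (peak_relative_change < 0 || peak_relative_change >= 1)
    abort_validation("peak_relative_change must be in [0, 1)")
  if (n_dynamic_series < 1L)
    abort_validation("n_dynamic_series must be >= 1")
  if (washout_halflife_min <= 0)
    abort_validation("washout_halflife_min must be positive")
  if (arrival_series_index > n_dynamic_series)
    abort_validation("arrival_series_index must not exceed n_dynamic_series")
  structure(list(baseline_r2 = baseline_r2,
                 peak_relative_change = peak_relative_change,
                 washout_halflife_min = washout_halflife_min,
                 n_dynamic_series = as.integer(n_dynamic_series),
                 series_duration_min = series_duration_min,
                 arrival_series_index = as.integer(arrival_series_index)),
            class = "rat_dynamics_params")
}

#' True relative R2 change at a post-injection timepoint
#'
#' Zero before arrival; `peak * 2^(-(t - t_arrival) / halflife)` from
#' arrival onwards, with `t_i = i * series_duration_min`.
#'
#' @param params A [rat_dynamics_params()].
#' @param series_index Post-series index (1-based); vectorized.
#' @return Dimensionless relative change(s).
#' @export
true_relative_change <- function(params, series_index) {
  t <- series_index * params$series_duration_min
  t_arr <- params$arrival_series_index * params$series_duration_min
  ifelse(series_index < params$arrival_series_index, 0,
         params$peak_relative_change *
           2^(-(t - t_arr) / params$washout_halflife_min))
}

brain_ellipse_mask <- function(protocol, semi_axes_mm = c(16, 12)) {
  shp <- protocol$matrix_shape
  vx <- protocol$voxel_size_mm
  xs <- (seq_len(shp[1]) - (shp[1] + 1) / 2) * vx[1]
  ys <- (seq_len(shp[2]) - (shp[2] + 1) / 2) * vx[2]
  in2d <- outer(xs, ys, function(x, y)
    (x / semi_axes_mm[1])^2 + (y / semi_axes_mm[2])^2 <= 1)
  array(rep(in2d, shp[3]), shp)
}

#' Simulate the dynamic rat-brain bolus experiment
#'
#' Renders a baseline multi-echo series and `n_dynamic_series` post
#' series on the 8-echo TSE timing (unless overridden). Inside an
#' elliptical brain region the true R2 follows the bolus model of
#' [true_relative_change()]; each timepoint is rendered by
#' [simulate_multiecho_series()] with a per-timepoint seed derived from
#' the noise seed (`seed + series index`), so the whole experiment is
#' reproducible from one seed.
#'
#' @param params A [rat_dynamics_params()].
#' @param protocol A multi-echo [acquisition_protocol()]; default the
#'   20-ms-interval 8-echo TSE.
#' @param noise A [noise_model()].
#' @param amplitude Signal amplitude inside the brain.
#' @param t1_ms,t2star_fraction Concentration-independent T1 and the
#'   T2*/T2 ratio of the rendered truth.
#' @param semi_axes_mm In-plane semi-axes of the brain ellipse (mm).
#' @return List with `baseline` ([image_series()]), `post` (list of
#'   [image_series()]), `mask` (logical 3-D array), `times_min`
#'   (post timestamps `i * series_duration_min`), `true_change`
#'   (true relative R2 change per timepoint) and `params`.
#' @export
simulate_rat_dynamics <- function(params = rat_dynamics_params(),
                                  protocol = tse_protocol(),
                                  noise = noise_model("none"),
                                  amplitude = 1000,
                                  t1_ms = 2000,
                                  t2star_fraction = 0.8,
                                  semi_axes_mm = c(16, 12)) {
  stopifnot(inherits(params, "rat_dynamics_params"))
  mask <- brain_ellipse_mask(protocol, semi_axes_mm)
  shp <- protocol$matrix_shape

  truth_at <- function(r2) {
    t2 <- array(t1_ms, shp)
    t2[mask] <- pmin(1000 / r2, t1_ms)
    amp <- array(0, shp); amp[mask] <- amplitude
    ground_truth_maps(array(t1_ms, shp), t2, t2 * t2star_fraction,
                      amp, array(0, shp))
  }
  render <- function(r2, seed_offset) {
    nm <- noise
    nm$seed <- noise$seed + as.integer(seed_offset)
    simulate_multiecho_series(truth_at(r2), protocol, nm, decay = "t2")
  }

  baseline <- render(params$baseline_r2, 0L)
  idx <- seq_len(params$n_dynamic_series)
  change <- true_relative_change(params, idx)
  post <- lapply(idx, function(i)
    render(params$baseline_r2 * (1 + change[i]), i))
  list(baseline = baseline, post = post, mask = mask,
       times_min = idx * params$series_duration_min,
       true_change = change, params = params)
}
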