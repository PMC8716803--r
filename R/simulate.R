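#' Spoiled gradient-echo steady-state signal
#'
#' The variable-flip-angle SPGR magnetisation
#' `M0 * sin(theta) * (1 - E1) / (1 - cos(theta) * E1)` with
#' `E1 = exp(-TR / T1)`.
#'
#' @param m0 Equilibrium magnetisation (arbitrary units).
#' @param t1_ms Longitudinal relaxation time (ms).
#' @param tr_ms Repetition time (ms).
#' @param flip_deg Flip angle (degrees). Arguments recycle.
#' @return Signal intensity, same units as `m0`.
#' @export
vfa_signal <- function(m0, t1_ms, tr_ms, flip_deg) {
  th <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(th) * (1 - e1) / (1 - cos(th) * e1)
}

#' Mono-exponential echo-train signal
#'
#' `SI = k * exp(-TE / T)` with `T` the transverse relaxation time (T2 or
#' T2*, ms).
#'
#' @param k Amplitude at TE = 0.
#' @param t_ms Transverse relaxation time (ms).
#' @param te_ms Echo time (ms). Arguments recycle.
#' @return Signal intensity.
#' @export
monoexp_signal <- function(k, t_ms, te_ms) {
  k * exp(-te_ms / t_ms)
}

#' Noise model for the simulators
#'
#' @param kind `"rician"` or `"none"`. Magnitude MR images carry Rician
#'   noise; `"none"` renders noiseless signal.
#' @param sigma Gaussian channel standard deviation (intensity units);
#'   ignored for `kind = "none"`.
#' @param seed Integer RNG seed; every generator is bit-reproducible
#'   given the same parameters and seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("rician", "none"), sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    abort_validation("sigma must be a single non-negative number")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Add Rician noise to a magnitude image
#'
#' Each voxel value `s` becomes `sqrt((s + g1)^2 + g2^2)` with `g1`, `g2`
#' independent zero-mean Gaussians of standard deviation `sigma` — the
#' magnitude of a complex signal with independent Gaussian channel noise.
#' `sigma = 0` returns the input unchanged.
#'
#' @param x An [image_series()] or a numeric array.
#' @param sigma Channel noise standard deviation (>= 0).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Object of the same type as `x`.
#' @export
add_rician_noise <- function(x, sigma, seed) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    abort_validation("sigma must be a single non-negative number")
  if (sigma == 0) return(x)
  arr <- if (inherits(x, "image_series")) x$data else x
  noisy <- withr::with_seed(as.integer(seed), {
    n <- length(arr)
    sqrt((arr + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  })
  dim(noisy) <- dim(arr)
  if (inherits(x, "image_series")) {
    x$data <- noisy
    x
  } else noisy
}

apply_noise <- function(series, noise) {
  if (is.null(noise) || noise$kind == "none" || noise$sigma == 0) return(series)
  add_rician_noise(series, noise$sigma, noise$seed)
}

#' Channel sigma for a target first-frame SNR
#'
#' Computes the Rician channel standard deviation giving the requested
#' signal-to-noise ratio at the first frame, with signal taken as the
#' mean noiseless first-frame intensity over foreground voxels
#' (amplitude > 0).
#'
#' @param series A noiseless [image_series()].
#' @param snr Target first-frame SNR (dimensionless).
#' @param foreground Optional logical 3-D array selecting foreground;
#'   defaults to voxels with non-zero first-frame signal.
#' @return Channel sigma in intensity units.
#' @export
snr_sigma <- function(series, snr, foreground = NULL) {
  stopifnot(inherits(series, "image_series"), snr > 0)
  first <- series$data[, , , 1L]
  if (is.null(foreground)) foreground <- first > 0
  if (!any(foreground)) abort_validation("no foreground voxels to define SNR")
  mean(first[foreground]) / snr
}

#' Simulate a variable-flip-angle SPGR series
#'
#' Renders one frame per flip angle from the ground-truth T1 and
#' amplitude maps via the SPGR steady-state equation, then applies the
#' noise model.
#'
#' @param truth A [ground_truth_maps()] object.
#' @param protocol A `vfa_spgr` [acquisition_protocol()] with at least
#'   two flip angles.
#' @param noise A [noise_model()]; default noiseless.
#' @return An [image_series()] with `frame_axis = "flip_angle"`.
#' @export
simulate_vfa_series <- function(truth, protocol, noise = noise_model("none")) {
  stopifnot(inherits(truth, "ground_truth_maps"))
  if (protocol$sequence_kind != "vfa_spgr" ||
      length(protocol$flip_angles_deg) < 2L)
    abort_protocol("simulate_vfa_series needs a vfa_spgr protocol with >= 2 flip angles")
  check_truth_grid(truth, protocol)
  angles <- protocol$flip_angles_deg
  sp <- dim(truth$true_t1)
  data <- array(0, c(sp, length(angles)))
  for (f in seq_along(angles)) {
    data[, , , f] <- vfa_signal(truth$true_amplitude, truth$true_t1,
                                protocol$tr_ms, angles[f])
  }
  apply_noise(image_series(data, protocol, "flip_angle"), noise)
}

#' Simulate a multi-echo series
#'
#' Renders one frame per echo time as `k * exp(-TE / T)` with `T` the
#' ground-truth T2 (`decay = "t2"`) or T2* (`decay = "t2star"`), then
#' applies the noise model.
#'
#' @param truth A [ground_truth_maps()] object.
#' @param protocol A multi-echo [acquisition_protocol()] with at least
#'   three echoes.
#' @param noise A [noise_model()]; default noiseless.
#' @param decay Which transverse time decays the train.
#' @return An [image_series()] with `frame_axis = "echo"`.
#' @export
simulate_multiecho_series <- function(truth, protocol,
                                      noise = noise_model("none"),
                                      decay = c("t2", "t2star")) {
  decay <- match.arg(decay)
  stopifnot(inherits(truth, "ground_truth_maps"))
  if (length(protocol$echo_times_ms) < 3L)
    abort_protocol("simulate_multiecho_series needs >= 3 echo times")
  check_truth_grid(truth, protocol)
  tmap <- if (decay == "t2") truth$true_t2 else truth$true_t2star
  tes <- protocol$echo_times_ms
  sp <- dim(tmap)
  data <- array(0, c(sp, length(tes)))
  for (f in seq_along(tes)) {
    data[, , , f] <- monoexp_signal(truth$true_amplitude, tmap, tes[f])
  }
  apply_noise(image_series(data, protocol, "echo"), noise)
}

check_truth_grid <- function(truth, protocol) {
  if (!all(dim(truth$true_amplitude) == protocol$matrix_shape))
    abort_validation("ground-truth grid does not match the protocol matrix")
  invisible(TRUE)
}
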