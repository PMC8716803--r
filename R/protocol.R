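#' Acquisition protocol
#'
#' Describes the pulse-sequence timing and geometry that drive both the
#' signal simulators and the voxel-wise fitters. Exactly one of
#' `echo_times_ms` / `flip_angles_deg` is non-empty: multi-echo sequences
#' (`multiecho_tse`, `multiecho_gre`) carry an echo-time train, the
#' variable-flip-angle spoiled gradient echo (`vfa_spgr`) carries the
#' flip-angle list.
#'
#' @param sequence_kind One of `"vfa_spgr"`, `"multiecho_gre"`,
#'   `"multiecho_tse"`.
#' @param tr_ms Repetition time in milliseconds. For multi-echo sequences
#'   it must exceed the last echo time.
#' @param echo_times_ms Strictly increasing positive echo times (ms);
#'   empty for `vfa_spgr`.
#' @param flip_angles_deg Strictly increasing flip angles in (0, 90]
#'   degrees; empty for multi-echo kinds.
#' @param voxel_size_mm Length-3 positive voxel size (mm).
#' @param matrix_shape Length-3 positive integer acquisition matrix.
#' @param series_duration_min Duration of one dynamic series (min); only
#'   meaningful for dynamic acquisitions, `NA` otherwise.
#'
#' @return An object of class `acquisition_protocol`.
#' @seealso [tse_protocol()], [vfa_protocol()], [gre_t2star_protocol()]
#'   for the presets used throughout the phantom and animal experiments.
#' @export
acquisition_protocol <- function(sequence_kind,
                                 tr_ms,
                                 echo_times_ms = numeric(),
                                 flip_angles_deg = numeric(),
                                 voxel_size_mm = c(1.67, 1.67, 5),
                                 matrix_shape = c(96L, 96L, 1L),
                                 series_duration_min = NA_real_) {
  sequence_kind <- match.arg(sequence_kind,
                             c("vfa_spgr", "multiecho_gre", "multiecho_tse"))
  echo_times_ms <- as.numeric(echo_times_ms)
  flip_angles_deg <- as.numeric(flip_angles_deg)
  tr_ms <- as.numeric(tr_ms)

  if (length(tr_ms) != 1L || !is.finite(tr_ms) || tr_ms <= 0)
    abort_validation("tr_ms must be a single positive number")
  has_echoes <- length(echo_times_ms) > 0L
  has_flips <- length(flip_angles_deg) > 0L
  if (has_echoes == has_flips)
    abort_validation("exactly one of echo_times_ms / flip_angles_deg must be non-empty")
  if (has_echoes) {
    if (any(echo_times_ms <= 0) || any(diff(echo_times_ms) <= 0))
      abort_validation("echo_times_ms must be strictly increasing and positive")
    if (tr_ms <= max(echo_times_ms))
      abort_validation(sprintf("tr_ms (%g) must exceed the last echo time (%g)",
                               tr_ms, max(echo_times_ms)))
    if (sequence_kind == "vfa_spgr")
      abort_validation("vfa_spgr protocols take flip angles, not echo times")
  }
  if (has_flips) {
    if (any(flip_angles_deg <= 0) || any(flip_angles_deg > 90) ||
        any(diff(flip_angles_deg) <= 0))
      abort_validation("flip_angles_deg must be strictly increasing, in (0, 90]")
    if (sequence_kind != "vfa_spgr")
      abort_validation("multi-echo protocols take echo times, not flip angles")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    abort_validation("voxel_size_mm must be 3 positive numbers")
  matrix_shape <- as.integer(matrix_shape)
  if (length(matrix_shape) != 3L || any(is.na(matrix_shape)) ||
      any(matrix_shape < 1L))
    abort_validation("matrix_shape must be 3 positive integers")
  series_duration_min <- as.numeric(series_duration_min)
  if (length(series_duration_min) != 1L ||
      (!is.na(series_duration_min) && series_duration_min <= 0))
    abort_validation("series_duration_min must be a single positive number or NA")

  structure(
    list(sequence_kind = sequence_kind,
         tr_ms = tr_ms,
         echo_times_ms = echo_times_ms,
         flip_angles_deg = flip_angles_deg,
         voxel_size_mm = voxel_size_mm,
         matrix_shape = matrix_shape,
         series_duration_min = series_duration_min),
    class = "acquisition_protocol"
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("<acquisition_protocol>", x$sequence_kind, "\n")
  cat("  TR:", x$tr_ms, "ms\n")
  if (length(x$echo_times_ms))
    cat("  TEs (ms):", paste(x$echo_times_ms, collapse = ", "), "\n")
  if (length(x$flip_angles_deg))
    cat("  flip angles (deg):", paste(x$flip_angles_deg, collapse = ", "), "\n")
  cat("  matrix:", paste(x$matrix_shape, collapse = " x "),
      " voxel (mm):", paste(x$voxel_size_mm, collapse = " x "), "\n")
  if (!is.na(x$series_duration_min))
    cat("  series duration:", x$series_duration_min, "min\n")
  invisible(x)
}

n_protocol_frames <- function(protocol) {
  max(length(protocol$echo_times_ms), length(protocol$flip_angles_deg))
}

#' Multi-echo turbo spin-echo protocol preset
#'
#' The single-slice 8-echo T2-weighted TSE acquisition (TR 800 ms,
#' 1.67 x 1.67 x 5 mm voxels) with a configurable echo-time interval.
#' The 20-ms interval variant (TEs 20, 40, ..., 160 ms) is the sequence
#' used for both the phantom calibration and the dynamic brain series.
#'
#' @param te_interval_ms Echo spacing in ms (10, 20, 40 or 50 in the
#'   acquisition battery; any positive value is accepted).
#' @param n_echoes Number of echoes (default 8).
#' @param tr_ms Repetition time (ms).
#' @param matrix_shape,voxel_size_mm Geometry.
#' @param series_duration_min Duration of one dynamic repeat (min).
#' @return An [acquisition_protocol()].
#' @export
tse_protocol <- function(te_interval_ms = 20, n_echoes = 8, tr_ms = 800,
                         matrix_shape = c(96L, 96L, 1L),
                         voxel_size_mm = c(1.67, 1.67, 5),
                         series_duration_min = 3) {
  acquisition_protocol("multiecho_tse", tr_ms = tr_ms,
                       echo_times_ms = te_interval_ms * seq_len(n_echoes),
                       voxel_size_mm = voxel_size_mm,
                       matrix_shape = matrix_shape,
                       series_duration_min = series_duration_min)
}

#' Variable-flip-angle SPGR protocol preset
#'
#' 3-D T1-weighted spoiled gradient echo at TR 14 ms with flip angles
#' 5, 10, 15, 20 and 45 degrees.
#'
#' @param flip_angles_deg Flip-angle list (degrees).
#' @param tr_ms Repetition time (ms).
#' @param matrix_shape,voxel_size_mm Geometry (defaults to the 3-D
#'   192 x 192 x 15 acquisition at 1.88 x 1.88 x 5 mm).
#' @return An [acquisition_protocol()].
#' @export
vfa_protocol <- function(flip_angles_deg = c(5, 10, 15, 20, 45), tr_ms = 14,
                         matrix_shape = c(192L, 192L, 15L),
                         voxel_size_mm = c(1.88, 1.88, 5)) {
  acquisition_protocol("vfa_spgr", tr_ms = tr_ms,
                       flip_angles_deg = flip_angles_deg,
                       voxel_size_mm = voxel_size_mm,
                       matrix_shape = matrix_shape)
}

#' Multi-echo gradient-echo (T2*) protocol preset
#'
#' 2-D 12-echo gradient echo. The default echo train is the 1-ms-interval
#' set (TEs 1..12 ms) at TR 13 ms; the longer-interval variant requires a
#' TR exceeding its last echo, which protocol validation enforces.
#'
#' @param echo_times_ms Echo-time train (ms).
#' @param tr_ms Repetition time (ms); must exceed the last echo.
#' @param matrix_shape,voxel_size_mm Geometry.
#' @return An [acquisition_protocol()].
#' @export
gre_t2star_protocol <- function(echo_times_ms = 1:12, tr_ms = 13,
                                matrix_shape = c(96L, 96L, 13L),
                                voxel_size_mm = c(1.88, 1.88, 5)) {
  acquisition_protocol("multiecho_gre", tr_ms = tr_ms,
                       echo_times_ms = echo_times_ms,
                       voxel_size_mm = voxel_size_mm,
                       matrix_shape = matrix_shape)
}

#' Read / write a protocol sidecar
#'
#' Protocol sidecars are YAML files with keys `sequence_kind`, `tr_ms`,
#' `echo_times_ms`, `flip_angles_deg`, `voxel_size_mm`, `matrix_shape`
#' and `series_duration_min`; empty lists are omitted.
#'
#' @param path Sidecar file path.
#' @return `read_protocol()` returns an [acquisition_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("sidecar not found: %s", path))
  raw <- yaml::read_yaml(path)
  acquisition_protocol(
    sequence_kind = raw$sequence_kind,
    tr_ms = raw$tr_ms,
    echo_times_ms = if (is.null(raw$echo_times_ms)) numeric() else raw$echo_times_ms,
    flip_angles_deg = if (is.null(raw$flip_angles_deg)) numeric() else raw$flip_angles_deg,
    voxel_size_mm = raw$voxel_size_mm,
    matrix_shape = if (is.null(raw$matrix_shape)) c(96L, 96L, 1L) else raw$matrix_shape,
    series_duration_min = if (is.null(raw$series_duration_min)) NA_real_
                          else raw$series_duration_min
  )
}

#' @rdname read_protocol
#' @param protocol An [acquisition_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  out <- list(sequence_kind = protocol$sequence_kind,
              tr_ms = protocol$tr_ms,
              voxel_size_mm = protocol$voxel_size_mm,
              matrix_shape = protocol$matrix_shape)
  if (length(protocol$echo_times_ms))
    out$echo_times_ms <- protocol$echo_times_ms
  if (length(protocol$flip_angles_deg))
    out$flip_angles_deg <- protocol$flip_angles_deg
  if (!is.na(protocol$series_duration_min))
    out$series_duration_min <- protocol$series_duration_min
  yaml::write_yaml(out, path)
  invisible(path)
}
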