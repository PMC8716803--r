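#' Parametric relaxation map
#'
#' Per-voxel results of a relaxation fit: the relaxation time (ms), the
#' derived rate (s^-1, `rate = 1000 / time`), the fitted amplitude (M0 or
#' k), the residual sum of squares, and a convergence mask. Voxels that
#' were not fitted or did not converge carry `NaN` in the time/rate/
#' amplitude maps; the convergence mask is the authoritative record.
#'
#' @param time 3-D array of relaxation times (ms).
#' @param amplitude 3-D array of fitted amplitudes.
#' @param rss 3-D array of residual sums of squares.
#' @param converged 3-D logical array.
#' @param voxel_size_mm Length-3 voxel size (mm).
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(time, amplitude, rss, converged, voxel_size_mm) {
  stopifnot(is.array(time), is.array(converged),
            all(dim(time) == dim(converged)))
  converged <- array(as.logical(converged), dim(converged))
  time[!converged] <- NaN
  amplitude[!converged] <- NaN
  if (any(time[converged] <= 0, na.rm = TRUE))
    abort_validation("relaxation times must be positive on converged voxels")
  structure(
    list(time = time,
         rate = 1000 / time,
         amplitude = amplitude,
         rss = rss,
         converged = converged,
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "parametric_map"
  )
}

#' @export
print.parametric_map <- function(x, ...) {
  d <- dim(x$time)
  cat(sprintf("<parametric_map> %dx%dx%d, %d/%d voxels converged\n",
              d[1], d[2], d[3], sum(x$converged), length(x$converged)))
  if (any(x$converged))
    cat(sprintf("  rate (s^-1): median %.3g [%.3g, %.3g]\n",
                stats::median(x$rate[x$converged]),
                min(x$rate[x$converged]), max(x$rate[x$converged])))
  invisible(x)
}

#' Recompute the rate map from the time map
#'
#' Applies the fixed unit convention `rate [s^-1] = 1000 / time [ms]`.
#' Idempotent; `NaN` sentinels on non-converged voxels propagate.
#'
#' @param map A [parametric_map()].
#' @return The map with `rate` refreshed from `time`.
#' @export
to_rate_map <- function(map) {
  stopifnot(inherits(map, "parametric_map"))
  map$rate <- 1000 / map$time
  map
}

map_file_names <- function(prefix) {
  paste0(prefix, "_", c("time", "rate", "amplitude", "rss", "converged_mask"),
         ".nii.gz")
}

#' Save / load a parametric-map bundle
#'
#' `save_parametric_map()` writes five NIfTI volumes into `out_dir`,
#' named `<prefix>_time.nii.gz`, `_rate`, `_amplitude`, `_rss` and
#' `_converged_mask` (the mask as 0/1 integers, everything else as
#' floating point with `NaN` sentinels on non-converged voxels).
#' `load_parametric_map()` reads such a bundle back.
#'
#' @param map A [parametric_map()].
#' @param out_dir Output directory (created if missing).
#' @param prefix File-name prefix, default `"map"`.
#' @return `save_parametric_map()`: named character vector of the five
#'   paths, invisibly. `load_parametric_map()`: a [parametric_map()].
#' @export
save_parametric_map <- function(map, out_dir, prefix = "map") {
  stopifnot(inherits(map, "parametric_map"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      abort_io(sprintf("cannot create directory: %s", out_dir))
  if (file.access(out_dir, 2) != 0)
    abort_io(sprintf("directory not writable: %s", out_dir))
  paths <- file.path(out_dir, map_file_names(prefix))
  names(paths) <- c("time", "rate", "amplitude", "rss", "converged_mask")
  write_nifti_volume(map$time, paths["time"], map$voxel_size_mm)
  write_nifti_volume(map$rate, paths["rate"], map$voxel_size_mm)
  write_nifti_volume(map$amplitude, paths["amplitude"], map$voxel_size_mm)
  write_nifti_volume(map$rss, paths["rss"], map$voxel_size_mm)
  write_nifti_volume(array(as.integer(map$converged), dim(map$converged)),
                     paths["converged_mask"], map$voxel_size_mm,
                     datatype = "uint8")
  invisible(paths)
}

#' @rdname save_parametric_map
#' @param dir Directory holding a saved bundle.
#' @export
load_parametric_map <- function(dir, prefix = "map") {
  paths <- file.path(dir, map_file_names(prefix))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    abort_io(paste("missing map files:", paste(missing, collapse = ", ")))
  time <- read_nifti_volume(paths[1])
  parametric_map(time = time$data,
                 amplitude = read_nifti_volume(paths[3])$data,
                 rss = read_nifti_volume(paths[4])$data,
                 converged = read_nifti_volume(paths[5])$data != 0,
                 voxel_size_mm = time$voxel_size_mm)
}
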