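#' Image series
#'
#' A magnitude image stack on a fixed spatial grid whose 4th axis is the
#' acquisition frame: one frame per echo time, per flip angle, or per
#' dynamic timepoint.
#'
#' @param data 3-D or 4-D non-negative array; a 3-D array is treated as a
#'   single frame.
#' @param protocol The [acquisition_protocol()] that produced the stack.
#' @param frame_axis `"echo"`, `"flip_angle"`, `"dynamic"`, or `"auto"`
#'   (derive from the protocol's sequence kind).
#' @return An object of class `image_series` with elements `data`
#'   (4-D array), `protocol` and `frame_axis`.
#' @export
image_series <- function(data, protocol,
                         frame_axis = c("auto", "echo", "flip_angle", "dynamic")) {
  frame_axis <- match.arg(frame_axis)
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (!is.array(data)) abort_validation("data must be an array")
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    abort_validation("data must have 3 or 4 dimensions")
  if (anyNA(data) || any(data < 0))
    abort_validation("magnitude intensities must be non-negative and finite")
  if (frame_axis == "auto") {
    frame_axis <- if (protocol$sequence_kind == "vfa_spgr") "flip_angle" else "echo"
  }
  n_frames <- dim(data)[4L]
  expected <- switch(frame_axis,
                     echo = length(protocol$echo_times_ms),
                     flip_angle = length(protocol$flip_angles_deg),
                     dynamic = n_frames)
  if (n_frames != expected)
    abort_protocol(sprintf(
      "frame count mismatch: series has %d frames but the protocol lists %d %s values",
      n_frames, expected, sub("_", " ", frame_axis)))
  if (!all(dim(data)[1:3] == protocol$matrix_shape))
    abort_protocol(sprintf(
      "spatial grid %s does not match the protocol matrix %s",
      paste(dim(data)[1:3], collapse = "x"),
      paste(protocol$matrix_shape, collapse = "x")))
  structure(list(data = data, protocol = protocol, frame_axis = frame_axis),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series> %dx%dx%d, %d frame(s) [%s], %s\n",
              d[1], d[2], d[3], d[4], x$frame_axis,
              x$protocol$sequence_kind))
  invisible(x)
}

n_frames <- function(series) dim(series$data)[4L]

# NIfTI-1 stores singleton trailing dimensions ambiguously (a one-slice
# volume reads back as 2-D and a naive write drops its slice thickness),
# so all package I/O goes through these helpers: writes carry an explicit
# dim/pixdim header, reads recover the geometry from the header and
# return a plain array.
write_nifti_volume <- function(arr, path, voxel_size_mm,
                               datatype = "double") {
  d <- dim(arr)
  hdr <- list(dim = c(length(d), d, rep(1L, 7L - length(d))),
              pixdim = c(-1, voxel_size_mm, rep(1, 4))[1:8])
  img <- RNifti::asNifti(arr, reference = RNifti::niftiHeader(hdr))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_nifti_volume <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("NIfTI file not found: %s", path))
  hdr <- RNifti::niftiHeader(path)
  stored <- hdr$dim[-1L]
  if (any(stored[5:7] > 1))
    abort_validation(sprintf("expected a 3-D or 4-D NIfTI, got %d dimensions",
                             max(which(stored > 1))))
  nd <- max(3L, hdr$dim[1L])
  dims <- pmax(stored[seq_len(nd)], 1L)
  vox <- hdr$pixdim[2:4]
  vox[!is.finite(vox) | vox <= 0] <- 1
  arr <- as.array(RNifti::readNifti(path))
  list(data = array(as.vector(arr), dims), voxel_size_mm = vox)
}

#' Load an image series from NIfTI plus a protocol sidecar
#'
#' Reads a 3-D or 4-D NIfTI-1 volume, pairs it with its YAML protocol
#' sidecar, and cross-checks frame count and voxel size. The 4th NIfTI
#' dimension is the frame axis and its order must match the sidecar's
#' echo-time / flip-angle list order.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param sidecar YAML sidecar path (see [read_protocol()]).
#' @param frame_axis Frame-axis meaning, `"auto"` by default.
#' @return An [image_series()].
#' @export
load_image_series <- function(path, sidecar,
                              frame_axis = c("auto", "echo", "flip_angle", "dynamic")) {
  frame_axis <- match.arg(frame_axis)
  protocol <- read_protocol(sidecar)
  vol <- read_nifti_volume(path)
  arr <- vol$data
  vox <- vol$voxel_size_mm
  if (any(abs(vox - protocol$voxel_size_mm) > 1e-3))
    abort_protocol(sprintf(
      "voxel size mismatch: NIfTI header says %s mm, sidecar says %s mm",
      paste(signif(vox, 4), collapse = "x"),
      paste(protocol$voxel_size_mm, collapse = "x")))
  if (any(dim(arr)[1:3] != protocol$matrix_shape))
    protocol$matrix_shape <- as.integer(dim(arr)[1:3])
  if (any(arr < 0))
    abort_validation("negative intensities found; magnitude images expected")
  image_series(arr, protocol, frame_axis)
}

#' Save an image series as NIfTI plus its sidecar
#'
#' @param series An [image_series()].
#' @param path Output NIfTI path.
#' @param sidecar Output sidecar path; defaults to `path` with a
#'   `.yaml` extension.
#' @return Named character vector of the files written, invisibly.
#' @export
save_image_series <- function(series, path, sidecar = NULL) {
  stopifnot(inherits(series, "image_series"))
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".yaml")
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    abort_io(sprintf("directory not writable: %s", dir))
  write_nifti_volume(series$data, path, series$protocol$voxel_size_mm)
  write_protocol(series$protocol, sidecar)
  invisible(c(nifti = path, sidecar = sidecar))
}

#' Load a binary mask on the grid of a reference series
#'
#' @param path NIfTI mask path; any non-zero voxel is inside the mask.
#' @param reference An [image_series()] (or `parametric_map`) defining the
#'   expected spatial grid.
#' @return A logical 3-D array with at least one `TRUE` voxel.
#' @export
load_mask <- function(path, reference) {
  if (!file.exists(path)) abort_io(sprintf("mask file not found: %s", path))
  arr <- read_nifti_volume(path)$data
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) dim(arr) <- dim(arr)[1:3]
  ref_dim <- if (inherits(reference, "image_series")) dim(reference$data)[1:3]
             else if (inherits(reference, "parametric_map")) dim(reference$time)
             else dim(reference)[1:3]
  if (length(dim(arr)) != 3L || any(dim(arr) != ref_dim))
    abort_validation(sprintf(
      "mask grid %s does not match reference grid %s",
      paste(dim(arr), collapse = "x"), paste(ref_dim, collapse = "x")))
  mask <- arr != 0
  if (!any(mask)) abort_o17("mask contains no voxels", "o17_empty_mask_error")
  mask
}
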