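#' Automatic circular vial ROI detection
#'
#' Detects the vials of a cylindrical calibration phantom on the central
#' slice of the first frame: Otsu foreground thresholding, connected-
#' component labelling, a circularity filter
#' (`4 * pi * area / perimeter^2 > 0.7`) plus a minimum-area filter, and
#' a disc ROI of the target area centred at each component centroid.
#' The ROI voxel count is `round(target_area_mm2 / in-plane voxel
#' area)`; the disc is the set of that many voxels nearest the centroid.
#' ROIs are replicated on the centred 5 slices (or all slices when the
#' volume has fewer).
#'
#' @param series An [image_series()] with vial contrast against the
#'   background.
#' @param layout Optional [make_phantom_layout()] hint; when given, each
#'   ROI is matched to the nearest hole centre and labelled with its
#'   vial id and concentration, and a count mismatch raises a warning
#'   with a partial result.
#' @param target_area_mm2 ROI area per slice (mm^2), default 118.
#' @param frame Frame used for detection (default 1, the highest-signal
#'   echo).
#' @param n_slices ROI slice extent (default 5, clipped to the volume).
#' @return List of `vial_roi` objects: `center` (voxel coordinates),
#'   `voxels` (two-column in-plane index matrix), `slice_indices`,
#'   `radius_voxels`, `area_mm2`, `vial_id`, `concentration`.
#' @export
detect_vial_rois <- function(series, layout = NULL, target_area_mm2 = 118,
                             frame = 1L, n_slices = 5L) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$data)
  mid <- ceiling(d[3] / 2)
  img <- series$data[, , mid, frame]
  mx <- max(img)
  if (mx <= 0)
    abort_o17("no vials detected: image has no signal", "o17_detection_error")
  norm <- EBImage::Image(img / mx)
  th <- EBImage::otsu(norm)
  lab <- EBImage::bwlabel(norm > th)
  nobj <- max(lab)
  if (nobj == 0)
    abort_o17("no vials detected above threshold", "o17_detection_error")
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  vx <- series$protocol$voxel_size_mm
  vox_area <- vx[1] * vx[2]
  n_vox <- round(target_area_mm2 / vox_area)
  circ <- 4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1)^2
  keep <- which(circ > 0.7 & shp[, "s.area"] >= n_vox / 2)
  if (!length(keep))
    abort_o17("no components passed the circularity filter",
              "o17_detection_error")

  slices <- if (d[3] <= n_slices) seq_len(d[3]) else {
    half <- (n_slices - 1) %/% 2
    (mid - half):(mid - half + n_slices - 1)
  }

  # disc of exactly n_vox voxels nearest the centroid, ties by index order
  grid <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  rois <- lapply(keep, function(k) {
    cx <- mom[k, "m.cx"]; cy <- mom[k, "m.cy"]
    dist2 <- ((grid$i - cx) * vx[1])^2 + ((grid$j - cy) * vx[2])^2
    sel <- order(dist2)[seq_len(n_vox)]
    structure(list(center = c(cx, cy),
                   voxels = cbind(i = grid$i[sel], j = grid$j[sel]),
                   slice_indices = slices,
                   radius_voxels = sqrt(n_vox / pi),
                   area_mm2 = n_vox * vox_area,
                   vial_id = NA_integer_,
                   concentration = NA_real_),
              class = "vial_roi")
  })

  if (!is.null(layout)) {
    rois <- match_rois_to_layout(rois, layout, series$protocol)
    expected <- nrow(layout$assignments)
    if (length(rois) != expected)
      warn_o17(sprintf(
        "detected %d vial(s) but the layout lists %d; returning the partial match",
        length(rois), expected))
  }
  rois
}

match_rois_to_layout <- function(rois, layout, protocol) {
  vx <- protocol$voxel_size_mm
  shp <- protocol$matrix_shape
  to_mm <- function(center)
    c((center[1] - (shp[1] + 1) / 2) * vx[1],
      (center[2] - (shp[2] + 1) / 2) * vx[2])
  holes <- as.matrix(layout$assignments[, c("x_mm", "y_mm")])
  for (k in seq_along(rois)) {
    mm <- to_mm(rois[[k]]$center)
    dd <- sqrt((holes[, 1] - mm[1])^2 + (holes[, 2] - mm[2])^2)
    best <- which.min(dd)
    if (dd[best] > layout$geometry$vial_radius_mm)
      abort_o17(sprintf(
        "ROI at (%.1f, %.1f) mm is %.1f mm from the nearest layout hole",
        mm[1], mm[2], dd[best]), "o17_pairing_error")
    rois[[k]]$vial_id <- layout$assignments$hole[best]
    rois[[k]]$concentration <- layout$assignments$concentration[best]
  }
  ids <- vapply(rois, function(r) r$vial_id, integer(1))
  if (anyDuplicated(ids))
    warn_o17("two detected components matched the same layout hole")
  rois
}

roi_values <- function(map_array, roi) {
  vals <- lapply(roi$slice_indices, function(s)
    map_array[cbind(roi$voxels, s)])
  unlist(vals, use.names = FALSE)
}

#' Per-vial rate statistics pooled over repeats
#'
#' For every ROI, pools the converged voxel-wise relaxation rates across
#' all repeated acquisitions and reports the median and interquartile
#' range. Quartiles use linear interpolation
#' (`stats::quantile(type = 7)`).
#'
#' @param maps A [parametric_map()] or a list of them (one per repeat,
#'   all on one grid).
#' @param rois ROIs from [detect_vial_rois()], matched to a layout
#'   (non-`NA` `vial_id`).
#' @param layout The [make_phantom_layout()] the ROIs were matched to.
#' @return A data frame of class `vial_stats` with columns `vial_id`,
#'   `concentration`, `control`, `median_rate`, `iqr_rate`, `n_voxels`,
#'   `n_repeats`.
#' @export
summarize_vials <- function(maps, rois, layout) {
  if (inherits(maps, "parametric_map")) maps <- list(maps)
  unmatched <- which(vapply(rois, function(r) is.na(r$vial_id), logical(1)))
  if (length(unmatched))
    abort_o17(paste("ROI(s) not matched to a layout vial:",
                    paste(unmatched, collapse = ", ")), "o17_pairing_error")
  rows <- lapply(rois, function(roi) {
    pooled <- unlist(lapply(maps, function(m) {
      v <- roi_values(m$rate, roi)
      v[is.finite(v)]
    }), use.names = FALSE)
    if (!length(pooled))
      abort_numerical(sprintf("vial %d has no converged voxels", roi$vial_id))
    q <- stats::quantile(pooled, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(vial_id = roi$vial_id,
               concentration = roi$concentration,
               control = layout$assignments$control[
                 match(roi$vial_id, layout$assignments$hole)],
               median_rate = q[2],
               iqr_rate = q[3] - q[1],
               n_voxels = length(pooled),
               n_repeats = length(maps))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$concentration, out$vial_id), ]
  rownames(out) <- NULL
  class(out) <- c("vial_stats", "data.frame")
  out
}
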