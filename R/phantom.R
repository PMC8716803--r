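#' Ground-truth parameter maps for the simulators
#'
#' Voxel-wise true relaxation times, amplitude and tracer concentration on
#' a fixed spatial grid. The transverse ordering `T2* <= T2 <= T1` is
#' enforced voxel-wise wherever the object contains signal.
#'
#' @param true_t1,true_t2,true_t2star 3-D arrays of relaxation times (ms).
#' @param true_amplitude 3-D array of signal amplitudes (0 outside
#'   objects).
#' @param concentration 3-D array of H2-17O concentration in mole-percent
#'   of water molecules (0 outside objects).
#' @return An object of class `ground_truth_maps`.
#' @export
ground_truth_maps <- function(true_t1, true_t2, true_t2star,
                              true_amplitude, concentration) {
  dims <- dim(true_amplitude)
  for (a in list(true_t1, true_t2, true_t2star, concentration))
    if (!is.array(a) || !all(dim(a) == dims))
      abort_validation("all ground-truth maps must share one spatial grid")
  inside <- true_amplitude > 0
  if (any(true_t2star[inside] > true_t2[inside] + 1e-9) ||
      any(true_t2[inside] > true_t1[inside] + 1e-9))
    abort_validation("ground truth must satisfy T2* <= T2 <= T1 voxel-wise")
  if (any(concentration < 0))
    abort_validation("concentrations must be non-negative")
  structure(list(true_t1 = true_t1, true_t2 = true_t2,
                 true_t2star = true_t2star,
                 true_amplitude = true_amplitude,
                 concentration = concentration),
            class = "ground_truth_maps")
}

#' The canonical vial concentration set
#'
#' The 19 H2-17O concentrations (mole-percent) of the calibration vial
#' battery, from the 0.037% natural abundance of ordinary water up to
#' 6.5%.
#'
#' @return Numeric vector of 19 concentrations (%).
#' @export
canonical_concentrations <- function() {
  c(0.037, 0.043, 0.045, 0.050, 0.074, 0.093, 0.145, 0.245, 0.491,
    0.881, 1.270, 1.603, 2.0, 2.5, 3.1, 3.8, 4.6, 5.5, 6.5)
}

#' Phantom geometry template
#'
#' A cylindrical holder with 13 holes on a fixed template: one central
#' hole, an inner ring of 4 and an outer ring of 8. Hole order is
#' centre, inner ring (counter-clockwise from 45 degrees), outer ring
#' (counter-clockwise from 0 degrees); positions are mm offsets from the
#' image centre.
#'
#' @param cylinder_radius_mm Holder radius (mm).
#' @param vial_radius_mm Liquid radius of one 50-mL vial (mm).
#' @param inner_ring_mm,outer_ring_mm Ring radii (mm).
#' @return List with `hole_positions` (13 x 2 matrix, mm),
#'   `cylinder_radius_mm` and `vial_radius_mm`.
#' @export
phantom_geometry <- function(cylinder_radius_mm = 70, vial_radius_mm = 12,
                             inner_ring_mm = 26, outer_ring_mm = 55) {
  ang_in <- (c(45, 135, 225, 315)) * pi / 180
  ang_out <- (seq(0, 315, by = 45)) * pi / 180
  holes <- rbind(
    c(0, 0),
    cbind(inner_ring_mm * cos(ang_in), inner_ring_mm * sin(ang_in)),
    cbind(outer_ring_mm * cos(ang_out), outer_ring_mm * sin(ang_out))
  )
  if (outer_ring_mm + vial_radius_mm > cylinder_radius_mm)
    abort_validation("outer ring vials do not fit inside the cylinder")
  d <- as.matrix(stats::dist(holes))
  diag(d) <- Inf
  if (min(d) < 2 * vial_radius_mm)
    abort_validation("vials overlap on this template")
  list(hole_positions = holes,
       cylinder_radius_mm = cylinder_radius_mm,
       vial_radius_mm = vial_radius_mm)
}

#' Build a phantom layout
#'
#' Assigns vials to the 13-hole template: three control vials of plain
#' saline at natural abundance (0.037%) always occupy the first three
#' holes, and up to 10 experimental concentrations fill the following
#' holes in the order given.
#'
#' @param concentration_subset Experimental concentrations (%), at most
#'   10. Values outside [canonical_concentrations()] are allowed but
#'   flagged with a warning.
#' @param geometry A [phantom_geometry()].
#' @param control_concentration Control vial concentration (%), default
#'   natural abundance.
#' @return An object of class `phantom_layout` with a data-frame
#'   `assignments` (hole, concentration, control flag, x/y in mm) and the
#'   geometry.
#' @export
make_phantom_layout <- function(concentration_subset = numeric(),
                                geometry = phantom_geometry(),
                                control_concentration = 0.037) {
  concentration_subset <- as.numeric(concentration_subset)
  if (length(concentration_subset) > 10L)
    abort_o17(sprintf(
      "capacity exceeded: %d experimental concentrations but only 10 free holes",
      length(concentration_subset)), "o17_capacity_error")
  if (any(concentration_subset < 0))
    abort_validation("concentrations must be non-negative")
  canon <- canonical_concentrations()
  off <- concentration_subset[!vapply(concentration_subset, function(c)
    any(abs(c - canon) < 1e-9), logical(1))]
  if (length(off))
    warn_o17(paste("concentration(s) outside the canonical set:",
                   paste(off, collapse = ", ")))
  n <- 3L + length(concentration_subset)
  holes <- seq_len(n)
  conc <- c(rep(control_concentration, 3L), concentration_subset)
  assignments <- data.frame(
    hole = holes,
    concentration = conc,
    control = c(rep(TRUE, 3L), rep(FALSE, length(concentration_subset))),
    x_mm = geometry$hole_positions[holes, 1L],
    y_mm = geometry$hole_positions[holes, 2L]
  )
  structure(list(assignments = assignments, geometry = geometry),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("<phantom_layout> %d vials (%d controls)\n",
              nrow(x$assignments), sum(x$assignments$control)))
  print(x$assignments, row.names = FALSE)
  invisible(x)
}

#' The default two-phantom split of the canonical set
#'
#' Nineteen vials exceed the 13 holes of one holder, so the experimental
#' concentrations are split over two layouts (both carrying the three
#' natural-abundance controls). The 18 above-abundance values are
#' interleaved so each phantom spans the full range.
#'
#' @param geometry A [phantom_geometry()].
#' @return List of two [make_phantom_layout()] objects.
#' @export
default_layout_pair <- function(geometry = phantom_geometry()) {
  experimental <- setdiff(canonical_concentrations(), 0.037)
  idx <- seq_along(experimental)
  list(
    make_phantom_layout(experimental[idx %% 2L == 1L], geometry),
    make_phantom_layout(experimental[idx %% 2L == 0L], geometry)
  )
}

#' Forward truth model: relaxation times from concentration
#'
#' The simulation ground truth. R2 rises linearly with H2-17O
#' concentration, `R2 = slope * C + intercept` (s^-1), so
#' `T2 = 1000 / R2` ms. T1 is concentration-independent (saline-like
#' 3000 ms by default) and T2* is a fixed fraction of T2, matching the
#' null findings for R1 and R2*.
#'
#' @param concentration Concentration(s) in %, >= 0.
#' @param tissue List of forward-model constants: `r2_slope` (s^-1 per
#'   %), `r2_intercept` (s^-1), `t1_ms`, `t2star_fraction`.
#' @return Data frame with columns `concentration`, `true_t1`, `true_t2`,
#'   `true_t2star` (ms).
#' @export
true_relaxation_from_concentration <- function(concentration,
                                               tissue = tissue_defaults()) {
  if (any(concentration < 0)) abort_validation("concentration must be >= 0")
  # pure linear response; T2 < T1 holds for every concentration at or
  # above natural abundance with the default constants
  r2 <- tissue$r2_slope * concentration + tissue$r2_intercept
  t2 <- 1000 / r2
  data.frame(concentration = concentration,
             true_t1 = rep(tissue$t1_ms, length(concentration)),
             true_t2 = t2,
             true_t2star = t2 * tissue$t2star_fraction)
}

#' @rdname true_relaxation_from_concentration
#' @export
tissue_defaults <- function() {
  list(r2_slope = 0.405, r2_intercept = 0.3215,
       t1_ms = 3000, t2star_fraction = 0.8)
}

#' Render ground-truth maps for a phantom layout
#'
#' Rasterizes the vial layout onto the protocol grid by nearest-voxel
#' assignment: a voxel belongs to a vial when its in-plane centre lies
#' within the vial radius of the hole centre. Signal amplitude is uniform
#' inside vials and zero elsewhere (the holder material is proton-free).
#'
#' @param layout A [make_phantom_layout()] object.
#' @param protocol An [acquisition_protocol()] defining grid and voxel
#'   size.
#' @param amplitude Signal amplitude inside vials.
#' @param tissue Forward-model constants, see
#'   [true_relaxation_from_concentration()].
#' @return A [ground_truth_maps()] object.
#' @export
phantom_truth_maps <- function(layout, protocol, amplitude = 1000,
                               tissue = tissue_defaults()) {
  stopifnot(inherits(layout, "phantom_layout"))
  shp <- protocol$matrix_shape
  vx <- protocol$voxel_size_mm
  xs <- (seq_len(shp[1]) - (shp[1] + 1) / 2) * vx[1]
  ys <- (seq_len(shp[2]) - (shp[2] + 1) / 2) * vx[2]
  conc2d <- matrix(0, shp[1], shp[2])
  amp2d <- matrix(0, shp[1], shp[2])
  r2 <- layout$geometry$vial_radius_mm^2
  for (i in seq_len(nrow(layout$assignments))) {
    cx <- layout$assignments$x_mm[i]
    cy <- layout$assignments$y_mm[i]
    inside <- outer(xs, ys, function(x, y) (x - cx)^2 + (y - cy)^2 <= r2)
    conc2d[inside] <- layout$assignments$concentration[i]
    amp2d[inside] <- amplitude
  }
  conc <- array(rep(conc2d, shp[3]), shp)
  amp <- array(rep(amp2d, shp[3]), shp)
  rel <- true_relaxation_from_concentration(as.vector(conc), tissue)
  mk <- function(v) array(v, shp)
  t1 <- mk(rel$true_t1); t2 <- mk(rel$true_t2); t2s <- mk(rel$true_t2star)
  # background voxels carry no signal; park their times at the saline T1
  t2[amp == 0] <- tissue$t1_ms; t2s[amp == 0] <- tissue$t1_ms
  ground_truth_maps(t1, t2, t2s, amp, conc)
}
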