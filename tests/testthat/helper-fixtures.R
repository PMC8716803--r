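# Small in-code fixtures shared across the suite.

# uniform-parameter ground truth on a small grid
uniform_truth <- function(shape = c(4L, 4L, 1L), t1 = 3000, t2 = 50,
                          t2star = 40, amplitude = 1000, concentration = 0) {
  mk <- function(v) array(v, shape)
  ground_truth_maps(mk(t1), mk(t2), mk(t2star), mk(amplitude),
                    mk(concentration))
}

# a converged parametric map with the given rate everywhere
flat_rate_map <- function(rate, shape = c(4L, 4L, 1L),
                          voxel_size = c(1.67, 1.67, 5)) {
  time <- array(1000 / rate, shape)
  parametric_map(time, array(1000, shape), array(0, shape),
                 array(TRUE, shape), voxel_size)
}

# a hand-built ROI over explicit voxels, matched to a one-vial layout
manual_roi <- function(voxels, vial_id = 1L, concentration = 0.037,
                       slice_indices = 1L) {
  structure(list(center = colMeans(voxels),
                 voxels = voxels,
                 slice_indices = slice_indices,
                 radius_voxels = sqrt(nrow(voxels) / pi),
                 area_mm2 = nrow(voxels) * 1.67^2,
                 vial_id = as.integer(vial_id),
                 concentration = concentration),
            class = "vial_roi")
}

# grid-search oracle for the mono-exponential fit: profiled amplitude,
# exhaustive search over relaxation times
grid_oracle_monoexp <- function(y, te, t_grid) {
  best <- list(rss = Inf)
  for (tt in t_grid) {
    e <- exp(-te / tt)
    k <- sum(y * e) / sum(e * e)
    rss <- sum((k * e - y)^2)
    if (rss < best$rss) best <- list(t = tt, k = k, rss = rss)
  }
  best
}

# same oracle for the variable-flip-angle model
grid_oracle_vfa <- function(y, th_deg, tr, t_grid) {
  th <- th_deg * pi / 180
  best <- list(rss = Inf)
  for (tt in t_grid) {
    e <- exp(-tr / tt)
    g <- sin(th) * (1 - e) / (1 - cos(th) * e)
    m0 <- sum(y * g) / sum(g * g)
    rss <- sum((m0 * g - y)^2)
    if (rss < best$rss) best <- list(t = tt, m0 = m0, rss = rss)
  }
  best
}

# wrap a single voxel's echo train as a fittable series
single_voxel_series <- function(y, protocol) {
  image_series(array(y, c(1L, 1L, 1L, length(y))),
               modify_shape(protocol, c(1L, 1L, 1L)))
}

modify_shape <- function(protocol, shape) {
  protocol$matrix_shape <- as.integer(shape)
  protocol
}
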