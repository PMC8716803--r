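make_detected_phantom <- function(seed = 5) {
  lay <- make_phantom_layout(canonical_concentrations()[9:18])
  pr <- tse_protocol()
  truth <- phantom_truth_maps(lay, pr)
  clean <- simulate_multiecho_series(truth, pr)
  noisy <- add_rician_noise(clean, snr_sigma(clean, 50,
                                             truth$true_amplitude > 0), seed)
  list(layout = lay, protocol = pr, truth = truth, series = noisy)
}

test_that("vial ROIs are detected at the generator's hole centres", {
  ph <- make_detected_phantom()
  rois <- detect_vial_rois(ph$series, ph$layout)
  expect_length(rois, 13L)
  # centres within one voxel of the truth
  vx <- ph$protocol$voxel_size_mm
  for (roi in rois) {
    a <- ph$layout$assignments[ph$layout$assignments$hole == roi$vial_id, ]
    true_center <- c(a$x_mm / vx[1] + 48.5, a$y_mm / vx[2] + 48.5)
    expect_lt(sqrt(sum((roi$center - true_center)^2)), 1)
  }
  # every ROI has round(118 / (1.67 * 1.67)) = 42 voxels per slice and
  # conserves the target area to within one voxel-area
  for (roi in rois) {
    expect_equal(nrow(roi$voxels), 42L)
    expect_lt(abs(roi$area_mm2 - 118), 1.67^2)
  }
})

test_that("ROI detection fails cleanly on a signal-free image", {
  pr <- tse_protocol(matrix_shape = c(32L, 32L, 1L))
  noise_only <- image_series(
    add_rician_noise(array(0, c(32, 32, 1, 8)), 5, seed = 1), pr)
  expect_error(detect_vial_rois(noise_only),
               class = "o17_detection_error")
})

test_that("a partial detection against a layout hint warns", {
  # layout claims one more vial than the image contains
  ph <- make_detected_phantom()
  bigger <- make_phantom_layout(canonical_concentrations()[8:18][1:10])
  bigger$assignments <- rbind(
    bigger$assignments,
    data.frame(hole = 14L, concentration = 9.9, control = FALSE,
               x_mm = 0, y_mm = -26))
  expect_warning(detect_vial_rois(ph$series, bigger),
                 class = "o17_warning")
})

test_that("vial summaries use linear-interpolation quartiles", {
  # pooled sample {1, 2, 3, 4, 5}: median 3, IQR 4 - 2 = 2
  shape <- c(5L, 1L, 1L)
  time <- array(1000 / (1:5), shape)
  map <- parametric_map(time, array(1, shape), array(0, shape),
                        array(TRUE, shape), c(1.67, 1.67, 5))
  roi <- manual_roi(cbind(i = 1:5, j = rep(1L, 5)))
  lay <- make_phantom_layout()
  st <- summarize_vials(map, list(roi), lay)
  expect_equal(st$median_rate, 3)
  expect_equal(st$iqr_rate, 2)
  expect_equal(st$n_voxels, 5L)
  # constant field: median equals the value, IQR 0
  map2 <- flat_rate_map(2.0, shape)
  st2 <- summarize_vials(map2, list(roi), lay)
  expect_equal(st2$median_rate, 2)
  expect_equal(st2$iqr_rate, 0)
  # an unmatched ROI is a pairing error
  roi_na <- manual_roi(cbind(i = 1:5, j = rep(1L, 5)), vial_id = NA)
  roi_na$vial_id <- NA_integer_
  expect_error(summarize_vials(map, list(roi_na), lay),
               class = "o17_pairing_error")
})

test_that("per-vial medians pooled over repeats recover the truth", {
  ph <- make_detected_phantom()
  rois <- detect_vial_rois(ph$series, ph$layout)
  clean <- simulate_multiecho_series(ph$truth, ph$protocol)
  sigma <- snr_sigma(clean, 50, ph$truth$true_amplitude > 0)
  maps <- lapply(1:3, function(r)
    fit_monoexp(add_rician_noise(clean, sigma, seed = 300 + r)))
  st <- summarize_vials(maps, rois, ph$layout)
  expect_equal(unique(st$n_repeats), 3L)
  truth_r2 <- 0.405 * st$concentration + 0.3215
  expect_true(all(abs(st$median_rate - truth_r2) < 0.06))
})

test_that("Spearman correlation handles monotone, antitone and tied data", {
  st <- data.frame(concentration = c(0.25, 0.5, 1, 2, 4),
                   median_rate = c(0.4, 0.5, 0.7, 1.1, 1.9))
  expect_equal(spearman_vs_concentration(st)$rho, 1)
  st$median_rate <- rev(st$median_rate)
  expect_equal(spearman_vs_concentration(st)$rho, -1)
  # tie-free permutation against the closed-form rank formula
  withr::with_seed(8, {
    x <- sample(1:10); y <- sample(1:10)
  })
  st2 <- data.frame(concentration = x, median_rate = y)
  d <- rank(x) - rank(y)
  rho_formula <- 1 - 6 * sum(d^2) / (10 * (10^2 - 1))
  expect_equal(spearman_vs_concentration(st2)$rho, rho_formula,
               tolerance = 1e-12)
  # degenerate input
  st3 <- data.frame(concentration = rep(1, 5), median_rate = 1:5)
  expect_error(spearman_vs_concentration(st3),
               class = "o17_undefined_correlation_error")
  expect_error(spearman_vs_concentration(st[1:3, ]),
               class = "o17_validation_error")
})

test_that("normality test is calibrated under the null and powered", {
  # fraction of null samples passing at alpha = 0.05
  ps <- withr::with_seed(12, vapply(1:100, function(i)
    normality_test(rnorm(500))$p_value, numeric(1)))
  expect_gte(mean(ps > 0.05), 0.90)
  # strong log-normal alternative
  p_ln <- withr::with_seed(13, normality_test(exp(rnorm(500, sd = 1)))$p_value)
  expect_lt(p_ln, 0.001)
  expect_error(normality_test(c(1, 2)), class = "o17_validation_error")
  expect_error(normality_test(rnorm(6000)), class = "o17_validation_error")
})

test_that("Games-Howell flags separated groups and spares null pairs", {
  withr::with_seed(14, {
    null_groups <- list(a = rnorm(200, 2, 0.1), b = rnorm(200, 2, 0.1))
    gh_null <- games_howell_pairwise(null_groups)
    expect_gt(gh_null$p_adj, 0.2)
    # the phantom contrast between high concentrations: 2.0 vs 2.6 s^-1
    sep <- list(low = rnorm(30, 2.0, 0.1), high = rnorm(30, 2.6, 0.1))
    expect_lt(games_howell_pairwise(sep)$p_adj, 0.001)
  })
  # zero-variance conventions
  gh_eq <- games_howell_pairwise(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_equal(gh_eq$p_adj, 1)
  gh_ne <- games_howell_pairwise(list(a = c(1, 1, 1), b = c(2, 2, 2)))
  expect_equal(gh_ne$p_adj, 0)
  expect_error(games_howell_pairwise(list(a = 1:3)),
               class = "o17_validation_error")
  expect_error(games_howell_pairwise(list(a = 1:3, b = 2)),
               class = "o17_validation_error")
})

test_that("Games-Howell agrees with a permutation reference", {
  # adjusted p for pair (i, j) referenced to the permutation null of the
  # maximum pairwise statistic (the family-wise analogue of the
  # studentized-range tail)
  perm_reference <- function(groups, n_perm = 3000) {
    q_of <- function(gs) {
      k <- length(gs)
      n <- lengths(gs); m <- vapply(gs, mean, 1); v <- vapply(gs, stats::var, 1)
      combs <- utils::combn(k, 2)
      apply(combs, 2, function(ij) {
        se2 <- v[ij[1]] / n[ij[1]] + v[ij[2]] / n[ij[2]]
        abs(m[ij[1]] - m[ij[2]]) * sqrt(2) / sqrt(se2)
      })
    }
    q_obs <- q_of(groups)
    pooled <- unlist(groups)
    sizes <- lengths(groups)
    null_max <- replicate(n_perm, {
      shuffled <- sample(pooled)
      gs <- split(shuffled, rep(seq_along(sizes), sizes))
      max(q_of(gs))
    })
    vapply(q_obs, function(q) mean(null_max >= q), numeric(1))
  }
  groups <- withr::with_seed(15, list(a = rnorm(40, 0, 1),
                                      b = rnorm(40, 0.02, 1),
                                      c = rnorm(40, 8, 1)))
  gh <- games_howell_pairwise(groups)
  p_perm <- withr::with_seed(16, perm_reference(groups))
  expect_true(all(abs(gh$p_adj - p_perm) < 0.01))
})

test_that("calibration OLS recovers the printed line from exact points", {
  conc <- canonical_concentrations()
  in_range <- conc[conc >= 0.245 & conc <= 5.5]
  expect_length(in_range, 11L)
  st <- data.frame(concentration = conc,
                   median_rate = 0.405 * conc + 0.3215)
  cal <- fit_calibration(st)
  expect_equal(cal$slope, 0.405, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.3215, tolerance = 1e-12)
  expect_equal(cal$n_points, 11L)
  expect_equal(cal$r_spearman, 1)
  # two in-range points: exact interpolating line (wide range)
  st2 <- data.frame(concentration = c(0.5, 1.5, 4),
                    median_rate = c(0.6, 1.0, 2.0))
  cal2 <- fit_calibration(st2, fit_range = c(0.4, 2))
  expect_equal(cal2$n_points, 2L)
  expect_equal(cal2$slope, (1.0 - 0.6) / (1.5 - 0.5), tolerance = 1e-12)
  expect_equal(cal2$intercept, 0.6 - cal2$slope * 0.5, tolerance = 1e-12)
})

test_that("calibration OLS equals the normal-equations oracle", {
  withr::with_seed(18, {
    x <- runif(10, 0.3, 5); y <- 0.4 * x + 0.3 + rnorm(10, 0, 0.05)
  })
  st <- data.frame(concentration = x, median_rate = y)
  cal <- fit_calibration(st, fit_range = c(0, 6))
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(cal$intercept, beta[1], tolerance = 1e-10)
  expect_equal(cal$slope, beta[2], tolerance = 1e-10)
  # too few in-range vials
  expect_error(fit_calibration(st, fit_range = c(4.9, 5.0)),
               class = "o17_insufficient_data_error")
})

test_that("calibration inversion is exact and flags extrapolation", {
  st <- data.frame(concentration = canonical_concentrations(),
                   median_rate = 0.405 * canonical_concentrations() + 0.3215)
  cal <- fit_calibration(st)
  # R2 = 2.549 s^-1 inverts to 5.5 %
  est <- estimate_concentration(2.549, cal)
  expect_equal(est$concentration, 5.5, tolerance = 1e-9)
  expect_false(est$out_of_range)
  # the intercept inverts to 0 %, outside the fit range
  est0 <- estimate_concentration(0.3215, cal)
  expect_equal(est0$concentration, 0, tolerance = 1e-9)
  expect_true(est0$out_of_range)
  # forward-then-invert identity on random in-range concentrations
  cs <- withr::with_seed(19, runif(100, 0.245, 5.5))
  back <- estimate_concentration(0.405 * cs + 0.3215, cal)
  expect_equal(back$concentration, cs, tolerance = 1e-9)
  expect_false(any(back$out_of_range))
  # degenerate slope
  flat <- cal; flat$slope <- 0
  expect_error(estimate_concentration(1, flat),
               class = "o17_inversion_error")
})
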