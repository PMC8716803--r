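test_that("noiseless simulate-fit round trip is an identity for T1, T2, T2*", {
  shape <- c(6L, 6L, 1L)
  t2 <- array(seq(300, 500, length.out = 36), shape)
  truth <- ground_truth_maps(array(3000, shape), t2, t2 * 0.8,
                             array(1000, shape), array(0, shape))
  # T2 on the 8-echo TSE timing
  m2 <- fit_monoexp(simulate_multiecho_series(
    truth, tse_protocol(matrix_shape = shape)))
  expect_true(all(m2$converged))
  expect_lt(max(abs(m2$time - t2) / t2), 1e-6)
  # T2* on the 12-echo gradient-echo timing
  t2s_truth <- ground_truth_maps(array(3000, shape),
                                 array(60, shape), array(48, shape),
                                 array(1000, shape), array(0, shape))
  m2s <- fit_monoexp(simulate_multiecho_series(
    t2s_truth, gre_t2star_protocol(matrix_shape = shape), decay = "t2star"))
  expect_lt(max(abs(m2s$time - 48) / 48), 1e-6)
  # T1 on the 5-angle VFA timing
  t1 <- array(seq(500, 3000, length.out = 36), shape)
  vtruth <- ground_truth_maps(t1, t1 * 0.5, t1 * 0.4,
                              array(1000, shape), array(0, shape))
  m1 <- fit_t1_vfa(simulate_vfa_series(vtruth,
                                       vfa_protocol(matrix_shape = shape)))
  expect_true(all(m1$converged))
  expect_lt(max(abs(m1$time - t1) / t1), 1e-6)
})

test_that("refined fits match the grid-search oracle", {
  tes <- seq(20, 160, by = 20)
  # noisy mono-exponential voxel
  y <- withr::with_seed(21,
    sqrt((monoexp_signal(1000, 50, tes) + rnorm(8, 0, 20))^2 +
           rnorm(8, 0, 20)^2))
  oracle <- grid_oracle_monoexp(y, tes, seq(10, 200, by = 0.1))
  map <- fit_monoexp(single_voxel_series(y, tse_protocol()),
                     fit_config(min_signal_fraction = 0))
  expect_lte(map$rss[1, 1, 1], oracle$rss + 1e-8)
  expect_lt(abs(map$time[1, 1, 1] - oracle$t), 0.1)
  # noisy VFA voxel against a T1 grid in [10, 5000] ms
  angles <- c(5, 10, 15, 20, 45)
  yv <- withr::with_seed(22,
    sqrt((vfa_signal(1000, 1000, 14, angles) + rnorm(5, 0, 2))^2 +
           rnorm(5, 0, 2)^2))
  vorc <- grid_oracle_vfa(yv, angles, 14, seq(10, 5000, by = 0.1))
  vser <- image_series(array(yv, c(1, 1, 1, 5)),
                       modify_shape(vfa_protocol(), c(1L, 1L, 1L)))
  vmap <- fit_t1_vfa(vser, fit_config(min_signal_fraction = 0))
  expect_lte(vmap$rss[1, 1, 1], vorc$rss + 1e-8)
  expect_lt(abs(vmap$time[1, 1, 1] - vorc$t), 0.1)
})

test_that("refined fit agrees with an independent per-voxel optimizer", {
  skip_if_not_installed("minpack.lm")
  tes <- seq(20, 160, by = 20)
  y <- withr::with_seed(31,
    sqrt((monoexp_signal(800, 400, tes) + rnorm(8, 0, 16))^2 +
           rnorm(8, 0, 16)^2))
  ref <- minpack.lm::nlsLM(y ~ k * exp(-tes / tt),
                           start = list(k = max(y), tt = 200),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  map <- fit_monoexp(single_voxel_series(y, tse_protocol()),
                     fit_config(min_signal_fraction = 0))
  expect_equal(map$time[1, 1, 1], unname(coef(ref)["tt"]), tolerance = 1e-5)
  expect_equal(map$amplitude[1, 1, 1], unname(coef(ref)["k"]),
               tolerance = 1e-5)
})

test_that("log-linear start equals the refined estimate on noiseless decay", {
  tes <- seq(20, 160, by = 20)
  y <- monoexp_signal(1000, 50, tes)
  # closed-form log-linear slope
  L <- log(y)
  slope <- sum((tes - mean(tes)) * L) / sum((tes - mean(tes))^2)
  t_loglin <- -1 / slope
  map <- fit_monoexp(single_voxel_series(y, tse_protocol()))
  expect_equal(map$time[1, 1, 1], t_loglin, tolerance = 1e-12)
  expect_equal(map$time[1, 1, 1], 50, tolerance = 1e-12)
  expect_equal(map$rate[1, 1, 1], 20, tolerance = 1e-10)
})

test_that("degenerate voxels are marked non-converged with sentinels", {
  # strictly increasing echo train is non-physical
  y_up <- seq(100, 800, by = 100)
  m_up <- fit_monoexp(single_voxel_series(y_up, tse_protocol()))
  expect_false(m_up$converged[1, 1, 1])
  expect_true(is.nan(m_up$time[1, 1, 1]))
  expect_true(is.nan(m_up$rate[1, 1, 1]))
  # constant signal across flip angles admits no interior T1
  yc <- rep(500, 5)
  mc <- fit_t1_vfa(image_series(array(yc, c(1, 1, 1, 5)),
                                modify_shape(vfa_protocol(), c(1L, 1L, 1L))))
  expect_false(mc$converged[1, 1, 1])
  # background voxels below the signal threshold are skipped
  shape <- c(4L, 4L, 1L)
  t2 <- array(50, shape)
  amp <- array(0, shape); amp[1:2, , ] <- 1000
  truth <- ground_truth_maps(array(3000, shape), t2, t2 * 0.8, amp,
                             array(0, shape))
  m <- fit_monoexp(simulate_multiecho_series(truth,
                                             tse_protocol(matrix_shape = shape)))
  expect_true(all(m$converged[1:2, , ]))
  expect_true(all(!m$converged[3:4, , ]))
  expect_true(all(is.nan(m$time[3:4, , ])))
})

test_that("fitted R2 is nearly unbiased at phantom SNR in the phantom regime", {
  # 10^4 voxels, T2 in the 300-500 ms regime, first-echo SNR 50
  shape <- c(100L, 100L, 1L)
  t2 <- array(rep(seq(300, 500, length.out = 100), each = 100), shape)
  truth <- ground_truth_maps(array(3000, shape), t2, t2 * 0.8,
                             array(1000, shape), array(0, shape))
  pr <- tse_protocol(matrix_shape = shape)
  clean <- simulate_multiecho_series(truth, pr)
  sigma <- snr_sigma(clean, 50)
  noisy <- add_rician_noise(clean, sigma, seed = 99)
  map <- fit_monoexp(noisy)
  r2_true <- 1000 / t2
  bias <- stats::median((map$rate - r2_true)[map$converged] /
                          r2_true[map$converged])
  expect_lt(abs(bias), 0.02)
  expect_gt(mean(map$converged), 0.99)
})

test_that("R1 and R2* per-vial medians show no concentration trend", {
  # negative control: T1 and T2* are simulated concentration-independent,
  # so their rank correlations with concentration are pure null draws;
  # the average |rho| over seeds must stay small while the R2 battery
  # (tested elsewhere) is near 1
  lay <- make_phantom_layout(canonical_concentrations()[9:18])
  truth <- phantom_truth_maps(lay, tse_protocol())
  truth$true_t2star <- array(50, dim(truth$true_t2star))
  gre <- gre_t2star_protocol(matrix_shape = c(96L, 96L, 1L),
                             voxel_size_mm = c(1.67, 1.67, 5))
  vfa <- vfa_protocol(matrix_shape = c(96L, 96L, 1L),
                      voxel_size_mm = c(1.67, 1.67, 5))
  clean_t2s <- simulate_multiecho_series(truth, gre, decay = "t2star")
  clean_t1 <- simulate_vfa_series(truth, vfa)
  sig_t2s <- snr_sigma(clean_t2s, 50, truth$true_amplitude > 0)
  sig_t1 <- snr_sigma(clean_t1, 50, truth$true_amplitude > 0)
  # pool per-vial medians over repeated acquisitions so the rank
  # correlation is estimated from 13 vials x 10 repeats
  st_t2s <- st_t1 <- list()
  for (s in 1:10) {
    n_t2s <- add_rician_noise(clean_t2s, sig_t2s, seed = 100 + s)
    rois <- detect_vial_rois(n_t2s, lay)
    st_t2s[[s]] <- summarize_vials(fit_monoexp(n_t2s), rois, lay)
    n_t1 <- add_rician_noise(clean_t1, sig_t1, seed = 200 + s)
    st_t1[[s]] <- summarize_vials(fit_t1_vfa(n_t1), rois, lay)
  }
  rho_t2s <- spearman_vs_concentration(do.call(rbind, st_t2s))$rho
  rho_t1 <- spearman_vs_concentration(do.call(rbind, st_t1))$rho
  expect_lt(abs(rho_t2s), 0.3)
  expect_lt(abs(rho_t1), 0.3)
})
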