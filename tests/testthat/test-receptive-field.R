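test_that("sinograms bin flash responses correctly with repeat averaging", {
  geom <- screen_geometry(20, 20, 1, 4)
  flash <- make_bar_flash_protocol(geom, extent_deg = 19.2, n_repeats = 2,
                                   seed = 2)
  # no response anywhere -> zero sinogram
  z <- responses_to_sinogram(rep(0, dim(flash$frames)[1]), flash$events, 4,
                             smooth_s = 0)
  expect_true(all(z$responses == 0))
  expect_equal(dim(z$responses), c(5, 6))

  # repeat averaging: put a known response at each flash of one pair
  fl <- events_of_kind(flash$events, "bar_flash")
  ang <- vapply(fl$payload, function(p) p$angle_deg, 0)
  pos <- vapply(fl$payload, function(p) p$position_deg, 0)
  pick <- which(ang == 36 & abs(pos - 1.6) < 1e-9)
  tr <- rep(0, dim(flash$frames)[1])
  amps <- c(0.6, 1.0)
  for (k in seq_along(pick)) {
    i0 <- floor(fl$time_s[pick[k]] * 4) + 1
    tr[i0 + 1] <- amps[k]
  }
  sg <- responses_to_sinogram(tr, flash$events, 4, smooth_s = 0)
  expect_equal(sg$responses[match(36, sg$angles_deg),
                            match(1.6, sg$positions_deg)],
               mean(amps))

  # missing coverage errors with the gap listed
  half <- flash$events[seq_len(20), ]
  class(half) <- c("event_log", "data.frame")
  expect_error(responses_to_sinogram(tr, half, 4), "coverage")
})

test_that("filtered back projection localises point sources and is linear", {
  angles <- c(0, 36, 72, 108, 144)
  pos <- seq(-9.6, 9.6, by = 3.2)

  # zero sinogram -> zero map
  z <- filtered_back_projection(sinogram(matrix(0, 5, length(pos)),
                                         angles, pos))
  expect_true(all(z$map == 0))

  # point source at (3.2, -3.2): forward-project then reconstruct
  src <- c(3.2, -3.2)
  R <- t(vapply(angles, function(a) {
    mu <- src[1] * cos(a * pi / 180) + src[2] * sin(a * pi / 180)
    exp(-(pos - mu)^2 / (2 * 0.8^2))
  }, numeric(length(pos))))
  m <- filtered_back_projection(sinogram(R, angles, pos), oversample = 2)
  peak <- which(m$map == max(m$map), arr.ind = TRUE)[1, ]
  expect_lte(abs(m$x_deg[peak[2]] - src[1]), 3.2)
  expect_lte(abs(m$y_deg[peak[1]] - src[2]), 3.2)

  # linearity: FBP(sum of sinograms) = sum of FBPs
  R2 <- matrix(runif(5 * length(pos)), 5)
  m1 <- filtered_back_projection(sinogram(R, angles, pos))
  m2 <- filtered_back_projection(sinogram(R2, angles, pos))
  m12 <- filtered_back_projection(sinogram(R + R2, angles, pos))
  expect_equal(m12$map, m1$map + m2$map, tolerance = 1e-9)

  expect_error(filtered_back_projection(sinogram(R[1:2, ], angles[1:2], pos)),
               "3 angles")
})

test_that("2D Gaussian fitting is exact on clean maps and flags degeneracy", {
  xs <- seq(-8, 8, by = 0.5)
  X <- matrix(xs, 33, 33, byrow = TRUE); Y <- matrix(xs, 33, 33)

  rf_true <- gaussian_rf(0.5, -1, 2.5, 1.25, theta_deg = 40)
  fit <- fit_gaussian_2d(rf_map(evaluate_rf(rf_true, X, Y), xs, xs))
  expect_equal(fit$center_x_deg, 0.5, tolerance = 1e-4)
  expect_equal(fit$center_y_deg, -1, tolerance = 1e-4)
  expect_equal(fit$major_sigma_deg, 2.5, tolerance = 1e-4)
  expect_equal(fit$minor_sigma_deg, 1.25, tolerance = 1e-4)
  expect_equal(fit$theta_deg, 40, tolerance = 0.01)

  # isotropic map: degenerate angle flag
  iso <- gaussian_rf(0, 0, 2, 2, 0)
  fit_iso <- fit_gaussian_2d(rf_map(evaluate_rf(iso, X, Y), xs, xs))
  expect_true(attr(fit_iso, "degenerate"))

  # noisy Gaussian at SNR 10: axes within 10%
  set.seed(4)
  noisy <- evaluate_rf(rf_true, X, Y) + rnorm(33 * 33, 0, 0.1)
  fit_n <- fit_gaussian_2d(rf_map(noisy, xs, xs))
  expect_equal(fit_n$major_sigma_deg, 2.5, tolerance = 0.1)
  expect_equal(fit_n$minor_sigma_deg, 1.25, tolerance = 0.1)
})

test_that("ellipticity definitions are exact", {
  expect_equal(ellipticity(gaussian_rf(0, 0, 2, 2, 0)), 0)
  expect_equal(ellipticity(gaussian_rf(0, 0, 2, 1, 0)), 0.5)
  expect_equal(ellipticity(gaussian_rf(0, 0, 10, 7, 0)), 0.3)
  expect_equal(ellipticity(gaussian_rf(0, 0, 2, 1, 0),
                           method = "axis_diff_ratio"), 1 / 3)
})

test_that("RF-to-OSI forward model matches a dense-grid oracle and its limits", {
  # circular RF -> OSI 0 at all frequencies
  circ <- gaussian_rf(0, 0, 2, 2, 0)
  expect_true(all(predict_osi_from_rf(circ, c(0.05, 0.1, 0.2)) < 0.02))

  # needle-like RF at a matched frequency -> OSI near 1
  needle <- gaussian_rf(0, 0, 4, 0.2, 0)
  expect_gt(predict_osi_from_rf(needle, 0.15), 0.9)

  # 2:1 Gaussian: coarse grid within 1% of a 3x denser quadrature
  rf <- gaussian_rf(0, 0, 3, 1.5, 30)
  coarse <- predict_osi_from_rf(rf, 0.1)
  dense <- predict_osi_from_rf(rf, 0.1, pixels_per_degree = 12)
  expect_equal(coarse, dense, tolerance = 0.01)

  # amplitude invariance
  rf_amp <- gaussian_rf(0, 0, 3, 1.5, 30, amplitude = 7)
  expect_equal(predict_osi_from_rf(rf_amp, 0.1), coarse, tolerance = 1e-9)

  expect_error(predict_osi_from_rf(rf, 0.5, pixels_per_degree = 1),
               "under-resolved")
})

test_that("population OSI prediction summarises correctly", {
  circles <- lapply(1:3, function(i) gaussian_rf(0, 0, 2, 2, 0))
  curve <- population_osi_prediction(circles, c(0.05, 0.1))
  expect_true(all(curve$mean_osi < 0.02))
  expect_true(all(curve$sd_osi < 0.02))

  single <- population_osi_prediction(list(gaussian_rf(0, 0, 3, 1.5, 0)), 0.1)
  expect_equal(single$sd_osi, 0)

  # a population at the observed median ellipticity stays well below 1
  # over the measured spatial-frequency band
  set.seed(6)
  pop <- lapply(1:12, function(i) {
    major <- runif(1, 2, 4)
    gaussian_rf(0, 0, major, major * 0.7, runif(1, 0, 180))
  })
  curve2 <- population_osi_prediction(pop, c(0.02, 0.05, 0.1))
  expect_true(all(curve2$mean_osi < 0.6))
})

test_that("flash protocol round trip recovers RF parameters", {
  geom <- screen_geometry(26, 26, 2, 10)
  flash <- make_bar_flash_protocol(geom, extent_deg = 19.2, n_repeats = 3,
                                   seed = 3)
  tm <- test_terminal("elliptical", theta = 60, cx = 1.3, cy = -2.1)
  tr <- terminal_dff_trace(tm, flash)
  set.seed(9)
  trn <- tr + rnorm(length(tr), 0, 0.03)   # ROI-averaged noise level
  sg <- responses_to_sinogram(trn, flash$events, 10)
  fit <- fit_gaussian_2d(filtered_back_projection(sg, oversample = 2),
                         sino = sg)
  expect_lt(sqrt((fit$center_x_deg - 1.3)^2 + (fit$center_y_deg + 2.1)^2),
            3.2)
  expect_lt(abs(ellipticity(fit) - 0.5), 0.1)
  expect_angle_close(fit$theta_deg, 60, 15)
})
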