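test_that("response detection applies the transient-vs-sustained rule", {
  fr <- 10
  set.seed(1)
  noise <- rnorm(400, 0, 0.01)

  # flat noiseless trace: no response
  r0 <- detect_response(rep(0.2, 400), 20, fr)
  expect_false(r0$responded)

  # sustained step of 10x the baseline MAD: responds with the epoch median
  tr <- noise; tr[201:400] <- tr[201:400] + 10 * mad_raw(noise[1:200])
  r1 <- detect_response(tr, 20, fr)
  expect_true(r1$responded)
  expect_false(r1$is_transient)
  expect_equal(r1$amplitude, stats::median(tr[201:300]))

  # brief 0.3 s pulse then return: the transient peak is the response
  tr2 <- noise; tr2[201:203] <- tr2[201:203] + 10 * mad_raw(noise[1:200])
  r2 <- detect_response(tr2, 20, fr)
  expect_true(r2$is_transient)
  expect_equal(r2$amplitude, max(tr2[201:205]))

  expect_error(detect_response(tr, 100, fr), "outside")
  expect_warning(detect_response(tr, 5, fr), "truncated")
})

test_that("OSI formula and invariants hold exhaustively", {
  expect_equal(compute_osi(1, 0), 1)
  expect_equal(compute_osi(0.3, 0.3), 0)
  expect_equal(compute_osi(0.75, 0.25), 0.5)
  expect_error(compute_osi(0, 0), "undefined")

  set.seed(7)
  for (i in 1:200) {
    a <- rnorm(1); b <- rnorm(1)
    if (abs(a) + abs(b) == 0) next
    osi <- compute_osi(a, b)
    expect_gte(osi, 0); expect_lte(osi, 1)
    expect_equal(compute_osi(3.7 * a, 3.7 * b), osi)   # scale invariance
    expect_equal(compute_osi(b, a), osi)               # symmetry
  }
})

test_that("grating OSI gate assigns OSI only for real differences", {
  stim <- test_stimulus(n_epochs = 4)
  fr <- 10
  g_inh <- grating_osi_sygcamp(
    terminal_dff_trace(test_terminal("inhibition_sharpened", 0), stim),
    stim$events, fr)
  expect_gte(g_inh$osi, 0.9)
  expect_equal(g_inh$preferred_orientation_deg, 0)

  g_unt <- grating_osi_sygcamp(
    terminal_dff_trace(test_terminal("untuned", 90), stim),
    stim$events, fr)
  expect_true(is.na(g_unt$osi))

  # a = 0.5 epoch vs b = 0 epoch with tiny MAD -> OSI 1
  tr <- rep(0, 430)
  tr[331:430] <- rep(c(0.5, 0.5001), 50)
  ev <- event_log(c(3, 13, 23, 33),
                  c("grating_on", rep("orientation_switch", 3)),
                  list(list(orientation_deg = 90), list(orientation_deg = 0),
                       list(orientation_deg = 90), list(orientation_deg = 0)))
  g <- grating_osi_sygcamp(tr, ev, fr)
  expect_equal(g$osi, 1, tolerance = 1e-3)
})

test_that("RGC classification separates dpc, static and insensitive outputs", {
  # the session construction used by the pipeline: scattered, strongly
  # tuned pools per orientation plus an untuned pool
  stim <- test_stimulus(frame_rate_hz = 20, n_epochs = 6)
  fr <- 20
  pool <- sample_population(population_spec(
    n_terminals = 40, fraction_os = 1,
    os_mix = c(elliptical = 0, inhibition_sharpened = 1), seed = 1001))
  prefs <- vapply(pool, function(t) t$rf$theta_deg, 0)
  t0s <- pool[prefs == 0]; t90s <- pool[prefs == 90]
  unt <- sample_population(population_spec(n_terminals = 12,
                                           fraction_os = 0, seed = 2001))

  s1 <- simulate_rgc_session(c(t0s[1:4], t90s[1:4]), stim, "on",
                             noise_sd = 0.01, seed = 511)
  s2 <- simulate_rgc_session(t0s[1:8], stim, "off", noise_sd = 0.01,
                             seed = 512)
  s3 <- simulate_rgc_session(unt[1:8], stim, "off", noise_sd = 0.01,
                             seed = 513)
  expect_equal(classify_rgc(s1$output, s1$events, fr), "dpc")
  expect_equal(classify_rgc(s2$output, s2$events, fr), "static_os")
  expect_true(classify_rgc(s3$output, s3$events, fr) %in%
                c("contrast_only", "non_os"))

  expect_error(classify_rgc(s1$output, event_log(), fr), "events")
})

test_that("orientation vector sums and the Moore statistic match closed forms", {
  dirs <- seq(0, 315, by = 45)

  # equal responses at all orientations -> zero vector
  expect_equal(orientation_vector_sum(rep(1, 8), dirs), c(x = 0, y = 0),
               tolerance = 1e-12)
  # response only at 0 deg -> vector along +x
  v <- orientation_vector_sum(c(2, 0, 0, 0, 2, 0, 0, 0), dirs)
  expect_equal(unname(v), c(2, 0), tolerance = 1e-12)
  # arbitrary table against a direct summation oracle
  set.seed(5)
  r <- abs(rnorm(8))
  v2 <- orientation_vector_sum(r, dirs)
  pooled <- (r[1:4] + r[5:8]) / 2
  th <- c(0, 45, 90, 135) * pi / 180
  expect_equal(unname(v2),
               c(sum(pooled * cos(2 * th)), sum(pooled * sin(2 * th))),
               tolerance = 1e-12)

  # identical directions, n = 10: R* = 55 / 10^1.5
  vi <- matrix(rep(c(1, 0), each = 10), ncol = 2) * (1:10)
  expect_equal(moore_rayleigh_stat(vi), 55 / 10^1.5)

  # antipodal cancelling pairs -> ~0 (rank-symmetric lengths)
  vp <- rbind(c(1, 0), c(-1, 0), c(2, 0), c(-2, 0), c(3, 0), c(-3, 0))
  expect_lt(moore_rayleigh_stat(vp), 1e-9)

  expect_error(moore_rayleigh_stat(matrix(0, 2, 2)), "at least 3")
})

test_that("Moore statistic is rotation- and scale-invariant", {
  set.seed(11)
  for (i in 1:25) {
    v <- matrix(rnorm(20), 10, 2)
    s <- moore_rayleigh_stat(v)
    phi <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    expect_equal(moore_rayleigh_stat(v %*% Rm), s, tolerance = 1e-9)
    # monotone rescaling of magnitudes preserves ranks, hence the statistic
    mag <- sqrt(rowSums(v^2))
    v_scaled <- v * (mag^2 / mag)   # magnitudes -> mag^2
    expect_equal(moore_rayleigh_stat(v_scaled), s, tolerance = 1e-9)
  }
})

test_that("shuffle calibration yields the designed false-positive rate", {
  calib <- null_trial_tables(400, seed = 21)
  held <- null_trial_tables(400, seed = 22)
  cv <- calibrate_critical_value(calib, seed = 5)

  # by construction ~1% of the shuffled calibration set is classified OS
  self_rate <- mean(classify_os_moving_bars(calib, cv)$is_os)
  # held-out null population close to 1% (binomial 99% bound at n = 400)
  held_rate <- mean(classify_os_moving_bars(held, cv)$is_os)
  expect_lt(held_rate, 0.03)

  # doubling amplitudes leaves classification unchanged (rank-based)
  doubled <- lapply(held, function(tab) 2 * tab)
  expect_identical(classify_os_moving_bars(doubled, cv)$is_os,
                   classify_os_moving_bars(held, cv)$is_os)

  # strongly tuned terminals are detected
  tuned <- retinotune:::with_seed(31, lapply(1:50, function(i) {
    tab <- matrix(abs(rnorm(80, 0, 0.2)), 10, 8)
    tab[, c(1, 5)] <- tab[, c(1, 5)] + 1    # consistent 0-deg tuning
    tab
  }))
  expect_gt(mean(classify_os_moving_bars(tuned, cv)$is_os), 0.9)

  expect_error(calibrate_critical_value(calib[1:10]), ">= 100")
})

test_that("double-exponential fits recover generator parameters", {
  tt <- seq(0, 25, by = 0.05)

  # pure single exponential: tau within 1%, second amplitude ~ 0
  y1 <- 0.2 + 0.8 * exp(-tt / 1.3)
  f1 <- fit_double_exponential(y1, tt)
  expect_equal(f1$tau1_s, 1.3, tolerance = 0.01)
  expect_lt(f1$A2, 0.01)

  # constant trace
  fc <- fit_double_exponential(rep(2, 100), seq(0, 9.9, 0.1))
  expect_equal(fc$y0, 2)
  expect_equal(fc$A1 + fc$A2, 0)

  # noiseless double exponential at the depression kinetics: 2% recovery
  p <- double_exp_params()
  y2 <- p$y0 + p$A1 * exp(-tt / p$tau1_s) + p$A2 * exp(-tt / p$tau2_s)
  f2 <- fit_double_exponential(y2, tt)
  expect_equal(f2$tau1_s, p$tau1_s, tolerance = 0.02)
  expect_equal(f2$tau2_s, p$tau2_s, tolerance = 0.02)
  expect_equal(f2$fraction_fast, p$A1 / (p$A1 + p$A2), tolerance = 0.02)
  expect_equal(f2$y0, p$y0, tolerance = 0.02)
})

test_that("preferred orientation estimators handle ties and recover tuning", {
  expect_equal(preferred_orientation(c(1, 0, 0, 0), c(0, 45, 90, 135)), 0)
  expect_warning(p <- preferred_orientation(c(1, 0, 1, 0), c(0, 45, 90, 135)),
                 "tie")
  expect_true(is.na(p))
  expect_warning(p0 <- preferred_orientation(c(0, 0), c(0, 90)), "zero")
  expect_true(is.na(p0))

  # continuous estimator on a smooth tuning curve peaked at 30 deg
  oris <- c(0, 36, 72, 108, 144)
  resp <- exp(cos(2 * (oris - 30) * pi / 180))
  est <- preferred_orientation(resp, oris, method = "vector")
  d <- abs(est - 30) %% 180
  expect_lt(min(d, 180 - d), 5)

  # synthetic elliptical terminal with a 30 deg RF prefers ~30 deg
  stim30 <- make_orientation_switch_movie(
    screen_geometry(30, 30, 2, 10), 0.1, epoch_s = 5,
    orientations_deg = c(30, 120, 30, 120), pre_s = 1)
  tr <- terminal_dff_trace(test_terminal("inhibition_sharpened", 30), stim30)
  g <- grating_osi_sygcamp(tr, stim30$events, 10, epoch_s = 5)
  expect_equal(g$preferred_orientation_deg, 30)
})
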