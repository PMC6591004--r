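test_that("linear drive follows RF geometry, with a brute-force oracle", {
  stim <- test_stimulus(n_epochs = 2, epoch_s = 5, pre_s = 0)

  # zero-contrast movie -> identically zero drive
  blank <- stimulus_movie(array(0, dim(stim$frames)), stim$geometry,
                          stim$events)
  tm <- test_terminal("elliptical", theta = 0)
  expect_true(all(linear_drive(tm, blank) == 0))

  # circular RF: phase-averaged drive equal for both orientations
  circ <- ground_truth_terminal(gaussian_rf(0, 0, 3, 3, 0), "untuned")
  d <- linear_drive(circ, stim)
  tt <- frame_times(stim)
  expect_equal(mean(d[tt < 5]), mean(d[tt >= 5]), tolerance = 0.05)

  # elongated RF: preferred orientation yields strictly larger drive
  d_e <- linear_drive(tm, stim)          # prefers 0 deg; epochs are 90 then 0
  expect_gt(mean(d_e[tt >= 5]), mean(d_e[tt < 5]))

  # brute-force pixel-sum oracle for one frame
  gr <- pixel_grid(stim$geometry)
  w <- evaluate_rf(tm$rf, gr$x, gr$y, normalize = TRUE)
  oracle <- max(0, -sum(w * stim$frames[3, , ]))   # OFF polarity
  expect_equal(as.numeric(d_e[3]), oracle, tolerance = 1e-12)

  expect_error(
    linear_drive(test_terminal(cx = 100), stim), "outside")
})

test_that("inhibition sharpening nulls the orthogonal response and dips below baseline", {
  stim <- test_stimulus(n_epochs = 2, epoch_s = 5, pre_s = 0)
  tm <- test_terminal("inhibition_sharpened", theta = 0, gain = 1)
  d <- linear_drive(tm, stim)
  tt <- frame_times(stim)
  expect_equal(max(d[tt < 5]), 0)             # orthogonal epoch silenced
  expect_gt(max(d[tt >= 5]), 0)
  expect_lt(min(attr(d, "pre")[tt < 5]), -0.1)  # inhibition-driven dip

  tr <- terminal_dff_trace(tm, stim)
  expect_lt(min(tr), 0)                       # calcium dips below baseline
  trg <- terminal_dff_trace(tm, stim, modality = "glutamate")
  expect_gte(min(trg), 0)                     # release cannot be negative
})

test_that("adaptation has the closed-form step response and indicator limits", {
  p <- double_exp_params()
  drive <- c(rep(0, 20), rep(1, 600))

  # no depression when both amplitudes are zero
  flat <- apply_adaptation_and_indicator(
    drive, double_exp_params(y0 = 1, A1 = 0, A2 = 0), 0.2, dt = 0.05)
  expect_equal(max(flat), 1, tolerance = 1e-6)

  # steady-state / peak ratio = y0 / (y0 + A1 + A2), exactly, without filter
  out <- apply_adaptation_and_indicator(drive, p, 0, dt = 0.05,
                                        drive_scale = 1)
  expect_equal(tail(out, 1) / max(out), p$y0 / (p$y0 + p$A1 + p$A2),
               tolerance = 1e-3)

  # indicator tau -> 0 is the identity on the adapted drive
  out0 <- apply_adaptation_and_indicator(drive, p, 0, dt = 0.05)
  out_eps <- apply_adaptation_and_indicator(drive, p, 1e-9, dt = 0.05)
  expect_equal(out0, out_eps, tolerance = 1e-6)

  expect_error(apply_adaptation_and_indicator(c(-1, 0), p, 0, 0.1),
               "non-negative")
})

test_that("population sampling is deterministic with exact mechanism counts", {
  spec <- population_spec(n_terminals = 12, fraction_os = 0.5, seed = 3)
  pop <- sample_population(spec)
  mech <- vapply(pop, function(t) t$mechanism, "")
  expect_equal(sum(mech != "untuned"), 6)
  expect_equal(sum(mech == "inhibition_sharpened"), round(6 * 0.7))

  # fraction_os = 0 -> all untuned
  pop0 <- sample_population(population_spec(n_terminals = 5,
                                            fraction_os = 0, seed = 1))
  expect_true(all(vapply(pop0, function(t) t$mechanism, "") == "untuned"))

  # reproducible from seed
  pop2 <- sample_population(spec)
  expect_equal(pop[[4]]$rf$center_x_deg, pop2[[4]]$rf$center_x_deg)

  # preferred-orientation weights are respected at scale (chi-squared)
  spec_b <- population_spec(n_terminals = 400, fraction_os = 1,
                            pref_weights = c(0.8, 0.2), seed = 9)
  prefs <- vapply(sample_population(spec_b, movie_nx = 256, movie_ny = 256),
                  function(t) t$rf$theta_deg, 0)
  p <- stats::chisq.test(table(prefs), p = c(0.8, 0.2))$p.value
  expect_gt(p, 0.001)
})

test_that("rendered movies reproduce traces at spot centers with requested noise", {
  stim <- test_stimulus(n_epochs = 2, epoch_s = 5, pre_s = 1)
  tm1 <- test_terminal("elliptical", theta = 0,
                       position_px = c(10, 10))
  tm2 <- test_terminal("elliptical", theta = 0,
                       position_px = c(24, 24))
  tr <- terminal_dff_trace(tm1, stim)
  traces <- cbind(tr, tr)

  # noiseless: center-pixel series proportional to the trace,
  # identical-trace spots correlate at 1
  mv <- render_movie(list(tm1, tm2), traces, 32, 32, noise_sd = 0, f0 = 100)
  px <- mv$data[, 10, 10]
  expect_gt(stats::cor(px, tr), 0.999999)
  expect_equal(stats::cor(mv$data[, 10, 10], mv$data[, 24, 24]), 1,
               tolerance = 1e-9)

  # measured pixel noise matches the request within 5% (sampled over a
  # blank region far from both spots)
  mvn <- render_movie(list(tm1, tm2), traces, 32, 32, noise_sd = 0.1,
                      f0 = 100, seed = 8)
  blank <- as.numeric(mvn$data[, 1:3, 28:32])
  expect_equal(stats::sd(blank) / 100, 0.1, tolerance = 0.05)

  expect_warning(
    render_movie(list(tm1, test_terminal(position_px = c(11, 10))),
                 traces, 32, 32, noise_sd = 0),
    "spacing")
})

test_that("RGC sessions have the designed output structure", {
  stim <- test_stimulus(frame_rate_hz = 20, n_epochs = 4)
  mk <- function(th) test_terminal("inhibition_sharpened", theta = th,
                                   cx = runif(1, -5, 5), cy = runif(1, -5, 5))
  set.seed(42)
  mixed <- c(lapply(1:3, function(i) mk(0)), lapply(1:3, function(i) mk(90)))

  s_on <- simulate_rgc_session(mixed, stim, "on", noise_sd = 0)
  s_off <- simulate_rgc_session(mixed, stim, "off", noise_sd = 0)

  # ffi on: transient at every orientation switch, re-nulled between
  sw <- events_of_kind(stim$events, "orientation_switch")$time_s
  tt <- (seq_along(s_on$output) - 1) / 20
  for (t0 in sw) {
    peak <- max(s_on$output[tt >= t0 & tt < t0 + 1])
    steady <- stats::median(s_on$output[tt >= t0 + 5 & tt < t0 + 9.5])
    expect_gt(peak, steady + 0.02)
  }
  # ffi off: sustained output tracks total drive
  late <- stats::median(s_off$output[tt > 30])
  expect_gt(late, 0.05)

  # single untuned input, ffi off -> output proportional to rectified input
  s1 <- simulate_rgc_session(list(test_terminal("untuned")), stim, "off",
                             noise_sd = 0)
  expect_equal(s1$output, pmax(s1$input_sum, 0), tolerance = 1e-9)
})
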