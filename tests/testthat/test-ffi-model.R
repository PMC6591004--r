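test_that("the membrane model conserves rest and matches the RC closed form", {
  m <- reduced_rgc()
  n <- 2000
  vm <- simulate_membrane(m, rep(0, n), rep(0, n))
  expect_lt(max(abs(vm - m$e_leak_mv)), 1e-9)

  # one-compartment limit against the analytic RC solution
  m1 <- reduced_rgc(n_dendrite = 1, dend_length_um = 1, dend_diam_um = 0.1,
                    syn_compartment = 1)
  gE <- rep(0.001, 40000)
  vm1 <- simulate_membrane(m1, gE, rep(0, length(gE)), dt_s = 2e-5)
  gl <- m1$gleak_uS[1]; C <- m1$cap_nF[1]
  vinf <- (gl * m1$e_leak_mv + 0.001 * m1$e_exc_mv) / (gl + 0.001)
  tau_ms <- C / (gl + 0.001)
  tt <- seq_len(length(gE)) * 0.02
  va <- vinf + (m1$e_leak_mv - vinf) * exp(-tt / tau_ms)
  expect_lt(max(abs(vm1 - va)), 0.05)

  expect_error(simulate_membrane(m, rep(0, 10), rep(0, 10), dt_s = 1),
               "dt")
})

test_that("feedforward inhibition makes the step response transient", {
  m <- reduced_rgc()
  n <- 2000
  ev <- data.frame(onset_s = 0.1, duration_s = 0.6)
  gE <- conductance_trace(ev, n, 5e-4, 0.003)
  ratios <- vapply(c(0, 1, 2), function(r) {
    gI <- conductance_trace(ev, n, 5e-4, r * 0.003, tau_rise_s = 0.004,
                            tau_decay_s = 0.016, delay_s = 0.01)
    dv <- simulate_membrane(m, gE, gI) - m$e_leak_mv
    dv[1300] / max(dv)              # plateau / peak
  }, numeric(1))

  # excitation alone: monotonic depolarization to a sustained plateau
  expect_gt(ratios[1], 0.99)
  # increasing inhibition makes the response progressively more transient
  expect_true(all(diff(ratios) < -0.1))
  expect_lt(ratios[3], 0.5)
})

test_that("NLMS identifies a known FIR filter and degenerate mappings", {
  set.seed(3)
  h <- c(0.2, 0.5, 1, 0.7, 0.3, -0.2, -0.4, -0.3, -0.1, 0.05)
  x <- rnorm(20000)
  y <- as.numeric(signal::filter(h, 1, x))
  f <- estimate_filter_nlms(x, y, fs_hz = 100, filter_length_s = 0.1,
                            mu = 0.5, n_passes = 4)
  expect_lt(sqrt(mean((f$kernel - h)^2)), 0.01 * max(abs(h)))

  # identity mapping -> unit impulse
  fi <- estimate_filter_nlms(x, x, fs_hz = 100, filter_length_s = 0.05,
                             mu = 0.5, n_passes = 3)
  expect_equal(fi$kernel[1], 1, tolerance = 1e-3)
  expect_lt(max(abs(fi$kernel[-1])), 1e-3)

  # zero output -> zero kernel
  fz <- estimate_filter_nlms(x, rep(0, length(x)), fs_hz = 100,
                             filter_length_s = 0.05)
  expect_true(all(fz$kernel == 0))
})

test_that("the derived FFI filter is high-pass at the 2:1 ratio", {
  f2 <- derive_ffi_filter(i_to_e_ratio = 2, seed = 2)
  f0 <- derive_ffi_filter(i_to_e_ratio = 0, seed = 2)
  g2 <- filter_gain(f2); g0 <- filter_gain(f0)

  expect_lt(g2$dc / g2$peak, 0.3)                  # high-pass
  expect_gt(g0$dc / g0$peak, 3 * g2$dc / g2$peak)  # no-FFI far less so

  # determinism from seed
  f2b <- derive_ffi_filter(i_to_e_ratio = 2, seed = 2)
  expect_identical(f2$kernel, f2b$kernel)
})

test_that("model 1 nulls sustained input while model 2 does not", {
  dt <- 0.1
  k <- ffi_kernel_biphasic(dt)
  expect_equal(sum(k$kernel), 0, tolerance = 1e-12)   # exact DC null

  const <- rep(1, 300)
  out1 <- apply_model1(const, k, baseline_idx = 1:5)
  expect_equal(tail(out1, 1), 0, tolerance = 1e-9)

  # sub-threshold input -> zero model-2 output; sustained input sustained
  base <- c(rnorm(50, 0, 0.01), rep(1, 250))
  out2 <- apply_model2(base, baseline_idx = 1:50)
  expect_gt(tail(out2, 1), 0.5)
  expect_lt(max(apply_model2(rnorm(100, 0, 0.01), baseline_idx = 1:50)),
            1e-4)

  # model-2 peak time equals the input peak time (pointwise map)
  x <- c(rep(0, 50), stats::dnorm(seq(-3, 3, length.out = 100)), rep(0, 50))
  o2 <- apply_model2(x, baseline_idx = 1:40)
  expect_equal(which.max(o2), which.max(x))
})

test_that("time-to-peak deltas detect constructed shifts", {
  fr <- 20
  x <- rep(0, 400)
  for (t0 in c(5, 10, 15)) {
    idx <- round(t0 * fr) + seq_len(30)
    x[idx] <- x[idx] + stats::dnorm(seq(-2, 4, length.out = 30))
  }
  same <- time_to_peak_delta(x, x, c(5, 10, 15), fr)
  expect_equal(same$median_s, 0)
  shifted <- c(rep(0, 4), x[seq_len(396)])   # +0.2 s shift
  d <- time_to_peak_delta(x, shifted, c(5, 10, 15), fr)
  expect_equal(d$median_s, 0.2, tolerance = 1e-9)

  # flat traces are skipped
  dflat <- time_to_peak_delta(rep(0, 400), x, c(5, 10, 15), fr)
  expect_length(dflat$deltas_s, 0)
})

test_that("input-output R^2 matches hand computation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(input_output_r2(x, 2 * x), 1)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(input_output_r2(x, y), stats::cor(x, y)^2)
  set.seed(12)
  expect_lt(input_output_r2(rnorm(10000), rnorm(10000)), 0.01)
  expect_error(input_output_r2(x, rep(1, 5)), "zero-variance")
})

test_that("spectrograms localise power and the FFI output loses low frequencies", {
  fr <- 40
  tt <- seq(0, 20, by = 1 / fr)
  sine <- sin(2 * pi * 5 * tt)
  sp <- spectrogram(sine, fr, window_s = 2)
  pk <- sp$freq_hz[apply(sp$power, 1, which.max)]
  expect_true(all(abs(pk - 5) < 0.5))
  expect_true(all(spectrogram(rep(0, 500), fr)$power == 0))

  # model-1 output carries less power below 5 Hz than its input
  stim <- test_stimulus(frame_rate_hz = 20, n_epochs = 4)
  set.seed(2)
  terms <- c(lapply(1:2, function(i)
    test_terminal("inhibition_sharpened", 0, cx = runif(1, -5, 5))),
    lapply(1:2, function(i)
      test_terminal("inhibition_sharpened", 90, cx = runif(1, -5, 5))))
  s <- simulate_rgc_session(terms, stim, "on", noise_sd = 0)
  bp_in <- band_power(s$input_sum / max(s$input_sum), 20, c(0, 5))
  bp_out <- band_power(s$output / max(s$output), 20, c(0, 5))
  expect_lt(bp_out, bp_in)
})
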