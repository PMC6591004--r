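# Shared small fixtures, built in code.

small_geom <- function(frame_rate_hz = 10, ppd = 2, size_deg = 20) {
  screen_geometry(size_deg, size_deg, ppd, frame_rate_hz)
}

# standard alternating-orientation grating session used across tests
test_stimulus <- function(frame_rate_hz = 10, n_epochs = 4, epoch_s = 10,
                          sf = 0.1, pre_s = 3, size_deg = 30, ppd = 2) {
  make_orientation_switch_movie(
    screen_geometry(size_deg, size_deg, ppd, frame_rate_hz),
    sf, reversal_hz = 5, epoch_s = epoch_s,
    orientations_deg = rep(c(90, 0), length.out = n_epochs),
    pre_s = pre_s)
}

test_terminal <- function(mechanism = "elliptical", theta = 0,
                          major = 3, minor = 1.5, cx = 0, cy = 0,
                          gain = 1, ...) {
  if (mechanism == "untuned") minor <- major * 0.985
  ground_truth_terminal(gaussian_rf(cx, cy, major, minor, theta),
                        mechanism = mechanism, inhibition_gain = gain, ...)
}

# trial tables of orientation-independent (null) moving-bar responses
null_trial_tables <- function(n_terminals, n_trials = 10, n_dir = 8,
                              seed = 1) {
  retinotune:::with_seed(seed, lapply(seq_len(n_terminals), function(i)
    matrix(abs(stats::rnorm(n_trials * n_dir)), n_trials, n_dir)))
}

expect_angle_close <- function(a, b, tol) {
  d <- abs(a - b) %% 180
  expect_lt(min(d, 180 - d), tol)
}
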