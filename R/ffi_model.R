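#' Reduced passive retinal ganglion cell model
#'
#' A soma plus a single unbranched dendrite of `n_dendrite` segments,
#' passive membrane only, with one excitatory and one inhibitory
#' synapse co-located on the same dendritic compartment. Specific
#' membrane parameters follow standard vertebrate RGC passive values
#' and are fully configurable.
#'
#' @param n_dendrite Number of dendritic segments.
#' @param soma_diam_um Soma diameter (sphere, micrometers).
#' @param dend_length_um,dend_diam_um Dendrite total length / diameter.
#' @param rm_ohm_cm2 Specific membrane resistance.
#' @param cm_uF_cm2 Specific membrane capacitance.
#' @param ra_ohm_cm Axial resistivity.
#' @param e_leak_mv Leak reversal (resting potential).
#' @param e_exc_mv,e_inh_mv Excitatory / inhibitory synaptic reversals.
#' @param syn_compartment Compartment index carrying both synapses
#'   (1 = soma; default mid-dendrite).
#' @return Object of class `reduced_rgc` with per-compartment
#'   capacitances (nF), leak conductances (uS) and axial couplings
#'   (uS).
#' @export
reduced_rgc <- function(n_dendrite = 4, soma_diam_um = 15,
                        dend_length_um = 150, dend_diam_um = 1.2,
                        rm_ohm_cm2 = 20000, cm_uF_cm2 = 1,
                        ra_ohm_cm = 120, e_leak_mv = -60,
                        e_exc_mv = 0, e_inh_mv = -70,
                        syn_compartment = NULL) {
  nc <- n_dendrite + 1L
  soma_area <- pi * (soma_diam_um * 1e-4)^2              # sphere, cm^2
  seg_len <- dend_length_um / n_dendrite * 1e-4          # cm
  seg_area <- pi * (dend_diam_um * 1e-4) * seg_len
  areas <- c(soma_area, rep(seg_area, n_dendrite))

  cap_nF <- cm_uF_cm2 * areas * 1e3                      # uF -> nF
  gleak_uS <- areas / rm_ohm_cm2 * 1e6                   # S -> uS
  ga <- pi * (dend_diam_um * 1e-4)^2 / 4 / (ra_ohm_cm * seg_len) * 1e6
  ga_uS <- rep(ga, nc - 1L)

  m <- list(n_compartments = nc, cap_nF = cap_nF, gleak_uS = gleak_uS,
            ga_uS = ga_uS, e_leak_mv = e_leak_mv, e_exc_mv = e_exc_mv,
            e_inh_mv = e_inh_mv,
            syn_compartment = syn_compartment %||% (1L + ceiling(n_dendrite / 2)))
  class(m) <- "reduced_rgc"
  m
}

#' @export
print.reduced_rgc <- function(x, ...) {
  cat(sprintf(
    "<reduced_rgc> soma + %d dendrite segments, synapses on compartment %d\n",
    x$n_compartments - 1, x$syn_compartment))
  cat(sprintf("  total leak %.4g uS, total capacitance %.4g nF, tau_m %.1f ms\n",
              sum(x$gleak_uS), sum(x$cap_nF),
              sum(x$cap_nF) / sum(x$gleak_uS)))
  invisible(x)
}

#' Synaptic conductance trace from an event list
#'
#' Each event is a boxcar of its duration convolved with a unitary
#' difference-of-exponentials waveform (area-normalized), so a long
#' event plateaus at `g_peak_uS * amplitude` and a brief event reaches
#' proportionally less.
#'
#' @param events Data frame with `onset_s`, `duration_s` and optional
#'   `amplitude` columns.
#' @param n_samples,dt_s Length and sample interval of the trace.
#' @param g_peak_uS Plateau conductance of a sustained unit event.
#' @param tau_rise_s,tau_decay_s Waveform kinetics.
#' @param delay_s Onset delay (used for feedforward inhibition, which
#'   mirrors the excitatory event times after a disynaptic delay).
#' @return Conductance trace in uS.
#' @export
conductance_trace <- function(events, n_samples, dt_s, g_peak_uS,
                              tau_rise_s = 0.002, tau_decay_s = 0.008,
                              delay_s = 0) {
  if (tau_decay_s <= tau_rise_s) stop("tau_decay_s must exceed tau_rise_s")
  box <- numeric(n_samples)
  amp <- events$amplitude %||% rep(1, nrow(events))
  for (i in seq_len(nrow(events))) {
    i0 <- floor((events$onset_s[i] + delay_s) / dt_s) + 1L
    i1 <- min(n_samples, i0 + round(events$duration_s[i] / dt_s) - 1L)
    if (i0 > n_samples) next
    idx <- max(1L, i0):i1
    box[idx] <- box[idx] + amp[i]
  }
  # conv(box, exp(-t/tau)) == tau * (unit-DC one-pole filter of box)
  lp <- function(x, tau) {
    a <- exp(-dt_s / tau)
    as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
  }
  g_peak_uS * (tau_decay_s * lp(box, tau_decay_s) -
                 tau_rise_s * lp(box, tau_rise_s)) /
    (tau_decay_s - tau_rise_s)
}

#' Simulate the membrane potential of the reduced RGC
#'
#' Backward-Euler (implicit, unconditionally stable) integration of the
#' passive cable with conductance-based synaptic currents
#' `g(t) (V - E)` at the synapse compartment; somatic membrane
#' potential is returned.
#'
#' @param model A [reduced_rgc()].
#' @param gE_uS,gI_uS Excitatory / inhibitory conductance traces (uS),
#'   equal length.
#' @param dt_s Integration step (default 0.5 ms). Steps above 1/10 of
#'   the membrane time constant are rejected with guidance.
#' @param record_every Keep every k-th sample (default 1).
#' @return Somatic membrane potential trace (mV).
#' @export
simulate_membrane <- function(model, gE_uS, gI_uS, dt_s = 5e-4,
                              record_every = 1L) {
  tau_m_s <- sum(model$cap_nF) / sum(model$gleak_uS) * 1e-3
  if (dt_s > tau_m_s / 10)
    stop(sprintf("dt too coarse for the membrane: use dt <= %.3g s",
                 tau_m_s / 10))
  simulate_cable_cpp(model$cap_nF, model$gleak_uS, model$e_leak_mv,
                     model$ga_uS, model$syn_compartment,
                     gE_uS, gI_uS, model$e_exc_mv, model$e_inh_mv,
                     dt_s * 1e3, as.integer(record_every), 1L)
}

#' Temporal filter (FIR kernel)
#'
#' @param kernel Numeric vector of taps (first tap = zero lag).
#' @param dt_s Sample interval of the taps.
#' @return Object of class `temporal_filter`.
#' @export
temporal_filter <- function(kernel, dt_s) {
  stopifnot(all(is.finite(kernel)), dt_s > 0)
  f <- list(kernel = as.numeric(kernel), dt_s = dt_s,
            length_s = length(kernel) * dt_s)
  class(f) <- "temporal_filter"
  f
}

#' @export
print.temporal_filter <- function(x, ...) {
  g <- filter_gain(x)
  cat(sprintf("<temporal_filter> %d taps (%.3f s), |DC|/peak gain %.3f\n",
              length(x$kernel), x$length_s, g$dc / g$peak))
  invisible(x)
}

#' DC and peak frequency-response gain of a temporal filter
#'
#' @param filter A [temporal_filter()].
#' @return List with `dc` (absolute DC gain `|sum w|`) and `peak`
#'   (maximum of `|H(f)|`). A high-pass kernel has `dc` well below
#'   `peak`.
#' @export
filter_gain <- function(filter) {
  w <- filter$kernel
  H <- Mod(stats::fft(c(w, rep(0, 7 * length(w)))))
  list(dc = abs(sum(w)), peak = max(H))
}

#' Estimate an FIR filter by NLMS adaptive filtering
#'
#' Normalized least-mean-squares identification of the linear kernel
#' mapping `input` to `output`:
#' `w <- w + mu * e * x / (eps + ||x||^2)` per sample, run over the
#' record `n_passes` times. Signals are used as supplied (no
#' centering); pass baseline-subtracted traces.
#'
#' @param input,output Aligned traces at the same sample rate.
#' @param fs_hz Sample rate.
#' @param filter_length_s Kernel length in seconds (default 0.75).
#' @param mu NLMS step size (default 0.1).
#' @param eps Normalisation regulariser.
#' @param n_passes Passes over the record (default 4).
#' @return A [temporal_filter()]; pass mean-squared errors are attached
#'   as attribute `"mse"`. Errors if the error energy grows between
#'   passes (divergence).
#' @export
estimate_filter_nlms <- function(input, output, fs_hz,
                                 filter_length_s = 0.75, mu = 0.1,
                                 eps = 1e-6, n_passes = 4) {
  L <- max(1L, round(filter_length_s * fs_hz))
  res <- nlms_cpp(as.numeric(input), as.numeric(output), L, mu, eps,
                  as.integer(n_passes))
  mse <- res$mse
  if (n_passes > 1 && mse[n_passes] > 2 * mse[1] && mse[n_passes] > 1e-12)
    stop("NLMS diverged (error energy growing); reduce mu")
  f <- temporal_filter(res$w, 1 / fs_hz)
  attr(f, "mse") <- mse
  f
}

#' Derive the feedforward-inhibition temporal filter
#'
#' Generates a long training record of randomly timed excitatory
#' synaptic events of varying duration, mirrors them onto a delayed
#' inhibitory conductance scaled by `i_to_e_ratio`, simulates the
#' reduced RGC membrane, and identifies the excitation-to-voltage
#' kernel by NLMS. With a 2:1 inhibitory:excitatory ratio the kernel is
#' biphasic and high-pass (DC gain well below peak); with the ratio at
#' 0 it is low-pass.
#'
#' @param model A [reduced_rgc()].
#' @param i_to_e_ratio Inhibitory / excitatory conductance ratio
#'   (default 2).
#' @param n_events Number of training events (default 1600).
#' @param record_s Training record length (default 804 s).
#' @param g_peak_uS Excitatory plateau conductance (default 0.003 uS;
#'   strong enough to engage shunting, see the methods vignette).
#' @param inh_delay_s Feedforward (disynaptic) delay of inhibition.
#' @param event_duration_range_s Log-uniform range of event durations.
#' @param fs_hz Sample rate of the identified kernel (default 200).
#' @param dt_s Membrane integration step.
#' @param filter_length_s Kernel length (default 0.75 s).
#' @param mu,n_passes NLMS settings.
#' @param seed Seed for the event pattern.
#' @return A [temporal_filter()], kernel normalized to unit peak
#'   magnitude.
#' @export
derive_ffi_filter <- function(model = reduced_rgc(), i_to_e_ratio = 2,
                              n_events = 1600, record_s = 804,
                              g_peak_uS = 0.003, inh_delay_s = 0.01,
                              event_duration_range_s = c(0.02, 0.5),
                              fs_hz = 200, dt_s = 5e-4,
                              filter_length_s = 0.75, mu = 0.2,
                              n_passes = 6, seed = 1) {
  events <- with_seed(seed, {
    data.frame(onset_s = sort(stats::runif(n_events, 0, record_s - 1)),
               duration_s = exp(stats::runif(n_events,
                                             log(event_duration_range_s[1]),
                                             log(event_duration_range_s[2]))),
               amplitude = stats::runif(n_events, 0.5, 1))
  })
  n <- round(record_s / dt_s)
  gE <- conductance_trace(events, n, dt_s, g_peak_uS,
                          tau_rise_s = 0.002, tau_decay_s = 0.008)
  gI <- conductance_trace(events, n, dt_s, i_to_e_ratio * g_peak_uS,
                          tau_rise_s = 0.004, tau_decay_s = 0.016,
                          delay_s = inh_delay_s)
  keep <- round(1 / (fs_hz * dt_s))
  vm <- simulate_membrane(model, gE, gI, dt_s, record_every = keep)
  x <- gE[seq_along(gE) %% keep == 0]
  x <- x[seq_along(vm)] / max(gE)
  d <- vm - model$e_leak_mv
  f <- estimate_filter_nlms(x, d, fs_hz, filter_length_s, mu = mu,
                            n_passes = n_passes)
  temporal_filter(f$kernel / max(abs(f$kernel)), f$dt_s)
}

#' Parametric biphasic high-pass kernel
#'
#' A convenient stand-alone high-pass temporal filter (fast positive
#' lobe, slower negative lobe) of the shape produced by feedforward
#' inhibition, with exactly the requested DC gain (default 0: sustained
#' inputs are nulled completely). Used as the default session filter by
#' [simulate_rgc_session()].
#'
#' @param dt_s Sample interval.
#' @param length_s Kernel length (default 0.75 s).
#' @param tau_fast_s,tau_slow_s Positive / negative lobe time
#'   constants.
#' @param dc_gain Fraction of the positive lobe's area retained at DC.
#' @return A [temporal_filter()], peak normalized to 1.
#' @export
ffi_kernel_biphasic <- function(dt_s, length_s = 0.75, tau_fast_s = 0.1,
                                tau_slow_s = 0.5, dc_gain = 0) {
  tt <- seq(0, length_s - dt_s, by = dt_s)
  ef <- exp(-tt / tau_fast_s)
  es <- exp(-tt / tau_slow_s)
  # weight of the slow negative lobe chosen so that the discrete DC sum
  # equals dc_gain times the positive lobe's sum, exactly
  cc <- (1 - dc_gain) * sum(ef) / sum(es)
  k <- ef - cc * es
  temporal_filter(k / max(abs(k)), dt_s)
}

#' Apply model 1: high-pass filter then threshold-linear nonlinearity
#'
#' The input is causally convolved with the FFI temporal filter and
#' passed through a static nonlinearity
#' `scale * max(x - threshold, 0)^exponent` with the threshold set to
#' `threshold_mult` (default 3) times the noise (SD) of the filtered
#' signal's pre-stimulus baseline.
#'
#' @param input Input trace (summed excitatory drive).
#' @param filter A [temporal_filter()]; resampled to the input's
#'   sample interval if needed.
#' @param dt_s Sample interval of `input` (default: the filter's).
#' @param threshold_mult Threshold in baseline-noise units (default 3).
#' @param exponent Nonlinearity exponent (1 for model 1).
#' @param output_scale Output scale factor.
#' @param baseline_idx Indices of the pre-stimulus baseline (default
#'   the first 5% of samples).
#' @return Predicted output trace.
#' @export
apply_model1 <- function(input, filter, dt_s = NULL, threshold_mult = 3,
                         exponent = 1, output_scale = 1,
                         baseline_idx = NULL) {
  dt_s <- dt_s %||% filter$dt_s
  w <- filter$kernel
  if (abs(dt_s - filter$dt_s) > 1e-12) {
    t_old <- (seq_along(w) - 1) * filter$dt_s
    t_new <- seq(0, filter$length_s - dt_s, by = dt_s)
    w <- stats::approx(t_old, w, xout = t_new, rule = 2)$y *
      (dt_s / filter$dt_s)
  }
  z <- as.numeric(signal::filter(w, 1, input))
  baseline_idx <- baseline_idx %||% seq_len(max(2, round(0.05 * length(input))))
  med <- stats::median(z[baseline_idx])
  thr <- threshold_mult * stats::sd(z[baseline_idx])
  output_scale * pmax(z - med - thr, 0)^exponent
}

#' Apply model 2: threshold then power-law nonlinearity (no filter)
#'
#' Pointwise static transform `scale * max(x - threshold, 0)^exponent`
#' of the raw input (default exponent 2), with the threshold set as in
#' [apply_model1()] but on the raw input baseline.
#'
#' @inheritParams apply_model1
#' @param exponent Nonlinearity exponent (default 2).
#' @return Predicted output trace.
#' @export
apply_model2 <- function(input, threshold_mult = 3, exponent = 2,
                         output_scale = 1, baseline_idx = NULL) {
  baseline_idx <- baseline_idx %||% seq_len(max(2, round(0.05 * length(input))))
  med <- stats::median(input[baseline_idx])
  thr <- threshold_mult * stats::sd(input[baseline_idx])
  output_scale * pmax(input - med - thr, 0)^exponent
}

#' Per-transition time-to-peak difference between output and input
#'
#' For each stimulus transition the time of the maximum of each trace
#' within `window_s` after the transition is found;
#' `delta = t_peak(output) - t_peak(input)` (negative deltas mean the
#' output leads the input, the signature of a high-pass filter).
#' Transitions where a trace is flat over the window are skipped.
#'
#' @param input,output Aligned traces.
#' @param transitions_s Transition times (s).
#' @param frame_rate_hz Sample rate.
#' @param window_s Post-transition search window (default 2 s).
#' @param smooth_s Width of a centered moving-average applied before
#'   peak finding (default 0: none). Useful when residual
#'   contrast-reversal flicker would otherwise jitter the argmax.
#' @return List with per-transition `deltas_s` and their `median_s`.
#' @export
time_to_peak_delta <- function(input, output, transitions_s,
                               frame_rate_hz, window_s = 2,
                               smooth_s = 0) {
  if (smooth_s > 0) {
    k <- max(1L, round(smooth_s * frame_rate_hz))
    sm <- function(x) {
      y <- stats::filter(x, rep(1 / k, k), sides = 2)
      y[is.na(y)] <- x[is.na(y)]
      as.numeric(y)
    }
    input <- sm(input); output <- sm(output)
  }
  n <- length(input)
  deltas <- numeric(0)
  for (t0 in transitions_s) {
    i0 <- floor(t0 * frame_rate_hz) + 1L
    i1 <- min(n, i0 + round(window_s * frame_rate_hz))
    if (i0 >= i1) next
    xin <- input[i0:i1]; xout <- output[i0:i1]
    if (max(xin) == min(xin) || max(xout) == min(xout)) next
    deltas <- c(deltas,
                (which.max(xout) - which.max(xin)) / frame_rate_hz)
  }
  list(deltas_s = deltas, median_s = stats::median(deltas))
}

#' Squared Pearson correlation between input and output
#'
#' @param input,output Equal-length traces.
#' @return R-squared; errors when either trace has zero variance.
#' @export
input_output_r2 <- function(input, output) {
  if (length(input) != length(output)) stop("traces must have equal length")
  if (stats::sd(input) == 0 || stats::sd(output) == 0)
    stop("R^2 undefined for a zero-variance trace")
  stats::cor(input, output)^2
}

#' Short-time Fourier power spectrogram
#'
#' @param trace Signal.
#' @param frame_rate_hz Sample rate.
#' @param window_s STFT window length (default 2 s).
#' @param overlap Fractional window overlap (default 0.5).
#' @return List with `t_s`, `freq_hz` and the `time x frequency` power
#'   matrix `power`.
#' @export
spectrogram <- function(trace, frame_rate_hz, window_s = 2,
                        overlap = 0.5) {
  nwin <- round(window_s * frame_rate_hz)
  if (nwin >= length(trace)) stop("window longer than trace")
  sp <- signal::specgram(trace, n = nwin, Fs = frame_rate_hz,
                         overlap = round(overlap * nwin))
  list(t_s = as.numeric(sp$t), freq_hz = as.numeric(sp$f),
       power = t(Mod(sp$S)^2))
}

#' Band power of a trace up to a cutoff frequency
#'
#' Convenience summary for comparing how strongly sustained/flicker
#' components are attenuated between input and output.
#'
#' @param trace Signal.
#' @param frame_rate_hz Sample rate.
#' @param band_hz Length-2 frequency band (default 0 to 5 Hz).
#' @return Total spectral power in the band.
#' @export
band_power <- function(trace, frame_rate_hz, band_hz = c(0, 5)) {
  n <- length(trace)
  P <- Mod(stats::fft(trace))^2 / n
  f <- (seq_len(n) - 1) * frame_rate_hz / n
  keep <- f >= band_hz[1] & f <= band_hz[2] & f <= frame_rate_hz / 2
  sum(P[keep])
}
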