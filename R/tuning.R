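#' Event-aligned response detection
#'
#' Implements the response rules used for grating transitions. The
#' baseline is the `baseline_s` (default 15 s) preceding the
#' transition; a response occurred if the signal differs from the
#' baseline median by more than `threshold_mult` (default 4) times the
#' baseline's raw median absolute deviation. The response value is
#' transient-aware: if the maximum within `transient_s` (default 0.5 s)
#' after the transition exceeds the median over the whole `epoch_s`
#' (default 10 s) epoch by more than 4 times the epoch MAD, the maximum
#' is taken as the response; otherwise the epoch median is.
#'
#' @param trace dF/F trace.
#' @param transition_time_s Transition time (s from trace start).
#' @param frame_rate_hz Sampling rate.
#' @param baseline_s,epoch_s,transient_s Window lengths (s).
#' @param threshold_mult Response threshold in baseline-MAD units.
#' @return Object of class `event_aligned_response` with fields
#'   `baseline_median`, `baseline_mad`, `epoch_median`,
#'   `transient_peak`, `is_transient`, `amplitude`, `responded`.
#' @export
detect_response <- function(trace, transition_time_s, frame_rate_hz,
                            baseline_s = 15, epoch_s = 10,
                            transient_s = 0.5, threshold_mult = 4) {
  n <- length(trace)
  i0 <- floor(transition_time_s * frame_rate_hz) + 1L
  if (i0 < 1 || i0 > n) stop("transition time outside trace")
  nb <- round(baseline_s * frame_rate_hz)
  b0 <- max(1L, i0 - nb)
  if (i0 - b0 < nb && i0 > 1)
    warning("baseline truncated to available pre-transition data")
  bidx <- if (i0 > 1) b0:(i0 - 1L) else i0
  eidx <- i0:min(n, i0 + round(epoch_s * frame_rate_hz) - 1L)
  tidx <- i0:min(n, i0 + round(transient_s * frame_rate_hz) - 1L)

  b_med <- stats::median(trace[bidx])
  b_mad <- mad_raw(trace[bidx])
  e_med <- stats::median(trace[eidx])
  e_mad <- mad_raw(trace[eidx])
  t_peak <- max(trace[tidx])
  is_transient <- t_peak > e_med + threshold_mult * e_mad
  amplitude <- if (is_transient) t_peak else e_med
  out <- list(transition_time_s = transition_time_s,
              baseline_median = b_med, baseline_mad = b_mad,
              epoch_median = e_med, epoch_mad = e_mad,
              transient_peak = t_peak, is_transient = is_transient,
              amplitude = amplitude,
              responded = abs(amplitude - b_med) > threshold_mult * b_mad)
  class(out) <- "event_aligned_response"
  out
}

#' Orientation selectivity index
#'
#' `OSI = |a - b| / (|a| + |b|)` for the responses `a` and `b` to the
#' last two orthogonal grating orientations. Always lies in `[0, 1]`
#' and is invariant to common positive scaling.
#'
#' @param a,b Responses to the two orthogonal orientations.
#' @return OSI in `[0, 1]`.
#' @examples
#' compute_osi(0.75, 0.25)  # 0.5
#' @export
compute_osi <- function(a, b) {
  if (abs(a) + abs(b) == 0)
    stop("OSI undefined: both responses are zero")
  abs(a - b) / (abs(a) + abs(b))
}

# epoch boundaries (grating_on + switches/phase steps), each epoch
# [start, end) in seconds; last ends at trace end
grating_epochs <- function(events, n_frames, frame_rate_hz) {
  ev <- events[events$kind %in% c("grating_on", "orientation_switch",
                                  "phase_step"), , drop = FALSE]
  if (!nrow(ev)) stop("no grating events in log")
  starts <- ev$time_s
  ends <- c(starts[-1], n_frames / frame_rate_hz)
  ori <- vapply(ev$payload, function(p)
    as.numeric(p$orientation_deg %||% NA_real_), 0)
  data.frame(start_s = starts, end_s = ends, kind = ev$kind,
             orientation_deg = ori)
}

epoch_indices <- function(start_s, end_s, frame_rate_hz, n) {
  i0 <- floor(start_s * frame_rate_hz) + 1L
  i1 <- min(n, ceiling(end_s * frame_rate_hz))
  i0:max(i0, i1)
}

#' Classify a retinal ganglion cell from its grating response
#'
#' A cell is `dpc` (dynamic predictive coding) if it responds with a
#' transient at *every* orientation transition exceeding the steady
#' state of the previous epoch by at least `sd_mult` (default 4)
#' standard deviations of that steady state. Otherwise it is
#' `static_os` if the responses to the final two gratings differ by 4
#' standard deviations of their steady-state responses; otherwise
#' `contrast_only` if only the grating-onset response exceeds
#' threshold; otherwise `non_os`.
#'
#' @param trace dF/F trace of the cell's output.
#' @param events [event_log()] of the grating protocol.
#' @param frame_rate_hz Sampling rate.
#' @param sd_mult Threshold multiplier (default 4).
#' @param steady_frac Final fraction of each epoch treated as its
#'   steady state (default 0.5).
#' @param transient_s Post-transition window for transient peaks.
#' @param smooth_s Centered moving-average width applied before the
#'   rules (default 0.25 s, one contrast-reversal cycle): the
#'   steady-state dispersion should reflect noise, not stimulus-locked
#'   flicker.
#' @return Character label: `"dpc"`, `"static_os"`, `"contrast_only"`
#'   or `"non_os"`.
#' @export
classify_rgc <- function(trace, events, frame_rate_hz, sd_mult = 4,
                         steady_frac = 0.5, transient_s = 1,
                         smooth_s = 0.25) {
  if (!nrow(events)) stop("no events supplied")
  # flicker-smoothed copy used by the transient (dpc) rule only; the
  # steady-state rules use the raw trace's dispersion
  smoothed <- trace
  if (smooth_s > 0) {
    k <- max(1L, round(smooth_s * frame_rate_hz))
    sm <- stats::filter(trace, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- trace[is.na(sm)]
    smoothed <- as.numeric(sm)
  }
  n <- length(trace)
  ep <- grating_epochs(events, n, frame_rate_hz)
  sw <- which(ep$kind == "orientation_switch")
  if (length(sw) < 2) stop("need at least 2 orientation transitions")

  steady <- function(e) {
    idx <- epoch_indices(ep$start_s[e], ep$end_s[e], frame_rate_hz, n)
    k <- length(idx)
    idx[max(1, floor((1 - steady_frac) * k) + 1):k]
  }
  transient_peak <- function(t_s, x) {
    idx <- epoch_indices(t_s, t_s + transient_s, frame_rate_hz, n)
    max(x[idx])
  }

  # dpc rule: transient at every transition vs prior steady state
  dpc_ok <- vapply(sw, function(e) {
    s <- smoothed[steady(e - 1)]
    transient_peak(ep$start_s[e], smoothed) >
      stats::median(s) + sd_mult * stats::sd(s)
  }, logical(1))
  if (all(dpc_ok)) return("dpc")

  # static OS rule on final two epochs
  n_ep <- nrow(ep)
  s1 <- trace[steady(n_ep - 1)]; s2 <- trace[steady(n_ep)]
  pooled_sd <- sqrt((stats::var(s1) + stats::var(s2)) / 2)
  if (abs(stats::median(s2) - stats::median(s1)) > sd_mult * pooled_sd)
    return("static_os")

  # any detectable switch response at all?
  sw_resp <- vapply(sw, function(e) {
    s <- trace[steady(e - 1)]
    thr <- sd_mult * max(stats::sd(s), .Machine$double.eps)
    idx <- epoch_indices(ep$start_s[e], ep$end_s[e], frame_rate_hz, n)
    transient_peak(ep$start_s[e], trace) > stats::median(s) + thr ||
      abs(stats::median(trace[idx]) - stats::median(s)) > thr
  }, logical(1))

  onset_t <- ep$start_s[1]
  onset_resp <- if (onset_t > 0) {
    pre <- trace[seq_len(max(1, floor(onset_t * frame_rate_hz)))]
    transient_peak(onset_t, trace) >
      stats::median(pre) + sd_mult * max(stats::sd(pre), .Machine$double.eps)
  } else TRUE

  if (!any(sw_resp) && onset_resp) "contrast_only" else "non_os"
}

#' Grating OSI for presynaptic calcium recordings
#'
#' OSI computed from the median dF/F amplitudes over the final two
#' (orthogonal) grating epochs, `a` at 90 deg and `b` at 0 deg. An OSI
#' is only assigned if `|a - b|` exceeds `mad_mult` (default 2) times
#' the raw MAD of the smaller response's epoch; otherwise the OSI is
#' undefined (`NA`).
#'
#' @param trace dF/F trace.
#' @param events [event_log()] with orientation payloads.
#' @param frame_rate_hz Sampling rate.
#' @param epoch_s Nominal epoch length (s); shorter epochs are used in
#'   full with a warning.
#' @param mad_mult Gate multiplier (default 2).
#' @return List with `osi` (or `NA`), `a`, `b`, `defined`,
#'   `preferred_orientation_deg`.
#' @export
grating_osi_sygcamp <- function(trace, events, frame_rate_hz,
                                epoch_s = 10, mad_mult = 2) {
  n <- length(trace)
  ep <- grating_epochs(events, n, frame_rate_hz)
  if (nrow(ep) < 2) stop("need at least two grating epochs")
  ep2 <- ep[(nrow(ep) - 1):nrow(ep), ]
  d_ori <- abs(ep2$orientation_deg[1] - ep2$orientation_deg[2]) %% 180
  if (!isTRUE(all.equal(d_ori, 90)))
    stop("final two epochs are not orthogonal")
  if (any(ep2$end_s - ep2$start_s < epoch_s - 1e-9))
    warning("epochs shorter than nominal length; using available span")
  med <- numeric(2); madv <- numeric(2)
  for (i in 1:2) {
    idx <- epoch_indices(ep2$start_s[i], ep2$end_s[i], frame_rate_hz, n)
    med[i] <- stats::median(trace[idx])
    madv[i] <- mad_raw(trace[idx])
  }
  # a = response at 90 deg, b = at 0 deg (generalised: larger-angle epoch)
  ord <- order(ep2$orientation_deg, decreasing = TRUE)
  a <- med[ord[1]]; b <- med[ord[2]]
  smaller <- which.min(abs(med))
  defined <- abs(a - b) > mad_mult * madv[smaller]
  list(osi = if (defined) compute_osi(a, b) else NA_real_,
       a = a, b = b, defined = defined,
       preferred_orientation_deg =
         if (defined) ep2$orientation_deg[which.max(med)] else NA_real_)
}

#' Orientation-space vector sum for one trial
#'
#' Responses to opposite motion directions are pooled into
#' `n_directions / 2` orientations and summed as vectors in
#' doubled-angle orientation space:
#' `v = sum_k r_k (cos 2 theta_k, sin 2 theta_k)`. Negative pooled
#' responses are clipped to 0.
#'
#' @param responses Response to each motion direction (one trial).
#' @param directions_deg Motion directions; opposite pairs are pooled.
#' @return Length-2 numeric vector `(x, y)` in orientation space.
#' @export
orientation_vector_sum <- function(responses,
                                   directions_deg = seq(0, 315, by = 45)) {
  stopifnot(length(responses) == length(directions_deg))
  ori <- directions_deg %% 180
  pooled <- tapply(responses, ori, mean)
  th <- as.numeric(names(pooled)) * pi / 180
  r <- pmax(as.numeric(pooled), 0)
  c(x = sum(r * cos(2 * th)), y = sum(r * sin(2 * th)))
}

#' Moore-Rayleigh statistic for a set of trial vectors
#'
#' Rank-based test for directional concentration: trial vectors are
#' ranked by magnitude (average ranks on ties) and
#' `R* = sqrt((sum_i i cos phi_i)^2 + (sum_i i sin phi_i)^2) / n^(3/2)`
#' with `phi_i` the angle of the vector of rank `i`. Invariant to a
#' common rotation of all vectors and to any strictly monotone
#' rescaling of their magnitudes.
#'
#' @param vectors `n x 2` matrix of trial vectors (n >= 3), e.g. rows
#'   from [orientation_vector_sum()].
#' @return The statistic `R*` (non-negative scalar).
#' @examples
#' v <- matrix(rep(c(1, 0), each = 10), ncol = 2)  # identical directions
#' moore_rayleigh_stat(v * (1:10))                 # = 55 / 10^1.5
#' @export
moore_rayleigh_stat <- function(vectors) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 3) stop("need at least 3 trial vectors")
  mag <- sqrt(rowSums(vectors^2))
  rk <- rank(mag, ties.method = "average")
  phi <- atan2(vectors[, 2], vectors[, 1])
  phi[mag == 0] <- 0  # zero vectors carry the lowest ranks anyway
  sqrt(sum(rk * cos(phi))^2 + sum(rk * sin(phi))^2) / n^1.5
}

#' Per-terminal Moore-Rayleigh statistic from a trial table
#'
#' @param trial_table `trials x directions` matrix of responses.
#' @param directions_deg Motion directions of the columns.
#' @return The Moore-Rayleigh statistic of the per-trial orientation
#'   vectors.
#' @export
moving_bar_stat <- function(trial_table,
                            directions_deg = seq(0, 315, by = 45)) {
  v <- t(apply(trial_table, 1, orientation_vector_sum,
               directions_deg = directions_deg))
  moore_rayleigh_stat(v)
}

#' Shuffle-calibrated critical value for the Moore-Rayleigh test
#'
#' The whole population is re-analysed with the angle information
#' shuffled: within each terminal, each trial's responses are randomly
#' permuted across direction labels (independently per trial, seeded).
#' The critical value is set so that exactly `ceiling(fpr * N)` of the
#' shuffled population reaches it, giving a design false-positive rate
#' of `fpr` (default 1%).
#'
#' @param trial_tables List of `trials x directions` response matrices,
#'   one per terminal (>= 100 terminals for a stable 1% quantile).
#' @param directions_deg Motion directions of the table columns.
#' @param fpr Design false-positive rate (default 0.01).
#' @param seed Shuffle seed.
#' @return The calibrated critical value of the statistic.
#' @export
calibrate_critical_value <- function(trial_tables,
                                     directions_deg = seq(0, 315, by = 45),
                                     fpr = 0.01, seed = 1) {
  N <- length(trial_tables)
  if (N < 100) stop("need >= 100 terminals for a stable calibration")
  stats_sh <- with_seed(seed, vapply(trial_tables, function(tab) {
    sh <- t(apply(tab, 1, sample))
    moving_bar_stat(sh, directions_deg)
  }, numeric(1)))
  sort(stats_sh, decreasing = TRUE)[ceiling(fpr * N)]
}

#' Classify terminals as orientation-selective by the calibrated test
#'
#' @param trial_tables List of `trials x directions` response matrices.
#' @param critical_value Critical value from
#'   [calibrate_critical_value()].
#' @param directions_deg Motion directions.
#' @return Data frame with `moore_stat` and logical `is_os` per
#'   terminal.
#' @export
classify_os_moving_bars <- function(trial_tables, critical_value,
                                    directions_deg = seq(0, 315, by = 45)) {
  st <- vapply(trial_tables, moving_bar_stat, numeric(1),
               directions_deg = directions_deg)
  data.frame(moore_stat = st, is_os = st >= critical_value)
}

#' Fit a double exponential to a decaying response
#'
#' Least-squares fit of
#' `y(t) = y0 + A1 exp(-(t - t0)/tau1) + A2 exp(-(t - t0)/tau2)` with
#' `tau1 < tau2`, by multi-start Levenberg-Marquardt over log-spaced
#' initial time constants (bounds: one sample interval to the trace
#' length). A pure single-exponential candidate (`A2 = 0`) is included
#' and preferred when it fits equally well.
#'
#' @param y Response values.
#' @param t_s Sample times (s).
#' @param t0_s Decay onset time (default `t_s[1]`).
#' @return Object of class `double_exp_fit`: the parameters plus
#'   `fraction_fast = A1 / (A1 + A2)`, `rss` and `r_squared`.
#' @export
fit_double_exponential <- function(y, t_s, t0_s = NULL) {
  t0_s <- t0_s %||% t_s[1]
  keep <- t_s >= t0_s
  y <- y[keep]; ts <- t_s[keep] - t0_s
  if (length(y) < 5) stop("too few samples after t0")
  dt <- stats::median(diff(ts))
  span <- max(ts)

  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    out <- list(y0 = mean(y), A1 = 0, tau1_s = dt, A2 = 0, tau2_s = span,
                t0_s = t0_s, fraction_fast = NA_real_, rss = 0,
                r_squared = 1)
    class(out) <- "double_exp_fit"
    return(out)
  }

  y0_init <- mean(utils::tail(y, max(3, round(length(y) / 10))))
  A_init <- y[1] - y0_init
  dat <- data.frame(ts = ts, y = y)
  lower <- c(-Inf, 0, dt / 2, 0, dt / 2)
  upper <- c(Inf, Inf, 2 * span, Inf, 2 * span)
  tau_grid <- exp(seq(log(max(dt, span / 200)), log(span), length.out = 4))

  best <- NULL; best_rss <- Inf
  try_fit <- function(start, single) {
    fit <- tryCatch(
      if (single) {
        minpack.lm::nlsLM(y ~ y0 + A1 * exp(-ts / tau1), data = dat,
                          start = start[c("y0", "A1", "tau1")],
                          lower = lower[1:3], upper = upper[1:3],
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ y0 + A1 * exp(-ts / tau1) +
                            A2 * exp(-ts / tau2), data = dat,
                          start = start, lower = lower, upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }, error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(coef = stats::coef(fit), rss = sum(stats::resid(fit)^2),
         single = single)
  }

  best_single <- NULL
  for (i in seq_along(tau_grid)) {
    f <- try_fit(list(y0 = y0_init, A1 = max(A_init, 1e-6),
                      tau1 = tau_grid[i]), single = TRUE)
    if (!is.null(f) && (is.null(best_single) || f$rss < best_single$rss))
      best_single <- f
  }
  if (!is.null(best_single)) { best <- best_single; best_rss <- best$rss }
  for (i in seq_along(tau_grid)) for (j in seq_along(tau_grid)) {
    if (tau_grid[j] <= tau_grid[i]) next
    f <- try_fit(list(y0 = y0_init, A1 = max(A_init / 2, 1e-6),
                      tau1 = tau_grid[i], A2 = max(A_init / 2, 1e-6),
                      tau2 = tau_grid[j]), single = FALSE)
    if (!is.null(f) && f$rss < best_rss) { best <- f; best_rss <- f$rss }
  }
  if (is.null(best)) stop("double-exponential fit failed to converge")
  # prefer the single-exponential solution when it fits equally well
  tss <- sum((y - mean(y))^2)
  if (!best$single && !is.null(best_single) &&
      best_single$rss <= best_rss + 1e-9 * tss) {
    best <- best_single; best_rss <- best$rss
  }
  cf <- best$coef
  if (best$single) {
    pars <- c(y0 = unname(cf["y0"]), A1 = unname(cf["A1"]),
              tau1 = unname(cf["tau1"]), A2 = 0, tau2 = span)
  } else {
    pars <- c(y0 = unname(cf["y0"]), A1 = unname(cf["A1"]),
              tau1 = unname(cf["tau1"]), A2 = unname(cf["A2"]),
              tau2 = unname(cf["tau2"]))
    if (pars["tau1"] > pars["tau2"]) {
      pars <- pars[c("y0", "A2", "tau2", "A1", "tau1")]
      names(pars) <- c("y0", "A1", "tau1", "A2", "tau2")
    }
  }
  atot <- pars["A1"] + pars["A2"]
  out <- list(y0 = unname(pars["y0"]), A1 = unname(pars["A1"]),
              tau1_s = unname(pars["tau1"]), A2 = unname(pars["A2"]),
              tau2_s = unname(pars["tau2"]), t0_s = t0_s,
              fraction_fast = if (atot > 0) unname(pars["A1"] / atot)
                              else NA_real_,
              rss = best$rss, r_squared = 1 - best$rss / tss)
  class(out) <- "double_exp_fit"
  out
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf(
    "<double_exp_fit> y0 %.3g + %.3g exp(-t/%.3g) + %.3g exp(-t/%.3g), R^2 %.4f\n",
    x$y0, x$A1, x$tau1_s, x$A2, x$tau2_s, x$r_squared))
  invisible(x)
}

#' Preferred orientation of a tuning table
#'
#' Either the argmax orientation (suited to the 4-orientation moving
#' bar protocol) or half the angle of the mean doubled-angle response
#' vector (a continuous estimator).
#'
#' @param responses Response per orientation (negative values clipped
#'   to 0 for the vector estimator).
#' @param orientations_deg Orientations of the responses.
#' @param method `"argmax"` or `"vector"`.
#' @return Preferred orientation in `[0, 180)` degrees, or `NA` with a
#'   warning for all-zero or tied responses.
#' @export
preferred_orientation <- function(responses, orientations_deg,
                                  method = c("argmax", "vector")) {
  method <- match.arg(method)
  if (length(responses) < 2) stop("need at least 2 orientations")
  if (all(responses == 0)) {
    warning("all responses zero; preferred orientation undefined")
    return(NA_real_)
  }
  if (method == "argmax") {
    mx <- max(responses)
    at <- which(responses == mx)
    if (length(at) > 1) {
      warning("tied maximal responses; preferred orientation undefined")
      return(NA_real_)
    }
    orientations_deg[at] %% 180
  } else {
    r <- pmax(responses, 0)
    th <- orientations_deg * pi / 90  # doubled angle
    vx <- sum(r * cos(th)); vy <- sum(r * sin(th))
    if (vx^2 + vy^2 < 1e-24) {
      warning("zero mean vector; preferred orientation undefined")
      return(NA_real_)
    }
    (atan2(vy, vx) * 90 / pi) %% 180
  }
}
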