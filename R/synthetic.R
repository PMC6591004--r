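#' 2D Gaussian receptive field
#'
#' Parameterises a receptive-field center as a rotated anisotropic
#' Gaussian. `theta_deg` uses the stimulus orientation convention: it is
#' the orientation of the grating whose bars run along the RF's major
#' axis (0 = major axis vertical), so an elongated RF's preferred
#' grating orientation equals its `theta_deg`.
#'
#' @param center_x_deg,center_y_deg RF center in visual degrees.
#' @param major_sigma_deg,minor_sigma_deg Gaussian sigmas along the
#'   major/minor axes; `major >= minor > 0`.
#' @param theta_deg Major-axis orientation in `[0, 180)` (stimulus
#'   convention).
#' @param amplitude Peak amplitude (default 1).
#' @return Object of class `gaussian_rf`.
#' @export
gaussian_rf <- function(center_x_deg = 0, center_y_deg = 0,
                        major_sigma_deg = 3, minor_sigma_deg = 1.5,
                        theta_deg = 0, amplitude = 1) {
  stopifnot_scalar_pos(major_sigma_deg, "major_sigma_deg")
  stopifnot_scalar_pos(minor_sigma_deg, "minor_sigma_deg")
  if (minor_sigma_deg > major_sigma_deg)
    stop("major_sigma_deg must be >= minor_sigma_deg")
  rf <- list(center_x_deg = center_x_deg, center_y_deg = center_y_deg,
             major_sigma_deg = major_sigma_deg,
             minor_sigma_deg = minor_sigma_deg,
             theta_deg = theta_deg %% 180, amplitude = amplitude)
  class(rf) <- "gaussian_rf"
  rf
}

#' @export
print.gaussian_rf <- function(x, ...) {
  cat(sprintf(
    "<gaussian_rf> center (%.2f, %.2f) deg, sigma %.2f x %.2f deg, theta %.1f deg\n",
    x$center_x_deg, x$center_y_deg, x$major_sigma_deg, x$minor_sigma_deg,
    x$theta_deg))
  invisible(x)
}

#' Evaluate a Gaussian RF on a coordinate grid
#'
#' @param rf A [gaussian_rf()].
#' @param x,y Matrices of degree coordinates (e.g. from [pixel_grid()]).
#' @param normalize If `TRUE`, scale so the weights sum to 1
#'   (a normalized RF for drive computations).
#' @return Matrix of RF weights, same shape as `x`.
#' @export
evaluate_rf <- function(rf, x, y, normalize = FALSE) {
  th <- rf$theta_deg * pi / 180
  # major axis runs along the bars of a grating at orientation theta
  mj <- c(-sin(th), cos(th))
  mn <- c(cos(th), sin(th))
  dx <- x - rf$center_x_deg
  dy <- y - rf$center_y_deg
  um <- dx * mj[1] + dy * mj[2]
  un <- dx * mn[1] + dy * mn[2]
  g <- rf$amplitude * exp(-(um^2 / (2 * rf$major_sigma_deg^2) +
                              un^2 / (2 * rf$minor_sigma_deg^2)))
  if (normalize) {
    s <- sum(g)
    if (s <= 0) stop("RF has zero mass on this grid")
    g <- g / s
  }
  g
}

#' Double-exponential kinetics parameters
#'
#' Parameters of `y(t) = y0 + A1 exp(-(t - t0)/tau1) +
#' A2 exp(-(t - t0)/tau2)`, the form used both to describe synaptic
#' depression and to fit response decays. Defaults are the depression
#' kinetics of bipolar cell synapses: the response declines by 49% over
#' 10 s with time constants 0.21 s and 4.2 s carrying 61% and 39% of the
#' decay.
#'
#' @param y0 Steady-state level.
#' @param A1,A2 Amplitudes of the fast and slow components (>= 0).
#' @param tau1_s,tau2_s Fast and slow time constants; `tau1 < tau2`.
#' @param t0_s Onset time.
#' @return Object of class `double_exp_params`.
#' @export
double_exp_params <- function(y0 = 0.51, A1 = 0.49 * 0.61, tau1_s = 0.21,
                              A2 = 0.49 * 0.39, tau2_s = 4.2, t0_s = 0) {
  if (A1 < 0 || A2 < 0) stop("amplitudes must be non-negative")
  if (tau1_s >= tau2_s) stop("tau1_s must be < tau2_s")
  p <- list(y0 = y0, A1 = A1, tau1_s = tau1_s, A2 = A2, tau2_s = tau2_s,
            t0_s = t0_s)
  class(p) <- "double_exp_params"
  p
}

#' Ground-truth synaptic terminal
#'
#' A simulated bipolar-cell terminal whose orientation tuning arises
#' from one of three mechanisms: `untuned` (near-circular RF, no
#' inhibition), `elliptical` (elongated RF center only), or
#' `inhibition_sharpened` (elongated RF plus subtractive lateral
#' inhibition from a large pooling field tuned to the orthogonal
#' orientation). The inhibitory field is the RF rotated by 90 deg with
#' its major axis scaled by `pool_scale` (default 4, reflecting
#' receptive-field centers roughly 4-fold smaller than the spatial
#' patterns signalled most strongly).
#'
#' @param rf A [gaussian_rf()].
#' @param mechanism One of `"untuned"`, `"elliptical"`,
#'   `"inhibition_sharpened"`.
#' @param inhibition_gain Strength of the orthogonal-orientation
#'   subtraction (>= 0; forced to 0 unless `mechanism =
#'   "inhibition_sharpened"`).
#' @param adaptation A [double_exp_params()] describing synaptic
#'   depression.
#' @param indicator_tau_s Fluorescence indicator decay time constant.
#' @param noise_sd Per-pixel noise, in dF/F units, used when rendering.
#' @param position_px Length-2 vector `(x, y)` pixel position in the
#'   rendered fluorescence movie.
#' @param polarity Contrast polarity of the terminal: `-1` (OFF,
#'   default, responds to dark bars) or `+1` (ON).
#' @param amplitude_dff Peak dF/F response amplitude.
#' @param pool_scale Major-axis scale factor of the inhibitory pooling
#'   field.
#' @return Object of class `gt_terminal`.
#' @export
ground_truth_terminal <- function(rf, mechanism = c("untuned", "elliptical",
                                                    "inhibition_sharpened"),
                                  inhibition_gain = 0,
                                  adaptation = double_exp_params(),
                                  indicator_tau_s = 0.4, noise_sd = 0.1,
                                  position_px = c(1, 1), polarity = -1,
                                  amplitude_dff = 1, pool_scale = 4) {
  mechanism <- match.arg(mechanism)
  if (inhibition_gain < 0) stop("inhibition_gain must be >= 0")
  if (mechanism != "inhibition_sharpened") inhibition_gain <- 0
  inh_rf <- NULL
  if (mechanism == "inhibition_sharpened") {
    inh_rf <- gaussian_rf(rf$center_x_deg, rf$center_y_deg,
                          major_sigma_deg = pool_scale * rf$major_sigma_deg,
                          minor_sigma_deg = rf$minor_sigma_deg,
                          theta_deg = (rf$theta_deg + 90) %% 180)
  }
  t <- list(rf = rf, mechanism = mechanism, inhibition_gain = inhibition_gain,
            inh_rf = inh_rf, adaptation = adaptation,
            indicator_tau_s = indicator_tau_s, noise_sd = noise_sd,
            position_px = position_px, polarity = polarity,
            amplitude_dff = amplitude_dff)
  class(t) <- "gt_terminal"
  t
}

#' Linear stimulus drive of a terminal
#'
#' Per-frame drive = the sum over pixels of the terminal's normalized
#' 2D-Gaussian RF multiplied by the stimulus frame (signed contrast,
#' multiplied by the terminal's polarity), half-wave rectified. For
#' `inhibition_sharpened` terminals the rectified drive of the large
#' orthogonal-orientation pooling field, scaled by `inhibition_gain`, is
#' subtracted before the final rectification, so the pre-rectification
#' signal can fall below baseline at the non-preferred orientation.
#'
#' @param terminal A [ground_truth_terminal()].
#' @param movie A [stimulus_movie()]; the RF must lie inside the field.
#' @param rectify If `FALSE`, return the signed pre-rectification drive.
#' @return Numeric drive trace (one value per frame). The rectified
#'   trace carries the signed trace as attribute `"pre"`.
#' @export
linear_drive <- function(terminal, movie, rectify = TRUE) {
  geom <- movie$geometry
  rf <- terminal$rf
  if (abs(rf$center_x_deg) > geom$width_deg / 2 ||
      abs(rf$center_y_deg) > geom$height_deg / 2)
    stop("RF center outside the stimulus field")
  gr <- pixel_grid(geom)
  w <- evaluate_rf(rf, gr$x, gr$y, normalize = TRUE)
  d <- dim(movie$frames)
  fm <- matrix(movie$frames, nrow = d[1])       # time x (y*x), column-major
  e <- terminal$polarity * as.numeric(fm %*% as.numeric(w))
  # release-driving excitation is itself rectified (hyperpolarizing
  # contrast phases stop release but do not push the signal negative);
  # lateral inhibition is subtracted afterwards, so only it can pull
  # the signed signal below baseline
  pre <- pmax(e, 0)
  if (!is.null(terminal$inh_rf) && terminal$inhibition_gain > 0) {
    wi <- evaluate_rf(terminal$inh_rf, gr$x, gr$y, normalize = TRUE)
    i <- terminal$polarity * as.numeric(fm %*% as.numeric(wi))
    pre <- pre - terminal$inhibition_gain * pmax(i, 0)
  }
  if (!rectify) return(pre)
  out <- pmax(pre, 0)
  attr(out, "pre") <- pre
  out
}

#' Apply synaptic depression and indicator kinetics to a drive trace
#'
#' The drive is multiplied by a divisive gain carrying two depression
#' states with double-exponential kinetics: under a sustained full
#' drive each state decays as `exp(-t/tau_i)` and the gain is
#' `(y0 + A1 r1 + A2 r2) / (y0 + A1 + A2)`, so the steady-state /
#' peak ratio of a step response is exactly `y0 / (y0 + A1 + A2)`.
#' States recover toward 1 with the same time constants when the drive
#' is absent. The adapted drive is then low-pass filtered by a causal
#' exponential indicator kernel of time constant `indicator_tau_s`
#' (unit DC gain; the identity when `indicator_tau_s <= 0`).
#'
#' @param drive Non-negative drive trace.
#' @param adaptation A [double_exp_params()].
#' @param indicator_tau_s Indicator decay time constant (s).
#' @param dt Sample interval of `drive` (s).
#' @param drive_scale Drive level treated as full depression drive;
#'   defaults to `max(drive)`.
#' @param sat_frac Fraction of `drive_scale` at which the (smoothed)
#'   drive already depletes at the full rate; depression tracks mean
#'   release rate, so a contrast-reversing stimulus whose rectified
#'   drive is active half the time still depresses fully.
#' @param adapt_smooth_tau_s Smoothing time constant of the release
#'   rate seen by the depression states.
#' @return dF/F-scaled trace, same length as `drive`.
#' @export
apply_adaptation_and_indicator <- function(drive, adaptation,
                                           indicator_tau_s, dt,
                                           drive_scale = NULL,
                                           sat_frac = 0.3,
                                           adapt_smooth_tau_s = 0.2) {
  if (any(drive < 0)) stop("drive must be non-negative")
  drive_scale <- drive_scale %||% max(drive)
  u <- if (drive_scale > 0) {
    sm <- indicator_filter(drive, adapt_smooth_tau_s, dt)
    pmin(pmax(sm, drive * 0) / (sat_frac * drive_scale), 1)
  } else drive * 0
  p <- adaptation
  norm <- p$y0 + p$A1 + p$A2
  gain <- rep(1, length(drive))
  if (norm > 0 && (p$A1 > 0 || p$A2 > 0)) {
    r1 <- 1; r2 <- 1
    for (n in seq_along(drive)) {
      gain[n] <- (p$y0 + p$A1 * r1 + p$A2 * r2) / norm
      # dr/dt = -u r / tau + (1 - u)(1 - r) / tau, exact exponential step
      for (k in 1:2) {
        tau <- if (k == 1) p$tau1_s else p$tau2_s
        a <- (1 - u[n]) / tau
        b <- 1 / tau                       # u/tau + (1 - u)/tau
        tgt <- a / b
        if (k == 1) r1 <- tgt + (r1 - tgt) * exp(-b * dt)
        else        r2 <- tgt + (r2 - tgt) * exp(-b * dt)
      }
    }
  }
  adapted <- drive * gain
  indicator_filter(adapted, indicator_tau_s, dt)
}

#' Causal exponential indicator filter
#'
#' First-order low-pass with unit DC gain; the identity when `tau_s <= 0`.
#'
#' @param x Numeric trace.
#' @param tau_s Decay time constant (s).
#' @param dt Sample interval (s).
#' @return Filtered trace.
#' @export
indicator_filter <- function(x, tau_s, dt) {
  if (tau_s <= 0) return(x)
  a <- exp(-dt / tau_s)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
}

#' Noiseless dF/F trace of a terminal under a stimulus
#'
#' Drive, depression and indicator kinetics chained. In the default
#' `"calcium"` modality (a SyGCaMP-like presynaptic reporter) the
#' rectified release drive is adapted and indicator-filtered, and the
#' below-baseline part of the pre-rectification signal (present in
#' inhibition-sharpened terminals at their non-preferred orientation)
#' is indicator-filtered and added back, so the trace can dip below
#' baseline as presynaptic calcium does under strong lateral
#' inhibition. In the `"glutamate"` modality (iGluSnFR-like, reporting
#' released transmitter) the trace is the non-negative release signal
#' only: inhibition can silence release but not make it negative.
#'
#' @param terminal A [ground_truth_terminal()].
#' @param movie A [stimulus_movie()].
#' @param modality `"calcium"` (default) or `"glutamate"`.
#' @param glu_tau_s Indicator time constant used for the glutamate
#'   modality (iGluSnFR kinetics are much faster than calcium
#'   reporters; default 0.1 s).
#' @return dF/F trace, one sample per frame.
#' @export
terminal_dff_trace <- function(terminal, movie,
                               modality = c("calcium", "glutamate"),
                               glu_tau_s = 0.1) {
  modality <- match.arg(modality)
  dt <- 1 / movie$geometry$frame_rate_hz
  dr <- linear_drive(terminal, movie)
  pre <- attr(dr, "pre")
  pk <- max(dr)
  if (pk <= 0) return(rep(0, length(dr)))
  tau <- if (modality == "glutamate") glu_tau_s else terminal$indicator_tau_s
  pos <- apply_adaptation_and_indicator(dr / pk, terminal$adaptation,
                                        tau, dt, drive_scale = 1)
  if (modality == "glutamate") return(terminal$amplitude_dff * pos)
  neg <- indicator_filter(pmin(pre, 0) / pk, terminal$indicator_tau_s, dt)
  terminal$amplitude_dff * (pos + neg)
}

#' Population specification for the synthetic generator
#'
#' @param n_terminals Number of terminals.
#' @param fraction_os Fraction of orientation-selective terminals
#'   (deterministic count `round(n * fraction_os)`).
#' @param os_mix Named fractions of the OS subpopulation by mechanism;
#'   default 30% `elliptical`, 70% `inhibition_sharpened`, matching the
#'   two observed OSI populations (a broad one near 0.3 and one near 1).
#' @param pref_orientations_deg Candidate preferred orientations.
#' @param pref_weights Sampling weights over
#'   `pref_orientations_deg` (e.g. biased toward vertical = 0 deg).
#' @param major_sigma_deg Mean RF major-axis sigma.
#' @param ellipticity_os Target ellipticity (1 - minor/major) of tuned
#'   terminals (population median 0.30).
#' @param ellipticity_sd SD of sampled ellipticities.
#' @param rf_center_scatter_deg RF centers are scattered uniformly
#'   within this half-width of the screen center, decorrelating the
#'   contrast-reversal flicker phase across terminals as scattered
#'   receptive fields do in the retina.
#' @param inhibition_gain Gain of the orthogonal subtraction for
#'   inhibition-sharpened terminals.
#' @param noise_sd Rendering noise in dF/F units.
#' @param amplitude_dff Peak response amplitude in dF/F units.
#' @param indicator_tau_s Indicator time constant.
#' @param seed Seed governing all sampling.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_terminals = 20, fraction_os = 0.5,
                            os_mix = c(elliptical = 0.3,
                                       inhibition_sharpened = 0.7),
                            pref_orientations_deg = c(0, 90),
                            pref_weights = c(0.5, 0.5),
                            major_sigma_deg = 3, ellipticity_os = 0.30,
                            ellipticity_sd = 0.08,
                            rf_center_scatter_deg = 6,
                            inhibition_gain = 1,
                            noise_sd = 0.1, amplitude_dff = 1,
                            indicator_tau_s = 0.4, seed = 1) {
  if (abs(sum(os_mix) - 1) > 1e-8) stop("os_mix fractions must sum to 1")
  if (fraction_os < 0 || fraction_os > 1) stop("fraction_os must be in [0,1]")
  s <- as.list(environment())
  class(s) <- "population_spec"
  s
}

#' Sample a ground-truth terminal population
#'
#' Mechanism counts are deterministic (`round`), all randomness
#' (preferred orientations, ellipticity jitter, movie positions) flows
#' from `spec$seed`. Terminal positions are laid out on a jittered grid
#' of the `movie_nx x movie_ny` fluorescence canvas with a guaranteed
#' minimum spacing.
#'
#' @param spec A [population_spec()].
#' @param movie_nx,movie_ny Fluorescence-movie canvas size in pixels.
#' @param margin_px Margin kept free of terminal centers.
#' @return List of [ground_truth_terminal()] objects.
#' @export
sample_population <- function(spec, movie_nx = 64, movie_ny = 64,
                              margin_px = 6) {
  n <- spec$n_terminals
  n_os <- round(n * spec$fraction_os)
  n_inh <- round(n_os * spec$os_mix[["inhibition_sharpened"]])
  n_ell <- n_os - n_inh
  mech <- c(rep("inhibition_sharpened", n_inh), rep("elliptical", n_ell),
            rep("untuned", n - n_os))

  with_seed(spec$seed, {
    # grid positions with jitter, shuffled assignment
    n_side <- ceiling(sqrt(n))
    gx <- seq(margin_px, movie_nx - margin_px, length.out = n_side)
    gy <- seq(margin_px, movie_ny - margin_px, length.out = n_side)
    pos <- expand.grid(x = gx, y = gy)[sample.int(n_side^2, n), ]
    step <- min(diff(gx)[1] %||% movie_nx, diff(gy)[1] %||% movie_ny)
    pos$x <- pos$x + stats::runif(n, -0.15, 0.15) * step
    pos$y <- pos$y + stats::runif(n, -0.15, 0.15) * step

    prefs <- sample(spec$pref_orientations_deg, n, replace = TRUE,
                    prob = spec$pref_weights)
    lapply(seq_len(n), function(i) {
      e <- if (mech[i] == "untuned") {
        max(stats::rnorm(1, 0.02, 0.015), 0)
      } else {
        min(max(stats::rnorm(1, spec$ellipticity_os, spec$ellipticity_sd),
                0.1), 0.6)
      }
      major <- spec$major_sigma_deg * exp(stats::rnorm(1, 0, 0.1))
      sc <- spec$rf_center_scatter_deg
      rf <- gaussian_rf(stats::runif(1, -sc, sc), stats::runif(1, -sc, sc),
                        major_sigma_deg = major,
                        minor_sigma_deg = major * (1 - e),
                        theta_deg = prefs[i])
      ground_truth_terminal(
        rf, mechanism = mech[i],
        inhibition_gain = if (mech[i] == "inhibition_sharpened")
          spec$inhibition_gain else 0,
        indicator_tau_s = spec$indicator_tau_s, noise_sd = spec$noise_sd,
        position_px = c(pos$x[i], pos$y[i]),
        amplitude_dff = spec$amplitude_dff)
    })
  })
}

#' Render a fluorescence movie from terminal traces
#'
#' Each terminal is drawn as an isotropic Gaussian spot (peak 1) whose
#' intensity follows `f0 * (1 + trace)`; i.i.d. Gaussian noise of
#' standard deviation `noise_sd * f0` is added per pixel and frame.
#' Terminals closer than `min_spacing_px` trigger a warning (their spots
#' overlap) but are still rendered.
#'
#' @param terminals List of [ground_truth_terminal()].
#' @param traces List or matrix (`time x terminal`) of dF/F traces.
#' @param movie_nx,movie_ny Canvas size in pixels.
#' @param frame_rate_hz Frame rate of the traces.
#' @param psf_sigma_px Spot Gaussian sigma in pixels.
#' @param noise_sd Noise SD in dF/F units (`NULL` = use each terminal's
#'   own `noise_sd`; a scalar overrides).
#' @param f0 Baseline fluorescence level.
#' @param min_spacing_px Minimum allowed center spacing before warning.
#' @param seed Noise seed.
#' @return A [pixel_stack()].
#' @export
render_movie <- function(terminals, traces, movie_nx = 64, movie_ny = 64,
                         frame_rate_hz = 10, psf_sigma_px = 1.5,
                         noise_sd = NULL, f0 = 100, min_spacing_px = 4,
                         seed = 1) {
  if (is.list(traces)) traces <- do.call(cbind, traces)
  nt <- length(terminals)
  stopifnot(ncol(traces) == nt)
  nT <- nrow(traces)

  ctrs <- t(vapply(terminals, function(t) t$position_px, c(0, 0)))
  if (nt > 1) {
    dmin <- min(stats::dist(ctrs))
    if (dmin < min_spacing_px)
      warning(sprintf("terminal spacing %.2f px below minimum %.1f px",
                      dmin, min_spacing_px))
  }

  xs <- seq_len(movie_nx); ys <- seq_len(movie_ny)
  spots <- lapply(seq_len(nt), function(i) {
    dx2 <- outer(rep(1, movie_ny), (xs - ctrs[i, 1])^2)
    dy2 <- outer((ys - ctrs[i, 2])^2, rep(1, movie_nx))
    exp(-(dx2 + dy2) / (2 * psf_sigma_px^2))
  })

  base <- matrix(0, nT, movie_ny * movie_nx)
  for (i in seq_len(nt)) {
    base <- base + traces[, i, drop = FALSE] %*%
      matrix(as.numeric(spots[[i]]), 1)
  }
  data <- f0 * (1 + base)
  sd_noise <- (noise_sd %||% terminals[[1]]$noise_sd) * f0
  if (sd_noise > 0) {
    data <- data + with_seed(seed,
      matrix(stats::rnorm(length(data), 0, sd_noise), nT))
  }
  pixel_stack(array(data, c(nT, movie_ny, movie_nx)), frame_rate_hz)
}

#' Bundle of synthetic movie, ground truth, and noiseless traces
#'
#' @param movie A [pixel_stack()] fluorescence movie.
#' @param truth List of [ground_truth_terminal()].
#' @param traces `time x terminal` matrix of noiseless dF/F traces,
#'   aligned 1:1 with `truth`.
#' @param stimulus The driving [stimulus_movie()].
#' @return Object of class `synthetic_bundle`.
#' @export
synthetic_bundle <- function(movie, truth, traces, stimulus) {
  stopifnot(ncol(traces) == length(truth))
  b <- list(movie = movie, truth = truth, traces = traces,
            stimulus = stimulus)
  class(b) <- "synthetic_bundle"
  b
}

#' Generate a complete synthetic imaging session
#'
#' Samples a terminal population, computes each terminal's noiseless
#' dF/F trace under the stimulus, and renders the fluorescence movie.
#'
#' @param spec A [population_spec()].
#' @param stimulus A [stimulus_movie()].
#' @param movie_nx,movie_ny Fluorescence canvas in pixels.
#' @param psf_sigma_px Spot sigma.
#' @param f0 Baseline fluorescence.
#' @return A [synthetic_bundle()].
#' @export
generate_synthetic_bundle <- function(spec, stimulus, movie_nx = 64,
                                      movie_ny = 64, psf_sigma_px = 1.5,
                                      f0 = 100) {
  truth <- sample_population(spec, movie_nx, movie_ny)
  traces <- vapply(truth, terminal_dff_trace, movie = stimulus,
                   numeric(dim(stimulus$frames)[1]))
  movie <- render_movie(truth, traces, movie_nx, movie_ny,
                        frame_rate_hz = stimulus$geometry$frame_rate_hz,
                        psf_sigma_px = psf_sigma_px,
                        noise_sd = spec$noise_sd, f0 = f0,
                        seed = spec$seed + 7919L)
  synthetic_bundle(movie, truth, traces, stimulus)
}

#' Simulate an RGC session from a mixture of terminal inputs
#'
#' The dendritic input traces are the terminals' dF/F traces under the
#' stimulus; the ganglion-cell output is the model-1 transform of the
#' summed input (high-pass FFI filter then threshold-linear
#' rectification) when `ffi = "on"`, or a thresholded copy of the summed
#' input when `ffi = "off"`.
#'
#' @param terminals List of [ground_truth_terminal()] inputs (>= 1).
#' @param stimulus A [stimulus_movie()].
#' @param ffi `"on"` or `"off"`.
#' @param filter A [temporal_filter()] for model 1; default
#'   [ffi_kernel_biphasic()] at the stimulus frame interval.
#' @param weights Input weights (default equal).
#' @param noise_sd Gaussian noise added to input and output traces.
#' @param threshold_mult Nonlinearity threshold in baseline-noise units.
#' @param glu_tau_s Effective time constant of the summed dendritic
#'   glutamate signal (indicator kinetics plus dendritic averaging;
#'   default 0.25 s).
#' @param seed Noise seed.
#' @return List with `inputs` (matrix), `input_sum`, `output`, `events`,
#'   `frame_rate_hz`, `ffi`.
#' @export
simulate_rgc_session <- function(terminals, stimulus, ffi = c("on", "off"),
                                 filter = NULL, weights = NULL,
                                 noise_sd = 0, threshold_mult = 3,
                                 glu_tau_s = 0.25, seed = 1) {
  ffi <- match.arg(ffi)
  if (length(terminals) < 1) stop("need at least one input terminal")
  dt <- 1 / stimulus$geometry$frame_rate_hz
  # dendritic input is released glutamate: non-negative by nature
  inputs <- vapply(terminals, terminal_dff_trace, movie = stimulus,
                   modality = "glutamate", glu_tau_s = glu_tau_s,
                   numeric(dim(stimulus$frames)[1]))
  weights <- weights %||% rep(1 / length(terminals), length(terminals))
  input_sum <- as.numeric(inputs %*% weights)
  if (noise_sd > 0) {
    input_sum <- input_sum + with_seed(seed,
      stats::rnorm(length(input_sum), 0, noise_sd))
  }
  baseline_idx <- baseline_frames(stimulus)
  if (ffi == "on") {
    filter <- filter %||% ffi_kernel_biphasic(dt)
    output <- apply_model1(input_sum, filter,
                           threshold_mult = threshold_mult,
                           baseline_idx = baseline_idx)
  } else {
    noise <- if (length(baseline_idx))
      stats::sd(input_sum[baseline_idx]) else 0
    output <- pmax(input_sum - threshold_mult * noise, 0)
  }
  if (noise_sd > 0) {
    output <- output + with_seed(seed + 1L,
      stats::rnorm(length(output), 0, noise_sd))
  }
  list(inputs = inputs, input_sum = input_sum, output = output,
       events = stimulus$events, frame_rate_hz = stimulus$geometry$frame_rate_hz,
       ffi = ffi)
}

# frames before the first logged event (pre-stimulus baseline), falling
# back to the first second of the record
baseline_frames <- function(stimulus) {
  fr <- stimulus$geometry$frame_rate_hz
  t1 <- if (nrow(stimulus$events)) stimulus$events$time_s[1] else Inf
  n <- dim(stimulus$frames)[1]
  idx <- seq_len(max(1, min(floor(t1 * fr), n)))
  if (length(idx) < 2) idx <- seq_len(min(n, max(2, round(fr))))
  idx
}
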