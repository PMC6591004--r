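#' Two-sided permutation test for RGC input composition
#'
#' Tests whether the tuned/untuned composition of the synapses sampled
#' on one RGC could arise by chance from the recorded population:
#' `N = sum(observed_counts)` synapses are drawn at random (without
#' replacement) from the population `n_resamples` times and the
#' two-sided p-value is the fraction of draws whose tuned count is at
#' least as far from its expectation as the observed one. The exact
#' hypergeometric version of the same probability is available with
#' `method = "exact"` (used as an oracle; the default mirrors the
#' resampling procedure).
#'
#' @param observed_counts Named or length-2 vector `c(tuned, untuned)`
#'   observed on the RGC.
#' @param population_labels Logical vector over the population
#'   (`TRUE` = tuned).
#' @param n_resamples Number of resamples (default 100000).
#' @param seed RNG seed for the resampling.
#' @param method `"resample"` (default) or `"exact"`.
#' @return The p-value.
#' @export
connectivity_permutation_test <- function(observed_counts,
                                          population_labels,
                                          n_resamples = 100000, seed = 1,
                                          method = c("resample", "exact")) {
  method <- match.arg(method)
  N <- sum(observed_counts)
  K <- sum(population_labels)
  M <- length(population_labels)
  if (N > M) stop("sampled more synapses than the population holds")
  obs_tuned <- observed_counts[[1]]
  expected <- N * K / M
  dev <- abs(obs_tuned - expected)
  if (method == "exact") {
    k <- 0:N
    return(sum(stats::dhyper(k, K, M - K, N)[abs(k - expected) >=
                                               dev - 1e-9]))
  }
  sims <- with_seed(seed, stats::rhyper(n_resamples, K, M - K, N))
  mean(abs(sims - expected) >= dev - 1e-9)
}

#' Vertical-to-horizontal input ratio of an RGC
#'
#' `R_0/90 = n_vertical / (n_vertical + n_horizontal)`: the fraction of
#' an RGC's orientation-tuned inputs preferring the vertical (0 deg).
#' Cells receiving a mixture of both tunings sit near 0.5; cells wired
#' to a single orientation sit at the extremes. Undefined (error) when
#' the cell has no tuned inputs at all.
#'
#' @param n_vertical,n_horizontal Counts of vertically / horizontally
#'   preferring inputs.
#' @return The ratio in `[0, 1]`.
#' @export
r_ratio <- function(n_vertical, n_horizontal) {
  if (n_vertical < 0 || n_horizontal < 0) stop("counts must be >= 0")
  if (n_vertical + n_horizontal == 0)
    stop("R_0/90 undefined: no orientation-tuned inputs")
  n_vertical / (n_vertical + n_horizontal)
}

#' Input tuning profile of an RGC
#'
#' @param labels Character vector over the RGC's inputs with values
#'   `"vertical"`, `"horizontal"` or `"untuned"`.
#' @return List with counts `n_v`, `n_h`, `n_u` and `r_0_90` (`NA`
#'   with a warning when no input is tuned).
#' @export
rgc_input_profile <- function(labels) {
  n_v <- sum(labels == "vertical")
  n_h <- sum(labels == "horizontal")
  n_u <- sum(labels == "untuned")
  r <- if (n_v + n_h > 0) r_ratio(n_v, n_h) else {
    warning("no tuned inputs; R_0/90 undefined")
    NA_real_
  }
  list(n_v = n_v, n_h = n_h, n_u = n_u, r_0_90 = r)
}

#' Default pipeline configuration
#'
#' A fully serializable nested list of the parameters for every stage
#' of an end-to-end synthetic run; a run is reproducible from its
#' config alone. See the methods vignette for the rationale behind the
#' default problem sizes.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory (`NULL` = no artifacts written).
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    stimulus = list(width_deg = 30, height_deg = 30, pixels_per_degree = 2,
                    frame_rate_hz = 20, spatial_frequency_cpd = 0.1,
                    reversal_hz = 5, epoch_s = 10, n_epochs = 6,
                    pre_s = 3),
    population = list(n_terminals = 20, fraction_os = 0.5,
                      noise_sd = 0.1, amplitude_dff = 1,
                      inhibition_gain = 1, indicator_tau_s = 0.4),
    movie = list(nx = 64, ny = 64, psf_sigma_px = 1.5, f0 = 100),
    segmentation = list(threshold = 0.3, min_quality = 4,
                        match_radius_px = 3),
    sessions = list(n_per_type = 4, n_inputs = 8, noise_sd = 0.01,
                    n_tuned_pool = 40, n_untuned_pool = 30),
    rf = list(enabled = TRUE, extent_deg = 19.2, spacing_deg = 3.2,
              pixels_per_degree = 2, frame_rate_hz = 10,
              n_terminals = 2, n_repeats = 3, noise_sd = 0.03)
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Save / load a pipeline configuration as YAML
#'
#' Round-trips losslessly: `load_run_config(save_run_config(cfg, f))`
#' equals `cfg`.
#'
#' @param config A [pipeline_config()] list.
#' @param path YAML file path.
#' @return `save_run_config` returns `path` invisibly;
#'   `load_run_config` returns a `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("run_config", "list")
  cfg
}

# build the alternating-orientation stimulus described by cfg$stimulus
pipeline_stimulus <- function(sc) {
  geom <- screen_geometry(sc$width_deg, sc$height_deg,
                          sc$pixels_per_degree, sc$frame_rate_hz)
  make_orientation_switch_movie(
    geom, sc$spatial_frequency_cpd, reversal_hz = sc$reversal_hz,
    epoch_s = sc$epoch_s,
    orientations_deg = rep(c(90, 0), length.out = sc$n_epochs),
    pre_s = sc$pre_s)
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates a ground-truth terminal population and fluorescence movie
#' under the orientation-switch protocol, segments the movie, scores
#' orientation tuning against ground truth, classifies simulated RGC
#' sessions (dynamic predictive coding with feedforward inhibition on,
#' statically tuned and orientation-insensitive with it off), runs the
#' model-1 / model-2 comparison, reconstructs receptive fields from a
#' flashed-bar protocol, and summarises the wiring statistics. All
#' randomness flows from `config$seed`; a rerun with the same config
#' yields a byte-identical summary.
#'
#' @param config A [pipeline_config()].
#' @return A list (invisibly also written as `summary.json`, with
#'   per-stage CSV/TIFF artifacts, when `config$out_dir` is set) with
#'   elements `segmentation`, `tuning`, `rgc_classification`,
#'   `model_comparison`, `rf_recovery`, `wiring`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  stim <- pipeline_stimulus(config$stimulus)
  fr <- config$stimulus$frame_rate_hz

  ## stage 1: population, traces, movie -------------------------------
  pop <- config$population
  spec <- population_spec(
    n_terminals = pop$n_terminals, fraction_os = pop$fraction_os,
    noise_sd = pop$noise_sd, amplitude_dff = pop$amplitude_dff,
    inhibition_gain = pop$inhibition_gain,
    indicator_tau_s = pop$indicator_tau_s, seed = seed)
  bundle <- generate_synthetic_bundle(
    spec, stim, movie_nx = config$movie$nx, movie_ny = config$movie$ny,
    psf_sigma_px = config$movie$psf_sigma_px, f0 = config$movie$f0)

  ## stage 2: segmentation and matching to ground truth ---------------
  base_idx <- seq_len(round(config$stimulus$pre_s * fr))
  rois <- segment(bundle$movie, threshold = config$segmentation$threshold,
                  min_quality = config$segmentation$min_quality,
                  baseline_idx = base_idx)
  centroids <- t(vapply(rois, function(r)
    c(mean(r$pixels[, "x"]), mean(r$pixels[, "y"])), c(0, 0)))
  match_r <- config$segmentation$match_radius_px
  matched <- vapply(bundle$truth, function(tm) {
    if (!length(rois)) return(NA_integer_)
    d <- sqrt((centroids[, 1] - tm$position_px[1])^2 +
                (centroids[, 2] - tm$position_px[2])^2)
    if (min(d) <= match_r) which.min(d) else NA_integer_
  }, 0L)
  seg_summary <- list(n_truth = length(bundle$truth),
                      n_rois = length(rois),
                      n_matched = sum(!is.na(matched)),
                      recovery_fraction = mean(!is.na(matched)))

  ## stage 3: per-terminal tuning on segmented traces -----------------
  tuning_rows <- lapply(seq_along(bundle$truth), function(i) {
    tm <- bundle$truth[[i]]
    row <- data.frame(terminal = i, mechanism = tm$mechanism,
                      true_pref_deg = tm$rf$theta_deg,
                      matched = !is.na(matched[i]), osi = NA_real_,
                      pred_pref_deg = NA_real_)
    if (!is.na(matched[i])) {
      dff <- compute_dff(rois[[matched[i]]]$mean_trace, base_idx)
      g <- grating_osi_sygcamp(dff, stim$events, fr)
      row$osi <- g$osi
      row$pred_pref_deg <- g$preferred_orientation_deg
    }
    row
  })
  tuning_tab <- do.call(rbind, tuning_rows)
  tuned_truth <- tuning_tab$mechanism != "untuned"
  ok <- tuning_tab$matched
  tuning_summary <- list(
    n_scored = sum(ok),
    os_assigned_fraction_tuned =
      mean(!is.na(tuning_tab$osi[ok & tuned_truth])),
    os_assigned_fraction_untuned =
      mean(!is.na(tuning_tab$osi[ok & !tuned_truth])),
    pref_correct_fraction = mean(
      tuning_tab$pred_pref_deg[ok & tuned_truth] ==
        tuning_tab$true_pref_deg[ok & tuned_truth], na.rm = TRUE),
    median_osi_inhibition_sharpened = stats::median(
      tuning_tab$osi[ok & tuning_tab$mechanism == "inhibition_sharpened"],
      na.rm = TRUE),
    median_osi_elliptical = stats::median(
      tuning_tab$osi[ok & tuning_tab$mechanism == "elliptical"],
      na.rm = TRUE))

  ## stage 4: RGC session classification ------------------------------
  # sessions sample their inputs from a wider retinal population than
  # the imaged field: strongly tuned (inhibition-sharpened) pools per
  # orientation, plus an untuned pool
  ses <- config$sessions
  tuned_pool <- sample_population(population_spec(
    n_terminals = ses$n_tuned_pool, fraction_os = 1,
    os_mix = c(elliptical = 0, inhibition_sharpened = 1),
    inhibition_gain = pop$inhibition_gain,
    indicator_tau_s = pop$indicator_tau_s, seed = seed + 1000L))
  prefs_pool <- vapply(tuned_pool, function(tm) tm$rf$theta_deg, 0)
  tuned0 <- tuned_pool[prefs_pool == 0]
  tuned90 <- tuned_pool[prefs_pool == 90]
  untuned <- sample_population(population_spec(
    n_terminals = ses$n_untuned_pool, fraction_os = 0,
    indicator_tau_s = pop$indicator_tau_s, seed = seed + 2000L))
  pick <- function(pool, k, s) with_seed(s,
    pool[sample.int(length(pool), min(k, length(pool)), replace = FALSE)])
  half <- max(1, floor(ses$n_inputs / 2))

  truth_lab <- character(0); pred_lab <- character(0)
  session_store <- list()
  for (j in seq_len(ses$n_per_type)) {
    mixed <- c(pick(tuned0, half, seed + 100 + j),
               pick(tuned90, half, seed + 200 + j))
    cases <- list(
      dpc = list(terms = mixed, ffi = "on"),
      # static sessions draw from a single orientation pool
      static_os = list(terms = pick(if (j %% 2) tuned0 else tuned90,
                                    ses$n_inputs, seed + 300 + j),
                       ffi = "off"),
      insensitive = list(terms = pick(untuned, ses$n_inputs,
                                      seed + 400 + j), ffi = "off"))
    for (lab in names(cases)) {
      s <- simulate_rgc_session(cases[[lab]]$terms, stim,
                                ffi = cases[[lab]]$ffi,
                                noise_sd = ses$noise_sd,
                                seed = seed + 500 + 10 * j)
      pred <- classify_rgc(s$output, s$events, fr)
      truth_lab <- c(truth_lab, lab)
      pred_lab <- c(pred_lab,
                    if (pred %in% c("contrast_only", "non_os"))
                      "insensitive" else pred)
      if (lab == "dpc" && j == 1) session_store$dpc <- s
    }
  }
  conf <- table(truth = truth_lab, predicted = pred_lab)
  rgc_summary <- list(
    confusion = as.data.frame(conf),
    accuracy = mean(truth_lab == pred_lab))

  ## stage 5: model 1 vs model 2 on a mixed-input session -------------
  # model predictions are compared against the session's measured
  # output: model 1 tracks it, model 2 (static nonlinearity only)
  # peaks late because the measured output leads the input
  s <- session_store$dpc
  bl <- baseline_frames(stim)
  m1 <- apply_model1(s$input_sum, ffi_kernel_biphasic(1 / fr),
                     dt_s = 1 / fr, baseline_idx = bl)
  m2 <- apply_model2(s$input_sum, baseline_idx = bl)
  trans <- events_of_kind(stim$events, "orientation_switch")$time_s
  lead <- time_to_peak_delta(s$input_sum, s$output, trans, fr,
                             smooth_s = 0.25)
  d1 <- time_to_peak_delta(s$output, m1, trans, fr, smooth_s = 0.25)
  d2 <- time_to_peak_delta(s$output, m2, trans, fr, smooth_s = 0.25)
  model_summary <- list(
    median_output_lead_s = lead$median_s,
    median_delta_model1_s = d1$median_s,
    median_delta_model2_s = d2$median_s,
    r2_input_output = input_output_r2(s$input_sum, s$output),
    r2_model1_output = input_output_r2(m1, s$output),
    band_power_ratio_output =
      band_power(s$output / max(s$output), fr) /
        band_power(s$input_sum / max(s$input_sum), fr))

  ## stage 6: receptive-field round trip ------------------------------
  rf_summary <- NULL
  if (isTRUE(config$rf$enabled)) {
    rfc <- config$rf
    geom_rf <- screen_geometry(rfc$extent_deg + 2 * rfc$spacing_deg,
                               rfc$extent_deg + 2 * rfc$spacing_deg,
                               rfc$pixels_per_degree, rfc$frame_rate_hz)
    flash <- make_bar_flash_protocol(geom_rf, spacing_deg = rfc$spacing_deg,
                                     extent_deg = rfc$extent_deg,
                                     n_repeats = rfc$n_repeats,
                                     seed = seed + 11)
    # map only plain-Gaussian (elliptical) terminals whose RF
    # (center +- 2 sigma) lies inside the flashed extent: the round
    # trip validates the Gaussian mapping chain, and lateral inhibition
    # adds a non-Gaussian component by design
    tuned <- Filter(function(tm) tm$mechanism == "elliptical", bundle$truth)
    if (!length(tuned))
      tuned <- Filter(function(tm) tm$mechanism != "untuned", bundle$truth)
    fits_in <- vapply(tuned, function(tm)
      max(abs(tm$rf$center_x_deg), abs(tm$rf$center_y_deg)) +
        2 * tm$rf$major_sigma_deg <= rfc$extent_deg / 2, logical(1))
    sel <- if (sum(fits_in) >= rfc$n_terminals) {
      pick(tuned[fits_in], rfc$n_terminals, seed + 12)
    } else {
      off <- vapply(tuned, function(tm)
        max(abs(tm$rf$center_x_deg), abs(tm$rf$center_y_deg)), 0)
      tuned[order(off)][seq_len(rfc$n_terminals)]
    }
    errs <- lapply(seq_along(sel), function(i) {
      tm <- sel[[i]]
      tr <- terminal_dff_trace(tm, flash)
      tr <- tr + with_seed(seed + 13 + i,
        stats::rnorm(length(tr), 0, rfc$noise_sd * tm$amplitude_dff))
      sg <- responses_to_sinogram(tr, flash$events, rfc$frame_rate_hz)
      fit <- fit_gaussian_2d(filtered_back_projection(sg, oversample = 2),
                             sino = sg)
      c(center_err_deg = sqrt((fit$center_x_deg - tm$rf$center_x_deg)^2 +
                                (fit$center_y_deg - tm$rf$center_y_deg)^2),
        ellipticity_err = ellipticity(fit) - ellipticity(tm$rf))
    })
    errs <- do.call(rbind, errs)
    rf_summary <- list(
      n = nrow(errs),
      max_center_err_deg = max(errs[, "center_err_deg"]),
      max_abs_ellipticity_err = max(abs(errs[, "ellipticity_err"])),
      spacing_deg = rfc$spacing_deg)
  }

  ## stage 7: wiring statistics ---------------------------------------
  pop_tuned <- vapply(bundle$truth, function(tm)
    tm$mechanism != "untuned", logical(1))
  lab_of <- function(tm) {
    if (tm$mechanism == "untuned") "untuned"
    else if (tm$rf$theta_deg == 0) "vertical" else "horizontal"
  }
  sel_static <- pick(tuned0, half, seed + 301)
  profile <- rgc_input_profile(vapply(sel_static, lab_of, ""))
  p_wiring <- connectivity_permutation_test(
    c(tuned = profile$n_v + profile$n_h,
      untuned = profile$n_u),
    pop_tuned, n_resamples = 10000, seed = seed + 21)
  wiring_summary <- list(example_profile = profile,
                         permutation_p = p_wiring)

  summary <- list(seed = seed,
                  segmentation = seg_summary,
                  tuning = tuning_summary,
                  rgc_classification = rgc_summary,
                  model_comparison = model_summary,
                  rf_recovery = rf_summary,
                  wiring = wiring_summary)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    op <- function(f) file.path(config$out_dir, f)
    write_event_log(stim$events, op("stimulus_events.json"))
    write_rois(rois, bundle$movie, op("roi_masks.tiff"),
               op("roi_traces.csv"), baseline_idx = base_idx)
    utils::write.csv(tuning_tab, op("tuning_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, op("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  summary
}
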