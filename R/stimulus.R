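#' Screen geometry for stimulus rendering
#'
#' Describes the projection screen in visual-degree coordinates together
#' with its spatial and temporal sampling. The pixel grid has
#' `round(size_deg * pixels_per_degree)` pixels along each axis and pixel
#' values are taken at pixel centers (no anti-aliasing), so rendered
#' square waves are strictly two-valued.
#'
#' @param width_deg,height_deg Screen extent in degrees of visual angle.
#' @param pixels_per_degree Spatial sampling density (pixels / degree).
#' @param frame_rate_hz Temporal sampling rate of rendered movies.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(20, 20, pixels_per_degree = 2, frame_rate_hz = 10)
#' @export
screen_geometry <- function(width_deg, height_deg,
                            pixels_per_degree = 4, frame_rate_hz = 20) {
  stopifnot_scalar_pos(width_deg, "width_deg")
  stopifnot_scalar_pos(height_deg, "height_deg")
  stopifnot_scalar_pos(pixels_per_degree, "pixels_per_degree")
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  g <- list(width_deg = width_deg, height_deg = height_deg,
            pixels_per_degree = pixels_per_degree,
            frame_rate_hz = frame_rate_hz,
            nx = round(width_deg * pixels_per_degree),
            ny = round(height_deg * pixels_per_degree))
  class(g) <- "screen_geometry"
  g
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %.1f x %.1f deg, %d x %d px, %.1f Hz\n",
              x$width_deg, x$height_deg, x$nx, x$ny, x$frame_rate_hz))
  invisible(x)
}

#' Pixel-center coordinate grids in visual degrees
#'
#' Returns matrices `x` and `y` (ny rows, nx columns) with the degree
#' coordinates of every pixel center, origin at the screen center.
#'
#' @param geometry A [screen_geometry()].
#' @return List with matrices `x` and `y`.
#' @export
pixel_grid <- function(geometry) {
  xs <- (seq_len(geometry$nx) - (geometry$nx + 1) / 2) / geometry$pixels_per_degree
  ys <- (seq_len(geometry$ny) - (geometry$ny + 1) / 2) / geometry$pixels_per_degree
  list(x = matrix(xs, geometry$ny, geometry$nx, byrow = TRUE),
       y = matrix(ys, geometry$ny, geometry$nx))
}

#' Square-wave grating specification
#'
#' Orientation follows the bar convention used for zebrafish retina
#' work: 0 deg = vertical bars (luminance modulated along x), 90 deg =
#' horizontal bars. The grating is a full-field square wave whose
#' amplitude spans `-contrast` to `+contrast` about the mean luminance
#' (luminance is expressed in contrast units, mean = 0), with the
#' center of a bar aligned to the screen center at zero phase. Contrast
#' reverses as a temporal square wave at `reversal_hz`.
#'
#' @param spatial_frequency_cpd Spatial frequency in cycles / degree.
#' @param orientation_deg Orientation of the bars, in `[0, 180)`.
#' @param phase_deg Spatial phase in degrees of a cycle.
#' @param contrast Signed contrast fraction in `[-1, 1]`.
#' @param reversal_hz Contrast reversal rate: polarity flips every
#'   `1 / (2 * reversal_hz)` seconds.
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(spatial_frequency_cpd, orientation_deg = 0,
                         phase_deg = 0, contrast = 1, reversal_hz = 5) {
  stopifnot_scalar_pos(spatial_frequency_cpd, "spatial_frequency_cpd")
  if (abs(contrast) > 1) stop("`contrast` must lie in [-1, 1]")
  stopifnot_scalar_pos(reversal_hz, "reversal_hz")
  s <- list(spatial_frequency_cpd = spatial_frequency_cpd,
            orientation_deg = orientation_deg %% 180,
            phase_deg = phase_deg, contrast = contrast,
            reversal_hz = reversal_hz)
  class(s) <- "grating_spec"
  s
}

# spatial square-wave pattern in {-1, +1}; +1 at the screen center for
# zero phase (bar center aligned with screen center)
grating_pattern <- function(spec, geometry) {
  gr <- pixel_grid(geometry)
  th <- spec$orientation_deg * pi / 180
  u <- gr$x * cos(th) + gr$y * sin(th)
  sgn(cos(2 * pi * spec$spatial_frequency_cpd * u + spec$phase_deg * pi / 180))
}

#' Render one frame of a contrast-reversing square-wave grating
#'
#' @param spec A [grating_spec()].
#' @param geometry A [screen_geometry()].
#' @param t Time in seconds (>= 0); sets the sign of the temporal
#'   square-wave contrast reversal.
#' @return A `ny x nx` luminance matrix in contrast units (`[-1, 1]`,
#'   0 = mean luminance).
#' @examples
#' g <- screen_geometry(10, 10, 2, 10)
#' fr <- make_grating_frame(grating_spec(0.1), g, t = 0)
#' @export
make_grating_frame <- function(spec, geometry, t) {
  if (!inherits(spec, "grating_spec")) stop("`spec` must be a grating_spec")
  if (t < 0) stop("`t` must be >= 0")
  if (spec$contrast == 0) {
    return(matrix(0, geometry$ny, geometry$nx))
  }
  tsign <- sgn(cos(2 * pi * spec$reversal_hz * t))
  spec$contrast * tsign * grating_pattern(spec, geometry)
}

#' Stimulus event logs
#'
#' An event log is an ordered table of stimulus transitions with columns
#' `time_s`, `kind` (one of `grating_on`, `orientation_switch`,
#' `phase_step`, `bar_sweep_start`, `bar_flash`, `stimulus_off`) and a
#' list-column `payload` of per-event metadata. Times must be strictly
#' increasing.
#'
#' @param time_s Numeric vector of event times (seconds).
#' @param kind Character vector of event kinds.
#' @param payload List of per-event payload lists (may be empty lists).
#' @return An object of class `event_log` (a data frame).
#' @export
event_log <- function(time_s = numeric(), kind = character(),
                      payload = rep(list(list()), length(time_s))) {
  kinds <- c("grating_on", "orientation_switch", "phase_step",
             "bar_sweep_start", "bar_flash", "stimulus_off")
  if (length(time_s) != length(kind) || length(kind) != length(payload))
    stop("time_s, kind and payload must have equal length")
  if (!all(kind %in% kinds))
    stop("unknown event kind: ", paste(setdiff(kind, kinds), collapse = ", "))
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stop("event times must be strictly increasing")
  el <- data.frame(time_s = as.numeric(time_s), kind = as.character(kind),
                   stringsAsFactors = FALSE)
  el$payload <- payload
  class(el) <- c("event_log", "data.frame")
  el
}

#' Select events of a given kind
#' @param events An [event_log()].
#' @param kind Event kind to keep.
#' @return An `event_log` subset.
#' @export
events_of_kind <- function(events, kind) {
  out <- events[events$kind == kind, , drop = FALSE]
  class(out) <- c("event_log", "data.frame")
  out
}

#' Write / read an event log as JSON
#'
#' Serialization is lossless: `read_event_log(write_event_log(x, f))`
#' reproduces `x`.
#'
#' @param events An [event_log()].
#' @param path File path for the JSON sidecar.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns an `event_log`.
#' @export
write_event_log <- function(events, path) {
  recs <- lapply(seq_len(nrow(events)), function(i) {
    list(time_s = events$time_s[i], kind = events$kind[i],
         payload = events$payload[[i]])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  event_log(time_s = vapply(recs, function(r) as.numeric(r$time_s), 0),
            kind = vapply(recs, function(r) as.character(r$kind), ""),
            payload = lapply(recs, function(r) {
              p <- r$payload
              if (is.null(p)) list() else lapply(p, function(v) unlist(v))
            }))
}

#' Stimulus movie container
#'
#' Bundles a rendered luminance array (`time x y x x`, contrast units)
#' with its [screen_geometry()] and [event_log()].
#'
#' @param frames 3-D numeric array `(time, y, x)`.
#' @param geometry A [screen_geometry()].
#' @param events An [event_log()].
#' @return Object of class `stimulus_movie`.
#' @export
stimulus_movie <- function(frames, geometry, events) {
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[2] != geometry$ny || dim(frames)[3] != geometry$nx)
    stop("frame dimensions do not match geometry")
  if (max(abs(frames)) > 1 + 1e-12)
    stop("luminance values must lie within the contrast range [-1, 1]")
  m <- list(frames = frames, geometry = geometry, events = events)
  class(m) <- "stimulus_movie"
  m
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_movie> %d frames (%0.1f s) of %d x %d px, %d events\n",
              d[1], d[1] / x$geometry$frame_rate_hz, d[2], d[3],
              nrow(x$events)))
  invisible(x)
}

#' Movie frame times
#' @param movie A [stimulus_movie()].
#' @return Numeric vector of frame onset times in seconds.
#' @export
frame_times <- function(movie) {
  (seq_len(dim(movie$frames)[1]) - 1) / movie$geometry$frame_rate_hz
}

#' Orientation-switch grating protocol
#'
#' A full-field square-wave grating reversing contrast at `reversal_hz`
#' whose orientation switches between epochs (the standard protocol:
#' horizontal 90 deg to vertical 0 deg and back every 5-10 s). An
#' optional phase protocol steps the spatial phase between epochs at a
#' fixed orientation instead.
#'
#' @param geometry A [screen_geometry()].
#' @param spatial_frequency_cpd Spatial frequency of the grating.
#' @param reversal_hz Contrast-reversal rate (default 5 Hz).
#' @param epoch_s Epoch duration(s) in seconds; a scalar or a vector with
#'   one entry per epoch (the protocol used 5-10 s epochs).
#' @param orientations_deg Orientation of each epoch; default alternates
#'   90, 0, 90, ...
#' @param phases_deg Spatial phase of each epoch (recycled). When the
#'   phase changes at an epoch boundary while the orientation does not, a
#'   `phase_step` event is logged instead of an `orientation_switch`.
#' @param contrast Grating contrast.
#' @param pre_s Mean-luminance seconds rendered before grating onset.
#' @return A [stimulus_movie()] whose log contains one `grating_on`
#'   event and one `orientation_switch`/`phase_step` per epoch boundary.
#' @export
make_orientation_switch_movie <- function(geometry, spatial_frequency_cpd,
                                          reversal_hz = 5, epoch_s = 10,
                                          orientations_deg = c(90, 0, 90, 0),
                                          phases_deg = 0, contrast = 1,
                                          pre_s = 0) {
  n_epoch <- length(orientations_deg)
  if (n_epoch < 2) stop("need at least one orientation switch (>= 2 epochs)")
  epoch_s <- rep_len(epoch_s, n_epoch)
  phases_deg <- rep_len(phases_deg, n_epoch)
  fr <- geometry$frame_rate_hz
  n_pre <- round(pre_s * fr)
  nf_epoch <- round(epoch_s * fr)
  n_total <- n_pre + sum(nf_epoch)
  frames <- array(0, c(n_total, geometry$ny, geometry$nx))

  t_ev <- numeric(); k_ev <- character(); p_ev <- list()
  t0 <- n_pre / fr
  t_ev <- c(t_ev, t0); k_ev <- c(k_ev, "grating_on")
  p_ev <- c(p_ev, list(list(orientation_deg = orientations_deg[1],
                            phase_deg = phases_deg[1])))
  offset <- n_pre
  for (e in seq_len(n_epoch)) {
    spec <- grating_spec(spatial_frequency_cpd, orientations_deg[e],
                         phases_deg[e], contrast, reversal_hz)
    pat <- contrast * grating_pattern(spec, geometry)
    idx <- offset + seq_len(nf_epoch[e])
    tt <- (idx - 1) / fr
    tsign <- sgn(cos(2 * pi * reversal_hz * (tt - t0)))
    for (j in seq_along(idx)) frames[idx[j], , ] <- tsign[j] * pat
    if (e > 1) {
      kind <- if (orientations_deg[e] != orientations_deg[e - 1])
        "orientation_switch" else "phase_step"
      t_ev <- c(t_ev, offset / fr); k_ev <- c(k_ev, kind)
      p_ev <- c(p_ev, list(list(orientation_deg = orientations_deg[e],
                                phase_deg = phases_deg[e])))
    }
    offset <- offset + nf_epoch[e]
  }
  stimulus_movie(frames, geometry, event_log(t_ev, k_ev, p_ev))
}

#' Moving-bar protocol
#'
#' A single dark bar (default -100% contrast, 4.1 deg wide) sweeps
#' across the screen at constant speed in each of `n_directions`
#' directions evenly spaced over 360 deg; the direction order is
#' pseudo-random per repeat and reproducible from `seed`. The bar spans
#' the full screen orthogonal to its motion.
#'
#' @param geometry A [screen_geometry()].
#' @param bar_width_deg Bar width in degrees (default 4.1).
#' @param speed_dps Sweep speed in degrees / second (default 18.6).
#' @param n_directions Number of motion directions (default 8, giving 4
#'   orientations after pooling).
#' @param gap_s Blank gap between sweeps (default 6 s).
#' @param n_repeats Number of repeats of the direction set (default 5).
#' @param contrast Bar contrast (default -1).
#' @param seed Seed for the pseudo-random direction order.
#' @return A [stimulus_movie()] with one `bar_sweep_start` event per
#'   sweep (payload: `direction_deg`, `repeat`).
#' @export
make_moving_bar_movie <- function(geometry, bar_width_deg = 4.1,
                                  speed_dps = 18.6, n_directions = 8,
                                  gap_s = 6, n_repeats = 5, contrast = -1,
                                  seed = 1) {
  if (bar_width_deg > min(geometry$width_deg, geometry$height_deg))
    stop("bar wider than screen")
  dirs <- seq(0, 360, length.out = n_directions + 1)[seq_len(n_directions)]
  order_per_rep <- with_seed(seed, lapply(seq_len(n_repeats), function(r)
    sample.int(n_directions)))

  fr <- geometry$frame_rate_hz
  gr <- pixel_grid(geometry)
  w2 <- geometry$width_deg / 2; h2 <- geometry$height_deg / 2

  sweeps <- list(); t_ev <- numeric(); p_ev <- list()
  t_cur <- 0
  for (r in seq_len(n_repeats)) {
    for (d in order_per_rep[[r]]) {
      phi <- dirs[d] * pi / 180
      R <- abs(w2 * cos(phi)) + abs(h2 * sin(phi))
      dur <- (2 * R + bar_width_deg) / speed_dps
      nf <- ceiling(dur * fr)
      proj <- gr$x * cos(phi) + gr$y * sin(phi)
      sweeps[[length(sweeps) + 1]] <-
        list(t0 = t_cur, nf = nf, proj = proj, R = R)
      t_ev <- c(t_ev, t_cur)
      p_ev <- c(p_ev, list(list(direction_deg = dirs[d], rep = r)))
      t_cur <- t_cur + nf / fr + gap_s
    }
  }
  n_total <- round(t_cur * fr)
  frames <- array(0, c(n_total, geometry$ny, geometry$nx))
  for (sw in sweeps) {
    i0 <- round(sw$t0 * fr)
    for (j in seq_len(sw$nf)) {
      tloc <- (j - 1) / fr
      ctr <- -sw$R - bar_width_deg / 2 + speed_dps * tloc
      mask <- abs(sw$proj - ctr) <= bar_width_deg / 2
      if (any(mask)) {
        f <- matrix(0, geometry$ny, geometry$nx)
        f[mask] <- contrast
        frames[i0 + j, , ] <- f
      }
    }
  }
  stimulus_movie(frames, geometry,
                 event_log(t_ev, rep("bar_sweep_start", length(t_ev)), p_ev))
}

#' Flashed-bar receptive-field mapping protocol
#'
#' Dark bars are flashed at `spacing_deg` intervals along the axis
#' normal to each of five bar angles (0-144 deg), each for `on_s`
#' seconds with a `duty_s` duty cycle, in a seeded pseudo-random order
#' covering every (angle, position) pair exactly once per repeat
#' (repeats are averaged downstream by [responses_to_sinogram()]).
#'
#' @param geometry A [screen_geometry()].
#' @param spacing_deg Bar spacing (and default bar width) in degrees.
#' @param angles_deg Bar orientations (default `c(0, 36, 72, 108, 144)`).
#' @param on_s Flash duration (default 0.5 s).
#' @param duty_s Duty cycle: one flash every `duty_s` seconds (default 2).
#' @param extent_deg Mapped extent along the position axis; defaults to
#'   the smaller screen dimension.
#' @param bar_width_deg Bar width; defaults to `spacing_deg / 2` so the
#'   bar does not blur the projections below the position sampling.
#' @param contrast Bar contrast (default -1).
#' @param n_repeats Number of shuffled repeats of the full
#'   (angle, position) grid (default 1).
#' @param seed Seed for the presentation order.
#' @return A [stimulus_movie()] with one `bar_flash` event per flash
#'   (payload: `angle_deg`, `position_deg`).
#' @export
make_bar_flash_protocol <- function(geometry, spacing_deg = 3.2,
                                    angles_deg = c(0, 36, 72, 108, 144),
                                    on_s = 0.5, duty_s = 2,
                                    extent_deg = NULL, bar_width_deg = NULL,
                                    contrast = -1, n_repeats = 1, seed = 1) {
  extent_deg <- extent_deg %||% min(geometry$width_deg, geometry$height_deg)
  # a mapping bar at half the position spacing keeps the projection
  # profiles resolvable at the sampling resolution
  bar_width_deg <- bar_width_deg %||% (spacing_deg / 2)
  n_pos <- ceiling(extent_deg / spacing_deg)
  positions <- (seq_len(n_pos) - (n_pos + 1) / 2) * spacing_deg

  grid1 <- expand.grid(angle = angles_deg, pos = positions)
  combos <- with_seed(seed, do.call(rbind, lapply(seq_len(n_repeats),
    function(r) grid1[sample.int(nrow(grid1)), ])))

  fr <- geometry$frame_rate_hz
  nf_duty <- round(duty_s * fr)
  nf_on <- round(on_s * fr)
  n_total <- nrow(combos) * nf_duty
  frames <- array(0, c(n_total, geometry$ny, geometry$nx))
  gr <- pixel_grid(geometry)

  t_ev <- numeric(nrow(combos)); p_ev <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    a <- combos$angle[i] * pi / 180
    proj <- gr$x * cos(a) + gr$y * sin(a)
    mask <- abs(proj - combos$pos[i]) <= bar_width_deg / 2
    f <- matrix(0, geometry$ny, geometry$nx)
    f[mask] <- contrast
    i0 <- (i - 1) * nf_duty
    for (j in seq_len(nf_on)) frames[i0 + j, , ] <- f
    t_ev[i] <- i0 / fr
    p_ev[[i]] <- list(angle_deg = combos$angle[i],
                      position_deg = combos$pos[i])
  }
  stimulus_movie(frames, geometry,
                 event_log(t_ev, rep("bar_flash", length(t_ev)), p_ev))
}

#' Write a stimulus movie as multi-page TIFF plus JSON event log
#'
#' Luminance in contrast units `[-1, 1]` is mapped affinely to `[0, 1]`
#' for the TIFF (32-bit float pages).
#'
#' @param movie A [stimulus_movie()].
#' @param tiff_path Output TIFF path.
#' @param events_path Output JSON path; default replaces the TIFF
#'   extension with `.events.json`.
#' @return Invisibly, `tiff_path`.
#' @export
write_stimulus_movie <- function(movie, tiff_path, events_path = NULL) {
  events_path <- events_path %||% sub("\\.tiff?$", ".events.json", tiff_path)
  pages <- lapply(seq_len(dim(movie$frames)[1]),
                  function(i) (movie$frames[i, , ] + 1) / 2)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  write_event_log(movie$events, events_path)
  invisible(tiff_path)
}
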