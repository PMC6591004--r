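#' Fluorescence pixel stack
#'
#' A `time x y x x` array of fluorescence values with its frame rate;
#' the container segmented into ROIs.
#'
#' @param data 3-D numeric array `(time, y, x)` with at least 2 frames.
#' @param frame_rate_hz Frame rate in Hz.
#' @return Object of class `pixel_stack`.
#' @export
pixel_stack <- function(data, frame_rate_hz) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] >= 2)
  if (!all(is.finite(data))) stop("stack must contain finite values")
  s <- list(data = data, frame_rate_hz = frame_rate_hz)
  class(s) <- "pixel_stack"
  s
}

#' @export
print.pixel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pixel_stack> %d frames x %d x %d px @ %.1f Hz\n",
              d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}

# time x pixels matrix of z-scored series scaled so that crossprod of
# two columns is their Pearson correlation; zero-variance pixels -> 0
standardize_stack <- function(stack) {
  d <- dim(stack$data)
  X <- matrix(stack$data, nrow = d[1])
  Xc <- sweep(X, 2, colMeans(X))
  nrm <- sqrt(colSums(Xc^2))
  zero <- nrm <= 0
  nrm[zero] <- 1
  Z <- sweep(Xc, 2, nrm, "/")
  Z[, zero] <- 0
  attr(Z, "zero_variance") <- zero
  Z
}

#' Local correlation map
#'
#' Each pixel's time series is Pearson-correlated with those of its 8
#' neighbours and the pixel is replaced by the maximum of those
#' correlations. Border pixels use their available neighbours;
#' correlations involving a zero-variance pixel are defined as 0.
#'
#' @param stack A [pixel_stack()].
#' @return `ny x nx` matrix of maximal neighbour correlations.
#' @export
local_correlation_map <- function(stack) {
  d <- dim(stack$data)
  ny <- d[2]; nx <- d[3]
  Za <- array(standardize_stack(stack), c(d[1], ny, nx))
  best <- matrix(-Inf, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- seq_len(ny); xs <- seq_len(nx)
    ys1 <- ys[ys + dy >= 1 & ys + dy <= ny]
    xs1 <- xs[xs + dx >= 1 & xs + dx <= nx]
    cc <- colSums(Za[, ys1, xs1, drop = FALSE] *
                    Za[, ys1 + dy, xs1 + dx, drop = FALSE], dims = 1)
    best[ys1, xs1] <- pmax(best[ys1, xs1], cc)
  }
  best
}

#' Region of interest
#'
#' @param pixels Integer matrix with columns `y`, `x`.
#' @param mean_trace Mean raw fluorescence trace over the pixel set.
#' @param seed_pixel The `(y, x)` seed the ROI was grown from.
#' @param quality Peak dF/F response in baseline-SD units (`NA` until
#'   scored).
#' @return Object of class `roi`.
#' @export
roi <- function(pixels, mean_trace, seed_pixel, quality = NA_real_) {
  colnames(pixels) <- c("y", "x")
  r <- list(pixels = pixels, mean_trace = mean_trace,
            seed_pixel = seed_pixel, quality = quality)
  class(r) <- "roi"
  r
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %d px, seed (%d, %d), quality %.2f\n",
              nrow(x$pixels), x$seed_pixel[1], x$seed_pixel[2], x$quality))
  invisible(x)
}

#' Grow one ROI from a seed pixel by iterative correlation testing
#'
#' Breadth-first growth over the 8-neighbourhood: a candidate pixel
#' joins the ROI iff the Pearson correlation of its time series with
#' the reference series reaches `threshold`; neighbours of every added
#' pixel are then tested in turn until no pixel is added. The reference
#' is the seed pixel's series (`reference = "seed"`, the default) or
#' the running mean of the ROI so far (`reference = "mean"`).
#'
#' @param stack A [pixel_stack()].
#' @param seed_pixel `(y, x)` seed.
#' @param threshold Correlation threshold in `(0, 1]`.
#' @param claimed Optional logical `ny x nx` matrix of pixels excluded
#'   from growth (already claimed by other ROIs).
#' @param reference `"seed"` or `"mean"`.
#' @return An [roi()].
#' @export
grow_roi <- function(stack, seed_pixel, threshold, claimed = NULL,
                     reference = c("seed", "mean")) {
  reference <- match.arg(reference)
  if (threshold <= 0 || threshold > 1)
    stop("`threshold` must lie in (0, 1]")
  d <- dim(stack$data)
  ny <- d[2]; nx <- d[3]
  if (is.null(claimed)) claimed <- matrix(FALSE, ny, nx)
  if (claimed[seed_pixel[1], seed_pixel[2]])
    stop("seed pixel is already claimed")
  Z <- standardize_stack(stack)
  pid <- function(y, x) (x - 1L) * ny + y

  in_roi <- matrix(FALSE, ny, nx)
  tested <- matrix(FALSE, ny, nx)
  in_roi[seed_pixel[1], seed_pixel[2]] <- TRUE
  tested[seed_pixel[1], seed_pixel[2]] <- TRUE
  zseed <- Z[, pid(seed_pixel[1], seed_pixel[2])]
  queue <- list(seed_pixel)
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      y <- p[1] + dy; x <- p[2] + dx
      if (y < 1 || y > ny || x < 1 || x > nx) next
      if (tested[y, x] || claimed[y, x]) next
      tested[y, x] <- TRUE
      zc <- Z[, pid(y, x)]
      ref <- if (reference == "seed") zseed else {
        idx <- which(in_roi)
        m <- rowMeans(Z[, idx, drop = FALSE])
        nm <- sqrt(sum(m^2)); if (nm > 0) m / nm else m
      }
      if (sum(zc * ref) >= threshold) {
        in_roi[y, x] <- TRUE
        queue[[length(queue) + 1]] <- c(y, x)
      }
    }
  }
  px <- which(in_roi, arr.ind = TRUE)
  colnames(px) <- c("y", "x")
  roi(px, roi_mean_trace(stack, px), seed_pixel)
}

#' Mean raw trace over a pixel set
#' @param stack A [pixel_stack()].
#' @param pixels Matrix with columns `y`, `x`.
#' @return Numeric trace.
#' @export
roi_mean_trace <- function(stack, pixels) {
  d <- dim(stack$data)
  X <- matrix(stack$data, nrow = d[1])
  idx <- (pixels[, 2] - 1L) * d[2] + pixels[, 1]
  rowMeans(X[, idx, drop = FALSE])
}

#' Compute dF/F from a raw trace
#'
#' `(F - F0) / F0` with `F0` the median of the baseline window.
#'
#' @param trace Raw fluorescence trace.
#' @param baseline_idx Indices of the baseline window.
#' @return dF/F trace.
#' @export
compute_dff <- function(trace, baseline_idx) {
  if (any(baseline_idx < 1) || any(baseline_idx > length(trace)))
    stop("baseline window outside trace")
  f0 <- stats::median(trace[baseline_idx])
  if (f0 <= 0) stop("baseline fluorescence F0 must be positive")
  (trace - f0) / f0
}

#' Segment a stack into ROIs
#'
#' Iterative correlation-seeded segmentation: the local correlation map
#' seeds the first ROI at its maximum; the ROI is grown with
#' [grow_roi()]; the next seed is the highest remaining (unclaimed)
#' map value, until no unclaimed pixel reaches `seed_threshold`. ROIs
#' whose peak dF/F response does not exceed `min_quality` baseline
#' standard deviations are discarded. Deterministic.
#'
#' @param stack A [pixel_stack()].
#' @param threshold Growth correlation threshold in `(0, 1]`.
#' @param min_quality Minimum peak response in baseline-SD units
#'   (default 4).
#' @param baseline_idx Baseline frame indices for dF/F and quality;
#'   default the first 10% of frames.
#' @param seed_threshold Minimum correlation-map value for a new seed;
#'   defaults to `threshold`.
#' @param min_size Minimum ROI pixel count (default 2).
#' @param reference Growth reference passed to [grow_roi()].
#' @return List of [roi()] objects with pairwise-disjoint pixel sets.
#' @export
segment <- function(stack, threshold = 0.5, min_quality = 4,
                    baseline_idx = NULL, seed_threshold = threshold,
                    min_size = 2, reference = "seed") {
  d <- dim(stack$data)
  baseline_idx <- baseline_idx %||% seq_len(max(2, round(0.1 * d[1])))
  cmap <- local_correlation_map(stack)
  claimed <- matrix(FALSE, d[2], d[3])
  rois <- list()
  repeat {
    cmap_open <- cmap
    cmap_open[claimed] <- -Inf
    m <- which.max(cmap_open)
    if (!length(m) || cmap_open[m] < seed_threshold) break
    seed <- c((m - 1L) %% d[2] + 1L, (m - 1L) %/% d[2] + 1L)
    r <- grow_roi(stack, seed, threshold, claimed = claimed,
                  reference = reference)
    claimed[r$pixels] <- TRUE
    if (nrow(r$pixels) < min_size) next
    dff <- compute_dff(r$mean_trace, baseline_idx)
    bsd <- stats::sd(dff[baseline_idx])
    base <- stats::median(dff[baseline_idx])
    r$quality <- if (bsd > 0) (max(dff) - base) / bsd else Inf
    if (r$quality > min_quality) rois[[length(rois) + 1]] <- r
  }
  rois
}

#' Join strongly correlated ROIs
#'
#' Single-linkage merging of ROIs whose mean traces are Pearson
#' correlated at or above `join_threshold` (the rule used for tectal
#' segmentation, where one axon gives rise to multiple terminals). The
#' merged trace is recomputed as the pixel mean over the union.
#'
#' @param rois List of [roi()] from one stack.
#' @param stack The [pixel_stack()] they were segmented from.
#' @param join_threshold Correlation threshold for joining.
#' @return List of [roi()] after merging.
#' @export
join_correlated_rois <- function(rois, stack, join_threshold = 0.8) {
  n <- length(rois)
  if (n <= 1) return(rois)
  tr <- vapply(rois, function(r) r$mean_trace,
               numeric(length(rois[[1]]$mean_trace)))
  cm <- suppressWarnings(stats::cor(tr))
  cm[is.na(cm)] <- 0
  adj <- cm >= join_threshold
  # connected components by repeated boolean expansion (single linkage)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      newc <- min(comp[nb])
      if (newc < comp[i]) { comp[comp == comp[i]] <- newc; changed <- TRUE }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cc) {
    members <- rois[comp == cc]
    if (length(members) == 1) return(members[[1]])
    px <- unique(do.call(rbind, lapply(members, function(r) r$pixels)))
    roi(px, roi_mean_trace(stack, px), members[[1]]$seed_pixel,
        quality = max(vapply(members, function(r) r$quality, 0)))
  })
}

#' Write ROI masks as a label-image TIFF and traces as CSV
#'
#' @param rois List of [roi()].
#' @param stack The source [pixel_stack()].
#' @param mask_path Output TIFF path for the label image (labels scaled
#'   to `[0, 1]`, label i = i / n).
#' @param traces_path Output CSV path with columns `roi_id, t, dff`.
#' @param baseline_idx Baseline for dF/F conversion.
#' @return Invisibly, `traces_path`.
#' @export
write_rois <- function(rois, stack, mask_path, traces_path,
                       baseline_idx = NULL) {
  d <- dim(stack$data)
  baseline_idx <- baseline_idx %||% seq_len(max(2, round(0.1 * d[1])))
  lab <- matrix(0, d[2], d[3])
  for (i in seq_along(rois)) lab[rois[[i]]$pixels] <- i
  tiff::writeTIFF(lab / max(1, length(rois)), mask_path,
                  bits.per.sample = 32L)
  tt <- (seq_len(d[1]) - 1) / stack$frame_rate_hz
  tabs <- lapply(seq_along(rois), function(i) {
    data.frame(roi_id = i, t = tt,
               dff = compute_dff(rois[[i]]$mean_trace, baseline_idx))
  })
  utils::write.csv(do.call(rbind, tabs), traces_path, row.names = FALSE)
  invisible(traces_path)
}

#' Read a fluorescence stack from a multi-page TIFF
#'
#' @param path TIFF file path.
#' @param frame_rate_hz Frame rate to attach.
#' @return A [pixel_stack()].
#' @export
read_stack_tiff <- function(path, frame_rate_hz) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  pixel_stack(arr, frame_rate_hz)
}
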