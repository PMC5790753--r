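# Frame/pixel indexing contract: all public metadata (stim_frame, windows,
# ROIs) is 0-based with half-open intervals; conversion to R's 1-based
# indexing happens only inside these functions.

baseline_window_idx <- function(stim_frame, n_baseline = 50L) {
  # 0-based frames [stim - n, stim) -> R indices
  (stim_frame - n_baseline + 1L):stim_frame
}

#' Per-pixel baseline statistics
#'
#' Mean and SD of each pixel's activity over the 50 frames preceding
#' photostimulation (0-based frames `[stim_frame - 50, stim_frame)`).
#'
#' @param movie A `vsd_movie` (raw intensities or a dI/I stack).
#' @param n_baseline Number of pre-stimulation frames to use (default 50).
#' @return A `baseline_stats` list: `mean` and `sd` matrices
#'   (height x width), `n_frames`, and `n_zero_sd` (pixels whose baseline
#'   is constant; their normalization is undefined and they are masked
#'   downstream).
#' @export
baseline_stats <- function(movie, n_baseline = 50L) {
  stopifnot(inherits(movie, "vsd_movie"))
  if (movie$stim_frame < n_baseline)
    stop("need ", n_baseline, " pre-stimulation frames; stim_frame = ",
         movie$stim_frame)
  idx <- baseline_window_idx(movie$stim_frame, n_baseline)
  base <- movie$data[idx, , , drop = FALSE]
  mu <- apply(base, c(2, 3), mean)
  sdev <- apply(base, c(2, 3), sd)
  res <- list(mean = mu, sd = sdev, n_frames = n_baseline,
              n_zero_sd = sum(sdev == 0))
  class(res) <- "baseline_stats"
  res
}

#' Per-pixel fractional intensity change (dI/I %)
#'
#' `100 * (I(t) - I0) / I0` per pixel, with `I0` the pixel's mean intensity
#' over the 50-frame baseline window.
#'
#' @inheritParams baseline_stats
#' @return A `vsd_movie` whose stack holds dI/I in percent.
#' @export
compute_dff <- function(movie, n_baseline = 50L) {
  stopifnot(inherits(movie, "vsd_movie"))
  stats <- baseline_stats(movie, n_baseline)
  i0 <- stats$mean
  n_bad <- sum(i0 <= 0)
  if (n_bad > 0)
    stop(n_bad, " pixel(s) have nonpositive baseline intensity; ",
         "dI/I is undefined there")
  nT <- dim(movie$data)[1]
  denom <- array(rep(i0, each = nT), dim = dim(movie$data))
  out <- movie
  out$data <- 100 * (movie$data - denom) / denom
  out$signal <- "dff_percent"
  out
}

#' Normalize a movie to baseline-SD multiples
#'
#' Expresses each pixel as `(value - baseline mean) / baseline SD`: SD
#' multiples above its own baseline, the scale used for display, activated
#' pixel detection and quantification. Pixels with zero baseline SD are
#' masked (set `NA`) and counted rather than propagated as infinities.
#' Because dI/I is an affine per-pixel transform, normalizing the raw stack
#' and normalizing the dI/I stack give identical results.
#'
#' @param movie A `vsd_movie` (raw or dI/I).
#' @param stats Optional precomputed [baseline_stats()] for `movie`.
#' @return A `vsd_norm` object: the normalized stack plus metadata,
#'   `smoothed = FALSE`, and the zero-SD pixel count.
#' @export
normalize_to_sd <- function(movie, stats = NULL) {
  stopifnot(inherits(movie, "vsd_movie"))
  if (is.null(stats)) stats <- baseline_stats(movie)
  if (all(stats$sd == 0))
    stop("all pixels have zero baseline SD; normalization undefined")
  nT <- dim(movie$data)[1]
  mu <- array(rep(stats$mean, each = nT), dim = dim(movie$data))
  sdev <- stats$sd
  sdev[sdev == 0] <- NA_real_
  sda <- array(rep(sdev, each = nT), dim = dim(movie$data))
  res <- list(data = (movie$data - mu) / sda,
              frame_interval_ms = movie$frame_interval_ms,
              stim_frame = movie$stim_frame,
              stim_site = movie$stim_site,
              rois = movie$rois,
              smoothed = FALSE,
              kernel = NULL,
              n_masked_pixels = stats$n_zero_sd)
  class(res) <- "vsd_norm"
  res
}

#' @export
print.vsd_norm <- function(x, ...) {
  d <- dim(x$data)
  cat("<vsd_norm> ", d[1], " frames x ", d[2], " x ", d[3],
      " px (baseline-SD units), smoothed: ", x$smoothed,
      if (x$n_masked_pixels > 0)
        paste0(", ", x$n_masked_pixels, " zero-SD pixel(s) masked"),
      "\n", sep = "")
  invisible(x)
}

#' Spatiotemporal Gaussian smoothing
#'
#' Convolves the stack with a truncated 5 x 5 spatial Gaussian (sigma 1
#' pixel) followed by a length-3 temporal Gaussian (sigma 1 frame), both
#' renormalized to unit sum (over in-bounds support at the borders), so
#' constant stacks pass through unchanged.
#'
#' @param normalized A `vsd_norm` (or `vsd_movie`).
#' @param spatial_size,spatial_sigma Spatial kernel length (pixels) and SD.
#' @param temporal_size,temporal_sigma Temporal kernel length (frames) and SD.
#' @return The same class of object, smoothed, with `smoothed = TRUE` and
#'   the kernel parameters recorded.
#' @export
smooth_movie <- function(normalized, spatial_size = 5L, spatial_sigma = 1,
                         temporal_size = 3L, temporal_sigma = 1) {
  normalized$data <- smooth_stack(normalized$data, spatial_size,
                                  spatial_sigma, temporal_size,
                                  temporal_sigma)
  normalized$smoothed <- TRUE
  normalized$kernel <- list(spatial_size = spatial_size,
                            spatial_sigma = spatial_sigma,
                            temporal_size = temporal_size,
                            temporal_sigma = temporal_sigma)
  normalized
}

#' Activated-pixel mask
#'
#' A pixel is activated at a frame iff its normalized amplitude is at least
#' `threshold` baseline-SD multiples above its baseline mean (inclusive:
#' exactly 1 SD counts at the default threshold).
#'
#' @param normalized A `vsd_norm`.
#' @param threshold Activation threshold in SD multiples (default 1).
#' @return A list: `mask` (logical stack; `NA`-masked pixels are `FALSE`),
#'   `per_frame` (activated-pixel count per frame), `threshold`.
#' @export
activation_mask <- function(normalized, threshold = 1) {
  stopifnot(inherits(normalized, "vsd_norm"))
  mask <- normalized$data >= threshold
  mask[is.na(mask)] <- FALSE
  list(mask = mask,
       per_frame = apply(mask, 1, sum),
       threshold = threshold)
}

#' ROI time course and peak latency
#'
#' Spatial mean over an ROI rectangle per frame; the peak is the maximum
#' over post-stimulation frames (ties broken to the earliest frame) and its
#' latency is reported in milliseconds relative to stimulation onset.
#'
#' @param normalized A `vsd_norm`.
#' @param roi ROI rectangle `c(r0, r1, c0, c1)`, 0-based half-open, or the
#'   name of an ROI stored in the object.
#' @param exclude_frames Number of frames from stimulation onset to exclude
#'   from the peak search (stimulation-artifact guard; default 0).
#' @return An `roi_timecourse` list: `trace` (per-frame mean), `peak_frame`
#'   (0-based), `peak_amplitude`, `latency_ms`
#'   (`(peak_frame - stim_frame) * frame_interval_ms`).
#' @export
roi_timecourse <- function(normalized, roi, exclude_frames = 0L) {
  stopifnot(inherits(normalized, "vsd_norm"))
  if (is.character(roi)) {
    if (is.null(normalized$rois[[roi]])) stop("no ROI named '", roi, "'")
    roi <- normalized$rois[[roi]]
  }
  d <- dim(normalized$data)
  check_roi(roi, d[2:3])
  sub <- normalized$data[, (roi[1] + 1L):roi[2], (roi[3] + 1L):roi[4],
                         drop = FALSE]
  trace <- rowMeans(matrix(sub, nrow = d[1]), na.rm = TRUE)
  first <- normalized$stim_frame + exclude_frames  # 0-based
  post <- trace[(first + 1L):d[1]]
  rel <- which.max(post) - 1L  # earliest maximum
  peak_frame <- first + rel
  res <- list(trace = trace,
              roi = roi,
              peak_frame = peak_frame,
              peak_amplitude = post[rel + 1L],
              latency_ms = (peak_frame - normalized$stim_frame) *
                normalized$frame_interval_ms,
              stim_frame = normalized$stim_frame,
              frame_interval_ms = normalized$frame_interval_ms)
  class(res) <- "roi_timecourse"
  res
}

#' Summarize a photostimulation response
#'
#' Within a post-stimulation analysis window (default 114 frames, about
#' 500 ms, starting at stimulation onset; the first `artifact_frames` are
#' excluded as the laser artifact), measures: the activated-pixel count
#' (union over window frames), the mean amplitude over activated
#' pixel-frames, each ROI's peak latency, and the CA1/SUB ratio of mean
#' window activity when ROIs named `CA1` and `SUB` are present.
#'
#' @param normalized A `vsd_norm`.
#' @param mask Optional [activation_mask()] result (recomputed if absent).
#' @param rois Named list of ROI rectangles (defaults to those stored in
#'   the object).
#' @param window Analysis window `c(start, end)`, 0-based half-open frame
#'   indices; default `c(stim, stim + 114)` clipped to the movie length.
#' @param artifact_frames Frames from stimulation onset excluded from all
#'   measures (default 2).
#' @param threshold Activation threshold passed on when `mask` is absent.
#' @return A `vsd_response` list: `n_activated`, `mean_amplitude`,
#'   `latencies_ms`, `peak_amplitudes`, `roi_window_means`,
#'   `ca1_sub_ratio` (or `NA` with a flag if the SUB mean is not positive),
#'   `window`, `artifact_frames`.
#' @export
summarize_response <- function(normalized, mask = NULL, rois = NULL,
                               window = NULL, artifact_frames = 2L,
                               threshold = 1) {
  stopifnot(inherits(normalized, "vsd_norm"))
  d <- dim(normalized$data)
  stim <- normalized$stim_frame
  if (is.null(window)) window <- c(stim, min(stim + 114L, d[1]))
  if (window[1] < stim || window[2] > d[1] || window[1] >= window[2])
    stop("analysis window [", window[1], ", ", window[2],
         ") must lie within the post-stimulation frames")
  if (is.null(mask)) mask <- activation_mask(normalized, threshold)
  if (is.null(rois)) rois <- normalized$rois
  eff_start <- window[1] + artifact_frames
  if (eff_start >= window[2])
    stop("artifact exclusion leaves an empty analysis window")
  fidx <- (eff_start + 1L):window[2]  # R indices of analysed frames
  wmask <- mask$mask[fidx, , , drop = FALSE]
  union_mask <- apply(wmask, c(2, 3), any)
  vals <- normalized$data[fidx, , , drop = FALSE][wmask]
  tcs <- lapply(rois, function(r)
    roi_timecourse(normalized, r, exclude_frames = artifact_frames))
  roi_window_means <- vapply(rois, function(r) {
    sub <- normalized$data[fidx, (r[1] + 1L):r[2], (r[3] + 1L):r[4],
                           drop = FALSE]
    mean(sub, na.rm = TRUE)
  }, numeric(1))
  ratio <- NA_real_
  ratio_flag <- NULL
  if (all(c("CA1", "SUB") %in% names(rois))) {
    if (is.na(roi_window_means[["SUB"]]) || roi_window_means[["SUB"]] <= 0) {
      ratio_flag <- "SUB ROI mean activity <= 0; CA1/SUB ratio undefined"
    } else {
      ratio <- roi_window_means[["CA1"]] / roi_window_means[["SUB"]]
    }
  }
  res <- list(n_activated = sum(union_mask),
              mean_amplitude = if (length(vals)) mean(vals) else NA_real_,
              per_frame_activated = mask$per_frame[fidx],
              latencies_ms = vapply(tcs, `[[`, numeric(1), "latency_ms"),
              peak_amplitudes = vapply(tcs, `[[`, numeric(1),
                                       "peak_amplitude"),
              timecourses = tcs,
              roi_window_means = roi_window_means,
              ca1_sub_ratio = ratio,
              ratio_flag = ratio_flag,
              window = window,
              artifact_frames = artifact_frames,
              threshold = mask$threshold)
  class(res) <- "vsd_response"
  res
}

#' @export
print.vsd_response <- function(x, ...) {
  cat("<vsd_response> window [", x$window[1], ", ", x$window[2],
      "), artifact frames excluded: ", x$artifact_frames, "\n",
      "  activated pixels (union): ", x$n_activated,
      ", mean amplitude: ", format(x$mean_amplitude, digits = 4), " SD\n",
      sep = "")
  if (length(x$latencies_ms))
    cat("  peak latencies (ms): ",
        paste(names(x$latencies_ms),
              format(x$latencies_ms, digits = 4), sep = " = ",
              collapse = ", "), "\n", sep = "")
  if (!is.na(x$ca1_sub_ratio))
    cat("  CA1/SUB activity ratio: ", format(x$ca1_sub_ratio, digits = 4),
        "\n", sep = "")
  invisible(x)
}

#' One-stop VSD quantification
#'
#' Runs the full pipeline in the canonical order: dI/I, baseline-SD
#' normalization, optional spatiotemporal smoothing, activated-pixel
#' masking and response summarization. Thresholding is applied to the
#' smoothed stack by default (matching the displayed activation maps); set
#' `smooth = FALSE` to threshold the unsmoothed normalized stack.
#'
#' @param movie A `vsd_movie`.
#' @param smooth Apply the Gaussian spatiotemporal filters (default TRUE).
#' @param threshold Activation threshold in SD multiples.
#' @param window,artifact_frames See [summarize_response()].
#' @return A `vsd_response`.
#' @export
#' @examples
#' mov <- generate_vsd_movie(vsd_config(frames = 150, baseline_frames = 60),
#'                           seed = 1)
#' vsd_quantify(mov)
vsd_quantify <- function(movie, smooth = TRUE, threshold = 1,
                         window = NULL, artifact_frames = 2L) {
  dff <- compute_dff(movie)
  nm <- normalize_to_sd(dff)
  if (smooth) nm <- smooth_movie(nm)
  summarize_response(nm, window = window, artifact_frames = artifact_frames,
                     threshold = threshold)
}
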