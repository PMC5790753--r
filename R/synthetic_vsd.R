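#' Configuration for the synthetic VSD movie generator
#'
#' Emulates a photostimulation trial in a hippocampal slice: a flat
#' baseline with i.i.d. Gaussian pixel noise, a brief stimulation artifact
#' at the uncaging site, and one activation component per responding
#' structure. Each component is a temporal Gaussian bump (the waveform is a
#' modeling choice; peak at its configured latency) scaled spatially by an
#' exponential decay with pixel distance from a designated border column
#' within its footprint, mimicking activation that falls off with distance
#' from the CA1/subiculum border. Component amplitudes are expressed in
#' baseline-SD units; a component with `couple_to_stim = TRUE` is further
#' attenuated by `exp(-|stim_col - border_col| / decay_px)`, so moving the
#' stimulation site away from the border weakens the coupled (downstream)
#' response.
#'
#' Defaults follow the acquisition protocol: 2000 frames of which 500 are
#' baseline, 4.4 ms/frame, 60 x 88 pixels, with a subiculum component
#' peaking 40.8 ms and a CA1 component peaking 78.2 ms after stimulation.
#'
#' @param frames Total frame count.
#' @param baseline_frames Frames before stimulation onset (stimulation
#'   frame = `baseline_frames`, 0-based). Must be < `frames` and >= 50.
#' @param frame_interval_ms Milliseconds per frame.
#' @param height,width Frame size in pixels.
#' @param baseline_level Mean baseline intensity (arbitrary camera units).
#' @param noise_sd SD of additive Gaussian pixel noise. Amplitudes given in
#'   SD units are realized as `amplitude * noise_sd` raw intensity (unit SD
#'   is assumed when `noise_sd = 0`, for noise-free construction checks).
#' @param artifact List `site = c(row, col)` (0-based), `amplitude_sd`,
#'   `n_frames`, `radius_px`: an impulse at the stimulation site.
#' @param stim_site `c(row, col)`, 0-based.
#' @param border_col 0-based column of the CA1/subiculum border.
#' @param rois Named list of 0-based half-open ROI rectangles.
#' @param components List of activation components; each a list with
#'   `name`, `footprint` (`c(r0, r1, c0, c1)`, 0-based half-open),
#'   `amplitude_sd`, `latency_ms` (> 0), `width_ms`, `border_col`,
#'   `decay_px`, `couple_to_stim`.
#' @return A `vsd_config` list.
#' @export
vsd_config <- function(frames = 2000L, baseline_frames = 500L,
                       frame_interval_ms = 4.4,
                       height = 60L, width = 88L,
                       baseline_level = 1000, noise_sd = 1,
                       artifact = list(amplitude_sd = 30, n_frames = 2L,
                                       radius_px = 2L),
                       stim_site = c(30L, 48L),
                       border_col = 44L,
                       rois = list(SUB = c(10L, 50L, 50L, 70L),
                                   CA1 = c(10L, 50L, 24L, 44L)),
                       components = NULL) {
  if (baseline_frames >= frames)
    stop("baseline_frames must be smaller than the total frame count")
  if (baseline_frames < 50)
    stop("need >= 50 baseline frames for baseline statistics")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.finite(baseline_level) || baseline_level <= 0)
    stop("baseline_level must be > 0")
  if (is.null(components)) {
    components <- list(
      list(name = "SUB", footprint = c(10L, 50L, border_col, width),
           amplitude_sd = 5, latency_ms = 40.8, width_ms = 10,
           border_col = stim_site[2], decay_px = 25,
           couple_to_stim = FALSE),
      list(name = "CA1", footprint = c(10L, 50L, 0L, border_col),
           amplitude_sd = 5, latency_ms = 78.2, width_ms = 10,
           border_col = border_col, decay_px = 20,
           couple_to_stim = TRUE))
  }
  for (comp in components) {
    check_roi(comp$footprint, c(height, width),
              paste0("component ", comp$name %||% "?"))
    if (!is.finite(comp$latency_ms) || comp$latency_ms <= 0)
      stop("component latencies must be > 0")
    if (!is.finite(comp$amplitude_sd) || comp$amplitude_sd < 0)
      stop("component amplitudes must be >= 0")
    if (!is.finite(comp$width_ms) || comp$width_ms <= 0)
      stop("component width_ms must be > 0")
  }
  for (nm in names(rois)) check_roi(rois[[nm]], c(height, width), nm)
  if (stim_site[1] < 0 || stim_site[1] >= height ||
      stim_site[2] < 0 || stim_site[2] >= width)
    stop("stim_site outside frame bounds")
  structure(list(frames = as.integer(frames),
                 baseline_frames = as.integer(baseline_frames),
                 frame_interval_ms = frame_interval_ms,
                 height = as.integer(height), width = as.integer(width),
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 artifact = artifact, stim_site = as.integer(stim_site),
                 border_col = as.integer(border_col), rois = rois,
                 components = components),
            class = "vsd_config")
}

# spatial weight of a component on the pixel grid: exponential decay with
# column distance from its border column, zero outside the footprint
component_weight <- function(comp, height, width) {
  wmat <- matrix(0, height, width)
  fp <- comp$footprint
  rows <- (fp[1] + 1L):fp[2]
  cols <- (fp[3] + 1L):fp[4]
  dist <- abs((cols - 1L) - comp$border_col)  # 0-based column distance
  wcol <- exp(-dist / comp$decay_px)
  wmat[rows, cols] <- matrix(wcol, length(rows), length(cols), byrow = TRUE)
  wmat
}

#' Generate a synthetic VSD movie
#'
#' Builds `baseline + noise + artifact + activation components` per the
#' configuration, embeds metadata (stimulation frame/site, ROIs), and is a
#' pure function of `(config, seed)`.
#'
#' @param config A [vsd_config()].
#' @param seed Integer seed for the pixel noise.
#' @return A `vsd_movie`.
#' @export
#' @examples
#' mov <- generate_vsd_movie(vsd_config(frames = 120, baseline_frames = 60),
#'                           seed = 1)
#' mov
generate_vsd_movie <- function(config = vsd_config(), seed = 1L) {
  stopifnot(inherits(config, "vsd_config"))
  set.seed(as.integer(seed))
  nT <- config$frames; h <- config$height; w <- config$width
  sd_unit <- if (config$noise_sd > 0) config$noise_sd else 1
  x <- array(config$baseline_level, dim = c(nT, h, w))
  if (config$noise_sd > 0)
    x <- x + array(rnorm(nT * h * w, sd = config$noise_sd), dim = c(nT, h, w))
  t_ms <- (seq_len(nT) - 1L - config$baseline_frames) * config$frame_interval_ms
  for (comp in config$components) {
    amp <- comp$amplitude_sd
    if (isTRUE(comp$couple_to_stim))
      amp <- amp * exp(-abs(config$stim_site[2] - comp$border_col) /
                         comp$decay_px)
    bump <- amp * sd_unit *
      exp(-(t_ms - comp$latency_ms)^2 / (2 * comp$width_ms^2))
    wmat <- component_weight(comp, h, w)
    fp <- comp$footprint
    rows <- (fp[1] + 1L):fp[2]; cols <- (fp[3] + 1L):fp[4]
    wsub <- wmat[rows, cols, drop = FALSE]
    # time x pixel outer product matches (frame, row, col) column-major layout
    x[, rows, cols] <- x[, rows, cols] +
      array(outer(bump, as.vector(wsub)),
            dim = c(nT, length(rows), length(cols)))
  }
  art <- config$artifact
  if (!is.null(art) && art$n_frames > 0) {
    site <- config$stim_site
    rr <- pmax(1L, site[1] + 1L - art$radius_px):pmin(h, site[1] + 1L + art$radius_px)
    cc <- pmax(1L, site[2] + 1L - art$radius_px):pmin(w, site[2] + 1L + art$radius_px)
    tt <- config$baseline_frames + seq_len(art$n_frames)  # R idx of stim..stim+n-1
    x[tt, rr, cc] <- x[tt, rr, cc] + art$amplitude_sd * sd_unit
  }
  vsd_movie(x, frame_interval_ms = config$frame_interval_ms,
            stim_frame = config$baseline_frames,
            stim_site = config$stim_site, rois = config$rois)
}
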