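#' Construct a VSD movie object
#'
#' A voltage-sensitive dye movie: an intensity stack with acquisition
#' metadata. Frames and pixels are indexed 0-based in all metadata
#' (stimulation frame, ROI rectangles) and all windows are half-open,
#' matching the sidecar file contract; R's 1-based indexing is internal.
#'
#' @param data Numeric array `frames x height x width`.
#' @param frame_interval_ms Acquisition interval per frame (default 4.4 ms).
#' @param stim_frame 0-based index of the photostimulation onset frame.
#'   Must be >= 50 so the 50-frame baseline window fits.
#' @param stim_site Optional `c(row, col)` (0-based) of the stimulation site.
#' @param rois Named list of ROI rectangles `c(r0, r1, c0, c1)`, 0-based
#'   half-open (`r0 <= row < r1`, `c0 <= col < c1`).
#' @param field_of_view_mm `c(height_mm, width_mm)` of the imaged field
#'   (default 1.07 x 1.28 mm over 60 x 88 pixels).
#' @return A `vsd_movie` object.
#' @export
vsd_movie <- function(data, frame_interval_ms = 4.4, stim_frame,
                      stim_site = NULL, rois = list(),
                      field_of_view_mm = c(1.07, 1.28)) {
  if (length(dim(data)) != 3) stop("data must be a frames x height x width array")
  if (!is.numeric(stim_frame) || stim_frame < 50)
    stop("stim_frame must be >= 50 so the 50-frame baseline window fits")
  if (stim_frame >= dim(data)[1])
    stop("stim_frame beyond the last frame")
  if (any(!is.finite(data))) stop("movie intensities must be finite")
  m <- structure(list(data = data,
                      frame_interval_ms = frame_interval_ms,
                      stim_frame = as.integer(stim_frame),
                      stim_site = if (!is.null(stim_site)) as.integer(stim_site),
                      rois = rois,
                      field_of_view_mm = field_of_view_mm),
                 class = "vsd_movie")
  for (nm in names(rois)) check_roi(rois[[nm]], dim(data)[2:3], nm)
  m
}

check_roi <- function(roi, hw, name = "roi") {
  if (length(roi) != 4) stop(name, ": ROI must be c(r0, r1, c0, c1)")
  r0 <- roi[1]; r1 <- roi[2]; c0 <- roi[3]; c1 <- roi[4]
  if (r0 < 0 || c0 < 0 || r1 > hw[1] || c1 > hw[2] || r0 >= r1 || c0 >= c1)
    stop(name, ": ROI [", paste(roi, collapse = ","),
         ") outside frame bounds ", hw[1], "x", hw[2], " or empty")
  invisible(roi)
}

#' @export
print.vsd_movie <- function(x, ...) {
  d <- dim(x$data)
  cat("<vsd_movie> ", d[1], " frames x ", d[2], " x ", d[3], " px, ",
      x$frame_interval_ms, " ms/frame, stim at frame ", x$stim_frame,
      " (0-based)\n", sep = "")
  if (length(x$rois))
    cat("  ROIs:", paste(names(x$rois), collapse = ", "), "\n")
  invisible(x)
}

#' Write a VSD movie as multi-frame TIFF plus JSON sidecar
#'
#' Intensities are stored as 32-bit TIFF samples scaled to `[0, 1]`; the
#' affine scale and offset are recorded in the sidecar so reading restores
#' the original values (round-trip error is about `range * 2^-32`). The
#' sidecar carries the acquisition metadata: frame interval, 0-based
#' stimulation frame/site, ROI rectangles and field of view.
#'
#' @param movie A `vsd_movie`.
#' @param path Output TIFF path; the sidecar is written next to it as
#'   `<path>.json` unless `sidecar` is given.
#' @param sidecar Optional explicit sidecar path.
#' @return `path`, invisibly.
#' @export
write_vsd_movie <- function(movie, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(movie, "vsd_movie"))
  x <- movie$data
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(x)[1]),
                   function(i) (x[i, , ] - lo) / scale)
  suppressWarnings(tiff::writeTIFF(frames, path, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  meta <- list(frame_interval_ms = movie$frame_interval_ms,
               stim_frame = movie$stim_frame,
               stim_site = movie$stim_site,
               rois = movie$rois,
               field_of_view_mm = movie$field_of_view_mm,
               n_frames = dim(x)[1], height = dim(x)[2], width = dim(x)[3],
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a VSD movie from TIFF plus JSON sidecar
#'
#' @param path TIFF path written by [write_vsd_movie()] (or any grayscale
#'   multi-frame TIFF with a conforming sidecar).
#' @param sidecar Sidecar JSON path (default `<path>.json`).
#' @return A `vsd_movie`.
#' @export
read_vsd_movie <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) stop("sidecar file not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$stim_frame)) stop("sidecar missing 'stim_frame'")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (!is.null(meta$n_frames) && length(frames) != meta$n_frames)
    stop("sidecar/TIFF mismatch: sidecar says ", meta$n_frames,
         " frames, file has ", length(frames))
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  x <- array(0, dim = c(length(frames), h, w))
  off <- meta$intensity_offset %||% 0
  sc <- meta$intensity_scale %||% 1
  for (i in seq_along(frames)) x[i, , ] <- frames[[i]] * sc + off
  rois <- lapply(meta$rois, unlist)
  vsd_movie(x, frame_interval_ms = meta$frame_interval_ms %||% 4.4,
            stim_frame = meta$stim_frame,
            stim_site = unlist(meta$stim_site),
            rois = rois,
            field_of_view_mm = unlist(meta$field_of_view_mm) %||% c(1.07, 1.28))
}
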