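# Time-lapse movie container.  Frames are stored as a 3D array
# [rows, cols, frames] in arbitrary fluorescence units, with the physical
# calibration (um per pixel, seconds per frame) attached.  Movies are 2D+T:
# any z dimension must be projected before entry.

#' Construct a time-lapse movie
#'
#' @param frames 3D numeric array `[rows, cols, frames]` (a matrix is treated
#'   as a single frame).  Intensities must be finite and non-negative.
#' @param pixel_size microns per pixel (> 0).
#' @param frame_interval seconds per frame (> 0).
#' @param channel_role `"pHluorin"` (dynamic green channel) or
#'   `"static_red"` (single-frame structural reporter).
#' @param t0 acquisition start time in seconds.
#' @return object of class `timelapse_movie`.
#' @export
timelapse_movie <- function(frames, pixel_size, frame_interval,
                            channel_role = c("pHluorin", "static_red"),
                            t0 = 0) {
  channel_role <- match.arg(channel_role)
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L) stop("frames must be a [rows, cols, frames] array")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0) stop("pixel_size must be a single positive number")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a single positive number")
  if (anyNA(frames) || any(!is.finite(frames))) stop("intensities must be finite")
  if (any(frames < 0)) stop("intensities must be >= 0")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, channel_role = channel_role, t0 = t0),
    class = "timelapse_movie"
  )
}

#' @export
print.timelapse_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<timelapse_movie> %d x %d px, %d frame(s), %.4g um/px, %.4g s/frame, %s\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval, x$channel_role))
  invisible(x)
}

#' @export
dim.timelapse_movie <- function(x) dim(x$frames)

n_frames <- function(movie) dim(movie$frames)[3]
frame_times <- function(movie) movie$t0 + (seq_len(n_frames(movie)) - 1L) * movie$frame_interval

#' Read a movie from a multi-page TIFF
#'
#' @param path TIFF stack path.
#' @param pixel_size,frame_interval physical calibration (um/px, s/frame).
#' @inheritParams timelapse_movie
#' @return `timelapse_movie`.
#' @export
read_movie <- function(path, pixel_size, frame_interval,
                       channel_role = c("pHluorin", "static_red"), t0 = 0) {
  timelapse_movie(read_tiff(path), pixel_size = pixel_size,
                  frame_interval = frame_interval,
                  channel_role = match.arg(channel_role), t0 = t0)
}

#' Write a movie to a multi-page TIFF (float32 pixels)
#'
#' Calibration is stored in a JSON side-car `<path>.json` so that
#' `read_movie` round-trips are self-describing.
#'
#' @param movie `timelapse_movie`.
#' @param path output path.
#' @param sidecar write the calibration side-car (default TRUE).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, sidecar = TRUE) {
  stopifnot(inherits(movie, "timelapse_movie"))
  write_tiff(movie$frames, path, bits = 32L)
  if (sidecar) {
    jsonlite::write_json(
      list(pixel_size = movie$pixel_size, frame_interval = movie$frame_interval,
           channel_role = movie$channel_role, t0 = movie$t0),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Kymograph of a movie along the axon path
#'
#' Position x time matrix: for every arc position sample of the axon path,
#' the maximum intensity over a small transverse band is taken per frame.
#'
#' @param movie `timelapse_movie`.
#' @param geometry `axon_geometry`.
#' @param half_width_px transverse half-width in pixels (default 1).
#' @return matrix `[position, time]` with arc positions (um) as rownames.
#' @export
kymograph <- function(movie, geometry, half_width_px = 1L) {
  s <- geometry$axon_samples
  nr <- dim(movie$frames)[1]
  ky <- matrix(0, nrow = nrow(s), ncol = n_frames(movie))
  for (i in seq_len(nrow(s))) {
    rows <- pmin(pmax((s$row[i] - half_width_px):(s$row[i] + half_width_px), 0L), nr - 1L)
    ky[i, ] <- apply(movie$frames[rows + 1L, s$col[i] + 1L, , drop = FALSE], 3, max)
  }
  rownames(ky) <- sprintf("%.3f", s$arc)
  ky
}

#' Export a kymograph as PNG
#'
#' Renders position (rows) by time (columns), dark-to-bright grayscale.
#' Requires a PNG-capable graphics device.
#'
#' @param ky kymograph matrix from [kymograph()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_kymograph_png <- function(ky, path) {
  grDevices::png(path, width = ncol(ky), height = nrow(ky))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::image(t(ky)[, rev(seq_len(nrow(ky))), drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  useRaster = TRUE)
  invisible(path)
}
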