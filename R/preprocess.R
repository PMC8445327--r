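# Preprocessing: rigid registration (integer translation, cross-correlation
# against the temporal median image), whole-field exponential bleach
# correction, and the dF/F_avg transform used for candidate detection.
# Order of operations in the pipeline: register first, then bleach-correct
# (registration is photometry-neutral; bleach fitting benefits from a stable
# field).

#' Fit a whole-field exponential bleach model
#'
#' Least-squares fit of `A * exp(-t / tau) + C` to the whole-field mean
#' intensity trace.  If the nonlinear fit does not converge, a log-linear
#' fit with `C = 0` is used and flagged.  A constant movie yields the
#' identity model (`A = 0`).
#'
#' @param movie `timelapse_movie` with at least 10 frames.
#' @return list of class `bleach_model`: `A`, `tau` (s), `C`,
#'   `residual_rms`, `fallback`, `constant`, plus the frame times.
#' @export
fit_bleach <- function(movie) {
  stopifnot(inherits(movie, "timelapse_movie"))
  nt <- n_frames(movie)
  if (nt < 10) stop("bleach fitting needs at least 10 frames")
  tt <- frame_times(movie) - movie$t0
  m <- colMeans(matrix(movie$frames, ncol = nt))
  out <- list(times = tt, fallback = FALSE, constant = FALSE)
  rel_sd <- stats::sd(m) / max(mean(m), .Machine$double.eps)
  if (rel_sd < 1e-9) {
    out <- c(out, list(A = 0, tau = Inf, C = mean(m), residual_rms = 0))
    out$constant <- TRUE
    class(out) <- "bleach_model"
    return(out)
  }
  # log-linear seed (C = 0)
  pos <- m > 0
  lf <- stats::lm(log(m[pos]) ~ tt[pos])
  tau0 <- if (stats::coef(lf)[2] < 0) -1 / stats::coef(lf)[2] else diff(range(tt)) * 10
  A0 <- exp(stats::coef(lf)[[1]])
  # an exact exponential (zero residual) breaks nls ("singular gradient");
  # take the closed-form fit directly when the log-linear model is perfect
  if (tau0 > 0 && all(pos)) {
    res0 <- m - A0 * exp(-tt / tau0)
    if (sqrt(mean(res0^2)) < 1e-8 * mean(m)) {
      out <- c(out, list(A = A0, tau = tau0, C = 0, residual_rms = 0))
      class(out) <- "bleach_model"
      return(out)
    }
  }
  start <- list(A = max(m) - min(m), tau = tau0, C = min(m) * 0.5)
  fit <- tryCatch(
    stats::nls(m ~ A * exp(-tt / tau) + C, start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit) && stats::coef(fit)[["tau"]] > 0) {
    cf <- stats::coef(fit)
    out <- c(out, list(A = cf[["A"]], tau = cf[["tau"]], C = cf[["C"]],
                       residual_rms = sqrt(mean(stats::resid(fit)^2))))
  } else {
    A <- exp(stats::coef(lf)[[1]])
    tau <- -1 / stats::coef(lf)[[2]]
    if (tau <= 0) tau <- Inf
    out <- c(out, list(A = A, tau = tau, C = 0,
                       residual_rms = sqrt(mean((m - A * exp(-tt / max(tau, 1e-12)))^2))))
    out$fallback <- TRUE
  }
  # a negligible fitted decay over the movie span is measurement jitter, not
  # bleaching: correcting by it would tilt flat baselines for no benefit
  decay_total <- if (is.finite(out$tau)) {
    abs(out$A) * (1 - exp(-max(tt) / out$tau))
  } else 0
  if (decay_total < 0.005 * mean(m)) {
    out$A <- 0; out$tau <- Inf; out$C <- mean(m); out$constant <- TRUE
  }
  class(out) <- "bleach_model"
  out
}

bleach_curve <- function(model, t) {
  if (model$constant || !is.finite(model$tau)) return(rep(model$A + model$C, length(t)))
  model$A * exp(-t / model$tau) + model$C
}

#' Apply a bleach model to a movie
#'
#' Frame `t` is divided by `fit(t) / fit(0)`, so the correction factor at
#' `t = 0` is exactly 1 and spatial contrasts within each frame are
#' preserved.
#'
#' @param movie `timelapse_movie`.
#' @param model `bleach_model` fitted on this movie (default: fit now).
#' @return bleach-corrected `timelapse_movie`.
#' @export
correct_bleach <- function(movie, model = fit_bleach(movie)) {
  tt <- frame_times(movie) - movie$t0
  if (model$constant) return(movie)
  f <- bleach_curve(model, tt)
  f0 <- bleach_curve(model, 0)
  if (any(f <= 0)) stop("bleach fit reaches non-positive values; cannot correct")
  fac <- f / f0
  frames <- movie$frames
  for (t in seq_along(fac)) frames[, , t] <- frames[, , t] / fac[t]
  timelapse_movie(frames, movie$pixel_size, movie$frame_interval,
                  movie$channel_role, movie$t0)
}

# FFT cross-correlation shift of one frame against a reference.
# Returns the integer (dr, dc) such that frame ~= reference shifted by (dr, dc),
# plus the normalized peak correlation.
.xcorr_shift <- function(ref, frame) {
  r <- ref - mean(ref); f <- frame - mean(frame)
  denom <- sqrt(sum(r^2) * sum(f^2))
  if (denom == 0) return(list(shift = c(0L, 0L), peak = 0))
  cc <- Re(stats::fft(Conj(stats::fft(r)) * stats::fft(f), inverse = TRUE)) /
    length(r)
  i <- which.max(cc)
  nr <- nrow(ref)
  dr <- (i - 1L) %% nr
  dc <- (i - 1L) %/% nr
  if (dr > nr / 2) dr <- dr - nr
  if (dc > ncol(ref) / 2) dc <- dc - ncol(ref)
  list(shift = c(as.integer(dr), as.integer(dc)), peak = max(cc) / denom)
}

#' Rigid (integer translation) registration
#'
#' Each frame is aligned to a reference image (temporal median by default)
#' by maximizing cross-correlation over integer translations; the inverse
#' shift is applied with edge-value padding.
#'
#' @param movie `timelapse_movie`.
#' @param reference `"median"` (temporal median image) or `"first"`.
#' @param max_shift_frac shifts beyond this fraction of the frame size flag
#'   the frame as a failed registration.
#' @param min_peak normalized correlation below which a frame is flagged
#'   unreliable (e.g. pure noise).
#' @return list of class `registration_model`: `shifts` (n x 2 integer
#'   matrix), `flagged` (logical per frame), `peaks`, `reference`,
#'   and `movie` (the registered movie).
#' @export
register_rigid <- function(movie, reference = c("median", "first"),
                           max_shift_frac = 0.2, min_peak = 0.3) {
  reference <- match.arg(reference)
  frames <- movie$frames
  d <- dim(frames)
  ref <- if (reference == "median") {
    # temporal median on a subsample of frames (<= 101) for tractability
    sel <- unique(round(seq(1, d[3], length.out = min(101L, d[3]))))
    m <- frames[, , sel, drop = FALSE]
    dim(m) <- c(d[1] * d[2], length(sel))
    matrix(apply(m, 1, stats::median), d[1], d[2])
  } else frames[, , 1]
  nT <- d[3]
  shifts <- matrix(0L, nT, 2)
  peaks <- numeric(nT)
  out <- frames
  for (t in seq_len(nT)) {
    xs <- .xcorr_shift(ref, frames[, , t])
    shifts[t, ] <- xs$shift
    peaks[t] <- xs$peak
    if (any(xs$shift != 0L)) out[, , t] <- .shift_pad(frames[, , t],
                                                      -xs$shift[1], -xs$shift[2])
  }
  flagged <- abs(shifts[, 1]) > max_shift_frac * d[1] |
    abs(shifts[, 2]) > max_shift_frac * d[2] | peaks < min_peak
  structure(list(shifts = shifts, peaks = peaks, flagged = flagged,
                 reference = reference,
                 movie = timelapse_movie(out, movie$pixel_size,
                                         movie$frame_interval,
                                         movie$channel_role, movie$t0)),
            class = "registration_model")
}

#' dF/F_avg transform
#'
#' Per pixel, `(F(t) - F_avg) / F_avg` where `F_avg` is that pixel's
#' all-time mean.  Background pixels — time-averaged intensity at or below
#' the floor — are set to 0.  The floor is the larger of the
#' `floor_quantile` quantile of the time-averaged image and
#' `floor_guard * q99.9` of it; the guard keeps the floor above background
#' on sparse fields where the axon covers only a few percent of pixels.
#'
#' @param movie bleach-corrected `timelapse_movie`.
#' @param floor_quantile quantile of the time-averaged image (default 0.05).
#' @param floor_guard fraction of the bright (99.9th percentile) intensity
#'   (default 0.25).
#' @return list of class `dff_movie`: `dff` array `[rows, cols, frames]`,
#'   `f_avg` matrix, `floor`, `mask` (TRUE = analyzable pixel), plus
#'   calibration fields.
#' @export
compute_dff_avg <- function(movie, floor_quantile = 0.05, floor_guard = 0.25) {
  frames <- movie$frames
  d <- dim(frames)
  m <- frames
  dim(m) <- c(d[1] * d[2], d[3])
  f_avg <- rowMeans(m)
  floor_val <- max(stats::quantile(f_avg, floor_quantile, names = FALSE),
                   floor_guard * stats::quantile(f_avg, 0.999, names = FALSE))
  mask <- f_avg > floor_val
  dff <- (m - f_avg) / ifelse(mask, f_avg, 1)
  dff[!mask, ] <- 0
  dim(dff) <- d
  structure(list(dff = dff, f_avg = matrix(f_avg, d[1], d[2]),
                 floor = floor_val, mask = matrix(mask, d[1], d[2]),
                 pixel_size = movie$pixel_size,
                 frame_interval = movie$frame_interval),
            class = "dff_movie")
}

#' Standard preprocessing chain
#'
#' Optional rigid registration, then bleach correction, then dF/F_avg.
#'
#' @param movie raw `timelapse_movie`.
#' @param register run rigid registration first (default TRUE).
#' @param reference registration reference, see [register_rigid()].
#' @return list: `movie` (registered + bleach-corrected), `dff`
#'   (`dff_movie`), `bleach` (`bleach_model`), `registration` (model or NULL).
#' @export
preprocess_movie <- function(movie, register = TRUE,
                             reference = c("median", "first")) {
  reg <- NULL
  if (register) {
    reg <- register_rigid(movie, match.arg(reference))
    movie <- reg$movie
    reg$movie <- NULL
  }
  bl <- fit_bleach(movie)
  corrected <- correct_bleach(movie, bl)
  list(movie = corrected, dff = compute_dff_avg(corrected), bleach = bl,
       registration = reg)
}
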