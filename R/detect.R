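# Fusion-event detection.  Candidate anchors are spatiotemporal local maxima
# of the dF/F_avg movie above a permissive floor; each anchor's ROI is grown
# down to one third of the peak (4-connected), re-anchored at the region's
# maximum raw-intensity pixel (the Wand-tool rule), and frozen at the peak
# frame for photometry.  Anchors are validated strongest-first on the
# ROI-mean raw trace — a rise 5-fold greater than the baseline SD sustained
# for at least 4 frames, baseline = the 10 frames preceding the event — and
# accepted events suppress weaker anchors over their above-threshold extent
# (validate-then-suppress, so a knife-edge event can be accepted through a
# neighbouring anchor when its strongest anchor narrowly fails).  Amplitude
# is measured on the seed-pixel trace, the fold-change the forward model
# defines; duration and validation use the ROI mean.  An exhaustive
# brute-force oracle feeds the same core from an independent enumeration for
# equivalence testing.
#
# Pixel coordinates and frame indices in inputs/outputs are 0-based.

#' Event detection configuration
#'
#' @param sd_multiple validation threshold in baseline SDs (default 5).
#' @param min_frames minimum number of frames above threshold (default 4).
#' @param baseline_frames baseline window before the event start (default 10).
#' @param min_baseline_frames smallest usable baseline; candidates earlier in
#'   the movie are rejected with reason `"no_baseline"` (default 3).
#' @param peak_window_frames amplitude search window after the start
#'   (default 10).
#' @param candidate_dff_threshold dF/F_avg floor for candidate pixels.
#' @param candidate_min_frames consecutive frames above the floor required of
#'   a candidate run (default 1).
#' @param merge_radius spatial non-maximum-suppression radius (um).
#' @param merge_frames temporal suppression window (frames).
#' @param displacement_substantial displacement below which an event is
#'   static (um).
#' @param displacement_exclusion displacement above which an event is
#'   excluded as mobile (um).
#' @param search_radius per-frame re-localization radius for tracking (um).
#' @param roi_max_px ROI growth cap; candidates exceeding it are rejected.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(sd_multiple = 5, min_frames = 4L,
                             baseline_frames = 10L, min_baseline_frames = 3L,
                             peak_window_frames = 10L,
                             candidate_dff_threshold = 0.3,
                             candidate_min_frames = 1L,
                             merge_radius = 1, merge_frames = 4L,
                             displacement_substantial = 2,
                             displacement_exclusion = 10,
                             search_radius = 1.5, roi_max_px = 400L) {
  stopifnot(sd_multiple > 0, min_frames >= 1, baseline_frames >= 1,
            min_baseline_frames >= 1, peak_window_frames >= 1,
            merge_radius > 0, displacement_substantial > 0,
            displacement_exclusion > displacement_substantial)
  structure(as.list(environment()), class = "detection_config")
}

# 4-connected ROI growth from a seed down to one third of the seed's value.
# Returns NULL if a grown pixel exceeds the seed (the seed is then not the
# event's maximum-intensity pixel; set allow_higher to keep growing, used
# after re-seeding at the raw-intensity maximum where a dimmer-baseline
# neighbour can carry a larger dF/F) or if the cap is exceeded.
.grow_roi <- function(arr, off, nr, nc, seed_r, seed_c, max_px = 400L,
                      allow_higher = FALSE) {
  # arr is the full dF/F array indexed linearly at frame offset `off`,
  # avoiding a frame-matrix copy per anchor
  peak <- arr[off + (seed_c - 1L) * nr + seed_r]
  if (peak <= 0) return(NULL)
  thr <- peak / 3
  visited <- logical(nr * nc)
  cap <- as.integer(max_px) + 8L
  queue <- integer(cap)          # linear pixel indices, FIFO
  seed_i <- (seed_c - 1L) * nr + seed_r
  queue[1L] <- seed_i
  visited[seed_i] <- TRUE
  head <- 1L; tail <- 1L
  out <- integer(cap); n_out <- 0L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    if (!allow_higher && arr[off + i] > peak + 1e-12) return(NULL)
    n_out <- n_out + 1L
    if (n_out > max_px) return(structure(list(), too_large = TRUE))
    out[n_out] <- i
    r <- (i - 1L) %% nr + 1L
    for (j in c(if (r > 1L) i - 1L, if (r < nr) i + 1L,
                if (i > nr) i - nr, if (i <= nr * (nc - 1L)) i + nr)) {
      if (!visited[j] && arr[off + j] >= thr) {
        visited[j] <- TRUE
        if (tail >= cap) return(structure(list(), too_large = TRUE))
        tail <- tail + 1L
        queue[tail] <- j
      }
    }
  }
  idx <- out[seq_len(n_out)]
  list(rows = (idx - 1L) %% nr + 1L, cols = (idx - 1L) %/% nr + 1L)
}

# ROI-mean and seed traces from the (bleach-corrected) raw movie, given the
# movie as a [pixels x frames] matrix (built once per detection run)
.roi_traces <- function(m, n_row, roi, seed_r, seed_c) {
  px <- (roi$cols - 1L) * n_row + roi$rows
  list(roi_mean = if (length(px) == 1L) m[px, ] else colMeans(m[px, , drop = FALSE]),
       seed = m[(seed_c - 1L) * n_row + seed_r, ])
}

# Build the final candidate for a dF/F local maximum: grow the one-third
# region in dF/F, re-anchor the seed at the region's maximum raw-intensity
# pixel (the Wand-tool rule), regrow around it if it moved, and extract the
# photometry traces.  Shared by the candidate detector and the oracle.
.build_candidate <- function(dff_arr, m, d, t, r, c, config) {
  n_row <- d[1]
  off <- (t - 1L) * d[1] * d[2]
  roi <- .grow_roi(dff_arr, off, d[1], d[2], r, c, config$roi_max_px)
  if (is.null(roi) || isTRUE(attr(roi, "too_large"))) return(NULL)
  raw <- m[(roi$cols - 1L) * n_row + roi$rows, t]
  k <- which.max(raw)
  if (roi$rows[k] != r || roi$cols[k] != c) {
    r <- roi$rows[k]; c <- roi$cols[k]
    roi <- .grow_roi(dff_arr, off, d[1], d[2], r, c, config$roi_max_px,
                     allow_higher = TRUE)
    if (is.null(roi) || isTRUE(attr(roi, "too_large"))) return(NULL)
  }
  tr <- .roi_traces(m, n_row, roi, r, c)
  list(row = r - 1L, col = c - 1L, peak_frame = t - 1L,
       peak_dff = dff_arr[off + (c - 1L) * n_row + r],
       roi = list(rows = roi$rows - 1L, cols = roi$cols - 1L),
       trace = tr$roi_mean, seed_trace = tr$seed)
}

# spatiotemporal local maxima of dff above the candidate threshold; returns
# data.frame(row, col, frame) (1-based) of seeds
.candidate_seeds <- function(dff_arr, thr, min_run) {
  d <- dim(dff_arr)
  m <- matrix(dff_arr, d[1] * d[2], d[3])
  above <- m > thr
  if (min_run > 1L) {
    run_ok <- above[, 1:(d[3] - min_run + 1L), drop = FALSE]
    for (k in 1L:(min_run - 1L)) {
      run_ok <- run_ok & above[, (1L + k):(d[3] - min_run + 1L + k), drop = FALSE]
    }
    keep_px <- which(rowSums(run_ok) > 0)
  } else {
    keep_px <- which(rowSums(above) > 0)
  }
  seeds <- list()
  for (px in keep_px) {
    a <- above[px, ]
    r <- rle(a)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= min_run
    for (i in which(ok)) {
      win <- starts[i]:ends[i]
      # every temporal local maximum within the run is a possible anchor;
      # a single anchor per run can differ from the exhaustive oracle on
      # knife-edge events whose acceptance depends on the anchor frame
      v <- m[px, win]
      prev <- c(if (win[1] > 1L) m[px, win[1] - 1L] else -Inf, v[-length(v)])
      nxt <- c(v[-1], if (win[length(win)] < d[3]) m[px, win[length(win)] + 1L]
                      else -Inf)
      for (pk in win[v >= prev & v >= nxt]) {
        seeds[[length(seeds) + 1L]] <- c(px, pk)
      }
    }
  }
  if (!length(seeds)) {
    return(data.frame(row = integer(0), col = integer(0), frame = integer(0),
                      dff = numeric(0)))
  }
  s <- do.call(rbind, seeds)
  row <- (s[, 1] - 1L) %% d[1] + 1L
  col <- (s[, 1] - 1L) %/% d[1] + 1L
  out <- data.frame(row = row, col = col, frame = s[, 2],
                    dff = m[cbind(s[, 1], s[, 2])])
  # spatial local max in the 3x3 neighbourhood at the peak frame (vectorized
  # neighbour lookups through linear indices into the 3D array)
  base <- (out$frame - 1L) * (d[1] * d[2]) + (out$col - 1L) * d[1] + out$row
  keep <- rep(TRUE, nrow(out))
  for (dr in -1L:1L) {
    for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      valid <- out$row + dr >= 1L & out$row + dr <= d[1] &
        out$col + dc >= 1L & out$col + dc <= d[2]
      idx <- base[valid] + dc * d[1] + dr
      keep[valid] <- keep[valid] & out$dff[valid] >= dff_arr[idx]
    }
  }
  out[keep, , drop = FALSE]
}

# shared non-maximum suppression / deduplication: strongest first, suppress
# anything within merge_radius (um) and merge_frames (frames)
.suppress <- function(df, strength, row, col, frame, pixel_size, config) {
  if (!nrow(df)) return(df)
  o <- order(-strength)
  rad2 <- (config$merge_radius / pixel_size)^2
  krow <- numeric(nrow(df)); kcol <- numeric(nrow(df)); kfr <- numeric(nrow(df))
  kidx <- integer(nrow(df)); nk <- 0L
  for (i in o) {
    if (nk > 0L) {
      s <- seq_len(nk)
      close_ <- (krow[s] - row[i])^2 + (kcol[s] - col[i])^2 <= rad2 &
        abs(kfr[s] - frame[i]) <= config$merge_frames
      if (any(close_)) next
    }
    nk <- nk + 1L
    krow[nk] <- row[i]; kcol[nk] <- col[i]; kfr[nk] <- frame[i]; kidx[nk] <- i
  }
  df[sort(kidx[seq_len(nk)]), , drop = FALSE]
}

#' Find candidate events in a dF/F_avg movie
#'
#' Spatiotemporal local maxima of dF/F_avg above
#' `candidate_dff_threshold`, non-maximum-suppressed within `merge_radius`
#' and `merge_frames`, each with its one-third-of-peak ROI grown at the peak
#' frame and its ROI-mean raw trace extracted.
#'
#' @param dff `dff_movie` from [compute_dff_avg()].
#' @param movie bleach-corrected `timelapse_movie` (photometry source).
#' @param config [detection_config()].
#' @return list of candidates; each has `row`, `col` (0-based), `peak_frame`
#'   (0-based), `peak_dff`, `roi`, `trace` (ROI mean), `seed_trace`.
#' @export
find_candidates <- function(dff, movie, config = detection_config()) {
  seeds <- .candidate_seeds(dff$dff, config$candidate_dff_threshold,
                            config$candidate_min_frames)
  seeds <- .suppress(seeds, seeds$dff, seeds$row, seeds$col, seeds$frame,
                     dff$pixel_size, config)
  d <- dim(movie$frames)
  m <- matrix(movie$frames, d[1] * d[2], d[3])
  out <- list()
  for (i in seq_len(nrow(seeds))) {
    cand <- .build_candidate(dff$dff, m, d, seeds$frame[i],
                             seeds$row[i], seeds$col[i], config)
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

#' Validate a candidate against the acceptance rule
#'
#' The start frame is the first frame of the rise: walking back from the
#' peak, the earliest frame whose predecessor is below the baseline
#' threshold `f0 + sd_multiple * sd0`, with `f0`/`sd0` computed from the
#' (up to) `baseline_frames` frames preceding it.  Accepted iff the ROI-mean
#' trace stays above the threshold for at least `min_frames` consecutive
#' frames from the start.  Candidates with fewer than `min_baseline_frames`
#' pre-event frames are rejected (`"no_baseline"`); baselines shorter than
#' `baseline_frames` are accepted but flagged.
#'
#' @param candidate candidate list from [find_candidates()].
#' @param config [detection_config()].
#' @return list: `accepted`, `start_frame` (0-based), `f0`, `sd0`,
#'   `n_above`, `baseline_frames_used`, `baseline_flag`, `reject_reason`.
#' @export
validate_event <- function(candidate, config = detection_config()) {
  trace <- candidate$trace
  nT <- length(trace)
  pk <- candidate$peak_frame + 1L
  reject <- function(reason, start = NA_integer_, f0 = NA_real_, sd0 = NA_real_,
                     bl = NA_integer_) {
    list(accepted = FALSE, start_frame = start, f0 = f0, sd0 = sd0,
         n_above = NA_integer_, baseline_frames_used = bl,
         baseline_flag = FALSE, reject_reason = reason)
  }
  # Find the event start: scanning candidate onsets from the peak backwards
  # over a lookback window, an onset s is valid when, with the baseline
  # taken from the (up to 10) frames preceding s, the trace is below
  # threshold at s-1, at or above it at s, and stays above it through the
  # peak.  The earliest valid onset wins, so an event riding on the tail of
  # an overlapping earlier rise is anchored to the clean pre-rise baseline
  # rather than to a contaminated one.
  lookback <- config$baseline_frames
  start <- NA_integer_; f0 <- NA_real_; sd0 <- NA_real_
  baseline_possible <- FALSE
  for (s in max(2L, pk - lookback):pk) {
    bl <- max(1L, s - config$baseline_frames):(s - 1L)
    if (length(bl) < config$min_baseline_frames) next
    baseline_possible <- TRUE
    f0s <- mean(trace[bl]); sd0s <- stats::sd(trace[bl])
    thr_s <- f0s + config$sd_multiple * sd0s
    # "<=" with a strict rise keeps the rule well-defined at sd0 = 0
    # (noise-free baselines sit exactly at the threshold)
    if (trace[s - 1L] <= thr_s && trace[s] > trace[s - 1L] &&
        all(trace[s:pk] >= thr_s)) {
      start <- s; f0 <- f0s; sd0 <- sd0s
      break
    }
  }
  if (!baseline_possible) return(reject("no_baseline"))
  if (is.na(start)) {
    # no onset in the lookback window crosses threshold up to the peak
    return(reject("below_threshold", pk - 1L))
  }
  bl <- max(1L, start - config$baseline_frames):(start - 1L)
  thr <- f0 + config$sd_multiple * sd0
  run <- 0L
  t <- start
  while (t <= nT && trace[t] >= thr) { run <- run + 1L; t <- t + 1L }
  if (run < config$min_frames) {
    return(reject("too_few_frames", start - 1L, f0, sd0, length(bl)))
  }
  list(accepted = TRUE, start_frame = start - 1L, f0 = f0, sd0 = sd0,
       n_above = run, baseline_frames_used = length(bl),
       baseline_flag = length(bl) < config$baseline_frames,
       reject_reason = NA_character_)
}

#' Event amplitude (dF/F0)
#'
#' The highest proportional increase over the baseline reached during the
#' peak period — the first `peak_window_frames` frames from the start.
#'
#' @param trace intensity trace (the seed-pixel trace in the standard
#'   pipeline).
#' @param f0 baseline intensity of that trace.
#' @param start_frame 0-based start frame.
#' @param peak_window_frames window length (frames).
#' @return amplitude (dimensionless).
#' @export
measure_amplitude <- function(trace, f0, start_frame,
                              peak_window_frames = 10L) {
  win <- (start_frame + 1L):min(length(trace), start_frame + peak_window_frames)
  max((trace[win] - f0) / f0)
}

#' Event duration
#'
#' Time from the start until the trace first decreases to within one
#' baseline SD of the baseline (`F <= f0 + sd0`).  If it never returns, the
#' duration is censored at the movie end and flagged.
#'
#' @param trace ROI-mean intensity trace.
#' @param f0,sd0 baseline mean and SD.
#' @param start_frame 0-based start frame.
#' @param frame_interval seconds per frame.
#' @return list: `duration_s`, `censored`.
#' @export
measure_duration <- function(trace, f0, sd0, start_frame, frame_interval) {
  nT <- length(trace)
  for (t in (start_frame + 1L):nT) {
    if (trace[t] <= f0 + sd0 + 1e-12) {
      return(list(duration_s = (t - 1L - start_frame) * frame_interval,
                  censored = FALSE))
    }
  }
  list(duration_s = (nT - 1L - start_frame) * frame_interval, censored = TRUE)
}

#' Track an event's displacement and classify its motion
#'
#' The maximum-intensity pixel is re-localized each frame within
#' `search_radius` of its previous position over the event's duration.
#' Cumulative displacement is the summed step length; a frame is "moving"
#' when its step exceeds one pixel.  Classes: `static` (cumulative below the
#' substantial-displacement threshold), `excluded_mobile` (cumulative above
#' the exclusion threshold, or moving in all but at most one frame, or
#' moving longer than static), otherwise `limited_displacement`.  Direction
#' is `unidirectional`/`bidirectional` for axonal events (sign agreement of
#' at least 90% of moving steps) and `anterograde`/`retrograde` for
#' collateral events (net motion away from / toward the axon).
#'
#' @param event list with `row`, `col`, `peak_frame`, `start_frame`, `f0`,
#'   `roi` fields (0-based) and `duration_s`.
#' @param movie bleach-corrected `timelapse_movie`.
#' @param compartment `"axon"` or `"collateral"` (controls direction labels).
#' @param config [detection_config()].
#' @return list: `cumulative_displacement`, `net_displacement` (um),
#'   `motion_class`, `direction_class`, `track_lost`.
#' @export
track_displacement <- function(event, movie, compartment = "axon",
                               config = detection_config()) {
  frames <- movie$frames
  d <- dim(frames)
  ps <- movie$pixel_size
  rad_px <- max(1L, round(config$search_radius / ps))
  n_track <- max(1L, ceiling(event$duration_s / movie$frame_interval))
  t0 <- event$start_frame + 1L
  t1 <- min(d[3], t0 + n_track - 1L)
  peak_int <- frames[event$row + 1L, event$col + 1L, event$peak_frame + 1L]
  lost_thr <- event$f0 + (peak_int - event$f0) / 3
  pos <- matrix(NA_real_, t1 - t0 + 1L, 2)
  cur <- c(event$row + 1L, event$col + 1L)
  track_lost <- FALSE
  n_done <- 0L
  for (t in t0:t1) {
    rr <- max(1L, cur[1] - rad_px):min(d[1], cur[1] + rad_px)
    cc <- max(1L, cur[2] - rad_px):min(d[2], cur[2] + rad_px)
    patch <- frames[rr, cc, t]
    i <- which.max(patch)
    if (patch[i] < lost_thr) { track_lost <- TRUE; break }
    cur <- c(rr[(i - 1L) %% length(rr) + 1L], cc[(i - 1L) %/% length(rr) + 1L])
    n_done <- n_done + 1L
    pos[n_done, ] <- cur
  }
  pos <- pos[seq_len(n_done), , drop = FALSE]
  if (n_done < 2L) {
    return(list(cumulative_displacement = 0, net_displacement = 0,
                motion_class = "static", direction_class = "none",
                track_lost = track_lost))
  }
  steps <- diff(pos) * ps
  step_len <- sqrt(rowSums(steps^2))
  cumulative <- sum(step_len)
  moving <- step_len > ps
  n_frames_track <- n_done
  axis <- if (compartment == "collateral") 1L else 2L  # rows for collaterals
  net <- (pos[n_done, axis] - pos[1, axis]) * ps
  motion_class <- if (cumulative < config$displacement_substantial) {
    "static"
  } else if (cumulative > config$displacement_exclusion ||
             sum(moving) >= n_frames_track - 1L) {
    "excluded_mobile"
  } else if (sum(!moving) > sum(moving)) {
    "limited_displacement"
  } else {
    "excluded_mobile"
  }
  direction_class <- if (cumulative < config$displacement_substantial) {
    "none"
  } else if (compartment == "collateral") {
    if (net > 0) "anterograde" else if (net < 0) "retrograde" else "none"
  } else {
    sgn <- sign(steps[moving, axis])
    sgn <- sgn[sgn != 0]
    if (!length(sgn)) "none"
    else if (max(mean(sgn > 0), mean(sgn < 0)) >= 0.9) "unidirectional"
    else "bidirectional"
  }
  list(cumulative_displacement = cumulative, net_displacement = net,
       motion_class = motion_class, direction_class = direction_class,
       track_lost = track_lost)
}

# assemble the event-table row for one validated candidate
.event_row <- function(id, cand, val, movie, geometry, config) {
  seed_bl <- {
    bl_hi <- val$start_frame            # 0-based start; baseline before it
    bl_lo <- max(0L, bl_hi - val$baseline_frames_used)
    mean(cand$seed_trace[(bl_lo + 1L):bl_hi])
  }
  amp <- measure_amplitude(cand$seed_trace, seed_bl, val$start_frame,
                           config$peak_window_frames)
  dur <- measure_duration(cand$trace, val$f0, val$sd0, val$start_frame,
                          movie$frame_interval)
  loc <- if (is.null(geometry)) {
    list(compartment_raw = "axon",
         arc_position = cand$col * movie$pixel_size,
         branch_id = NA_integer_, branch_arc = NA_real_)
  } else {
    locate_on_geometry(geometry, cand$row, cand$col)
  }
  ev <- list(row = cand$row, col = cand$col, peak_frame = cand$peak_frame,
             start_frame = val$start_frame, f0 = val$f0,
             duration_s = dur$duration_s, roi = cand$roi)
  disp <- track_displacement(ev, movie,
                             compartment = if (is.na(loc$compartment_raw)) "axon"
                                           else loc$compartment_raw,
                             config = config)
  data.frame(
    id = id, compartment_raw = loc$compartment_raw,
    arc_position = loc$arc_position, branch_id = loc$branch_id,
    branch_arc = loc$branch_arc, row = cand$row, col = cand$col,
    start_frame = val$start_frame, peak_frame = cand$peak_frame,
    amplitude = amp, duration_s = dur$duration_s,
    duration_censored = dur$censored,
    cumulative_displacement = disp$cumulative_displacement,
    net_displacement = disp$net_displacement,
    motion_class = disp$motion_class, direction_class = disp$direction_class,
    f0 = val$f0, sd0 = val$sd0,
    baseline_frames_used = val$baseline_frames_used,
    baseline_flag = val$baseline_flag, accepted = TRUE,
    reject_reason = NA_character_, stringsAsFactors = FALSE)
}

# Greedy detection core shared by the candidate detector and the oracle:
# anchors (possible seed/peak pairs) are visited strongest-dF/F first with a
# deterministic tie-break; an anchor within the merge radius and window of
# an already-ACCEPTED event is suppressed, otherwise it is grown, traced and
# validated.  Suppressing only around accepted events (not around stronger
# but invalid anchors) is what makes the two enumeration routes return the
# same accepted set: a knife-edge event whose strongest anchor narrowly
# fails can still be accepted through a neighbouring anchor on both routes.
.detect_from_seeds <- function(seeds, dff, movie, geometry, config,
                               keep_rejected = FALSE) {
  d <- dim(movie$frames)
  m <- matrix(movie$frames, d[1] * d[2], d[3])
  rows <- list(); rejected <- list()
  if (nrow(seeds)) {
    seeds <- seeds[order(-seeds$dff, seeds$frame, seeds$col, seeds$row), ,
                   drop = FALSE]
  }
  rad2 <- (config$merge_radius / movie$pixel_size)^2
  # accepted events suppress nearby anchors over their whole above-threshold
  # extent (start..end), padded by merge_frames: a second temporal local
  # maximum inside an accepted event's run is the same event
  acc_row <- numeric(0); acc_col <- numeric(0)
  acc_lo <- numeric(0); acc_hi <- numeric(0)
  near_accepted <- function(row0, col0, frame0) {
    length(acc_row) > 0 &&
      any((acc_row - row0)^2 + (acc_col - col0)^2 <= rad2 &
            frame0 >= acc_lo & frame0 <= acc_hi)
  }
  srow <- seeds$row; scol <- seeds$col; sframe <- seeds$frame
  for (i in seq_along(srow)) {
    if (near_accepted(srow[i] - 1L, scol[i] - 1L, sframe[i] - 1L)) next
    cand <- .build_candidate(dff$dff, m, d, sframe[i], srow[i], scol[i],
                             config)
    if (is.null(cand)) next
    # the anchor may have moved to the raw-intensity maximum; re-check
    if (near_accepted(cand$row, cand$col, cand$peak_frame)) next
    val <- validate_event(cand, config)
    if (!val$accepted) {
      if (keep_rejected) {
        rejected[[length(rejected) + 1L]] <- data.frame(
          id = NA_integer_, compartment_raw = NA_character_,
          arc_position = NA_real_, branch_id = NA_integer_,
          branch_arc = NA_real_, row = cand$row, col = cand$col,
          start_frame = val$start_frame, peak_frame = cand$peak_frame,
          amplitude = NA_real_, duration_s = NA_real_,
          duration_censored = NA, cumulative_displacement = NA_real_,
          net_displacement = NA_real_, motion_class = NA_character_,
          direction_class = NA_character_, f0 = val$f0, sd0 = val$sd0,
          baseline_frames_used = val$baseline_frames_used,
          baseline_flag = val$baseline_flag, accepted = FALSE,
          reject_reason = val$reject_reason, stringsAsFactors = FALSE)
      }
      next
    }
    acc_row <- c(acc_row, cand$row); acc_col <- c(acc_col, cand$col)
    acc_lo <- c(acc_lo, val$start_frame - config$merge_frames)
    acc_hi <- c(acc_hi, val$start_frame + val$n_above - 1L + config$merge_frames)
    rows[[length(rows) + 1L]] <- .event_row(NA_integer_, cand, val, movie,
                                            geometry, config)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else empty_event_table()
  if (nrow(ev)) {
    ev <- ev[order(ev$start_frame, ev$col, ev$row), , drop = FALSE]
    ev$id <- seq_len(nrow(ev))
  }
  ev <- as_event_table(ev)
  if (keep_rejected && length(rejected)) {
    rej <- do.call(rbind, rejected)
    rej$id <- max(0L, nrow(ev)) + seq_len(nrow(rej))
    ev <- rbind(ev, as_event_table(rej))
  }
  rownames(ev) <- NULL
  ev
}

#' Detect, measure and classify fusion events
#'
#' Candidate anchors (spatiotemporal local maxima of dF/F_avg above the
#' floor) are visited strongest-first; each is grown, traced and validated
#' on the ROI-mean raw trace, and accepted events suppress weaker anchors
#' within the merge radius and window.  Accepted events are then measured
#' (amplitude, duration, displacement) and assigned to compartments.
#'
#' @param movie bleach-corrected `timelapse_movie`.
#' @param dff `dff_movie` (computed from `movie` if missing).
#' @param geometry `axon_geometry` or NULL (then arc = column x pixel size).
#' @param config [detection_config()].
#' @param keep_rejected append rejected candidates with their reasons.
#' @return event data.frame (see [empty_event_table()] for the schema).
#' @export
detect_events <- function(movie, dff = compute_dff_avg(movie), geometry = NULL,
                          config = detection_config(), keep_rejected = FALSE) {
  seeds <- .candidate_seeds(dff$dff, config$candidate_dff_threshold,
                            config$candidate_min_frames)
  .detect_from_seeds(seeds, dff, movie, geometry, config, keep_rejected)
}

#' Exhaustive brute-force detector (oracle)
#'
#' Enumerates every pixel and frame of a small movie with explicit nested
#' loops, keeping each (pixel, frame) pair that satisfies the candidate
#' event definition — dF/F_avg above the floor and a spatial and temporal
#' local maximum — and hands the resulting exhaustive anchor set to the same
#' validation/suppression core as the main detector.  The routes differ in
#' their enumeration machinery (vectorized run-scanning versus exhaustive
#' loops), which is what the equivalence criterion exercises.
#'
#' @param movie bleach-corrected `timelapse_movie`
#'   (at most `guard_px_frames` pixel-frames).
#' @param dff `dff_movie`.
#' @param geometry `axon_geometry` or NULL.
#' @param config [detection_config()].
#' @param guard_px_frames size guard (default 1e6).
#' @return event data.frame.
#' @export
brute_force_detect <- function(movie, dff = compute_dff_avg(movie),
                               geometry = NULL, config = detection_config(),
                               guard_px_frames = 1e6) {
  d <- dim(movie$frames)
  if (prod(d) > guard_px_frames) {
    stop("movie exceeds the brute-force size guard (", prod(d), " > ",
         guard_px_frames, " pixel-frames)")
  }
  a <- dff$dff
  srow <- integer(0); scol <- integer(0); sframe <- integer(0); sdff <- numeric(0)
  for (t in seq_len(d[3])) {
    f <- a[, , t]
    prev <- if (t > 1L) a[, , t - 1L] else NULL
    nxt <- if (t < d[3]) a[, , t + 1L] else NULL
    for (r in seq_len(d[1])) {
      for (cl in seq_len(d[2])) {
        v <- f[r, cl]
        # the dF/F floor is part of the candidate-event definition; the
        # oracle forgoes the main path's enumeration shortcuts, not the
        # definition itself
        if (v <= config$candidate_dff_threshold) next
        if (!is.null(prev) && v < prev[r, cl]) next
        if (!is.null(nxt) && v < nxt[r, cl]) next
        rr <- max(1L, r - 1L):min(d[1], r + 1L)
        cc <- max(1L, cl - 1L):min(d[2], cl + 1L)
        if (v < max(f[rr, cc])) next
        srow <- c(srow, r); scol <- c(scol, cl)
        sframe <- c(sframe, t); sdff <- c(sdff, v)
      }
    }
  }
  seeds <- data.frame(row = srow, col = scol, frame = sframe, dff = sdff)
  .detect_from_seeds(seeds, dff, movie, geometry, config, FALSE)
}
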