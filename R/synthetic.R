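# Synthetic scene generator: time-lapse movies with known ground truth that
# emulate in vivo pHluorin imaging of a myelinating axon.  The axon is a
# straight horizontal line with vertical collaterals, so arc-length
# bookkeeping is exact and oracles are trivial.  The forward model renders:
#   residual surface reporter fluorescence along the axon (attenuated under
#   sheaths), focal fusion events (instantaneous rise, near-exponential decay
#   that returns to baseline exactly at the drawn duration), mobile
#   trafficking puncta, whole-field exponential photobleaching, per-frame
#   integer drift, and Poisson + Gaussian detector noise applied last.

#' Synthetic scene configuration
#'
#' Defaults describe the standard scene: 120 um of axon sampled at
#' 0.25 um/px, 600 frames at 1 s (a 10-min session), three collaterals,
#' ~30% myelin coverage, baseline event rate 0.2 events/um/h with 3-fold
#' heminodal enrichment and reduced under-sheath rate and baseline.
#'
#' @param field_length axon length sampled (um).
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @param n_frames number of frames.
#' @param axon_baseline residual surface fluorescence on the naked axon (a.u.).
#' @param background_level off-axon background (camera offset, a.u.).
#' @param under_sheath_attenuation multiplicative factor (0, 1] applied to the
#'   axon baseline under myelin gaps.
#' @param bleach_tau photobleaching time constant (s); `Inf` disables.
#' @param poisson_gain photons per count for shot noise; 0 disables.
#' @param read_sd Gaussian read noise SD (a.u.); 0 disables.
#' @param rate_nonmyelinated,rate_myelinated,rate_collateral event rates in
#'   events per um per hour for reporter-positive axon, under-sheath axon and
#'   collaterals.
#' @param heminodal_factor rate multiplier inside heminodal windows (3 um at
#'   gap borders).
#' @param amplitude_meanlog,amplitude_sdlog log-normal parameters of peak
#'   event amplitude (dF/F0, fold change over local baseline).
#' @param amplitude_min lower clip on drawn amplitudes (dF/F0); used to state
#'   scenes whose events all exceed a detector-relative floor.
#' @param duration_meanlog,duration_sdlog,duration_min log-normal parameters
#'   and lower clip of event duration (s).
#' @param mobile_fraction fraction of events that drift at `mobile_speed`
#'   (um/s) along their structure.
#' @param spot_sigma Gaussian spot SD (um).
#' @param gap_lengths myelin gap (sheath) lengths to place (um); empty for an
#'   unmyelinated axon.
#' @param gap_min_separation minimum positive length between gaps (um).
#' @param n_collaterals,collateral_length collateral count and length (um).
#' @param axon_row axon row (0-based pixel index).
#' @param axon_halfwidth_px transverse half-thickness of rendered structures.
#' @param drift_max_px maximum |shift| of the per-frame random-walk drift
#'   (pixels); 0 disables drift.
#' @param drift_step_prob probability per frame and axis of a one-pixel
#'   drift step.
#' @param growth_b0_nascent,growth_b1_nascent,growth_sd_nascent sheath growth
#'   model for nascent sheaths (< `nascent_threshold`): growth rate (um/h) =
#'   b0 + b1 x heminodal event frequency (events/3um/h) + N(0, sd).
#' @param growth_b0_stable,growth_b1_stable,growth_sd_stable same for
#'   stabilized sheaths.
#' @param nascent_threshold sheath length separating the two growth regimes (um).
#' @param session_times imaging session times for sheath time-courses (h).
#' @param red_baseline static red reporter intensity on positive axon (a.u.).
#' @param seed RNG seed used by [simulate_scene()].
#' @return list of class `scene_config`.
#' @export
scene_config <- function(field_length = 120, pixel_size = 0.25,
                         frame_interval = 1, n_frames = 600,
                         axon_baseline = 100, background_level = 20,
                         under_sheath_attenuation = 0.5, bleach_tau = 600,
                         poisson_gain = 1, read_sd = 2,
                         rate_nonmyelinated = 0.2, heminodal_factor = 3,
                         rate_myelinated = 0.06, rate_collateral = 0.2,
                         amplitude_meanlog = log(1.0), amplitude_sdlog = 0.4,
                         amplitude_min = 0,
                         duration_meanlog = log(6), duration_sdlog = 0.3,
                         duration_min = 2,
                         mobile_fraction = 0.1, mobile_speed = 0.5,
                         spot_sigma = 0.5,
                         gap_lengths = c(15, 12, 9), gap_min_separation = 8,
                         n_collaterals = 3, collateral_length = 10,
                         axon_row = 12L, axon_halfwidth_px = 1L,
                         drift_max_px = 0L, drift_step_prob = 0.05,
                         growth_b0_nascent = -0.6, growth_b1_nascent = 0.4,
                         growth_sd_nascent = 2.0,
                         growth_b0_stable = 1.0, growth_b1_stable = 0,
                         growth_sd_stable = 0.5,
                         nascent_threshold = 6, session_times = c(0, 4),
                         red_baseline = 150, seed = 1L) {
  bleach_tau <- as.numeric(bleach_tau)   # JSON configs carry Inf as a string
  gap_lengths <- as.numeric(gap_lengths)
  session_times <- as.numeric(session_times)
  cfg <- as.list(environment())
  stopifnot(field_length > 0, pixel_size > 0, frame_interval > 0, n_frames >= 1,
            under_sheath_attenuation > 0, under_sheath_attenuation <= 1,
            bleach_tau > 0, poisson_gain >= 0, read_sd >= 0,
            rate_nonmyelinated >= 0, heminodal_factor >= 0,
            rate_myelinated >= 0, rate_collateral >= 0,
            mobile_fraction >= 0, mobile_fraction <= 1,
            all(gap_lengths > 0) || !length(gap_lengths))
  if (sum(cfg$gap_lengths) > field_length)
    stop("requested total gap length exceeds field_length")
  structure(cfg, class = "scene_config")
}

# quantize an arc position to the pixel grid
.snap <- function(x, pixel_size) round(x / pixel_size) * pixel_size

#' Simulate a myelin profile and collateral placement
#'
#' Places non-overlapping gaps of the configured lengths (snapped to the
#' pixel grid) with at least `gap_min_separation` of positive axon between
#' them and the field edges, and collateral branch points in positive,
#' non-heminodal regions.  Placement is retried a bounded number of times.
#'
#' @param config [scene_config()].
#' @return list with `profile` (`myelin_profile`) and `collateral_arcs` (um).
#' @export
simulate_profile <- function(config) {
  fl <- config$field_length; ps <- config$pixel_size
  lens <- .snap(config$gap_lengths, ps)
  sep <- config$gap_min_separation
  placed <- NULL
  if (length(lens)) {
    ok <- FALSE
    for (try in 1:200) {
      starts <- .snap(sort(stats::runif(length(lens), sep, fl - sep - max(lens))), ps)
      o <- order(starts)
      s <- starts[o]; l <- lens[o]
      if (all(s + l <= fl - sep) &&
          (length(s) < 2 || all(s[-1] - (s[-length(s)] + l[-length(l)]) >= sep))) {
        placed <- data.frame(start = s, end = s + l)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place gaps after bounded retries; reduce coverage")
  }
  profile <- if (is.null(placed)) {
    profile_from_gaps(fl, numeric(0), numeric(0))
  } else {
    profile_from_gaps(fl, placed$start, placed$end)
  }
  # collaterals live in positive, non-heminodal axon, away from field edges
  margin <- 2
  forbidden <- rbind(
    if (!is.null(placed)) cbind(placed$start - margin, placed$end + margin),
    if (nrow(profile$heminodes)) cbind(profile$heminodes$start, profile$heminodes$end),
    cbind(-1, margin), cbind(fl - margin, fl + 1))
  arcs <- numeric(0)
  guard <- 0
  while (length(arcs) < config$n_collaterals && guard < 1000) {
    guard <- guard + 1
    a <- .snap(stats::runif(1, margin, fl - margin), ps)
    clear <- !any(a >= forbidden[, 1] & a <= forbidden[, 2]) &&
      (!length(arcs) || min(abs(arcs - a)) >= 2)
    if (clear) arcs <- c(arcs, a)
  }
  list(profile = profile, collateral_arcs = sort(arcs))
}

# region table for the event point processes: start, end (um), rate (ev/um/h),
# region label.  Heminodal windows carve out of the positive regions.
.event_regions <- function(config, profile) {
  seg <- profile$segments
  hemi <- profile$heminodes
  regions <- list()
  add <- function(s, e, rate, lab) {
    if (e > s + 1e-12)
      regions[[length(regions) + 1L]] <<- data.frame(
        start = s, end = e, rate = rate, region = lab)
  }
  hemi_rate <- config$rate_nonmyelinated * config$heminodal_factor
  for (i in seq_len(nrow(seg))) {
    if (seg$label[i] == "gap") {
      add(seg$start[i], seg$end[i], config$rate_myelinated, "myelinated")
    } else {
      h <- hemi[hemi$start >= seg$start[i] - 1e-9 & hemi$end <= seg$end[i] + 1e-9, ,
                drop = FALSE]
      cursor <- seg$start[i]
      if (nrow(h)) {
        h <- h[order(h$start), , drop = FALSE]
        for (j in seq_len(nrow(h))) {
          add(cursor, h$start[j], config$rate_nonmyelinated, "nonmyelinated")
          add(h$start[j], h$end[j], hemi_rate, "heminodal")
          cursor <- h$end[j]
        }
      }
      add(cursor, seg$end[i], config$rate_nonmyelinated, "nonmyelinated")
    }
  }
  do.call(rbind, regions)
}

#' Simulate ground-truth fusion events
#'
#' Independent homogeneous Poisson processes per compartment: positive
#' (non-myelinated) axon at the base rate, heminodal 3-um windows at
#' `heminodal_factor` times the base rate, under-sheath axon and collaterals
#' at their own rates.  Amplitudes and durations are i.i.d. log-normal; a
#' `mobile_fraction` of events drift at constant speed.
#'
#' @param config [scene_config()].
#' @param profile `myelin_profile` from [simulate_profile()].
#' @param duration_h observation duration in hours.
#' @param collateral_arcs collateral branch-point arcs (um).
#' @return data.frame of true events (possibly zero rows): compartment,
#'   region, arc_position, branch_id, branch_arc, start_frame, start_time_s,
#'   amplitude, duration_s, mobile, velocity_um_s.
#' @export
simulate_events <- function(config, profile, duration_h,
                            collateral_arcs = numeric()) {
  stopifnot(duration_h > 0)
  regions <- .event_regions(config, profile)
  if (length(collateral_arcs) && config$rate_collateral > 0) {
    coll <- data.frame(start = 0, end = config$collateral_length,
                       rate = config$rate_collateral, region = "collateral",
                       branch_arc0 = collateral_arcs)
  } else coll <- NULL
  total_s <- duration_h * 3600
  n_frame_slots <- max(1L, round(total_s / config$frame_interval))
  draw <- function(n, s, e, region, branch_id = NA_integer_, branch_arc0 = NA_real_) {
    if (n == 0) return(NULL)
    pos <- stats::runif(n, s, e)
    mobile <- stats::runif(n) < config$mobile_fraction
    data.frame(
      compartment = if (region == "collateral") "collateral" else "axon",
      region = region,
      arc_position = if (region == "collateral") rep(branch_arc0, n) else pos,
      branch_id = rep(branch_id, n),
      branch_arc = if (region == "collateral") pos else NA_real_,
      start_frame = sample.int(n_frame_slots, n, replace = TRUE) - 1L,
      amplitude = pmax(stats::rlnorm(n, config$amplitude_meanlog,
                                     config$amplitude_sdlog),
                       config$amplitude_min),
      duration_s = pmax(stats::rlnorm(n, config$duration_meanlog,
                                      config$duration_sdlog), config$duration_min),
      mobile = mobile,
      velocity_um_s = ifelse(mobile, sample(c(-1, 1), n, replace = TRUE) *
                               config$mobile_speed, 0),
      stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(regions))) {
    len <- regions$end[i] - regions$start[i]
    n <- stats::rpois(1, regions$rate[i] * len * duration_h)
    out[[length(out) + 1L]] <- draw(n, regions$start[i], regions$end[i],
                                    regions$region[i])
  }
  if (!is.null(coll)) {
    for (i in seq_len(nrow(coll))) {
      n <- stats::rpois(1, coll$rate[i] * (coll$end[i] - coll$start[i]) * duration_h)
      out[[length(out) + 1L]] <- draw(n, coll$start[i], coll$end[i], "collateral",
                                      branch_id = i,
                                      branch_arc0 = coll$branch_arc0[i])
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  ev <- if (length(out)) do.call(rbind, out) else draw(0, 0, 1, "nonmyelinated")
  if (is.null(ev)) {
    ev <- data.frame(compartment = character(0), region = character(0),
                     arc_position = numeric(0), branch_id = integer(0),
                     branch_arc = numeric(0), start_frame = integer(0),
                     amplitude = numeric(0), duration_s = numeric(0),
                     mobile = logical(0), velocity_um_s = numeric(0),
                     stringsAsFactors = FALSE)
  }
  ev$start_time_s <- ev$start_frame * config$frame_interval
  rownames(ev) <- NULL
  ev
}

# Temporal profile of an event: 1 at onset, shifted-exponential decay that
# reaches 0 exactly at the drawn duration (tau = duration / 2), so the
# noise-free trace returns to baseline at the drawn duration.
event_time_profile <- function(t_rel, duration) {
  tau <- duration / 2
  s <- (exp(-t_rel / tau) - exp(-duration / tau)) / (1 - exp(-duration / tau))
  s[t_rel < 0 | t_rel >= duration + 1e-9] <- 0
  pmax(s, 0)
}

.shift_pad <- function(m, dr, dc) {
  # integer shift with edge replication: output[r, c] = input[r - dr, c - dc]
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# baseline (noise-free, bleach-free) scene image and per-structure baselines
.scene_baseline <- function(config, profile, collateral_arcs) {
  ps <- config$pixel_size
  n_col <- round(config$field_length / ps)
  coll_px <- round(config$collateral_length / ps)
  n_row <- config$axon_row + coll_px + 12L
  hw <- config$axon_halfwidth_px
  B <- matrix(config$background_level, n_row, n_col)
  axon_rows <- (config$axon_row - hw):(config$axon_row + hw) + 1L
  # column arc midpoints decide gap membership
  arc_mid <- (seq_len(n_col) - 0.5) * ps
  level <- rep(config$axon_baseline, n_col)
  g <- gaps_of(profile)
  for (i in seq_len(nrow(g))) {
    inside <- arc_mid >= g$start[i] & arc_mid < g$end[i]
    level[inside] <- config$axon_baseline * config$under_sheath_attenuation
  }
  B[axon_rows, ] <- matrix(level, length(axon_rows), n_col, byrow = TRUE)
  for (a in collateral_arcs) {
    c0 <- round(a / ps)
    cols <- pmin(pmax((c0 - hw):(c0 + hw), 0L), n_col - 1L) + 1L
    rows <- (config$axon_row):(config$axon_row + coll_px) + 1L
    B[rows, cols] <- config$axon_baseline
  }
  B
}

#' Render a synthetic movie from a profile and ground-truth events
#'
#' The noise-free scene is the baseline image plus, per event, an isotropic
#' Gaussian spot whose peak adds `amplitude x local baseline` at onset and
#' decays back to baseline exactly at the drawn duration.  The whole frame is
#' then bleached by `exp(-t / bleach_tau)`, shifted by the per-frame drift,
#' and finally Poisson + Gaussian noise is applied.
#'
#' @param config [scene_config()].
#' @param profile `myelin_profile`.
#' @param events true-event data.frame from [simulate_events()].
#' @param collateral_arcs collateral branch-point arcs (um).
#' @param drift optional integer matrix `[n_frames, 2]` of (row, col) shifts;
#'   `NULL` draws the configured random walk.
#' @return list of class `ground_truth_scene`: `movie` (`timelapse_movie`),
#'   `red` (static red frame matrix), `geometry`, `profile`, `events`,
#'   `collateral_arcs`, `drift`, `config`.
#' @export
render_movie <- function(config, profile, events, collateral_arcs = numeric(),
                         drift = NULL) {
  ps <- config$pixel_size
  B <- .scene_baseline(config, profile, collateral_arcs)
  n_row <- nrow(B); n_col <- ncol(B)
  geometry <- straight_axon_geometry(config$field_length, ps,
                                     axon_row = config$axon_row,
                                     collateral_arcs = collateral_arcs,
                                     collateral_length = config$collateral_length)
  nT <- config$n_frames
  if (is.null(drift)) {
    drift <- matrix(0L, nT, 2)
    if (config$drift_max_px > 0) {
      for (ax in 1:2) {
        steps <- sample(c(-1L, 0L, 1L), nT, replace = TRUE,
                        prob = c(config$drift_step_prob / 2,
                                 1 - config$drift_step_prob,
                                 config$drift_step_prob / 2))
        drift[, ax] <- pmin(pmax(cumsum(steps), -config$drift_max_px),
                            config$drift_max_px)
      }
    }
  }
  stopifnot(nrow(drift) == nT)
  sigma_px <- config$spot_sigma / ps
  rad <- max(2L, ceiling(3.5 * sigma_px))
  # event center pixel (0-based) and local baseline
  ev <- events
  ev$row0 <- ifelse(ev$compartment == "axon", config$axon_row,
                    config$axon_row + round(ifelse(is.na(ev$branch_arc), 0,
                                                   ev$branch_arc) / ps))
  ev$col0 <- ifelse(ev$compartment == "axon", round(ev$arc_position / ps),
                    round(ev$arc_position / ps))
  ev$col0 <- pmin(pmax(ev$col0, 0L), n_col - 1L)
  ev$row0 <- pmin(pmax(ev$row0, 0L), n_row - 1L)
  ev$local_baseline <- B[cbind(ev$row0 + 1L, ev$col0 + 1L)]
  frames <- array(0, c(n_row, n_col, nT))
  times <- (seq_len(nT) - 1L) * config$frame_interval
  bleach <- if (is.finite(config$bleach_tau)) exp(-times / config$bleach_tau) else rep(1, nT)
  dur_frames <- ceiling(ev$duration_s / config$frame_interval)
  for (t in seq_len(nT)) {
    Ft <- B
    active <- which(ev$start_frame <= (t - 1L) &
                      (t - 1L) <= ev$start_frame + dur_frames)
    for (k in active) {
      t_rel <- times[t] - ev$start_time_s[k]
      s <- event_time_profile(t_rel, ev$duration_s[k])
      if (s <= 0) next
      # mobile events drift along their structure
      drow <- 0; dcol <- 0
      if (ev$mobile[k]) {
        disp_px <- round(ev$velocity_um_s[k] * t_rel / ps)
        if (ev$compartment[k] == "axon") dcol <- disp_px else drow <- disp_px
      }
      r0 <- ev$row0[k] + drow; c0 <- ev$col0[k] + dcol
      rr <- max(0L, r0 - rad):min(n_row - 1L, r0 + rad)
      cc <- max(0L, c0 - rad):min(n_col - 1L, c0 + rad)
      if (!length(rr) || !length(cc)) next
      gr <- exp(-((rr - r0)^2) / (2 * sigma_px^2))
      gc <- exp(-((cc - c0)^2) / (2 * sigma_px^2))
      Ft[rr + 1L, cc + 1L] <- Ft[rr + 1L, cc + 1L] +
        ev$amplitude[k] * ev$local_baseline[k] * s * outer(gr, gc)
    }
    Ft <- Ft * bleach[t]
    if (any(drift[t, ] != 0L)) Ft <- .shift_pad(Ft, drift[t, 1], drift[t, 2])
    if (config$poisson_gain > 0) {
      Ft <- stats::rpois(length(Ft), Ft / config$poisson_gain) * config$poisson_gain
      dim(Ft) <- c(n_row, n_col)
    }
    if (config$read_sd > 0) {
      Ft <- Ft + stats::rnorm(length(Ft), 0, config$read_sd)
      dim(Ft) <- c(n_row, n_col)
    }
    frames[, , t] <- pmax(Ft, 0)
  }
  movie <- timelapse_movie(frames, ps, config$frame_interval, "pHluorin")
  red <- .render_red(config, profile, collateral_arcs)
  structure(list(movie = movie, red = red, geometry = geometry,
                 profile = profile, events = ev,
                 collateral_arcs = collateral_arcs, drift = drift,
                 config = config),
            class = "ground_truth_scene")
}

# Static red reporter channel: positive axon bright, gaps dark, low noise
# (the red channel is acquired once with higher pixel dwell time).
.render_red <- function(config, profile, collateral_arcs) {
  cfg <- config
  cfg$axon_baseline <- config$red_baseline
  cfg$under_sheath_attenuation <- 1e-6   # reporter excluded from sheaths
  R <- .scene_baseline(cfg, profile, collateral_arcs)
  R[R < config$background_level] <- config$background_level / 2
  if (config$read_sd > 0) {
    R <- R + stats::rnorm(length(R), 0, config$read_sd / 2)
    dim(R) <- dim(.scene_baseline(cfg, profile, collateral_arcs))
  }
  pmax(R, 0)
}

#' Simulate a complete scene under one seed
#'
#' Profile placement, event draw, and rendering under a single RNG seed, so
#' that the full scene (movie bytes included) is reproducible.
#'
#' @param config [scene_config()].
#' @return `ground_truth_scene` (see [render_movie()]).
#' @export
simulate_scene <- function(config) {
  set.seed(config$seed)
  pr <- simulate_profile(config)
  duration_h <- config$n_frames * config$frame_interval / 3600
  ev <- simulate_events(config, pr$profile, duration_h, pr$collateral_arcs)
  render_movie(config, pr$profile, ev, pr$collateral_arcs)
}

#' Simulate sheath time-courses coupled to local event frequency
#'
#' For each complete gap, the growth rate over the observation interval is
#' `b0 + b1 x heminodal event frequency + N(0, sd)`, with separate
#' coefficients for nascent (< `nascent_threshold` um) and stabilized
#' sheaths.  Heminodal frequency is the number of true events inside the
#' sheath's flanking heminodes divided by the number of those heminodes and
#' the event observation duration (events per 3-um window per hour), i.e. the
#' same statistic the analysis modules measure.  Sheaths whose projected
#' length reaches zero fully retract.
#'
#' @param config [scene_config()].
#' @param profile `myelin_profile` at the first session.
#' @param events true-event data.frame (the fusion-imaging session).
#' @param events_duration_h duration over which `events` were observed (h).
#' @return data.frame, one row per sheath: sheath_id, initial/final length,
#'   session columns `length_t<k>`, growth_rate (um/h), heminodal_freq,
#'   under_sheath_freq, fate, free_to_grow, flank_left, flank_right.
#' @export
simulate_sheath_timecourse <- function(config, profile, events,
                                       events_duration_h =
                                         config$n_frames * config$frame_interval / 3600) {
  g <- gaps_of(profile, complete_only = TRUE)
  if (!nrow(g)) return(NULL)
  hemi <- profile$heminodes
  times <- config$session_times
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  ax <- events[events$compartment == "axon", , drop = FALSE]
  rows <- lapply(seq_len(nrow(g)), function(i) {
    L0 <- g$end[i] - g$start[i]
    # flanking heminodes: those abutting this gap
    hb <- hemi[abs(hemi$end - g$start[i]) < 1e-9 | abs(hemi$start - g$end[i]) < 1e-9, ,
               drop = FALSE]
    n_h <- nrow(hb)
    cnt <- 0
    if (n_h) {
      for (j in seq_len(n_h)) {
        cnt <- cnt + sum(ax$arc_position >= hb$start[j] & ax$arc_position < hb$end[j])
      }
    }
    hfreq <- if (n_h) cnt / n_h / events_duration_h else NA_real_
    under <- sum(ax$arc_position >= g$start[i] & ax$arc_position < g$end[i])
    ufreq <- under / L0 / events_duration_h
    nascent <- L0 < config$nascent_threshold
    b0 <- if (nascent) config$growth_b0_nascent else config$growth_b0_stable
    b1 <- if (nascent) config$growth_b1_nascent else config$growth_b1_stable
    sd <- if (nascent) config$growth_sd_nascent else config$growth_sd_stable
    rate <- b0 + b1 * (if (is.na(hfreq)) 0 else hfreq) + stats::rnorm(1, 0, sd)
    lengths <- pmax(L0 + rate * (times - times[1]), 0)
    retracted <- any(lengths == 0)
    if (retracted) lengths[which(lengths == 0)[1]:length(lengths)] <- 0
    fate <- if (retracted) "full_retraction"
            else if (lengths[length(lengths)] > L0) "grow"
            else if (lengths[length(lengths)] < L0) "shrink" else "stable"
    flank <- .gap_flanks(profile, g$start[i], g$end[i], config$pixel_size)
    row <- data.frame(sheath_id = i, start = g$start[i], end = g$end[i],
                      initial_length = L0, final_length = lengths[length(lengths)],
                      growth_rate = (lengths[length(lengths)] - L0) /
                        (times[length(times)] - times[1]),
                      heminodal_freq = hfreq, under_sheath_freq = ufreq,
                      heminodal_count = cnt, fate = fate,
                      flank_left = flank[1], flank_right = flank[2],
                      free_to_grow = !(flank[1] %in% c("node", "collateral") &
                                         flank[2] %in% c("node", "collateral")),
                      stringsAsFactors = FALSE)
    for (k in seq_along(times)) row[[sprintf("length_t%d", k)]] <- lengths[k]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# what flanks a gap on each side: "node", "collateral", or "open"
.gap_flanks <- function(profile, gstart, gend, pixel_size,
                        collateral_arcs = attr(profile, "collateral_arcs")) {
  nodes <- profile$nodes
  tol <- pixel_size
  side <- function(pos) {
    if (nrow(nodes) &&
        any(abs(nodes$end - pos) < tol | abs(nodes$start - pos) < tol))
      return("node")
    if (!is.null(collateral_arcs) && length(collateral_arcs) &&
        any(abs(collateral_arcs - pos) <= tol))
      return("collateral")
    "open"
  }
  c(side(gstart), side(gend))
}

#' Profile after applying a sheath time-course
#'
#' Rebuilds the gap intervals at the final session: each surviving sheath
#' keeps its midpoint and takes its final length, clipped so neighbours do
#' not overlap; fully retracted sheaths disappear.  Incomplete edge gaps are
#' carried over unchanged.
#'
#' @param profile session-1 `myelin_profile`.
#' @param timecourse output of [simulate_sheath_timecourse()].
#' @return `myelin_profile` at the final session.
#' @export
profile_after_timecourse <- function(profile, timecourse) {
  fl <- profile$field_length
  keep <- timecourse[timecourse$final_length > 0, , drop = FALSE]
  mids <- (keep$start + keep$end) / 2
  s <- mids - keep$final_length / 2
  e <- mids + keep$final_length / 2
  inc <- gaps_of(profile)
  inc <- inc[!inc$complete, , drop = FALSE]
  s <- c(s, inc$start); e <- c(e, inc$end)
  o <- order(s); s <- s[o]; e <- e[o]
  s <- pmax(s, 0); e <- pmin(e, fl)
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] < e[i - 1]) {  # clip symmetric growth at collisions
        mid <- (e[i - 1] + s[i]) / 2
        e[i - 1] <- mid; s[i] <- mid
      }
    }
  }
  ok <- e > s
  profile_from_gaps(fl, s[ok], e[ok], profile$config)
}

#' Serialize / load a ground-truth scene description (without pixels)
#'
#' Events, profile gaps, collateral arcs, drift and noise parameters
#' round-trip losslessly through JSON; the movie itself is stored separately
#' as TIFF.
#'
#' @param truth `ground_truth_scene`.
#' @param path JSON path.
#' @return `path` (write); list (read).
#' @export
write_ground_truth <- function(truth, path) {
  g <- gaps_of(truth$profile)
  jsonlite::write_json(
    list(config = unclass(truth$config),
         events = truth$events,
         gaps = data.frame(start = g$start, end = g$end),
         field_length = truth$profile$field_length,
         collateral_arcs = truth$collateral_arcs,
         drift = truth$drift),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(scene_config, x$config[names(x$config) %in% names(formals(scene_config))])
  profile <- profile_from_gaps(x$field_length,
                               if (length(x$gaps)) x$gaps$start else numeric(0),
                               if (length(x$gaps)) x$gaps$end else numeric(0))
  list(config = cfg, events = as.data.frame(x$events), profile = profile,
       collateral_arcs = as.numeric(x$collateral_arcs),
       drift = matrix(as.integer(x$drift), ncol = 2))
}
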