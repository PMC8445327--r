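# event_detection: validation rule boundaries, photometry definitions,
# displacement classes, candidate search behaviour.

# build a candidate around an explicit ROI-mean trace
trace_candidate <- function(trace, peak_frame = which.max(trace) - 1L) {
  list(row = 5L, col = 5L, peak_frame = as.integer(peak_frame),
       peak_dff = 1, roi = list(rows = 5L, cols = 5L),
       trace = trace, seed_trace = trace)
}

# baseline with tiny jitter so sd0 is well-defined and known-scale
jitter_baseline <- function(n, f0 = 100, sd0 = 1, seed = 1) {
  set.seed(seed)
  f0 + rep(c(-sd0, sd0), length.out = n)   # mean f0, sd ~ sd0
}

test_that("validation enforces the 5xSD / 4-frame rule at its boundaries", {
  base <- jitter_baseline(20)
  f0 <- mean(base); sd0 <- stats::sd(base)
  # 4 consecutive frames at f0 + 6 sd0 -> accepted
  tr4 <- c(base, rep(f0 + 6 * sd0, 4), base)
  v4 <- validate_event(trace_candidate(tr4, peak_frame = 20L))
  expect_true(v4$accepted)
  expect_equal(v4$start_frame, 20L)
  # 3 frames above -> rejected (boundary of "at least 4 frames")
  tr3 <- c(base, rep(f0 + 6 * sd0, 3), base)
  v3 <- validate_event(trace_candidate(tr3, peak_frame = 20L))
  expect_false(v3$accepted)
  expect_equal(v3$reject_reason, "too_few_frames")
  # peak at f0 + 4 sd0 -> rejected (boundary of "5-fold greater")
  trlow <- c(base, rep(f0 + 4 * sd0, 6), base)
  vlow <- validate_event(trace_candidate(trlow, peak_frame = 20L))
  expect_false(vlow$accepted)
  expect_equal(vlow$reject_reason, "below_threshold")
  # too close to the movie start -> no baseline
  trearly <- c(100, 100, rep(200, 5), base)
  vearly <- validate_event(trace_candidate(trearly, peak_frame = 2L))
  expect_false(vearly$accepted)
  expect_equal(vearly$reject_reason, "no_baseline")
  # short (>= 3 frame) baseline accepted but flagged
  trshort <- c(base[1:5], rep(f0 + 8 * sd0, 5), base)
  vshort <- validate_event(trace_candidate(trshort, peak_frame = 5L))
  expect_true(vshort$accepted)
  expect_true(vshort$baseline_flag)
  expect_equal(vshort$baseline_frames_used, 5L)
})

test_that("amplitude is the peak-window maximum over baseline", {
  # f0 = 100, max 160 within the first 10 frames -> 0.6
  tr <- c(rep(100, 12), 150, 160, 155, rep(110, 7), 180, rep(100, 5))
  expect_equal(measure_amplitude(tr, 100, 12L, 10L), 0.6)
  # the later 180 lies outside the peak period and is ignored
  expect_equal(measure_amplitude(tr, 100, 12L, 20L), 0.8)
})

test_that("duration runs until the trace returns to within one SD", {
  tr <- c(rep(100, 12), 200, 180, 160, 140, 130, 120, 115, 110, 100.5,
          rep(100, 5))
  d <- measure_duration(tr, f0 = 100, sd0 = 1, start_frame = 12L,
                        frame_interval = 1)
  expect_equal(d$duration_s, 8)            # returns at frame start + 8
  expect_false(d$censored)
  # never-returning trace is censored at the movie end
  tr2 <- c(rep(100, 12), rep(200, 10))
  d2 <- measure_duration(tr2, 100, 1, 12L, 1)
  expect_true(d2$censored)
  expect_equal(d2$duration_s, 9)
})

# movie with a spot following a per-frame column trajectory
moving_spot_movie <- function(traj_cols, row = 10L, n_extra = 0L,
                              nr = 24L, nc = 120L) {
  nT <- length(traj_cols) + n_extra
  frames <- array(100, c(nr, nc, nT))
  for (t in seq_len(nT)) {
    cc <- traj_cols[min(t, length(traj_cols))]
    frames[row + 1L, cc + 1L, t] <- 300
  }
  timelapse_movie(frames, 0.25, 1)
}

test_that("displacement tracking classifies motion per the stated rules", {
  # stationary spot -> static, zero displacement
  m0 <- moving_spot_movie(rep(30L, 12))
  ev0 <- list(row = 10L, col = 30L, peak_frame = 0L, start_frame = 0L,
              f0 = 100, duration_s = 12)
  d0 <- track_displacement(ev0, m0)
  expect_equal(d0$cumulative_displacement, 0)
  expect_equal(d0$motion_class, "static")
  expect_equal(d0$direction_class, "none")
  # 12 um unidirectional drift -> excluded_mobile (> 10 um rule)
  traj <- 10L + 2L * (0:24)                 # 2 px = 0.5 um per frame, 12 um
  m1 <- moving_spot_movie(traj)
  ev1 <- list(row = 10L, col = 10L, peak_frame = 0L, start_frame = 0L,
              f0 = 100, duration_s = 25)
  d1 <- track_displacement(ev1, m1)
  expect_gt(d1$cumulative_displacement, 10)
  expect_equal(d1$motion_class, "excluded_mobile")
  expect_equal(d1$direction_class, "unidirectional")
  # 4 um of stepping then static twice as long -> limited_displacement
  traj2 <- c(10L, 14L, 18L, 22L, 26L, rep(26L, 10))   # 4 moving, 10 static
  m2 <- moving_spot_movie(traj2)
  ev2 <- list(row = 10L, col = 10L, peak_frame = 0L, start_frame = 0L,
              f0 = 100, duration_s = 15)
  d2 <- track_displacement(ev2, m2)
  expect_equal(d2$cumulative_displacement, 4)
  expect_equal(d2$motion_class, "limited_displacement")
  # back-and-forth -> bidirectional
  traj3 <- c(10L, 14L, 18L, 14L, 10L, 14L, 18L, 14L, rep(10L, 8))
  m3 <- moving_spot_movie(traj3)
  ev3 <- list(row = 10L, col = 10L, peak_frame = 0L, start_frame = 0L,
              f0 = 100, duration_s = 16)
  expect_equal(track_displacement(ev3, m3)$direction_class, "bidirectional")
  # |net| <= cumulative always
  expect_lte(abs(d1$net_displacement), d1$cumulative_displacement + 1e-12)
  expect_lte(abs(d2$net_displacement), d2$cumulative_displacement + 1e-12)
})

test_that("candidate search finds spots and suppresses near-duplicates", {
  # flat noise-free movie -> no candidates
  flat <- timelapse_movie(array(100, c(10, 20, 30)), 0.25, 1)
  expect_length(find_candidates(compute_dff_avg(flat, floor_guard = 0), flat), 0L)
  # a single injected spot -> exactly one candidate at the spot
  frames <- array(100, c(10, 40, 40))
  frames[6, 21, 20:23] <- c(250, 220, 190, 160)
  frames[5:7, 20:22, 20] <- pmax(frames[5:7, 20:22, 20], 180)
  m <- timelapse_movie(frames, 0.25, 1)
  cands <- find_candidates(compute_dff_avg(m, floor_guard = 0), m)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$row, 5L)
  expect_equal(cands[[1]]$col, 20L)
  expect_equal(cands[[1]]$peak_frame, 19L)
  # two spots 0.5 um (2 px) apart with 1 um merge radius -> one candidate
  frames2 <- array(100, c(10, 40, 40))
  frames2[6, 21, 20:23] <- c(250, 220, 190, 160)
  frames2[6, 23, 20:23] <- c(240, 215, 185, 155)
  m2 <- timelapse_movie(frames2, 0.25, 1)
  cands2 <- find_candidates(compute_dff_avg(m2, floor_guard = 0), m2)
  expect_length(cands2, 1L)
  expect_equal(cands2[[1]]$col, 20L)        # the stronger spot wins
})

test_that("detection is invariant to a global intensity scale", {
  cfg <- oracle_scene_config(31)
  scene <- simulate_scene(cfg)
  prep <- preprocess_movie(scene$movie, register = FALSE)
  ev1 <- detect_events(prep$movie, prep$dff, scene$geometry)
  scaled <- timelapse_movie(prep$movie$frames * 7.5, prep$movie$pixel_size,
                            prep$movie$frame_interval)
  ev2 <- detect_events(scaled, compute_dff_avg(scaled), scene$geometry)
  expect_equal(nrow(ev1), nrow(ev2))
  expect_equal(ev1$start_frame, ev2$start_frame)
  expect_equal(ev1$amplitude, ev2$amplitude, tolerance = 1e-9)
})

test_that("raising injected amplitudes never loses events (monotonicity)", {
  counts <- vapply(c(1, 1.5, 2.2), function(boost) {
    cfg <- oracle_scene_config(32)
    set.seed(cfg$seed)
    pr <- simulate_profile(cfg)
    ev <- simulate_events(cfg, pr$profile, cfg$n_frames / 3600,
                          pr$collateral_arcs)
    ev$amplitude <- ev$amplitude * boost
    set.seed(999)                            # identical noise across boosts
    scene <- render_movie(cfg, pr$profile, ev, pr$collateral_arcs)
    nrow(detect_scene(scene))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
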