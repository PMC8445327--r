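# Shared scene builders and matching helpers for the test suite.
# All scenes are generated in code at test time; no stored fixtures.

# small scene that stays under the brute-force oracle's size guard
oracle_scene_config <- function(seed) {
  scene_config(field_length = 30, n_frames = 80, gap_lengths = c(8),
               n_collaterals = 1, collateral_length = 5,
               rate_nonmyelinated = 4, rate_collateral = 2,
               mobile_fraction = 0, bleach_tau = Inf, seed = seed)
}

# the standard recall scene: uniform event placement, amplitudes well above
# the 8x-baseline-SD floor (see the methods vignette for the knife-edge
# analysis at the floor itself), 6-s durations, default noise
recall_scene_config <- function(seed) {
  scene_config(amplitude_meanlog = log(1.8), amplitude_sdlog = 0.2,
               amplitude_min = 1.2,
               duration_meanlog = log(6), duration_sdlog = 0, duration_min = 6,
               rate_nonmyelinated = 1.0, heminodal_factor = 1,
               rate_myelinated = 0.5, rate_collateral = 0.6,
               mobile_fraction = 0, bleach_tau = Inf, seed = seed)
}

# isolated events on a grid for photometry calibration: no spatial or
# temporal overlap, clear of gap borders, movie edges and collaterals
isolated_events <- function(cfg, n, seed) {
  set.seed(seed)
  arcs <- seq(20, cfg$field_length - 20, length.out = n)
  arcs <- round(arcs / cfg$pixel_size) * cfg$pixel_size
  data.frame(
    compartment = "axon", region = "nonmyelinated", arc_position = arcs,
    branch_id = NA_integer_, branch_arc = NA_real_,
    start_frame = as.integer(round(seq(30, cfg$n_frames - 40, length.out = n))),
    amplitude = pmax(stats::rlnorm(n, log(1.0), 0.4), 0.5),
    duration_s = pmax(stats::rlnorm(n, log(6), 0.3), 3),
    mobile = FALSE, velocity_um_s = 0,
    start_time_s = NA_real_, stringsAsFactors = FALSE
  ) -> ev
  ev$start_time_s <- ev$start_frame * cfg$frame_interval
  ev
}

# set equality of two event tables up to position/start-frame tolerance
expect_same_event_set <- function(a, b, pixel_size, tol_um = 1, tol_frames = 2) {
  expect_equal(nrow(a), nrow(b))
  if (!nrow(a)) return(invisible(TRUE))
  used <- logical(nrow(b))
  for (i in seq_len(nrow(a))) {
    d <- sqrt((a$row[i] - b$row)^2 + (a$col[i] - b$col)^2) * pixel_size
    ok <- which(!used & d <= tol_um &
                  abs(a$start_frame[i] - b$start_frame) <= tol_frames)
    expect_true(length(ok) > 0,
                info = sprintf("event at (%d,%d) frame %d unmatched",
                               a$row[i], a$col[i], a$start_frame[i]))
    if (length(ok)) used[ok[1]] <- TRUE
  }
  invisible(TRUE)
}

# detect with the standard preprocessing (no registration unless drifting)
detect_scene <- function(scene, register = FALSE, config = detection_config(),
                         reference = "median") {
  prep <- preprocess_movie(scene$movie, register = register,
                           reference = reference)
  detect_events(prep$movie, prep$dff, scene$geometry, config)
}

# labelled ground-truth events for statistics-only simulations
truth_labelled <- function(cfg, profile, events) {
  assign_compartments(as_detected_events(events), profile)
}
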