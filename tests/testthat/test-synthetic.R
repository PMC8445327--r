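# synthetic_data: profile placement, Poisson event draw, forward model.

test_that("simulate_profile places requested coverage and is deterministic", {
  cfg <- scene_config(field_length = 100, gap_lengths = c(20, 10),
                      gap_min_separation = 8, seed = 4)
  set.seed(4)
  pr <- simulate_profile(cfg)
  expect_equal(pr$profile$percent_myelination, 30)   # 20 + 10 on 100 um
  expect_equal(pr$profile$axon_class, "myelinating")
  set.seed(4)
  pr2 <- simulate_profile(cfg)
  expect_identical(pr$profile$segments, pr2$profile$segments)
  expect_identical(pr$collateral_arcs, pr2$collateral_arcs)
  # zero coverage -> unmyelinated
  cfg0 <- scene_config(gap_lengths = numeric(0), seed = 4)
  set.seed(4)
  pr0 <- simulate_profile(cfg0)
  expect_equal(pr0$profile$percent_myelination, 0)
  expect_equal(pr0$profile$axon_class, "not_yet_myelinated")
  # infeasible placement errors out
  expect_error(scene_config(gap_lengths = c(70, 60)), "exceeds")
  cfg_bad <- scene_config(field_length = 50, gap_lengths = c(20, 20),
                          gap_min_separation = 8)
  set.seed(1)
  expect_error(simulate_profile(cfg_bad), "bounded retries")
})

test_that("event counts follow the configured Poisson processes", {
  # 2 events per 10 um per h on 100 um for 1 h -> mean 20
  cfg <- scene_config(field_length = 100, gap_lengths = numeric(0),
                      n_collaterals = 0, rate_nonmyelinated = 0.2,
                      heminodal_factor = 1)
  pr <- profile_from_gaps(100, numeric(0), numeric(0))
  set.seed(10)
  counts <- replicate(200, nrow(simulate_events(cfg, pr, 1)))
  se_mean <- sqrt(20 / 200)
  expect_lt(abs(mean(counts) - 20), 3 * se_mean)
  # variance consistent with Poisson (chi-squared interval, 3-SE-ish band)
  expect_lt(abs(var(counts) - 20), 3 * 20 * sqrt(2 / 199))
  # all rates zero -> empty
  cfg0 <- scene_config(rate_nonmyelinated = 0, rate_myelinated = 0,
                       rate_collateral = 0, heminodal_factor = 0)
  set.seed(1)
  pr0 <- simulate_profile(cfg0)
  expect_equal(nrow(simulate_events(cfg0, pr0$profile, 1, pr0$collateral_arcs)), 0L)
})

test_that("uniform placement when the heminodal factor is 1", {
  cfg <- scene_config(heminodal_factor = 1, rate_myelinated = 0,
                      n_collaterals = 0, rate_nonmyelinated = 1)
  set.seed(11)
  pr <- simulate_profile(cfg)
  pos <- pr$profile$segments[pr$profile$segments$label == "positive", ]
  arcs <- c()
  for (i in 1:120) {
    ev <- simulate_events(cfg, pr$profile, 1)
    arcs <- c(arcs, ev$arc_position)
  }
  # map arc onto cumulative positive length -> uniform [0, total)
  cum0 <- c(0, cumsum(pos$end - pos$start))
  u <- vapply(arcs, function(a) {
    i <- which(a >= pos$start & a < pos$end)[1]
    cum0[i] + (a - pos$start[i])
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(u / sum(pos$end - pos$start), "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("forward model matches its closed-form anchors", {
  # zero events, no noise, no bleach -> identical frames
  cfg <- scene_config(field_length = 30, n_frames = 10, poisson_gain = 0,
                      read_sd = 0, bleach_tau = Inf, gap_lengths = c(8),
                      n_collaterals = 1, collateral_length = 5,
                      rate_nonmyelinated = 0, rate_myelinated = 0,
                      rate_collateral = 0, heminodal_factor = 0, seed = 5)
  set.seed(5)
  pr <- simulate_profile(cfg)
  no_ev <- simulate_events(cfg, pr$profile, 1e-9, pr$collateral_arcs)
  scene <- render_movie(cfg, pr$profile, no_ev[0, ], pr$collateral_arcs)
  for (t in 2:10) expect_identical(scene$movie$frames[, , t],
                                   scene$movie$frames[, , 1])
  # one event of amplitude 2 -> peak pixel = 3 x local baseline at onset
  ev <- data.frame(compartment = "axon", region = "nonmyelinated",
                   arc_position = 15, branch_id = NA_integer_,
                   branch_arc = NA_real_, start_frame = 4L, amplitude = 2,
                   duration_s = 4, mobile = FALSE, velocity_um_s = 0,
                   start_time_s = 4)
  scene1 <- render_movie(cfg, pr$profile, ev, pr$collateral_arcs)
  base <- scene1$movie$frames[cfg$axon_row + 1, 61, 1]
  peak <- scene1$movie$frames[cfg$axon_row + 1, 61, 5]
  expect_equal(peak, 3 * base, tolerance = 1e-12)
  # and the spot is back at baseline exactly at the drawn duration
  expect_equal(scene1$movie$frames[cfg$axon_row + 1, 61, 9], base,
               tolerance = 1e-9)
  # bleach_tau = total time -> whole-field mean at the last frame ~ e^-1
  cfgb <- scene_config(field_length = 30, n_frames = 101, poisson_gain = 0,
                       read_sd = 0, bleach_tau = 100, gap_lengths = numeric(0),
                       n_collaterals = 0, rate_nonmyelinated = 0,
                       heminodal_factor = 0, seed = 6)
  prb <- profile_from_gaps(30, numeric(0), numeric(0))
  sb <- render_movie(cfgb, prb, ev[0, ], numeric(0))
  m0 <- mean(sb$movie$frames[, , 1])
  m1 <- mean(sb$movie$frames[, , 101])
  expect_equal(m1 / m0, exp(-1), tolerance = 1e-12)
})

test_that("scene simulation is byte-deterministic under a fixed seed", {
  cfg <- oracle_scene_config(9)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$movie$frames, s2$movie$frames)
  expect_identical(s1$events, s2$events)
  f1 <- tempfile(); f2 <- tempfile()
  write_movie(s1$movie, f1, sidecar = FALSE)
  write_movie(s2$movie, f2, sidecar = FALSE)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
})

test_that("ground truth serializes losslessly", {
  cfg <- oracle_scene_config(12)
  scene <- simulate_scene(cfg)
  f <- tempfile(fileext = ".json")
  write_ground_truth(scene, f)
  back <- read_ground_truth(f)
  expect_equal(back$events$arc_position, scene$events$arc_position)
  expect_equal(back$events$amplitude, scene$events$amplitude)
  expect_equal(gaps_of(back$profile)$start, gaps_of(scene$profile)$start)
  expect_identical(back$drift, scene$drift)
  # every true event lies inside field and time range
  expect_true(all(scene$events$arc_position >= 0 &
                    scene$events$arc_position <= cfg$field_length))
  expect_true(all(scene$events$start_frame >= 0 &
                    scene$events$start_frame < cfg$n_frames))
})

test_that("sheath growth model honours its degenerate anchors", {
  cfg <- scene_config(growth_b0_nascent = 0.5, growth_b1_nascent = 0,
                      growth_sd_nascent = 0, growth_b0_stable = 0.5,
                      growth_b1_stable = 0, growth_sd_stable = 0,
                      gap_lengths = c(4, 10), gap_min_separation = 10,
                      session_times = c(0, 4), seed = 13)
  set.seed(13)
  pr <- simulate_profile(cfg)
  ev <- simulate_events(cfg, pr$profile, 1/6, pr$collateral_arcs)
  ev <- ev[0, ]                             # no events: rate = b0 exactly
  tc <- simulate_sheath_timecourse(cfg, pr$profile, ev, 1/6)
  expect_true(all(tc$fate == "grow"))
  expect_equal(tc$growth_rate, rep(0.5, nrow(tc)))
  expect_equal(tc$final_length, tc$initial_length + 2)
  # forced shrink to zero -> full retraction at zero length
  cfg$growth_b0_nascent <- -5; cfg$growth_b0_stable <- -5
  tc2 <- simulate_sheath_timecourse(cfg, pr$profile, ev, 1/6)
  expect_true(all(tc2$final_length == 0))
  expect_true(all(tc2$fate == "full_retraction"))
})

test_that("no stabilized sheath fully retracts in the stated growth regime", {
  cfg <- scene_config(gap_lengths = c(8, 12, 16), gap_min_separation = 9,
                      field_length = 140)
  set.seed(14)
  n_stab_retract <- 0L; n_stab <- 0L
  while (n_stab < 500) {
    pr <- simulate_profile(cfg)
    ev <- simulate_events(cfg, pr$profile, 1/6, pr$collateral_arcs)
    tc <- simulate_sheath_timecourse(cfg, pr$profile, ev, 1/6)
    stab <- tc[tc$initial_length >= 6, ]
    n_stab <- n_stab + nrow(stab)
    n_stab_retract <- n_stab_retract + sum(stab$fate == "full_retraction")
  }
  expect_equal(n_stab_retract, 0L)
})
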