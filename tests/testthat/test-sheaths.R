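# sheath_dynamics: matching, growth rates and fates, the 6-um threshold
# table, activity correlation, fully-grown classification, fold changes.

test_that("sheath matching aligns by landmarks and reports retractions", {
  p1 <- profile_from_gaps(100, c(10, 40, 70), c(20, 50, 80))
  lm <- c(30, 60)
  # identical profiles -> all matched, none retracted or new
  m <- match_sheaths(p1, p1, lm, lm)
  expect_equal(nrow(m$matched), 3L)
  expect_length(m$retracted, 0L)
  expect_length(m$new, 0L)
  # middle sheath gone at t2 -> full retraction
  p2 <- profile_from_gaps(100, c(10, 70), c(20, 80))
  m2 <- match_sheaths(p1, p2, lm, lm)
  expect_equal(nrow(m2$matched), 2L)
  expect_equal(m2$retracted, 2L)
  # symmetric: swapping sessions maps retraction to new
  m2r <- match_sheaths(p2, p1, lm, lm)
  expect_length(m2r$retracted, 0L)
  expect_equal(m2r$new, 2L)
  # landmark offset is removed before midpoint comparison
  p3 <- profile_from_gaps(100, c(12, 42, 72), c(22, 52, 82))
  m3 <- match_sheaths(p1, p3, lm, lm + 2)
  expect_equal(nrow(m3$matched), 3L)
  expect_error(match_sheaths(p1, p2, c(30), c(30, 60)), "incompatible")
})

test_that("growth rate and fate are exact arithmetic", {
  g <- growth_rate(5, 8, 0, 24)
  expect_equal(g$rate, 0.125)
  expect_equal(g$fate, "grow")
  g2 <- growth_rate(5, 3, 0, 4)
  expect_equal(g2$rate, -0.5)
  expect_equal(g2$fate, "shrink")
  expect_equal(growth_rate(5, 5, 0, 4)$fate, "stable")
  # invariant to adding a constant to both session times
  expect_equal(growth_rate(5, 8, 100, 124)$rate, 0.125)
  expect_error(growth_rate(5, 8, 4, 4), "positive")
})

test_that("the nascent fate table splits at 6 um (half-open upward)", {
  sheaths <- data.frame(
    initial_length = c(3, 4, 5.9, 6.0, 8, 12, 2.5, 7),
    fate = c("grow", "shrink", "full_retraction", "grow", "grow", "grow",
             "stable", "shrink"))
  ft <- nascent_fate_table(sheaths)
  expect_equal(unname(ft$table["nascent", "grow"]), 1L)
  expect_equal(unname(ft$table["nascent", "shrink"]), 2L)  # retraction counts
  expect_equal(unname(ft$table["stabilized", "grow"]), 3L) # 6.0 is stabilized
  expect_equal(unname(ft$table["stabilized", "shrink"]), 1L)
  expect_equal(ft$n_stable_excluded, 1L)
  expect_equal(ft$n_full_retractions, 1L)
  expect_equal(unname(ft$retractions_by_class["nascent"]), 1L)
  # all growing -> shrink column zero, Fisher p undefined-friendly
  ft2 <- nascent_fate_table(data.frame(initial_length = c(3, 8),
                                       fate = c("grow", "grow")))
  expect_equal(sum(ft2$table[, "shrink"]), 0L)
})

test_that("generator regime: sub-6-um sheaths shrink more often", {
  cfg <- scene_config(gap_lengths = c(3.5, 5, 10, 14), gap_min_separation = 9,
                      field_length = 140)
  set.seed(70)
  tcs <- list()
  while (Reduce(`+`, lapply(tcs, nrow), 0) < 200) {
    pr <- simulate_profile(cfg)
    ev <- simulate_events(cfg, pr$profile, 1 / 6, pr$collateral_arcs)
    tcs[[length(tcs) + 1L]] <- simulate_sheath_timecourse(cfg, pr$profile, ev,
                                                          1 / 6)
  }
  tc <- do.call(rbind, tcs)
  shrinkish <- tc$fate %in% c("shrink", "full_retraction")
  f_nascent <- mean(shrinkish[tc$initial_length < 6])
  f_stable <- mean(shrinkish[tc$initial_length >= 6])
  expect_gt(f_nascent, f_stable)
  ft <- nascent_fate_table(tc)
  expect_lt(ft$fisher_p, 0.05)
})

test_that("growth/activity analysis recovers coupling and degenerates safely", {
  cfg <- scene_config(gap_lengths = c(3.5, 4.5, 5.5), gap_min_separation = 8)
  set.seed(71)
  tcs <- list()
  while (Reduce(`+`, lapply(tcs, nrow), 0) < 85) {
    pr <- simulate_profile(cfg)
    ev <- simulate_events(cfg, pr$profile, 1 / 6, pr$collateral_arcs)
    tcs[[length(tcs) + 1L]] <- simulate_sheath_timecourse(cfg, pr$profile, ev,
                                                          1 / 6)
  }
  tc <- do.call(rbind, tcs)[1:85, ]
  g <- growth_vs_heminodal_activity(tc)
  expect_gt(g$nascent$heminodal$r, 0)
  expect_lt(g$nascent$heminodal$p, 0.05)
  expect_equal(g$activity_groups$with$n + g$activity_groups$without$n,
               sum(tc$initial_length < 6))
  # constant growth rate -> r undefined, reported as such
  flat <- data.frame(initial_length = rep(3, 10), growth_rate = 1,
                     heminodal_freq = runif(10), under_sheath_freq = runif(10),
                     heminodal_count = rpois(10, 1))
  gf <- growth_vs_heminodal_activity(flat)
  expect_true(is.na(gf$nascent$heminodal$r))
})

test_that("fully-grown classification needs both flanks occupied", {
  # node on one side (0.8-um positive between gaps), collateral on the other
  p <- profile_from_gaps(100, c(30, 40.8), c(40, 50))
  cls <- fully_grown_classification(p, collateral_arcs = c(30))
  # first sheath: left flank collateral (at 30), right flank node
  expect_equal(cls$status[1], "fully_grown")
  expect_equal(cls$flank_left[1], "collateral")
  expect_equal(cls$flank_right[1], "node")
  # second sheath: node left, open right -> free
  expect_equal(cls$status[2], "free")
  # edge-incomplete sheaths are excluded
  pe <- profile_from_gaps(100, 0, 20)
  expect_equal(nrow(fully_grown_classification(pe)), 0L)
})

test_that("frequency fold change handles plain and zero-baseline cases", {
  p <- profile_from_gaps(100, numeric(0), numeric(0))
  mk <- function(arcs, dur) {
    n <- length(arcs)
    ev <- as_detected_events(data.frame(
      compartment = rep("axon", n), arc_position = arcs,
      branch_id = rep(NA_integer_, n), branch_arc = rep(NA_real_, n),
      start_frame = rep(0L, n), amplitude = rep(1, n), duration_s = rep(6, n),
      mobile = rep(FALSE, n)))
    frequency_report(assign_compartments(ev, p), p, NULL, dur)
  }
  # 0.5 -> 0.8 events/um/h is a 1.6-fold increase
  pre <- mk(seq(1, 99, length.out = 50), 1)      # 0.5 /um/h
  post <- mk(seq(1, 99, length.out = 80), 1)     # 0.8 /um/h
  fc <- frequency_fold_change(pre, post)
  expect_equal(fc$fold_change[fc$compartment == "axonal"], 1.6)
  # identical sessions -> 1.0
  fc1 <- frequency_fold_change(pre, pre)
  expect_equal(fc1$fold_change[fc1$compartment == "axonal"], 1)
  # zero pre-frequency -> NA with a finite pseudocount alternative
  none <- mk(numeric(0), 1)
  fc0 <- frequency_fold_change(none, post)
  i <- fc0$compartment == "axonal"
  expect_true(is.na(fc0$fold_change[i]))
  expect_true(is.finite(fc0$fold_change_pseudocount[i]))
})
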