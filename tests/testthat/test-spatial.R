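# spatial_stats: compartment assignment, frequency normalization,
# heminodal enrichment, paired test, co-localization.

label_events <- function(arcs, profile, compartment = "axon") {
  n <- length(arcs)
  ev <- as_detected_events(data.frame(
    compartment = rep(compartment, n), arc_position = arcs,
    branch_id = rep(NA_integer_, n), branch_arc = rep(NA_real_, n),
    start_frame = rep(0L, n), amplitude = rep(1, n), duration_s = rep(6, n),
    mobile = rep(FALSE, n)))
  assign_compartments(ev, profile)
}

test_that("events are point-assigned to exactly one compartment", {
  p <- profile_from_gaps(100, 40, 60)      # heminodes [37,40) and [60,63)
  lab <- label_events(c(38.0, 34.5, 50, 63.5, 60.0, 37.0), p)
  # 2.0 um from the gap edge on the positive side -> heminodal
  expect_equal(lab$compartment[1], "heminodal")
  # 3.5 um out -> positive_other (heminode is exactly 3 um)
  expect_equal(lab$compartment[2], "positive_other")
  expect_equal(lab$compartment[3], "gap_region")
  expect_equal(lab$compartment[4], "positive_other")  # 3.5 um past gap end
  # half-open intervals, lower bound inclusive: 60.0 is the heminode start
  expect_equal(lab$compartment[5], "heminodal")
  expect_equal(lab$compartment[6], "heminodal")
  # collaterals keep their own label; mobiles are excluded (NA)
  ev <- as_detected_events(data.frame(
    compartment = c("collateral", "axon"), arc_position = c(20, 50),
    branch_id = c(1L, NA), branch_arc = c(2, NA), start_frame = 0L,
    amplitude = 1, duration_s = 6, mobile = c(FALSE, TRUE)))
  lab2 <- assign_compartments(ev, p)
  expect_equal(lab2$compartment, c("collateral", NA))
  # outside the field is an error
  expect_error(label_events(150, p), "outside")
})

test_that("frequencies normalize to length and duration", {
  p <- profile_from_gaps(100, numeric(0), numeric(0))
  # 12 axonal events, 100 um, 0.2 h -> 0.6 events/um/h = 6 per 10 um h
  lab <- label_events(seq(5, 95, length.out = 12), p)
  fr <- frequency_report(lab, p, NULL, 0.2)
  expect_equal(unname(fr$freq["axonal"]), 0.6)
  expect_equal(unname(fr$freq_per10um["axonal"]), 6)
  # compartments with zero length are undefined, not zero
  expect_true(is.na(fr$freq["gap_region"]))
  expect_true(is.na(fr$freq["collateral"]))
  # zero events -> zero frequencies
  fr0 <- frequency_report(label_events(numeric(0), p), p, NULL, 1)
  expect_equal(unname(fr0$freq["axonal"]), 0)
  # excluded mobile events are not counted
  ev <- as_detected_events(data.frame(
    compartment = "axon", arc_position = c(10, 20, 30), branch_id = NA_integer_,
    branch_arc = NA_real_, start_frame = 0L, amplitude = 1, duration_s = 6,
    mobile = c(FALSE, TRUE, TRUE)))
  frm <- frequency_report(assign_compartments(ev, p), p, NULL, 1)
  expect_equal(unname(frm$counts["axonal"]), 1)
  expect_error(frequency_report(lab, p, NULL, 0), "duration")
})

test_that("counts are conserved across the compartment partition", {
  cfg <- scene_config(seed = 55)
  set.seed(55)
  pr <- simulate_profile(cfg)
  ev <- simulate_events(cfg, pr$profile, 1, pr$collateral_arcs)
  lab <- truth_labelled(cfg, pr$profile, ev)
  fr <- frequency_report(lab, pr$profile, NULL, 1)
  n_nonmobile <- sum(!ev$mobile)
  expect_equal(unname(fr$counts["axonal"] + fr$counts["collateral"]),
               n_nonmobile)
  expect_equal(unname(fr$counts["positive_region"] + fr$counts["gap_region"]),
               unname(fr$counts["axonal"]))
  expect_lte(fr$counts["heminodal"], fr$counts["positive_region"])
})

test_that("enrichment follows the predicted-uniform formula", {
  # 20 positive-region events on 60 um positive length in 2 h, 4 heminodes,
  # 6 of the events heminodal: predicted 0.5, observed 0.75, ratio 1.5
  p <- profile_from_gaps(80, c(20, 50), c(30, 60))   # 60 um positive, 4 hemi
  expect_equal(positive_length(p), 60)
  expect_equal(nrow(p$heminodes), 4L)
  arcs <- c(seq(18.2, 19.8, length.out = 3), seq(60.2, 62.8, length.out = 3),
            seq(2, 15, length.out = 8), seq(33.5, 46.5, length.out = 6))
  lab <- label_events(arcs, p)
  expect_equal(sum(lab$compartment == "heminodal"), 6L)
  enr <- heminodal_enrichment(lab, p, 2)
  expect_equal(enr$predicted, 0.5)
  expect_equal(enr$observed, 0.75)
  expect_equal(enr$ratio, 1.5)
  # zero positive events -> predicted 0, ratio undefined
  enr0 <- heminodal_enrichment(label_events(numeric(0), p), p, 2)
  expect_equal(enr0$predicted, 0)
  expect_true(is.na(enr0$ratio))
  # no heminodes -> undefined, reported as such
  pu <- profile_from_gaps(100, numeric(0), numeric(0))
  enru <- heminodal_enrichment(label_events(50, pu), pu, 1)
  expect_true(is.na(enru$ratio))
  expect_equal(enru$reason, "no_heminodes")
})

test_that("the paired enrichment test behaves at its anchors", {
  # all observed = predicted -> p = 1, no direction
  res <- paired_enrichment_test(rep(0.5, 10), rep(0.5, 10))
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")
  # sign flip gives the same p with reversed direction
  set.seed(60)
  obs <- runif(20, 0.5, 1.5); pred <- obs - runif(20, 0.1, 0.3)
  a <- paired_enrichment_test(obs, pred)
  b <- paired_enrichment_test(pred, obs)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$direction, "observed_higher")
  expect_equal(b$direction, "observed_lower")
  expect_error(paired_enrichment_test(1:3, 1:3 + 0.5), "at least 6")
})

test_that("co-localization overlap matches Poisson geometry", {
  expect_equal(colocalization_overlap(1:5, 1:5, 0.5)$fraction_events_overlapping, 1)
  expect_equal(colocalization_overlap(1:5, (1:5) + 10, 0.5)$events_near_puncta, 0)
  # randomized puncta: P(overlap) = 1 - exp(-2 tol density)
  set.seed(61)
  tol <- 1; dens <- 0.15; L <- 4000
  puncta <- runif(round(dens * L), 0, L)
  events <- runif(600, 50, L - 50)
  frac <- colocalization_overlap(events, puncta, tol)$fraction_events_overlapping
  expected <- 1 - exp(-2 * tol * dens)
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / 600))
})
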