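# myelin_profile: segmentation, percent myelination, axon class,
# heminode / node derivation.

test_that("segmentation finds gaps and applies the minimum-gap filter", {
  ps <- 0.25
  # uniform positive profile -> zero gaps, 0%
  u <- segment_profile(rep(150, 400), ps)
  expect_equal(sum(u$segments$label == "gap"), 0L)
  expect_equal(u$percent_myelination, 0)
  # one 20-um zero-intensity run on 100 um -> one complete 20-um gap
  x <- rep(150, 400)
  x[121:200] <- 0                      # 30-50 um
  p <- segment_profile(x, ps)
  g <- p$segments[p$segments$label == "gap", ]
  expect_equal(nrow(g), 1L)
  expect_equal(g$end - g$start, 20)
  expect_true(g$complete)
  expect_equal(p$percent_myelination, 20)
  # a 0.5-um dip is below min_gap_length and vanishes
  x2 <- rep(150, 400)
  x2[201:202] <- 0
  p2 <- segment_profile(x2, ps)
  expect_equal(sum(p2$segments$label == "gap"), 0L)
  # edge-touching gap flagged incomplete but counted in percent
  x3 <- rep(150, 400)
  x3[1:40] <- 0
  p3 <- segment_profile(x3, ps)
  g3 <- p3$segments[p3$segments$label == "gap", ]
  expect_false(g3$complete)
  expect_equal(p3$percent_myelination, 10)
  expect_error(segment_profile(rep(0, 100), ps), "no reporter-positive")
})

test_that("percent myelination is plain gap arithmetic", {
  p <- profile_from_gaps(100, c(10, 60), c(30, 70))
  expect_equal(percent_myelination(p), 30)           # 20 + 10 on 100
  expect_equal(percent_myelination(profile_from_gaps(100, numeric(0),
                                                     numeric(0))), 0)
  expect_equal(percent_myelination(profile_from_gaps(50, 0, 50)), 100)
})

test_that("axon classification follows the 5% / heminode-count rule", {
  expect_equal(profile_from_gaps(100, numeric(0), numeric(0))$axon_class,
               "not_yet_myelinated")
  # 4% but 4 heminodes (two interior gaps) -> myelinating
  p4 <- profile_from_gaps(100, c(30, 60), c(32, 62))
  expect_equal(percent_myelination(p4), 4)
  expect_equal(nrow(p4$heminodes), 4L)
  expect_equal(p4$axon_class, "myelinating")
  # 30% -> myelinating regardless
  expect_equal(profile_from_gaps(100, 10, 40)$axon_class, "myelinating")
  # exactly 5% with <= 2 heminodes -> not yet myelinated (strict ">")
  p5 <- profile_from_gaps(100, 0, 5)                 # edge gap: 1 heminode
  expect_equal(percent_myelination(p5), 5)
  cls <- classify_axon(p5)
  expect_equal(as.character(cls), "not_yet_myelinated")
  expect_true(isTRUE(attr(cls, "boundary")))
})

test_that("heminodes and nodes are derived per their definitions", {
  # one interior gap -> two 3-um heminodes abutting the gap
  p <- profile_from_gaps(100, 40, 60)
  expect_equal(nrow(p$heminodes), 2L)
  expect_equal(p$heminodes$end[1] - p$heminodes$start[1], 3)
  expect_equal(p$heminodes$end[1], 40)               # abuts the gap start
  expect_equal(p$heminodes$start[2], 60)             # abuts the gap end
  # 0.8-um positive segment between gaps -> node, no heminodes there
  pn <- profile_from_gaps(100, c(30, 40.8), c(40, 50))
  expect_equal(nrow(pn$nodes), 1L)
  expect_equal(pn$nodes$end - pn$nodes$start, 0.8)
  inner <- pn$heminodes$start >= 40 & pn$heminodes$end <= 40.8
  expect_false(any(inner))
  # 4-um positive segment between gaps -> two heminodes of 2 um
  ph <- profile_from_gaps(100, c(30, 44), c(40, 50))
  mid <- ph$heminodes[ph$heminodes$start >= 40 & ph$heminodes$end <= 44, ]
  expect_equal(nrow(mid), 2L)
  expect_equal(mid$end - mid$start, c(2, 2))
})

test_that("profiles tile the field and keep features disjoint", {
  set.seed(40)
  for (i in 1:20) {
    n_gap <- sample(0:3, 1)
    bounds <- sort(runif(2 * n_gap, 1, 99))
    gs <- bounds[seq(1, length.out = n_gap, by = 2)]
    ge <- bounds[seq(2, length.out = n_gap, by = 2)]
    ok <- !length(gs) || all(ge - gs > 0.1)
    if (!ok) next
    p <- profile_from_gaps(100, gs, ge)
    seg <- p$segments
    # tiling: segments cover [0, 100] without overlap
    expect_equal(seg$start[1], 0)
    expect_equal(seg$end[nrow(seg)], 100)
    if (nrow(seg) > 1) expect_equal(seg$start[-1], seg$end[-nrow(seg)])
    expect_equal(sum(seg$end - seg$start), 100)
    expect_true(p$percent_myelination >= 0 && p$percent_myelination <= 100)
    # heminodes never overlap gaps or each other
    if (nrow(p$heminodes)) {
      for (j in seq_len(nrow(p$heminodes))) {
        h <- p$heminodes[j, ]
        expect_lte(h$end - h$start, 3 + 1e-9)
        g <- seg[seg$label == "gap", ]
        overlap <- any(h$start < g$end - 1e-9 & h$end > g$start + 1e-9)
        expect_false(overlap)
      }
      o <- order(p$heminodes$start)
      hs <- p$heminodes[o, ]
      if (nrow(hs) > 1) {
        expect_true(all(hs$start[-1] >= hs$end[-nrow(hs)] - 1e-9))
      }
    }
  }
})

test_that("segmentation recovers simulated coverage within one pixel per edge", {
  cfg <- scene_config(seed = 41)
  set.seed(41)
  pr <- simulate_profile(cfg)
  scene <- render_movie(cfg, pr$profile,
                        simulate_events(cfg, pr$profile, 1e-9)[0, ],
                        pr$collateral_arcs)
  seg <- segment_profile(profile_intensity(scene$red, scene$geometry),
                         cfg$pixel_size)
  n_edges <- 2 * sum(pr$profile$segments$label == "gap")
  tol_pct <- 100 * n_edges * cfg$pixel_size / cfg$field_length
  expect_lt(abs(seg$percent_myelination - pr$profile$percent_myelination),
            tol_pct + 1e-9)
})

test_that("profile CSV round trip preserves gaps", {
  p <- profile_from_gaps(120, c(10.25, 50.5), c(30.75, 60))
  f <- tempfile(fileext = ".csv")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(gaps_of(p2)$start, gaps_of(p)$start, tolerance = 1e-12)
  expect_equal(p2$percent_myelination, p$percent_myelination)
})
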