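# Sheath dynamics: matching sheaths across imaging sessions by axonal
# landmarks, growth rates and fates, the 6-um nascent-sheath threshold
# analysis, correlation of growth with local event frequency, and
# per-compartment frequency fold changes between sessions.
#
# Sheath-centric analyses use complete gaps only (incomplete edge gaps are
# excluded).  A sheath exactly at the 6-um threshold belongs to the
# stabilized (>= 6 um) class.

#' Growth analysis configuration
#'
#' @param nascent_threshold length separating nascent from stabilized
#'   sheaths (um).
#' @param matching_tolerance midpoint agreement required to match sheaths
#'   across sessions (um).
#' @param flank_tolerance distance within which a node or collateral borders
#'   a sheath end (um); defaults to one pixel at the default scene scale.
#' @return list of class `growth_config`.
#' @export
growth_config <- function(nascent_threshold = 6, matching_tolerance = 2,
                          flank_tolerance = 0.25) {
  stopifnot(nascent_threshold > 0, matching_tolerance > 0)
  structure(as.list(environment()), class = "growth_config")
}

#' Match sheaths between two sessions
#'
#' Complete gaps only.  Landmarks (collateral branch points) align the two
#' sessions: the mean landmark offset is removed, then sheaths lying between
#' the same ordered pair of landmarks whose midpoints agree within the
#' tolerance are matched greedily (closest first).  Unmatched session-1
#' sheaths are full retractions; unmatched session-2 sheaths are new.
#'
#' @param profile_t1,profile_t2 `myelin_profile` objects for the two sessions.
#' @param landmarks_t1,landmarks_t2 collateral branch-point arcs (um); must
#'   have equal length (the same branches re-identified).
#' @param config [growth_config()].
#' @return list: `matched` data.frame (id1, id2, length1, length2, mid1,
#'   mid2), `retracted` (session-1 ids), `new` (session-2 ids),
#'   `landmark_offset` (um).
#' @export
match_sheaths <- function(profile_t1, profile_t2, landmarks_t1 = numeric(),
                          landmarks_t2 = landmarks_t1,
                          config = growth_config()) {
  if (length(landmarks_t1) != length(landmarks_t2)) {
    stop("landmark sets are incompatible (different counts)")
  }
  offset <- if (length(landmarks_t1)) mean(landmarks_t2 - landmarks_t1) else 0
  g1 <- gaps_of(profile_t1, complete_only = TRUE)
  g2 <- gaps_of(profile_t2, complete_only = TRUE)
  bins <- sort(c(-Inf, landmarks_t2, Inf))
  bin_of <- function(mid) findInterval(mid, bins)
  m1 <- (g1$start + g1$end) / 2 + offset
  m2 <- (g2$start + g2$end) / 2
  b1 <- bin_of(m1); b2 <- bin_of(m2)
  used2 <- logical(nrow(g2))
  matched <- list()
  if (nrow(g1) && nrow(g2)) {
    # candidate pairs in the same landmark interval, closest midpoints first
    pairs <- expand.grid(i = seq_len(nrow(g1)), j = seq_len(nrow(g2)))
    pairs <- pairs[b1[pairs$i] == b2[pairs$j], , drop = FALSE]
    pairs$d <- abs(m1[pairs$i] - m2[pairs$j])
    pairs <- pairs[pairs$d <= config$matching_tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    used1 <- logical(nrow(g1))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (used1[i] || used2[j]) next
      used1[i] <- TRUE; used2[j] <- TRUE
      matched[[length(matched) + 1L]] <- data.frame(
        id1 = i, id2 = j, length1 = g1$end[i] - g1$start[i],
        length2 = g2$end[j] - g2$start[j], mid1 = m1[i] - offset, mid2 = m2[j])
    }
    retracted <- which(!used1)
  } else {
    retracted <- seq_len(nrow(g1))
  }
  list(matched = if (length(matched)) do.call(rbind, matched) else
         data.frame(id1 = integer(0), id2 = integer(0), length1 = numeric(0),
                    length2 = numeric(0), mid1 = numeric(0), mid2 = numeric(0)),
       retracted = retracted, new = which(!used2),
       landmark_offset = offset)
}

#' Growth rate and fate of a matched sheath
#'
#' @param length1,length2 sheath lengths at the two sessions (um).
#' @param time1,time2 session times (h), `time2 > time1`.
#' @return list: `rate` (um/h), `fate` (`"grow"`, `"shrink"` or `"stable"`).
#' @export
growth_rate <- function(length1, length2, time1, time2) {
  dt <- time2 - time1
  if (!is.finite(dt) || dt <= 0) stop("session interval must be positive")
  rate <- (length2 - length1) / dt
  list(rate = rate,
       fate = if (rate > 0) "grow" else if (rate < 0) "shrink" else "stable")
}

#' Nascent-versus-stabilized fate contingency table
#'
#' Cross-tabulates sheath fate (grow / shrink) against initial length class
#' (below versus at-or-above the nascent threshold).  Full retractions count
#' as shrink and are also reported separately; zero-rate sheaths are
#' reported but excluded from the 2x2 table.  Fisher's exact test on the
#' table.
#'
#' @param sheaths data.frame with `initial_length` and `fate`
#'   (`grow`/`shrink`/`stable`/`full_retraction`), e.g. from
#'   [simulate_sheath_timecourse()].
#' @param config [growth_config()].
#' @return list: `table` (2x2), `fisher_p`, `n_stable_excluded`,
#'   `n_full_retractions`, `retractions_by_class`.
#' @export
nascent_fate_table <- function(sheaths, config = growth_config()) {
  thr <- config$nascent_threshold
  cls <- factor(ifelse(sheaths$initial_length < thr, "nascent", "stabilized"),
                levels = c("nascent", "stabilized"))
  fate <- sheaths$fate
  fate[fate == "full_retraction"] <- "shrink"
  keep <- fate %in% c("grow", "shrink")
  tab <- table(class = cls[keep],
               fate = factor(fate[keep], levels = c("grow", "shrink")))
  fp <- if (all(dim(tab) == c(2, 2)) && sum(tab) > 0) {
    stats::fisher.test(tab)$p.value
  } else NA_real_
  retr <- sheaths$fate == "full_retraction"
  list(table = tab, fisher_p = fp,
       n_stable_excluded = sum(!keep),
       n_full_retractions = sum(retr),
       retractions_by_class = table(cls[retr]))
}

#' Correlate sheath growth with local event frequency
#'
#' Pearson correlations of growth rate against heminodal and under-sheath
#' event frequency, separately for nascent and stabilized sheaths, plus the
#' with-/without-heminodal-activity group comparison (Mann-Whitney between
#' groups; one-sample Wilcoxon of each group's rates against zero).  A
#' sheath "with activity" had at least one heminodal event during the
#' observation window.
#'
#' @param sheaths data.frame with `initial_length`, `growth_rate`,
#'   `heminodal_freq`, `under_sheath_freq` and `heminodal_count` columns.
#' @param config [growth_config()].
#' @return nested list; correlations carry `r`, `p`, `n` (NA when degenerate
#'   or fewer than 3 sheaths).
#' @export
growth_vs_heminodal_activity <- function(sheaths, config = growth_config()) {
  corr <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(list(r = NA_real_, p = NA_real_, n = length(x)))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
  nas <- sheaths[sheaths$initial_length < config$nascent_threshold, , drop = FALSE]
  stab <- sheaths[sheaths$initial_length >= config$nascent_threshold, , drop = FALSE]
  with_act <- nas[nas$heminodal_count >= 1, , drop = FALSE]
  without <- nas[nas$heminodal_count == 0, , drop = FALSE]
  grp <- function(g) {
    if (nrow(g) < 3) return(list(n = nrow(g), p_vs_zero = NA_real_,
                                 median_rate = if (nrow(g)) stats::median(g$growth_rate)
                                               else NA_real_))
    list(n = nrow(g),
         p_vs_zero = suppressWarnings(
           stats::wilcox.test(g$growth_rate, mu = 0, exact = FALSE)$p.value),
         median_rate = stats::median(g$growth_rate))
  }
  mw <- if (nrow(with_act) >= 3 && nrow(without) >= 3) {
    suppressWarnings(stats::wilcox.test(with_act$growth_rate,
                                        without$growth_rate,
                                        exact = FALSE)$p.value)
  } else NA_real_
  list(
    nascent = list(
      heminodal = corr(nas$heminodal_freq, nas$growth_rate),
      under_sheath = corr(nas$under_sheath_freq, nas$growth_rate)),
    stabilized = list(
      heminodal = corr(stab$heminodal_freq, stab$growth_rate),
      under_sheath = corr(stab$under_sheath_freq, stab$growth_rate)),
    activity_groups = list(with = grp(with_act), without = grp(without),
                           mann_whitney_p = mw))
}

#' Classify complete sheaths as fully grown or free to grow
#'
#' A sheath is fully grown when both flanks are a node or a collateral
#' branch point (within the flank tolerance); otherwise it is free to grow.
#' Incomplete edge gaps are excluded.
#'
#' @param profile `myelin_profile`.
#' @param collateral_arcs collateral branch-point arcs (um).
#' @param config [growth_config()].
#' @return data.frame: start, end, length, flank_left, flank_right, status
#'   (`"fully_grown"`/`"free"`).
#' @export
fully_grown_classification <- function(profile, collateral_arcs = numeric(),
                                       config = growth_config()) {
  g <- gaps_of(profile, complete_only = TRUE)
  if (!nrow(g)) {
    return(data.frame(start = numeric(0), end = numeric(0), length = numeric(0),
                      flank_left = character(0), flank_right = character(0),
                      status = character(0)))
  }
  attr(profile, "collateral_arcs") <- collateral_arcs
  rows <- lapply(seq_len(nrow(g)), function(i) {
    fl <- .gap_flanks(profile, g$start[i], g$end[i], config$flank_tolerance,
                      collateral_arcs)
    data.frame(start = g$start[i], end = g$end[i],
               length = g$end[i] - g$start[i],
               flank_left = fl[1], flank_right = fl[2],
               status = if (all(fl %in% c("node", "collateral"))) "fully_grown"
                        else "free",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-compartment frequency fold change between two sessions
#'
#' Fold change = post frequency / pre frequency for each compartment of the
#' same axon.  A zero pre-frequency makes the plain fold change undefined
#' (NA); a pseudocount alternative (half an event added to both counts) is
#' reported alongside.
#'
#' @param report_pre,report_post `event_frequency_report` objects for the
#'   two sessions.
#' @return data.frame: compartment, freq_pre, freq_post, fold_change,
#'   fold_change_pseudocount.
#' @export
frequency_fold_change <- function(report_pre, report_post) {
  comps <- names(report_pre$freq)
  if (any(report_pre$lengths == 0 & report_post$lengths > 0)) {
    # a compartment present post but absent pre cannot be normalized
    stop("compartment lengths differ between sessions")
  }
  fold <- ifelse(is.na(report_pre$freq) | is.na(report_post$freq), NA_real_,
                 ifelse(report_pre$freq > 0,
                        report_post$freq / report_pre$freq, NA_real_))
  pseudo <- mapply(function(cp, cq, l, dp, dq) {
    if (l <= 0) return(NA_real_)
    ((cq + 0.5) / l / dq) / ((cp + 0.5) / l / dp)
  }, report_pre$counts, report_post$counts, report_pre$lengths,
     MoreArgs = list(dp = report_pre$duration_h, dq = report_post$duration_h))
  data.frame(compartment = comps,
             freq_pre = unname(report_pre$freq),
             freq_post = unname(report_post$freq),
             fold_change = unname(fold),
             fold_change_pseudocount = unname(pseudo),
             stringsAsFactors = FALSE)
}
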