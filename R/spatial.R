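# Spatial statistics: compartment assignment of events along the myelin
# profile, length- and duration-normalized frequencies, and the heminodal
# observed-versus-predicted enrichment statistic.
#
# Events are point-assigned by their peak arc position; intervals are
# half-open [start, end), lower bound inclusive.  Events excluded as mobile
# never enter frequency statistics.

.in_interval <- function(x, start, end) x >= start & x < end

.analyzable <- function(events) {
  events[events$accepted & events$motion_class != "excluded_mobile" &
           !is.na(events$compartment_raw), , drop = FALSE]
}

#' Assign events to axonal compartments
#'
#' Each accepted, non-excluded event receives exactly one label:
#' `collateral`, `gap_region` (under a sheath), `heminodal` (within the
#' first 3 um of positive axon bordering a gap) or `positive_other`.
#'
#' @param events event data.frame (detected or ground-truth-derived).
#' @param profile `myelin_profile`.
#' @return `events` with a `compartment` column added (NA for rows excluded
#'   from analysis).
#' @export
assign_compartments <- function(events, profile) {
  events$compartment <- rep(NA_character_, nrow(events))
  use <- which(events$accepted & events$motion_class != "excluded_mobile" &
                 !is.na(events$compartment_raw))
  fl <- profile$field_length
  hemi <- profile$heminodes
  gaps <- gaps_of(profile)
  for (i in use) {
    if (events$compartment_raw[i] == "collateral") {
      events$compartment[i] <- "collateral"
      next
    }
    a <- events$arc_position[i]
    if (is.na(a) || a < 0 || a > fl) {
      stop("event arc position ", a, " outside the imaged field [0, ", fl, "]")
    }
    lab <- "positive_other"
    if (nrow(gaps) && any(.in_interval(a, gaps$start, gaps$end))) {
      lab <- "gap_region"
    } else if (nrow(hemi) && any(.in_interval(a, hemi$start, hemi$end))) {
      lab <- "heminodal"
    }
    events$compartment[i] <- lab
  }
  events
}

#' Per-compartment event frequency report
#'
#' Frequencies in events per um per hour (with a per-10-um-per-hour view),
#' normalized to compartment length and imaging duration.  Compartments with
#' zero length are reported as NA (undefined), not zero.
#'
#' @param events labelled events from [assign_compartments()].
#' @param profile `myelin_profile`.
#' @param geometry `axon_geometry` (collateral lengths); NULL if no
#'   collaterals were imaged.
#' @param duration_h imaging duration in hours (> 0).
#' @return list of class `event_frequency_report` with counts, lengths (um),
#'   `freq` (events/um/h) and `freq_per10um` per compartment, and the
#'   imaging duration.
#' @export
frequency_report <- function(events, profile, geometry = NULL, duration_h) {
  if (!is.numeric(duration_h) || duration_h <= 0) stop("duration_h must be > 0")
  ev <- .analyzable(events)
  ax <- ev[ev$compartment_raw == "axon", , drop = FALSE]
  lengths <- c(
    axonal = profile$field_length,
    collateral = if (is.null(geometry)) 0 else total_collateral_length(geometry),
    positive_region = positive_length(profile),
    gap_region = profile$field_length - positive_length(profile),
    heminodal = if (nrow(profile$heminodes))
      sum(profile$heminodes$end - profile$heminodes$start) else 0)
  counts <- c(
    axonal = nrow(ax),
    collateral = sum(ev$compartment == "collateral"),
    positive_region = sum(ax$compartment %in% c("heminodal", "positive_other")),
    gap_region = sum(ax$compartment == "gap_region"),
    heminodal = sum(ax$compartment == "heminodal"))
  freq <- ifelse(lengths > 0, counts / lengths / duration_h, NA_real_)
  structure(list(counts = counts, lengths = lengths, freq = freq,
                 freq_per10um = freq * 10, duration_h = duration_h),
            class = "event_frequency_report")
}

#' Heminodal enrichment: observed versus predicted-uniform frequency
#'
#' The predicted heminodal frequency scales the overall event frequency in
#' the reporter-positive part of the axon to one 3-um window
#' (events/3um/h), which is what a uniform distribution over positive axon
#' would give; the observed frequency is the heminodal event count divided
#' by the number of heminodes and the imaging duration.
#'
#' @param events labelled events from [assign_compartments()].
#' @param profile `myelin_profile` with at least one heminode.
#' @param duration_h imaging duration (h).
#' @return list of class `hotspot_stats`: `observed`, `predicted`
#'   (events/3um/h), `ratio` (NA when predicted is 0), `n_heminodes`,
#'   `positive_count`, `heminodal_count`.
#' @export
heminodal_enrichment <- function(events, profile, duration_h) {
  stopifnot(duration_h > 0)
  n_h <- nrow(profile$heminodes)
  if (n_h < 1) {
    return(structure(list(observed = NA_real_, predicted = NA_real_,
                          ratio = NA_real_, n_heminodes = 0L,
                          positive_count = NA_integer_,
                          heminodal_count = NA_integer_,
                          reason = "no_heminodes"),
                     class = "hotspot_stats"))
  }
  pos_len <- positive_length(profile)
  if (pos_len <= 0) stop("no positive axon length")
  w <- profile$config$heminode_window
  ev <- .analyzable(events)
  ax <- ev[ev$compartment_raw == "axon", , drop = FALSE]
  pos_count <- sum(ax$compartment %in% c("heminodal", "positive_other"))
  hemi_count <- sum(ax$compartment == "heminodal")
  predicted <- pos_count / pos_len / duration_h * w
  observed <- hemi_count / n_h / duration_h
  structure(list(observed = observed, predicted = predicted,
                 ratio = if (predicted > 0) observed / predicted else NA_real_,
                 n_heminodes = n_h, positive_count = pos_count,
                 heminodal_count = hemi_count),
            class = "hotspot_stats")
}

#' Paired test of observed versus predicted heminodal frequency
#'
#' Wilcoxon matched-pairs signed-rank test across axons.
#'
#' @param observed,predicted per-axon frequencies (events/3um/h), or a list
#'   of `hotspot_stats` as the first argument.
#' @param min_pairs minimum number of defined pairs (default 6).
#' @return list: `p_value`, `direction` (`"observed_higher"`,
#'   `"observed_lower"` or `"none"`), `n_pairs`, `median_difference`.
#' @export
paired_enrichment_test <- function(observed, predicted = NULL, min_pairs = 6L) {
  if (is.list(observed) && is.null(predicted)) {
    predicted <- vapply(observed, function(s) s$predicted, numeric(1))
    observed <- vapply(observed, function(s) s$observed, numeric(1))
  }
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < min_pairs) {
    stop("need at least ", min_pairs, " defined observed/predicted pairs")
  }
  diffs <- observed - predicted
  if (all(diffs == 0)) {
    return(list(p_value = 1, direction = "none", n_pairs = length(diffs),
                median_difference = 0))
  }
  wt <- suppressWarnings(stats::wilcox.test(observed, predicted, paired = TRUE,
                                            exact = FALSE))
  md <- stats::median(diffs)
  list(p_value = wt$p.value,
       direction = if (md > 0) "observed_higher"
                   else if (md < 0) "observed_lower" else "none",
       n_pairs = length(diffs), median_difference = md)
}

#' Overlap counts between events and reference puncta
#'
#' Counts events lying within `tolerance` of any punctum and vice versa
#' (both directions reported), in shared arc coordinates.
#'
#' @param event_arcs event arc positions (um).
#' @param puncta_arcs punctum arc positions (um).
#' @param tolerance matching distance (um).
#' @return list: `events_near_puncta`, `puncta_near_events`, `n_events`,
#'   `n_puncta`, `fraction_events_overlapping`.
#' @export
colocalization_overlap <- function(event_arcs, puncta_arcs, tolerance = 1) {
  near <- function(x, ref) {
    if (!length(x)) return(0L)
    if (!length(ref)) return(0L)
    sum(vapply(x, function(a) any(abs(ref - a) <= tolerance), logical(1)))
  }
  n_ev <- length(event_arcs)
  list(events_near_puncta = near(event_arcs, puncta_arcs),
       puncta_near_events = near(puncta_arcs, event_arcs),
       n_events = n_ev, n_puncta = length(puncta_arcs),
       fraction_events_overlapping =
         if (n_ev) near(event_arcs, puncta_arcs) / n_ev else NA_real_)
}
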