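# Scoring detected events against the synthetic ground truth.

#' Ground-truth events as an analysis-ready event table
#'
#' Maps the generator's true-event list onto the detected-event schema
#' (accepted, static, with true amplitudes/durations), so that compartment
#' assignment, frequency and enrichment statistics can be computed directly
#' on ground truth without rendering and re-detecting.  Mobile events are
#' marked `excluded_mobile`, mirroring how the detector would treat them.
#'
#' @param true_events data.frame from [simulate_events()].
#' @return event data.frame in the canonical schema.
#' @export
as_detected_events <- function(true_events) {
  n <- nrow(true_events)
  if (!n) return(empty_event_table())
  as_event_table(data.frame(
    id = seq_len(n),
    compartment_raw = true_events$compartment,
    arc_position = true_events$arc_position,
    branch_id = true_events$branch_id,
    branch_arc = true_events$branch_arc,
    start_frame = true_events$start_frame,
    peak_frame = true_events$start_frame,
    amplitude = true_events$amplitude,
    duration_s = true_events$duration_s,
    duration_censored = FALSE,
    cumulative_displacement = 0,
    net_displacement = 0,
    motion_class = ifelse(true_events$mobile, "excluded_mobile", "static"),
    direction_class = "none",
    accepted = TRUE,
    stringsAsFactors = FALSE))
}

#' Score detection against ground truth
#'
#' Greedy one-to-one matching of accepted, non-excluded detected events to
#' non-mobile true events within a spatial and temporal tolerance
#' (closest pairs first).
#'
#' @param events detected event table.
#' @param truth true-event data.frame from a `ground_truth_scene` (with
#'   `row0`, `col0`, `start_frame`, `mobile` columns).
#' @param pixel_size um per pixel.
#' @param tol_um spatial matching tolerance (um).
#' @param tol_frames start-frame matching tolerance (frames).
#' @return list: `recall`, `precision`, `tp`, `fp`, `fn`, `n_true`,
#'   `n_detected`, and `matches` (data.frame of matched index pairs).
#' @export
score_detection <- function(events, truth, pixel_size, tol_um = 1,
                            tol_frames = 2L) {
  det <- events[events$accepted & events$motion_class != "excluded_mobile", ,
                drop = FALSE]
  tru <- truth[!truth$mobile, , drop = FALSE]
  n_d <- nrow(det); n_t <- nrow(tru)
  matches <- data.frame(det = integer(0), tru = integer(0))
  if (n_d && n_t) {
    pairs <- expand.grid(i = seq_len(n_d), j = seq_len(n_t))
    dist_um <- sqrt((det$row[pairs$i] - tru$row0[pairs$j])^2 +
                      (det$col[pairs$i] - tru$col0[pairs$j])^2) * pixel_size
    dt <- abs(det$start_frame[pairs$i] - tru$start_frame[pairs$j])
    ok <- dist_um <= tol_um & dt <= tol_frames
    pairs <- pairs[ok, , drop = FALSE]
    pairs <- pairs[order(dist_um[ok]), , drop = FALSE]
    used_d <- logical(n_d); used_t <- logical(n_t)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (used_d[i] || used_t[j]) next
      used_d[i] <- TRUE; used_t[j] <- TRUE
      matches <- rbind(matches, data.frame(det = i, tru = j))
    }
  }
  tp <- nrow(matches)
  list(recall = if (n_t) tp / n_t else NA_real_,
       precision = if (n_d) tp / n_d else NA_real_,
       tp = tp, fp = n_d - tp, fn = n_t - tp,
       n_true = n_t, n_detected = n_d, matches = matches)
}
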