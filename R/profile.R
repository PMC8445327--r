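# Myelin profile: partition of the axon's arc length into reporter-positive
# regions and reporter-negative gaps (sheaths), plus the derived heminodes,
# nodes, percent myelination and axon class.
#
# Conventions: arc intervals are half-open [start, end) microns; a gap is
# "incomplete" when it touches an edge of the imaged field; sheath-centric
# analyses use complete gaps only.

#' Profile segmentation configuration
#'
#' @param gap_threshold_fraction fraction of the robust positive-region
#'   intensity below which a position is called reporter-negative.
#' @param min_gap_length gaps shorter than this are re-labelled positive (um).
#' @param heminode_window heminode length: the first microns of positive axon
#'   bordering a gap (um).
#' @param node_max_length a positive segment shorter than this and flanked by
#'   two gaps is a node, not a pair of heminodes (um).
#' @param not_yet_myelinated_max percent-myelination bound for the
#'   yet-to-be-myelinated class.
#' @param min_heminodes_for_myelinating heminode count that forces the
#'   myelinating class (strictly more than `min_heminodes_for_myelinating - 1`).
#' @return list of class `profile_config`.
#' @export
profile_config <- function(gap_threshold_fraction = 0.5, min_gap_length = 1,
                           heminode_window = 3, node_max_length = 1,
                           not_yet_myelinated_max = 5,
                           min_heminodes_for_myelinating = 3) {
  stopifnot(gap_threshold_fraction > 0, gap_threshold_fraction < 1,
            min_gap_length > 0, heminode_window > 0, node_max_length > 0)
  structure(list(gap_threshold_fraction = gap_threshold_fraction,
                 min_gap_length = min_gap_length,
                 heminode_window = heminode_window,
                 node_max_length = node_max_length,
                 not_yet_myelinated_max = not_yet_myelinated_max,
                 min_heminodes_for_myelinating = min_heminodes_for_myelinating),
            class = "profile_config")
}

#' Build a profile from known gap intervals
#'
#' Constructs the full profile object (segments, heminodes, nodes, percent
#' myelination, axon class) from explicit gap intervals.  Used by the
#' segmenter and by the synthetic generator, where gaps are known exactly.
#'
#' @param field_length sampled axon length (um).
#' @param gap_starts,gap_ends gap interval bounds (um), non-overlapping.
#' @param config [profile_config()].
#' @return `myelin_profile`.
#' @export
profile_from_gaps <- function(field_length, gap_starts, gap_ends,
                              config = profile_config()) {
  stopifnot(field_length > 0, length(gap_starts) == length(gap_ends))
  o <- order(gap_starts)
  gap_starts <- gap_starts[o]; gap_ends <- gap_ends[o]
  if (any(gap_ends <= gap_starts)) stop("gap end must exceed gap start")
  if (any(gap_starts < 0) || any(gap_ends > field_length + 1e-9))
    stop("gaps must lie within [0, field_length]")
  if (length(gap_starts) > 1 && any(gap_starts[-1] < gap_ends[-length(gap_ends)]))
    stop("gaps must not overlap")
  # tile [0, field_length) alternating positive / gap
  starts <- c(); ends <- c(); labels <- c()
  cursor <- 0
  for (i in seq_along(gap_starts)) {
    if (gap_starts[i] > cursor + 1e-12) {
      starts <- c(starts, cursor); ends <- c(ends, gap_starts[i])
      labels <- c(labels, "positive")
    }
    starts <- c(starts, gap_starts[i]); ends <- c(ends, gap_ends[i])
    labels <- c(labels, "gap")
    cursor <- gap_ends[i]
  }
  if (cursor < field_length - 1e-12) {
    starts <- c(starts, cursor); ends <- c(ends, field_length)
    labels <- c(labels, "positive")
  }
  if (!length(starts)) { starts <- 0; ends <- field_length; labels <- "positive" }
  segments <- data.frame(start = starts, end = ends, label = labels,
                         stringsAsFactors = FALSE)
  segments$complete <- TRUE
  edge <- segments$label == "gap" &
    (segments$start <= 1e-9 | segments$end >= field_length - 1e-9)
  segments$complete[edge] <- FALSE
  profile <- structure(list(segments = segments, field_length = field_length,
                            config = config),
                       class = "myelin_profile")
  hn <- derive_heminodes_nodes(profile, config)
  profile$heminodes <- hn$heminodes
  profile$nodes <- hn$nodes
  profile$percent_myelination <- percent_myelination(profile)
  profile$axon_class <- classify_axon(profile, config)
  profile
}

#' Segment a reporter intensity profile into positive regions and gaps
#'
#' Positions whose intensity falls below `gap_threshold_fraction` times the
#' robust positive-region intensity are labelled gaps.  The reference
#' intensity is computed iteratively: the median over all positions seeds the
#' threshold, then the median over positions currently called positive
#' (two iterations).  Gap runs shorter than `min_gap_length` are re-labelled
#' positive; gaps touching the field edge are flagged incomplete.
#'
#' @param intensity numeric vector: reporter intensity per arc sample
#'   (one sample per pixel along the axon path, transverse-averaged).
#' @param pixel_size arc length per sample (um).
#' @param config [profile_config()].
#' @return object of class `myelin_profile` with `segments`, `heminodes`,
#'   `nodes`, `percent_myelination` and `axon_class`.
#' @export
segment_profile <- function(intensity, pixel_size, config = profile_config()) {
  stopifnot(is.numeric(intensity), length(intensity) >= 2, pixel_size > 0)
  if (max(intensity) <= 0) stop("no reporter-positive signal in profile")
  ref <- stats::median(intensity)
  for (i in 1:2) {
    thr <- config$gap_threshold_fraction * ref
    pos <- intensity >= thr
    if (!any(pos)) stop("no reporter-positive signal in profile")
    ref <- stats::median(intensity[pos])
  }
  thr <- config$gap_threshold_fraction * ref
  is_gap <- intensity < thr
  # drop sub-resolution gaps
  r <- rle(is_gap)
  min_px <- config$min_gap_length / pixel_size
  r$values[r$values & r$lengths < min_px] <- FALSE
  is_gap <- inverse.rle(r)
  r <- rle(is_gap)
  ends_px <- cumsum(r$lengths)
  starts_px <- ends_px - r$lengths
  gs <- starts_px[r$values] * pixel_size
  ge <- ends_px[r$values] * pixel_size
  field_length <- length(intensity) * pixel_size
  profile_from_gaps(field_length, gs, ge, config)
}

#' Transverse-mean reporter intensity along the axon path
#'
#' @param image matrix (single frame) or `timelapse_movie` whose first frame
#'   is used (the static red channel is acquired once).
#' @param geometry `axon_geometry`.
#' @param half_width_px transverse half-width of the averaging band (pixels).
#' @return numeric vector, one value per axon arc sample.
#' @export
profile_intensity <- function(image, geometry, half_width_px = 1L) {
  if (inherits(image, "timelapse_movie")) image <- image$frames[, , 1]
  s <- geometry$axon_samples
  nr <- nrow(image)
  vapply(seq_len(nrow(s)), function(i) {
    rows <- pmin(pmax((s$row[i] - half_width_px):(s$row[i] + half_width_px), 0L),
                 nr - 1L)
    mean(image[rows + 1L, s$col[i] + 1L])
  }, numeric(1))
}

#' Percent myelination of a profile
#'
#' 100 x summed gap length (incomplete gaps included) over the field length.
#'
#' @param profile `myelin_profile`.
#' @return percentage in `[0, 100]`.
#' @export
percent_myelination <- function(profile) {
  g <- profile$segments[profile$segments$label == "gap", , drop = FALSE]
  100 * sum(g$end - g$start) / profile$field_length
}

#' Classify an axon as yet-to-be-myelinated or myelinating
#'
#' Yet-to-be-myelinated: percent myelination < 5 and at most 2 putative
#' heminodes.  Myelinating: percent > 5 or more than 2 heminodes.  An axon at
#' exactly 5% with at most 2 heminodes is assigned to the yet-to-be class
#' (the myelinating definition is strict ">"), and flagged as a boundary case
#' via the `"boundary"` attribute.
#'
#' @param profile `myelin_profile` with heminodes derived.
#' @param config [profile_config()].
#' @return `"not_yet_myelinated"` or `"myelinating"`.
#' @export
classify_axon <- function(profile, config = profile_config()) {
  pct <- percent_myelination(profile)
  n_hemi <- if (is.null(profile$heminodes)) {
    nrow(derive_heminodes_nodes(profile, config)$heminodes)
  } else nrow(profile$heminodes)
  myelinating <- pct > config$not_yet_myelinated_max ||
    n_hemi > (config$min_heminodes_for_myelinating - 1L)
  out <- if (myelinating) "myelinating" else "not_yet_myelinated"
  if (!myelinating && pct == config$not_yet_myelinated_max)
    attr(out, "boundary") <- TRUE
  out
}

#' Derive heminodes and nodes from a segmented profile
#'
#' For each gap border inside the field, the adjacent positive interval up to
#' `heminode_window` (3 um) is a heminode, truncated by the next feature.  A
#' positive segment shorter than `node_max_length` (1 um) between two gaps is
#' a node and yields no heminodes.  A positive segment of length L between
#' two gaps with `node_max_length <= L < 2 * heminode_window` is split evenly
#' into two heminodes of L/2.
#'
#' @param profile `myelin_profile` (segments only is enough).
#' @param config [profile_config()].
#' @return list with data.frames `heminodes` (start, end, gap_side) and
#'   `nodes` (start, end).
#' @export
derive_heminodes_nodes <- function(profile, config = profile_config()) {
  seg <- profile$segments
  w <- config$heminode_window
  hemi <- list(); nodes <- list()
  for (i in seq_len(nrow(seg))) {
    if (seg$label[i] != "positive") next
    L <- seg$end[i] - seg$start[i]
    left_gap <- i > 1 && seg$label[i - 1] == "gap"
    right_gap <- i < nrow(seg) && seg$label[i + 1] == "gap"
    if (left_gap && right_gap) {
      if (L < config$node_max_length) {
        nodes[[length(nodes) + 1L]] <- data.frame(start = seg$start[i], end = seg$end[i])
      } else if (L < 2 * w) {
        hemi[[length(hemi) + 1L]] <- data.frame(
          start = c(seg$start[i], seg$start[i] + L / 2),
          end = c(seg$start[i] + L / 2, seg$end[i]),
          gap_side = c("left", "right"))
      } else {
        hemi[[length(hemi) + 1L]] <- data.frame(
          start = c(seg$start[i], seg$end[i] - w),
          end = c(seg$start[i] + w, seg$end[i]),
          gap_side = c("left", "right"))
      }
    } else if (left_gap || right_gap) {
      len <- min(w, L)
      if (left_gap) {
        hemi[[length(hemi) + 1L]] <- data.frame(
          start = seg$start[i], end = seg$start[i] + len, gap_side = "left")
      } else {
        hemi[[length(hemi) + 1L]] <- data.frame(
          start = seg$end[i] - len, end = seg$end[i], gap_side = "right")
      }
    }
  }
  empty <- data.frame(start = numeric(0), end = numeric(0))
  list(
    heminodes = if (length(hemi)) do.call(rbind, hemi) else
      cbind(empty, data.frame(gap_side = character(0))),
    nodes = if (length(nodes)) do.call(rbind, nodes) else empty
  )
}

#' Gap (sheath) intervals of a profile
#' @param profile `myelin_profile`.
#' @param complete_only drop gaps touching the field edge.
#' @return data.frame with start, end, label, complete.
#' @export
gaps_of <- function(profile, complete_only = FALSE) {
  g <- profile$segments[profile$segments$label == "gap", , drop = FALSE]
  if (complete_only) g <- g[g$complete, , drop = FALSE]
  g
}

#' Total reporter-positive length of a profile (um)
#' @param profile `myelin_profile`.
#' @return numeric length.
#' @export
positive_length <- function(profile) {
  p <- profile$segments[profile$segments$label == "positive", , drop = FALSE]
  sum(p$end - p$start)
}

#' Write / read a profile segment table as CSV
#'
#' @param profile `myelin_profile`.
#' @param path CSV path.
#' @return `path` (write) or `myelin_profile` (read).
#' @export
write_profile <- function(profile, path) {
  seg <- profile$segments
  seg$start <- sprintf("%.17g", seg$start)
  seg$end <- sprintf("%.17g", seg$end)
  seg$field_length <- sprintf("%.17g", profile$field_length)
  utils::write.csv(seg, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  g <- df[df$label == "gap", , drop = FALSE]
  profile_from_gaps(as.numeric(df$field_length[1]),
                    as.numeric(g$start), as.numeric(g$end))
}

#' @export
print.myelin_profile <- function(x, ...) {
  cat(sprintf("<myelin_profile> %.1f um field, %.1f%% myelinated (%s), %d gap(s), %d heminode(s), %d node(s)\n",
              x$field_length, x$percent_myelination, x$axon_class,
              sum(x$segments$label == "gap"), nrow(x$heminodes), nrow(x$nodes)))
  invisible(x)
}
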