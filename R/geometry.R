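# Axon geometry: linearizes the axon so that events and myelin gaps get
# arc-length coordinates.  Pixel indices are 0-based; arc positions are
# continuous microns measured from the anterior end of the sampled field
# (convention: anterior = low arc position).  Intervals are half-open
# [start, end).

#' Construct an axon geometry
#'
#' @param axon_path integer matrix `[n, 2]` of (row, col) pixel coordinates
#'   (0-based) ordered from the anterior end; consecutive points must be
#'   adjacent or near-adjacent pixels.
#' @param pixel_size microns per pixel.
#' @param collaterals list of branch polylines, each an integer matrix
#'   `[m, 2]` of (row, col) starting at the branch point on the axon.
#' @param field_length total sampled axon length (um); defaults to the path
#'   arc length plus one pixel (the last sample covers a full pixel).
#' @return object of class `axon_geometry` with per-pixel arc samples for the
#'   axon and each collateral, and `field_length` (um).
#' @export
axon_geometry <- function(axon_path, pixel_size, collaterals = list(),
                          field_length = NULL) {
  stopifnot(is.matrix(axon_path), ncol(axon_path) == 2, nrow(axon_path) >= 2,
            pixel_size > 0)
  arc <- c(0, cumsum(sqrt(rowSums(diff(axon_path)^2))) * pixel_size)
  if (any(diff(arc) <= 0)) stop("axon path arc positions must be strictly increasing")
  axon_samples <- data.frame(row = axon_path[, 1], col = axon_path[, 2], arc = arc)
  coll <- lapply(seq_along(collaterals), function(i) {
    p <- collaterals[[i]]
    stopifnot(is.matrix(p), ncol(p) == 2, nrow(p) >= 2)
    # branch point = nearest axon sample to the first branch pixel
    d2 <- (axon_samples$row - p[1, 1])^2 + (axon_samples$col - p[1, 2])^2
    j <- which.min(d2)
    barc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))) * pixel_size)
    data.frame(row = p[, 1], col = p[, 2], arc = barc,
               branch_id = i, branch_point_arc = axon_samples$arc[j])
  })
  if (is.null(field_length)) field_length <- max(arc) + pixel_size
  structure(
    list(axon_samples = axon_samples, collaterals = coll,
         pixel_size = pixel_size, field_length = field_length),
    class = "axon_geometry"
  )
}

#' Build the straight-axon geometry used by the synthetic scenes
#'
#' Horizontal axon at a fixed row with vertical collateral branches growing
#' downward from given arc positions.
#'
#' @param field_length axon length sampled (um).
#' @param pixel_size um per pixel.
#' @param axon_row axon row index (0-based).
#' @param start_col first axon column (0-based).
#' @param collateral_arcs arc positions (um) of collateral branch points.
#' @param collateral_length length of each collateral (um).
#' @return `axon_geometry`.
#' @export
straight_axon_geometry <- function(field_length, pixel_size, axon_row = 12L,
                                   start_col = 0L, collateral_arcs = numeric(),
                                   collateral_length = 10) {
  n_col <- round(field_length / pixel_size)
  path <- cbind(rep(axon_row, n_col), start_col + 0:(n_col - 1L))
  colls <- lapply(collateral_arcs, function(a) {
    c0 <- start_col + round(a / pixel_size)
    len_px <- round(collateral_length / pixel_size)
    cbind(axon_row + 0:len_px, rep(c0, len_px + 1L))
  })
  axon_geometry(path, pixel_size, colls, field_length = field_length)
}

#' Locate a pixel on the geometry
#'
#' Maps an image pixel to the nearest structure sample.  Axonal hits win ties
#' against collaterals.
#'
#' @param geometry `axon_geometry`.
#' @param row,col 0-based pixel coordinates.
#' @param max_dist_um maximum allowed distance to a structure (default 2 um).
#' @return list with `compartment_raw` ("axon"/"collateral"), `arc_position`
#'   (axon arc, um; branch-point arc for collateral events), `branch_id`,
#'   `branch_arc` (arc along the branch, um) and `dist_um`.
#' @export
locate_on_geometry <- function(geometry, row, col, max_dist_um = 2) {
  ps <- geometry$pixel_size
  s <- geometry$axon_samples
  d2 <- (s$row - row)^2 + (s$col - col)^2
  j <- which.min(d2)
  best <- list(compartment_raw = "axon", arc_position = s$arc[j],
               branch_id = NA_integer_, branch_arc = NA_real_,
               dist_um = sqrt(d2[j]) * ps)
  for (cc in geometry$collaterals) {
    d2c <- (cc$row - row)^2 + (cc$col - col)^2
    k <- which.min(d2c)
    dist <- sqrt(d2c[k]) * ps
    if (dist < best$dist_um - 1e-12) {
      best <- list(compartment_raw = "collateral",
                   arc_position = cc$branch_point_arc[k],
                   branch_id = cc$branch_id[k], branch_arc = cc$arc[k],
                   dist_um = dist)
    }
  }
  if (best$dist_um > max_dist_um) {
    best$compartment_raw <- NA_character_
  }
  best
}

total_collateral_length <- function(geometry) {
  if (!length(geometry$collaterals)) return(0)
  sum(vapply(geometry$collaterals, function(cc) max(cc$arc), numeric(1)))
}

#' Write / read geometry as JSON
#'
#' @param geometry `axon_geometry`.
#' @param path JSON path.
#' @return `path` (write) or `axon_geometry` (read).
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(
    list(pixel_size = geometry$pixel_size,
         axon_path = unname(as.matrix(geometry$axon_samples[, c("row", "col")])),
         collaterals = lapply(geometry$collaterals, function(cc)
           unname(as.matrix(cc[, c("row", "col")])))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  colls <- g$collaterals
  if (is.null(colls)) {
    colls <- list()
  } else if (is.array(colls) && length(dim(colls)) == 3) {
    # jsonlite collapses equal-shaped branch polylines into one 3D array
    colls <- lapply(seq_len(dim(colls)[1]), function(i) colls[i, , ])
  } else if (is.matrix(colls)) {
    colls <- list(colls)
  }
  axon_geometry(as.matrix(g$axon_path), g$pixel_size, lapply(colls, as.matrix))
}
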