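# Event tables.  One row per detected (or rejected, if kept) event, with a
# stable column order and a lossless CSV round-trip (numerics written with 17
# significant digits).

EVENT_COLUMNS <- c(
  id = "integer", compartment_raw = "character", arc_position = "numeric",
  branch_id = "integer", branch_arc = "numeric",
  row = "integer", col = "integer",
  start_frame = "integer", peak_frame = "integer",
  amplitude = "numeric", duration_s = "numeric", duration_censored = "logical",
  cumulative_displacement = "numeric", net_displacement = "numeric",
  motion_class = "character", direction_class = "character",
  f0 = "numeric", sd0 = "numeric",
  baseline_frames_used = "integer", baseline_flag = "logical",
  accepted = "logical", reject_reason = "character"
)

#' Empty event table with the canonical schema
#' @return zero-row data.frame with all event columns.
#' @export
empty_event_table <- function() {
  cols <- lapply(EVENT_COLUMNS, function(cl) vector(cl, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

as_event_table <- function(df) {
  out <- empty_event_table()
  if (!nrow(df)) return(out)
  for (nm in names(EVENT_COLUMNS)) {
    if (is.null(df[[nm]])) {
      df[[nm]] <- vector(EVENT_COLUMNS[[nm]], 1L)[NA]
    }
    df[[nm]] <- switch(EVENT_COLUMNS[[nm]],
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = as.logical(df[[nm]]),
                       character = as.character(df[[nm]]))
  }
  df[, names(EVENT_COLUMNS), drop = FALSE]
}

#' Write an event table to CSV
#'
#' Stable column order; numeric fields serialized with 17 significant digits
#' so that write-then-read is lossless to double precision.
#'
#' @param events event data.frame (as returned by [detect_events()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  events <- as_event_table(events)
  fmt <- events
  for (nm in names(EVENT_COLUMNS)) {
    if (EVENT_COLUMNS[[nm]] == "numeric") {
      fmt[[nm]] <- ifelse(is.na(events[[nm]]), NA, sprintf("%.17g", events[[nm]]))
    }
  }
  utils::write.csv(fmt, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#' @param path CSV path.
#' @return event data.frame with canonical column types.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_event_table(df)   # coerces each column to its canonical type
}
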