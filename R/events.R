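#' Read a beam-break event stream from delimited text
#'
#' Expects a CSV with header \code{column_id, timestamp, detector_index};
#' timestamps ISO-8601, interpreted as UTC on the experiment clock.  Events
#' are validated against the detector geometry and returned time-sorted per
#' column, ties broken by ascending detector index.
#'
#' @param path path to the event CSV
#' @param geometry a \linkS4class{SensorGeometry} used for validation
#' @return data.frame with columns \code{column_id}, \code{timestamp}
#'   (POSIXct, UTC), \code{detector_index}
#' @examples
#' f <- system.file("extdata", "example_events.csv", package = "krillclock")
#' head(readEvents(f))
#' @export
readEvents <- function(path, geometry = sensorGeometry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "integer"))
  need <- c("column_id", "timestamp", "detector_index")
  if (!identical(colnames(df), need))
    stop("event file header must be exactly: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) {
    df$timestamp <- as.POSIXct(character(0), tz = "UTC")
    return(df)
  }
  ts <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  alt <- is.na(ts)
  if (any(alt))
    ts[alt] <- as.POSIXct(strptime(df$timestamp[alt], "%Y-%m-%d %H:%M:%OS",
                                   tz = "UTC"))
  bad_ts <- which(is.na(ts))
  bad_det <- which(is.na(df$detector_index) | df$detector_index < 1L |
                   df$detector_index > geometry@nDetectors)
  if (length(bad_ts) || length(bad_det)) {
    msg <- c(
      if (length(bad_ts))
        sprintf("unparseable timestamp at data row(s): %s",
                paste(utils::head(bad_ts, 10), collapse = ", ")),
      if (length(bad_det))
        sprintf("detector_index outside 1..%d at data row(s): %s",
                geometry@nDetectors,
                paste(utils::head(bad_det, 10), collapse = ", ")))
    stop(paste(msg, collapse = "; "))
  }
  df$timestamp <- ts
  sortEvents(df)
}

#' @describeIn readEvents write an event stream to CSV (ISO-8601, UTC)
#' @param events event data.frame
#' @export
writeEvents <- function(events, path) {
  out <- events
  out$timestamp <- format(events$timestamp, "%Y-%m-%dT%H:%M:%OS3",
                          tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic event order: column, time, then detector index
sortEvents <- function(events) {
  ord <- order(events$column_id, events$timestamp, events$detector_index)
  out <- events[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract upward swimming movements from a beam-break stream
#'
#' Krill are negatively buoyant, so only upward movements are counted as
#' active swimming.  Within each column's chronologically ordered stream, a
#' detection at detector \eqn{d \ge 2} is kept exactly when the immediately
#' preceding detection (same column) occurred at the adjacent lower detector
#' \eqn{d - 1}; this counts contiguous upward traversals over the full
#' column height.
#'
#' @param events event data.frame, time-sorted within each column (ties by
#'   detector index); a violation raises an error
#' @param geometry a \linkS4class{SensorGeometry}
#' @return the retained upward events, original timestamps preserved
#' @export
extractUpward <- function(events, geometry = sensorGeometry()) {
  if (nrow(events) == 0) return(events)
  if (any(events$detector_index < 1L |
          events$detector_index > geometry@nDetectors))
    stop("detector_index outside geometry bounds")
  o <- order(events$column_id, events$timestamp, events$detector_index)
  if (!identical(o, seq_len(nrow(events))))
    stop("events must be sorted by column, time, detector (see sortEvents)")
  same_col <- c(FALSE,
                events$column_id[-1] == events$column_id[-nrow(events)])
  step <- c(NA_integer_,
            diff(events$detector_index))
  keep <- same_col & !is.na(step) & step == 1L
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin upward events into a raw activity series
#'
#' Sums events per half-open bin \code{[t, t + binWidth)} on a grid aligned
#' to the experiment-clock midnight \code{origin}, one series per column.
#' Bins with no events are 0; the column sums equal the per-column event
#' totals.
#'
#' @param upward upward-event data.frame (see \code{\link{extractUpward}})
#' @param binWidth bin width in minutes (must divide 60)
#' @param span POSIXct length-2, start and end of the grid; must cover all
#'   events; defaults to whole days around the event range
#' @param origin POSIXct midnight anchoring the grid and the experiment
#'   clock; defaults to \code{span[1]}
#' @param ddOnset hours since origin at which constant darkness begins
#'   (\code{NULL}: all LD), used for phase labels
#' @param columns column identifiers to include (default: those present);
#'   listed columns with no events yield all-zero series
#' @return an \linkS4class{ActivityExperiment} with assay \code{"counts"}
#' @export
binCounts <- function(upward, binWidth = 10, span = NULL, origin = NULL,
                      ddOnset = NULL, columns = NULL) {
  stopifnot(60 %% binWidth == 0)
  if (is.null(span)) {
    if (nrow(upward) == 0)
      stop("'span' is required for an empty event stream")
    day_s <- 86400
    t0 <- min(upward$timestamp); t1 <- max(upward$timestamp)
    start <- as.POSIXct(floor(as.numeric(t0) / day_s) * day_s,
                        origin = "1970-01-01", tz = "UTC")
    end <- as.POSIXct(ceiling(as.numeric(t1) / day_s + 1e-9) * day_s,
                      origin = "1970-01-01", tz = "UTC")
    span <- c(start, end)
  }
  if (is.null(origin)) origin <- span[1]
  rel_h <- as.numeric(difftime(upward$timestamp, origin, units = "hours"))
  span_h <- as.numeric(difftime(span, origin, units = "hours"))
  outside <- which(rel_h < span_h[1] | rel_h >= span_h[2])
  if (length(outside))
    stop(sprintf("%d event(s) outside span, e.g. data row(s): %s",
                 length(outside),
                 paste(utils::head(outside, 10), collapse = ", ")))
  bw <- binWidth / 60
  nbin <- round((span_h[2] - span_h[1]) / bw)
  if (abs(nbin * bw - (span_h[2] - span_h[1])) > 1e-9)
    stop("span must be a whole number of bins")
  if (is.null(columns)) columns <- sort(unique(upward$column_id))
  cmat <- matrix(0L, nrow = nbin, ncol = length(columns),
                 dimnames = list(NULL, columns))
  if (nrow(upward)) {
    bin_idx <- floor((rel_h - span_h[1]) / bw) + 1L
    tab <- table(factor(bin_idx, levels = seq_len(nbin)),
                 factor(upward$column_id, levels = columns))
    cmat[] <- as.integer(tab)
  }
  newActivityExperiment(cmat, binWidth = binWidth, origin = origin,
                        ddOnset = ddOnset, startHour = span_h[1])
}
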