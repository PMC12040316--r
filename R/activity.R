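#' Construct an ActivityExperiment from a bins-by-individuals count matrix
#'
#' @param counts integer matrix, one column per individual, one row per bin
#'   on a gap-free grid
#' @param binWidth bin width, minutes (must divide 60)
#' @param origin POSIXct (UTC) midnight of experiment day 0
#' @param ddOnset hours since origin at which constant darkness starts;
#'   \code{NULL} labels every bin LD
#' @param startHour grid start in hours since origin
#' @param assayName name of the initial assay
#' @return an \linkS4class{ActivityExperiment}
#' @export
newActivityExperiment <- function(counts, binWidth = 10,
                                  origin = as.POSIXct("2021-05-31 00:00:00",
                                                      tz = "UTC"),
                                  ddOnset = NULL, startHour = 0,
                                  assayName = "counts") {
  counts <- as.matrix(counts)
  time_h <- startHour + (seq_len(nrow(counts)) - 1) * binWidth / 60
  phase <- if (is.null(ddOnset)) rep("LD", nrow(counts)) else
    ifelse(time_h >= ddOnset, "DD", "LD")
  rd <- DataFrame(time_h = time_h, phase = phase,
                  day = as.integer(floor(time_h / 24)))
  se <- SummarizedExperiment(
    assays = stats::setNames(list(counts), assayName), rowData = rd,
    colData = DataFrame(individual_id = colnames(counts),
                        row.names = colnames(counts)),
    metadata = list(binWidth = binWidth, origin = origin,
                    ddOnset = ddOnset, state = assayName))
  ae <- new("ActivityExperiment", se)
  validObject(ae)
  ae
}

#' @describeIn newActivityExperiment name of the most recently added assay
#'   (the current processing state)
#' @param ae an \linkS4class{ActivityExperiment}
#' @export
activityState <- function(ae) metadata(ae)$state

#' @describeIn newActivityExperiment bin width in minutes
#' @export
binWidth <- function(ae) metadata(ae)$binWidth

#' @describeIn newActivityExperiment bin start times, hours since origin
#' @export
timeHours <- function(ae) rowData(ae)$time_h

#' @describeIn newActivityExperiment per-bin phase labels ("LD"/"DD")
#' @export
phaseLabels <- function(ae) rowData(ae)$phase

setMethod("show", "ActivityExperiment", function(object) {
  cat(sprintf(
    "ActivityExperiment: %d bins x %d individuals (%g-min bins, %s)\n",
    nrow(object), ncol(object), metadata(object)$binWidth,
    paste(assayNames(object), collapse = " -> ")))
  ph <- table(rowData(object)$phase)
  cat("  phases:", paste(sprintf("%s=%d", names(ph), ph), collapse = ", "),
      "\n")
  invisible(NULL)
})

addAssayState <- function(ae, values, name) {
  assay(ae, name) <- values
  metadata(ae)$state <- name
  ae
}

#' Normalize each individual's activity to [0, 1]
#'
#' Min-max normalization over the full recording of each individual:
#' \code{(v - min) / (max - min)}.  A constant (degenerate) series maps to
#' all zeros.
#'
#' @param ae an \linkS4class{ActivityExperiment}
#' @param assay assay to normalize (default: current state)
#' @return the experiment with an added \code{"normalized"} assay
#' @export
normalizeActivity <- function(ae, assay = activityState(ae)) {
  m <- assay(ae, assay)
  out <- apply(m, 2, function(v) {
    rng <- range(v)
    if (rng[2] == rng[1]) rep(0, length(v))
    else (v - rng[1]) / (rng[2] - rng[1])
  })
  dimnames(out) <- dimnames(m)
  addAssayState(ae, out, "normalized")
}

#' Centered moving average
#'
#' For window \code{w}, averages the \code{floor(w/2)} points before through
#' \code{ceiling(w/2) - 1} points after each point (the symmetric centered
#' window for odd \code{w}; for even \code{w} the extra point is taken on
#' the leading side).  At the series ends the window shrinks to the
#' available points, so no data are fabricated and the output has the input
#' length.
#'
#' @param x numeric vector
#' @param window window length in points, \code{>= 1}
#' @return smoothed numeric vector
#' @export
movingAverage <- function(x, window) {
  n <- length(x)
  if (window < 1) stop("'window' must be >= 1")
  if (window > n) stop("'window' larger than the series")
  before <- floor(window / 2)
  after <- ceiling(window / 2) - 1
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth activity by a centered moving average
#'
#' With phase-specific windows (the defaults used throughout: 6 points under
#' light-dark cycles, 24 points under constant darkness, both on 10-min
#' bins), each contiguous phase segment is smoothed independently so the
#' LD-DD transition does not bleed across.  Pass \code{window} to use one
#' window for the whole series instead.
#'
#' @param ae an \linkS4class{ActivityExperiment}
#' @param window single window (points) overriding the phase-specific ones
#' @param windowLD,windowDD windows (points) for LD and DD segments
#' @param assay assay to smooth (default: current state)
#' @return the experiment with an added \code{"smoothed"} assay
#' @export
smoothActivity <- function(ae, window = NULL, windowLD = 6, windowDD = 24,
                           assay = activityState(ae)) {
  m <- assay(ae, assay)
  out <- m
  if (!is.null(window)) {
    for (j in seq_len(ncol(m))) out[, j] <- movingAverage(m[, j], window)
  } else {
    ph <- rowData(ae)$phase
    seg <- cumsum(c(TRUE, ph[-1] != ph[-length(ph)]))
    for (s in unique(seg)) {
      idx <- which(seg == s)
      w <- if (ph[idx[1]] == "DD") windowDD else windowLD
      w <- min(w, length(idx))
      for (j in seq_len(ncol(m)))
        out[idx, j] <- movingAverage(m[idx, j], w)
    }
  }
  addAssayState(ae, out, "smoothed")
}

#' Remove each individual's daily mean activity
#'
#' Subtracts the mean activity of each experiment day (midnight to midnight
#' on the experiment clock) from every value of that day, removing
#' individual baseline drift while preserving within-day shape.
#'
#' @param ae an \linkS4class{ActivityExperiment}
#' @param assay assay to detrend (default: current state)
#' @return the experiment with an added \code{"detrended"} assay
#' @export
detrendActivity <- function(ae, assay = activityState(ae)) {
  m <- assay(ae, assay)
  day <- rowData(ae)$day
  out <- m
  for (j in seq_len(ncol(m)))
    out[, j] <- m[, j] - stats::ave(m[, j], day)
  addAssayState(ae, out, "detrended")
}
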