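# Independent reference implementations and small generators used across the
# suite.  These deliberately avoid the package's own code paths.

TEST_ORIGIN <- as.POSIXct("2021-05-31 00:00:00", tz = "UTC")

# naive upward-movement reference: for every event, scan backwards for the
# chronologically preceding event of the same column (ties resolved by
# detector index, as the interface contract states) and keep the event iff
# that predecessor sat one detector lower.  O(n^2) on purpose.
bruteForceUpward <- function(events) {
  ord <- order(events$column_id, events$timestamp, events$detector_index)
  ev <- events[ord, , drop = FALSE]
  rownames(ev) <- NULL
  n <- nrow(ev)
  keep <- logical(n)
  for (i in seq_len(n)) {
    prev <- 0L
    for (j in seq_len(i - 1L))
      if (ev$column_id[j] == ev$column_id[i]) prev <- j
    if (prev > 0L &&
        ev$detector_index[i] - ev$detector_index[prev] == 1L)
      keep[i] <- TRUE
  }
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# textbook least-squares route to the Scargle periodogram: at each trial
# frequency, regress the centered series on the cos/sin pair and convert the
# explained sum of squares to variance-normalized power.  Spans the same
# two-dimensional model space as the time-offset Lomb formula, so the powers
# must agree to numerical precision.
leastSquaresPower <- function(t, x, periods) {
  xc <- x - mean(x)
  vr <- sum(xc^2) / (length(x) - 1)
  vapply(periods, function(p) {
    w <- 2 * pi / p
    fit <- stats::lm.fit(cbind(cos(w * t), sin(w * t)), xc)
    (sum(xc^2) - sum(fit$residuals^2)) / (2 * vr)
  }, numeric(1))
}

randomEventStream <- function(n, nColumns = 3, nDetectors = 5,
                              spanSeconds = 3600) {
  data.frame(
    column_id = sample(sprintf("c%02d", seq_len(nColumns)), n,
                       replace = TRUE),
    timestamp = TEST_ORIGIN + stats::runif(n, 0, spanSeconds),
    detector_index = sample.int(nDetectors, n, replace = TRUE))
}

# single-assay experiment around a plain matrix, for direct classification
matrixExperiment <- function(m, ddOnset = 0, assayName = "detrended") {
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("s%04d", seq_len(ncol(m)))
  newActivityExperiment(m, binWidth = 10, origin = TEST_ORIGIN,
                        ddOnset = ddOnset, assayName = assayName)
}

# counts -> normalized -> phase-smoothed -> detrended, the classification
# input state used throughout
processedCohort <- function(sim) {
  detrendActivity(smoothActivity(normalizeActivity(sim$truth)))
}
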