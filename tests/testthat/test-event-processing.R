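test_that("event CSV round-trips and malformed rows are reported", {
  ev <- data.frame(
    column_id = c("c01", "c01", "c02"),
    timestamp = TEST_ORIGIN + c(10, 4, 7),
    detector_index = c(2L, 1L, 3L))
  f <- withr::local_tempfile(fileext = ".csv")
  writeEvents(ev, f)
  back <- readEvents(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$column_id, c("c01", "c01", "c02"))
  expect_equal(back$detector_index, c(1L, 2L, 3L))  # time-sorted per column
  expect_equal(as.numeric(back$timestamp), as.numeric(TEST_ORIGIN) + c(4, 10, 7))

  # empty stream: header only, no error
  writeLines("column_id,timestamp,detector_index", f)
  expect_equal(nrow(readEvents(f)), 0)

  # detector index outside the geometry, named by row
  writeLines(c("column_id,timestamp,detector_index",
               "c01,2021-05-31T00:00:01,2",
               "c01,2021-05-31T00:00:02,9"), f)
  expect_error(readEvents(f, sensorGeometry(nDetectors = 5)), "row\\(s\\): 2")

  writeLines(c("column_id,timestamp,detector_index",
               "c01,not-a-time,2"), f)
  expect_error(readEvents(f), "timestamp")
})

test_that("upward extraction keeps adjacent-lower-predecessor events only", {
  asc <- data.frame(column_id = "c01",
                    timestamp = TEST_ORIGIN + 1:5,
                    detector_index = 1:5)
  up <- extractUpward(asc)
  expect_equal(nrow(up), 4)
  expect_equal(up$detector_index, 2:5)
  expect_equal(up$timestamp, asc$timestamp[2:5])  # original times kept

  desc <- data.frame(column_id = "c01",
                     timestamp = TEST_ORIGIN + 1:5,
                     detector_index = 5:1)
  expect_equal(nrow(extractUpward(desc)), 0)

  unsorted <- asc[c(3, 1, 2, 4, 5), ]
  expect_error(extractUpward(unsorted), "sorted")
})

test_that("upward extraction equals the brute-force reference", {
  set.seed(202)
  for (k in 1:1000) {
    ev <- sortEvents(randomEventStream(sample(5:40, 1)))
    expect_identical(extractUpward(ev), bruteForceUpward(ev))
  }
})

test_that("binning conserves counts on half-open bins", {
  span <- c(TEST_ORIGIN, TEST_ORIGIN + 3600)
  six <- data.frame(column_id = "c01",
                    timestamp = TEST_ORIGIN + seq(660, 1150, length.out = 6),
                    detector_index = 2L)
  ae <- binCounts(six, binWidth = 10, span = span)
  cc <- SummarizedExperiment::assay(ae, "counts")[, 1]
  expect_equal(cc[2], 6)
  expect_equal(sum(cc), 6)
  expect_equal(length(cc), 6)

  set.seed(7)
  ev <- sortEvents(randomEventStream(500, spanSeconds = 3500))
  ae2 <- binCounts(ev, binWidth = 10, span = span)
  expect_equal(sum(SummarizedExperiment::assay(ae2, "counts")), 500)

  late <- data.frame(column_id = "c01", timestamp = TEST_ORIGIN + 4000,
                     detector_index = 2L)
  expect_error(binCounts(late, span = span), "outside span")
})

test_that("noise-free sensor synthesis round-trips through the pipeline", {
  geom <- sensorGeometry(noiseRate = 0)
  truthCounts <- c(3L, 5L, 2L, 0L, 7L)
  ev <- synthesizeBeamBreaks(truthCounts, geom, binWidth = 10, seed = 21)
  up <- extractUpward(sortEvents(ev), geom)
  # each full transit over 5 detectors yields 4 adjacent-pair events
  expect_equal(nrow(up), 4 * sum(truthCounts))
  ae <- binCounts(up, binWidth = 10,
                  span = c(TEST_ORIGIN, TEST_ORIGIN + 50 * 60),
                  origin = TEST_ORIGIN)
  got <- SummarizedExperiment::assay(ae, "counts")[, 1] / 4
  expect_identical(as.integer(got), truthCounts)
})

test_that("normalization maps to [0,1] and is idempotent", {
  m <- cbind(a = c(0, 5, 10), b = c(4, 4, 4))
  ae <- newActivityExperiment(m, binWidth = 10, ddOnset = 0)
  nae <- normalizeActivity(ae)
  nm <- SummarizedExperiment::assay(nae, "normalized")
  expect_equal(nm[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(nm[, "b"], c(0, 0, 0), ignore_attr = TRUE)  # degenerate

  set.seed(1)
  ae2 <- matrixExperiment(matrix(rpois(720 * 3, 4), ncol = 3),
                          assayName = "counts")
  n1 <- SummarizedExperiment::assay(normalizeActivity(ae2), "normalized")
  expect_equal(apply(n1, 2, min), rep(0, 3), ignore_attr = TRUE)
  expect_equal(apply(n1, 2, max), rep(1, 3), ignore_attr = TRUE)
  n2 <- SummarizedExperiment::assay(
    normalizeActivity(normalizeActivity(ae2)), "normalized")
  expect_equal(n2, n1)
})

test_that("centered moving average behaves as a shrinking box filter", {
  expect_equal(movingAverage(rep(2.5, 50), 6), rep(2.5, 50))
  expect_equal(movingAverage(c(0, 0, 1, 0, 0), 3), c(0, 1, 1, 1, 0) / 3)
  expect_error(movingAverage(1:5, 6), "larger")
  expect_error(movingAverage(1:5, 0), ">= 1")

  # even window: floor(w/2) before, ceiling(w/2)-1 after
  x <- c(rep(0, 10), 1, rep(0, 10))
  sm <- movingAverage(x, 6)
  expect_equal(which(sm > 0), 11 - 2 + seq_len(6) - 1)

  set.seed(33)
  reduced <- vapply(1:100, function(i) {
    z <- rnorm(200)
    var(movingAverage(z, 6)) < var(z)
  }, logical(1))
  expect_true(all(reduced))
})

test_that("detrending removes daily means and is idempotent", {
  m <- matrix(0.7, nrow = 3 * 144, ncol = 1, dimnames = list(NULL, "a"))
  ae <- matrixExperiment(m, assayName = "normalized")
  d <- SummarizedExperiment::assay(detrendActivity(ae), "detrended")
  expect_true(all(d == 0))

  # identical within-day shape under different daily offsets
  shape <- sin(2 * pi * seq(0, 24 - 1 / 6, by = 1 / 6) / 24)^2
  m2 <- matrix(c(shape + 0.2, shape + 0.8), ncol = 1,
               dimnames = list(NULL, "a"))
  ae2 <- matrixExperiment(m2, assayName = "normalized")
  d2 <- SummarizedExperiment::assay(detrendActivity(ae2), "detrended")
  expect_equal(d2[1:144, 1], d2[145:288, 1], ignore_attr = TRUE)
  day <- rep(0:1, each = 144)
  expect_true(all(abs(tapply(d2[, 1], day, mean)) < 1e-9))

  dd2 <- SummarizedExperiment::assay(
    detrendActivity(detrendActivity(ae2)), "detrended")
  expect_equal(dd2, d2)
})

test_that("detrending a drifting sinusoid preserves the periodogram peak", {
  t <- seq(0, 5 * 24 - 1 / 6, by = 1 / 6)
  drift <- 0.1 * floor(t / 24)
  x <- 0.3 * sin(2 * pi * t / 24) + drift
  ae <- matrixExperiment(matrix(x, ncol = 1, dimnames = list(NULL, "a")),
                         assayName = "normalized")
  d <- SummarizedExperiment::assay(detrendActivity(ae), "detrended")
  expect_true(all(abs(tapply(d[, 1], floor(t / 24), mean)) < 1e-9))
  pk_before <- peakPeriod(lombScargle(t, x))
  pk_after <- peakPeriod(lombScargle(t, d[, 1]))
  expect_equal(pk_after, 24, tolerance = 0.06)
  expect_equal(pk_before, pk_after, tolerance = 0.06)
})

test_that("phase-specific smoothing smooths each segment independently", {
  set.seed(5)
  m <- matrix(rpois(4 * 144, 5), ncol = 1, dimnames = list(NULL, "a"))
  ae <- newActivityExperiment(m, binWidth = 10, ddOnset = 48)
  sm <- SummarizedExperiment::assay(
    smoothActivity(ae, windowLD = 6, windowDD = 24), "smoothed")
  ld <- 1:288; dd <- 289:576
  expect_equal(sm[ld, 1], movingAverage(m[ld, 1], 6), ignore_attr = TRUE)
  expect_equal(sm[dd, 1], movingAverage(m[dd, 1], 24), ignore_attr = TRUE)
})
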