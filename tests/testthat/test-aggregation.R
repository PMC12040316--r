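test_that("FRP correction rescales one cycle onto one day and inverts", {
  t <- seq(72, 72 + 120, by = 1 / 6)
  expect_equal(frpCorrect(t, tau = 24, ddOnset = 72), t - 72)   # identity
  expect_equal(frpCorrect(72 + 20, tau = 20, ddOnset = 72), 24)
  # invertible for any tau > 0
  tc <- frpCorrect(t, tau = 26.3, ddOnset = 72)
  expect_equal(tc * 26.3 / 24 + 72, t)
  expect_error(frpCorrect(t, tau = 0), "positive")
  expect_error(frpCorrect(t, tau = -3), "positive")
})

test_that("a 26 h rhythm is 24 h-periodic after FRP correction", {
  t <- seq(72, 72 + 120 - 1 / 6, by = 1 / 6)
  x <- sin(2 * pi * (t - 72) / 26)
  tc <- frpCorrect(t, tau = 26, ddOnset = 72)
  pg <- lombScargle(tc, x)
  step24 <- 24^2 / (diff(range(tc)) * 4)  # grid step at 24 h
  expect_lt(abs(peakPeriod(pg) - 24), step24)
})

test_that("group mean rebins, averages and propagates s.e.m.", {
  t <- seq(0, 24 - 1 / 6, by = 1 / 6)
  one <- data.frame(individual_id = "a", time_h = t, value = sin(t))
  expect_warning(p1 <- groupMean(one, smoothWindow = 1), "single")
  expect_equal(p1$mean, sin(t), tolerance = 1e-12)
  expect_true(all(p1$sem == 0))
  expect_true(all(p1$n == 1))

  two <- rbind(one, transform(one, individual_id = "b"))
  p2 <- groupMean(two, smoothWindow = 1)
  expect_true(all(p2$sem == 0))
  expect_true(all(p2$n == 2))

  # two offset series: mean is the midpoint, sem = sd/sqrt(2)
  off <- rbind(one, transform(one, individual_id = "b", value = value + 1))
  p3 <- groupMean(off, smoothWindow = 1)
  expect_equal(p3$mean, sin(t) + 0.5, tolerance = 1e-12)
  expect_equal(p3$sem, rep(sd(c(0, 1)) / sqrt(2), length(t)),
               tolerance = 1e-12)

  expect_error(groupMean(one[0, ]), "empty")
})

test_that("cohort group profile peaks at the programmed bout phases", {
  sim <- simulateCohort(10, simulationParams(tau = 24, dampingHalflife = Inf),
                        lightRegime(5.5), daysLD = 3, daysDD = 5,
                        sensors = FALSE, seed = 31)
  ae <- processedCohort(sim)
  cls <- classifyGroup(ae, assay = "detrended")
  long <- frpCorrectGroup(ae, cls, assay = "detrended")
  avg <- averageDay(long, smoothWindow = 24)
  expect_equal(nrow(avg), 144)
  expect_equal(countActivityPeaks(avg$mean, 0.1), 2L)
  # strongest peak at the late-night bout (03:30), second at evening (16:00)
  expect_lt(abs(avg$time_h[which.max(avg$mean)] - 3.5), 1)
  ev <- avg$time_h >= 12 & avg$time_h <= 20
  expect_lt(abs(avg$time_h[ev][which.max(avg$mean[ev])] - 16), 1)
})

test_that("the average day of a 24 h-periodic series is one period", {
  t <- seq(0, 5 * 24 - 1 / 6, by = 1 / 6)
  shape <- cos(2 * pi * t / 24) + 0.5 * sin(4 * pi * t / 24)
  long <- data.frame(individual_id = "a", time_h = t, value = shape)
  avg <- suppressWarnings(averageDay(long, smoothWindow = 1))
  expect_equal(avg$mean, shape[1:144], tolerance = 1e-9)

  flat <- suppressWarnings(
    averageDay(data.frame(individual_id = "a", time_h = t, value = 0.42),
               smoothWindow = 6))
  expect_true(all(abs(flat$mean - 0.42) < 1e-12))
})

test_that("daily amplitudes score full days of the processed series", {
  # constant day -> 0; known span -> max - min
  v <- c(rep(0.5, 144), runif(144, 0.1, 0.9))
  v[145] <- 0.1; v[200] <- 0.9
  ae <- matrixExperiment(matrix(v, ncol = 1, dimnames = list(NULL, "a")),
                         ddOnset = 24, assayName = "smoothed")
  amps <- dailyAmplitudes(ae)
  expect_equal(amps$amplitude, c(0, 0.8))
  expect_equal(amps$day, c(0, 1))

  # partial trailing day is excluded
  vp <- c(v, rep(0, 30))
  aep <- matrixExperiment(matrix(vp, ncol = 1, dimnames = list(NULL, "a")),
                          ddOnset = 24, assayName = "smoothed")
  expect_equal(nrow(dailyAmplitudes(aep)), 2)

  # amplitude is offset-invariant and scale-equivariant
  ae2 <- matrixExperiment(matrix(3 * v + 10, ncol = 1,
                                 dimnames = list(NULL, "a")),
                          ddOnset = 24, assayName = "smoothed")
  expect_equal(dailyAmplitudes(ae2)$amplitude, 3 * amps$amplitude)
})

test_that("expected amplitude decays across days under damping", {
  perday <- matrix(0, nrow = 5, ncol = 100)
  for (s in 1:100) {
    sim <- simulateCohort(1, simulationParams(dampingHalflife = 48),
                          lightRegime(0), daysLD = 0, daysDD = 5,
                          sensors = FALSE, seed = s, gainCV = 0)
    ae <- detrendActivity(smoothActivity(normalizeActivity(sim$truth)))
    a <- dailyAmplitudes(ae)
    perday[, s] <- a$amplitude[order(a$day)]
  }
  expect_true(all(diff(rowMeans(perday)) < 0))
})

test_that("amplitude tests match closed forms and degenerate cases", {
  # hand-computed paired t: differences .3 .3 .4 .3 -> t = 0.325/(0.05/2) = 13
  amps <- rbind(
    data.frame(individual_id = letters[1:4], day = 0, phase = "LD",
               amplitude = c(0.95, 1.05, 1.15, 0.85)),
    data.frame(individual_id = letters[1:4], day = 3, phase = "DD",
               amplitude = c(1.1, 1.0, 0.9, 1.2)),
    data.frame(individual_id = letters[1:4], day = 7, phase = "DD",
               amplitude = c(0.8, 0.7, 0.5, 0.9)))
  rep1 <- amplitudeTests(amps)
  tRow <- rep1[rep1$test == "paired_t_firstDD_vs_lastDD", ]
  expect_equal(tRow$statistic, 13)
  expect_equal(tRow$df, 3)
  expect_equal(tRow$p_value, 2 * pt(13, df = 3, lower.tail = FALSE))

  # identical LD and DD amplitude distributions: U-test does not reject
  same <- rbind(
    data.frame(individual_id = "a", day = 0:9, phase = "LD",
               amplitude = seq(0.1, 1, by = 0.1)),
    data.frame(individual_id = "a", day = 10:19, phase = "DD",
               amplitude = seq(0.1, 1, by = 0.1)))
  expect_error(amplitudeTests(same), "paired t-test")  # 1 individual only
  same2 <- rbind(same,
                 transform(same, individual_id = "b",
                           amplitude = amplitude + 0.001))
  repSame <- amplitudeTests(same2)
  expect_gt(repSame$p_value[repSame$test == "mann_whitney_LD_vs_DD"], 0.9)

  # first-day amplitudes identical to last-day amplitudes: t = 0, p = 1
  const <- rbind(
    data.frame(individual_id = letters[1:3], day = 0, phase = "LD",
               amplitude = c(0.5, 0.6, 0.7)),
    data.frame(individual_id = letters[1:3], day = 3, phase = "DD",
               amplitude = c(0.4, 0.5, 0.6)),
    data.frame(individual_id = letters[1:3], day = 7, phase = "DD",
               amplitude = c(0.4, 0.5, 0.6)))
  repC <- amplitudeTests(const)
  tC <- repC[repC$test == "paired_t_firstDD_vs_lastDD", ]
  expect_equal(tC$statistic, 0)
  expect_equal(tC$p_value, 1)

  expect_error(amplitudeTests(amps[amps$phase == "DD", ]), "Mann-Whitney")

  expect_equal(significanceStars(c(0.2, 0.03, 0.009, 5e-4)),
               c("ns", "*", "**", "***"))
})

test_that("peak counting respects prominence and circularity", {
  tod <- (0:143) / 6
  two <- exp(-((tod - 16)^2) / 2) + 0.4 * exp(-((tod - 3.5)^2) / 2)
  expect_equal(countActivityPeaks(two, 0.1), 2L)
  expect_equal(countActivityPeaks(two, 0.5), 1L)   # small bout filtered
  # a bout wrapping midnight is one peak, not two
  wrap <- exp(-(pmin(abs(tod - 0), 24 - abs(tod - 0))^2) / 2)
  expect_equal(countActivityPeaks(wrap, 0.1), 1L)
  expect_equal(countActivityPeaks(rep(1, 144), 0.1), 0L)
})
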