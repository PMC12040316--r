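#' Rescale timestamps by an individual's free-running period
#'
#' Maps time since the switch to constant darkness onto a 24 h experimental
#' day: \eqn{t' = (t - t_{DD}) \cdot 24 / \tau}.  Values are untouched and
#' the original sampling resolution is preserved (no resampling); a
#' \eqn{\tau}-periodic series becomes 24 h-periodic.  The identity for
#' \eqn{\tau = 24}.
#'
#' @param time_h times, hours since the experiment origin
#' @param tau the individual's free-running period, hours
#' @param ddOnset hours since origin at which constant darkness begins (the
#'   anchor, so the LD-to-DD transition phase is shared across individuals)
#' @return rescaled times, hours on the 24 h experimental day axis
#' @export
frpCorrect <- function(time_h, tau, ddOnset = 0) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0)
    stop("'tau' must be a single positive period in hours")
  (time_h - ddOnset) * 24 / tau
}

#' Long-format series from an activity experiment
#'
#' @param ae an \linkS4class{ActivityExperiment}
#' @param assay assay to extract
#' @param phase keep only bins with this phase label (\code{NULL}: all)
#' @return data.frame with \code{individual_id}, \code{time_h}, \code{value}
#' @export
activityLong <- function(ae, assay = activityState(ae), phase = NULL) {
  keep <- if (is.null(phase)) rep(TRUE, nrow(ae)) else
    rowData(ae)$phase == phase
  m <- assay(ae, assay)[keep, , drop = FALSE]
  data.frame(
    individual_id = rep(colnames(m), each = nrow(m)),
    time_h = rep(rowData(ae)$time_h[keep], times = ncol(m)),
    value = as.vector(m))
}

#' FRP-corrected series for the rhythmic individuals of a cohort
#'
#' Extracts each classified individual's series (detrended DD segment by
#' default) and reassigns timestamps so that one free-running cycle covers
#' one 24 h experimental day.
#'
#' @param ae an \linkS4class{ActivityExperiment}
#' @param classification result of \code{\link{classifyGroup}}
#' @param assay assay to extract (default: current state)
#' @param phase phase segment to correct (default \code{"DD"})
#' @param ddOnset anchor, hours since origin; default from the experiment
#'   metadata
#' @param rhythmicOnly keep only individuals classified rhythmic
#' @return long data.frame \code{individual_id}, \code{time_h} (corrected,
#'   hours since DD onset on the 24 h day axis), \code{value}, \code{tau}
#' @export
frpCorrectGroup <- function(ae, classification, assay = activityState(ae),
                            phase = "DD",
                            ddOnset = metadata(ae)$ddOnset,
                            rhythmicOnly = TRUE) {
  if (is.null(ddOnset)) ddOnset <- 0
  cls <- as.data.frame(classification)
  if (rhythmicOnly) cls <- cls[cls$is_rhythmic, , drop = FALSE]
  if (nrow(cls) == 0) stop("no rhythmic individuals to correct")
  long <- activityLong(ae, assay, phase)
  long <- long[long$individual_id %in% cls$individual_id, , drop = FALSE]
  tau <- stats::setNames(cls$tau, cls$individual_id)
  long$tau <- tau[long$individual_id]
  long$time_h <- (long$time_h - ddOnset) * 24 / long$tau
  rownames(long) <- NULL
  long
}

# shared rebin/mean/sem core for group profiles
profileFromLong <- function(long, binWidth, smoothWindow, fold = FALSE) {
  if (nrow(long) == 0) stop("empty collection")
  bw <- binWidth / 60
  tt <- if (fold) long$time_h %% 24 else long$time_h
  long$bin <- floor(tt / bw + 1e-9)
  # average values of one individual falling in the same target bin first
  percell <- stats::aggregate(value ~ bin + individual_id, long, mean)
  bins <- if (fold) seq_len(round(24 / bw)) - 1 else
    seq(min(percell$bin), max(percell$bin))
  g <- factor(percell$bin, levels = bins)
  n <- as.integer(table(g))
  s1 <- tapply(percell$value, g, sum)
  mean <- as.numeric(s1) / n
  sdv <- as.numeric(tapply(percell$value, g, stats::sd))
  sem <- ifelse(n > 1, sdv / sqrt(n), ifelse(n == 1, 0, NA_real_))
  if (any(n == 1))
    warning("bins with a single contributing series: s.e.m. reported as 0")
  prof <- data.frame(time_h = bins * bw, mean = mean, sem = sem, n = n)
  prof$missing <- prof$n == 0
  present <- !prof$missing
  if (sum(present) >= 2) {
    w <- min(smoothWindow, sum(present))
    prof$mean[present] <- movingAverage(prof$mean[present], w)
  }
  prof
}

#' Group mean activity profile
#'
#' Rebins (FRP-corrected or plain) per-individual series to a common grid,
#' averages across individuals per bin, computes the standard error of the
#' mean, and smooths the mean.  Values of one individual falling into the
#' same target bin are averaged first.  Bins reached by no individual are
#' flagged \code{missing}; single-individual bins report \code{sem = 0}
#' with a warning.
#'
#' @param long long data.frame with \code{individual_id}, \code{time_h},
#'   \code{value} (e.g. from \code{\link{frpCorrectGroup}} or
#'   \code{\link{activityLong}})
#' @param binWidth target grid width, minutes
#' @param smoothWindow moving-average window (points) applied to the mean
#' @return data.frame \code{time_h}, \code{mean}, \code{sem}, \code{n},
#'   \code{missing}
#' @export
groupMean <- function(long, binWidth = 10, smoothWindow = 24) {
  profileFromLong(long, binWidth, smoothWindow, fold = FALSE)
}

#' Average-day activity profile
#'
#' Pools every value onto its time of day (modulo 24 h) over all experiment
#' days and individuals, then computes the per-bin mean and s.e.m. over a
#' single 24 h day (144 bins at 10 min) and smooths the mean.  Under LD the
#' input should be normalized+smoothed activity on wall-clock time; under
#' DD, detrended FRP-corrected activity.
#'
#' @inheritParams groupMean
#' @return data.frame over one 24 h day: \code{time_h}, \code{mean},
#'   \code{sem}, \code{n}, \code{missing}
#' @export
averageDay <- function(long, binWidth = 10, smoothWindow = 6) {
  profileFromLong(long, binWidth, smoothWindow, fold = TRUE)
}

#' Daily activity amplitudes
#'
#' The amplitude of an experiment day is the difference between that day's
#' maximal and minimal activity of the processed (normalized, detrended,
#' phase-appropriately smoothed) series.  Only full days (complete bin
#' coverage) are scored; partial setup days are excluded.
#'
#' @param ae an \linkS4class{ActivityExperiment}
#' @param assay assay to score (default: current state)
#' @return data.frame \code{individual_id}, \code{day}, \code{phase},
#'   \code{amplitude}
#' @export
dailyAmplitudes <- function(ae, assay = activityState(ae)) {
  m <- assay(ae, assay)
  rd <- rowData(ae)
  bpd <- round(24 * 60 / metadata(ae)$binWidth)
  out <- list()
  for (d in unique(rd$day)) {
    idx <- which(rd$day == d)
    if (length(idx) < bpd) next              # partial day
    ph <- rd$phase[idx]
    for (j in seq_len(ncol(m))) {
      v <- m[idx, j]
      out[[length(out) + 1]] <- data.frame(
        individual_id = colnames(m)[j], day = d,
        phase = ph[1], amplitude = max(v) - min(v))
    }
  }
  if (!length(out))
    return(data.frame(individual_id = character(0), day = integer(0),
                      phase = character(0), amplitude = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$individual_id, res$day), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Significance stars
#'
#' @param p p-value(s)
#' @return "***" (p<0.001), "**" (p<0.01), "*" (p<0.05) or "ns"
#' @export
significanceStars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Hypothesis tests on daily amplitudes
#'
#' Two tests of amplitude change: (a) a two-sided Mann-Whitney U-test on the
#' pooled daily amplitudes under LD versus DD (exact distribution when both
#' groups have at most 20 untied observations, normal approximation with
#' continuity correction otherwise); (b) a two-sided paired t-test of each
#' individual's first-DD-day amplitude against its last-DD-day amplitude.
#'
#' @param amps data.frame from \code{\link{dailyAmplitudes}}
#' @return data.frame report with one row per test: \code{test},
#'   \code{statistic}, \code{df}, \code{n}, \code{p_value}, \code{stars}
#' @export
amplitudeTests <- function(amps) {
  rows <- list()

  ld <- amps$amplitude[amps$phase == "LD"]
  dd <- amps$amplitude[amps$phase == "DD"]
  if (length(ld) == 0 || length(dd) == 0)
    stop("Mann-Whitney U-test needs daily amplitudes under both LD and DD")
  if (length(unique(c(ld, dd))) == 1) {
    # every amplitude identical (e.g. all zero): no evidence either way
    ustat <- length(ld) * length(dd) / 2; up <- 1
  } else {
    exact <- length(ld) <= 20 && length(dd) <= 20 &&
      !any(duplicated(c(ld, dd)))
    u <- stats::wilcox.test(ld, dd, exact = exact, correct = TRUE)
    ustat <- unname(u$statistic); up <- u$p.value
  }
  rows$mann_whitney <- data.frame(
    test = "mann_whitney_LD_vs_DD", statistic = ustat,
    df = NA_real_, n = length(ld) + length(dd), p_value = up,
    stars = significanceStars(up))

  ddamp <- amps[amps$phase == "DD", , drop = FALSE]
  first_day <- min(ddamp$day); last_day <- max(ddamp$day)
  ids <- intersect(ddamp$individual_id[ddamp$day == first_day],
                   ddamp$individual_id[ddamp$day == last_day])
  if (length(ids) < 2 || first_day == last_day)
    stop("paired t-test needs >= 2 individuals scored on both the first ",
         "and last DD day")
  d1 <- ddamp[ddamp$day == first_day, ]
  d2 <- ddamp[ddamp$day == last_day, ]
  a1 <- d1$amplitude[match(ids, d1$individual_id)]
  a2 <- d2$amplitude[match(ids, d2$individual_id)]
  tt <- if (stats::sd(a1 - a2) == 0) NULL else
    tryCatch(stats::t.test(a1, a2, paired = TRUE), error = function(e) NULL)
  if (is.null(tt)) {
    # essentially constant differences across individuals
    d <- mean(a1 - a2); tdf <- length(ids) - 1
    tstat <- if (d == 0) 0 else sign(d) * Inf
    tp <- if (d == 0) 1 else 0
  } else {
    tstat <- unname(tt$statistic); tdf <- unname(tt$parameter)
    tp <- tt$p.value
  }
  rows$paired_t <- data.frame(
    test = "paired_t_firstDD_vs_lastDD", statistic = tstat,
    df = tdf, n = length(ids), p_value = tp,
    stars = significanceStars(tp))

  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Count prominent activity peaks in a daily profile
#'
#' Counts local maxima of a (typically average-day) profile whose
#' topographic prominence exceeds \code{minProminence} times the profile
#' range.  The profile is treated as circular (time of day wraps), so a
#' bout spanning midnight is a single peak.
#'
#' @param x numeric profile values (e.g. the \code{mean} column of
#'   \code{\link{averageDay}})
#' @param minProminence minimal prominence as a fraction of the range
#' @param circular treat the profile as periodic
#' @return integer number of prominent peaks
#' @export
countActivityPeaks <- function(x, minProminence = 0.1, circular = TRUE) {
  n <- length(x)
  rng <- diff(range(x))
  if (rng == 0) return(0L)
  thr <- minProminence * rng
  if (circular) {
    k <- which.min(x)
    x <- x[c(k:n, seq_len(k - 1))]
  }
  is_peak <- function(i) {
    if (i == 1 || i == n) return(FALSE)
    x[i] > x[i - 1] && x[i] >= x[i + 1]
  }
  count <- 0L
  for (i in seq_len(n)) {
    if (!is_peak(i)) next
    # walk out to the nearest higher ground on each side, tracking the
    # lowest saddle passed; prominence = height above the higher saddle
    base <- function(dir) {
      lo <- x[i]; j <- i + dir
      while (j >= 1 && j <= n && x[j] <= x[i]) {
        lo <- min(lo, x[j]); j <- j + dir
      }
      if (j < 1 || j > n) min(lo, x[1], x[n]) else lo
    }
    prom <- x[i] - max(base(-1L), base(1L))
    if (prom >= thr) count <- count + 1L
  }
  count
}
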