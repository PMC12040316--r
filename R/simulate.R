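#' Ground-truth simulation parameters for synthetic krill
#'
#' Defaults encode the behavioural structure reported for Antarctic krill
#' under a simulated short day: a free-running period of 24.2 h, an evening
#' activity bout shortly after lights-off (16:00 for the 5.5 h photoperiod)
#' and a late-night bout (03:30), strong suppression of clock-driven
#' activity by light, a 30-min lights-on startle bout, and amplitude damping
#' with a 120 h half-life under constant darkness (about a halving of the
#' clock-driven amplitude over five DD days).
#'
#' @param tau free-running period, hours
#' @param phaseEvening,phaseLateNight bout centers as circadian phase in
#'   [0, 1) of the (entrained) 24 h day
#' @param boutWidth Gaussian s.d. of each bout, hours
#' @param gainEvening,gainLateNight peak bout rate above baseline, events/bin
#' @param baselineRate baseline activity, events/bin
#' @param dampingHalflife amplitude halving time under DD, hours (Inf: none)
#' @param maskingCoeff fractional suppression of the clock-driven component
#'   at peak light, in [0, 1]
#' @param startleGain,startleDuration lights-on startle bout rate (events/bin)
#'   and duration (minutes)
#' @param seed integer random seed
#' @return a \linkS4class{SimulationParams}
#' @export
simulationParams <- function(tau = 24.2, phaseEvening = 16 / 24,
                             phaseLateNight = 3.5 / 24, boutWidth = 2.5,
                             gainEvening = 2, gainLateNight = 8,
                             baselineRate = 2, dampingHalflife = 120,
                             maskingCoeff = 0.9, startleGain = 6,
                             startleDuration = 30, seed = 1L) {
  new("SimulationParams", tau = tau, phaseEvening = phaseEvening,
      phaseLateNight = phaseLateNight, boutWidth = boutWidth,
      gainEvening = gainEvening, gainLateNight = gainLateNight,
      baselineRate = baselineRate, dampingHalflife = dampingHalflife,
      maskingCoeff = maskingCoeff, startleGain = startleGain,
      startleDuration = startleDuration, seed = as.integer(seed))
}

#' Stacked-detector column geometry
#'
#' @param nDetectors number of infrared detector modules (bottom = 1)
#' @param transitGap seconds between consecutive detector crossings during
#'   one full upward transit of the column
#' @param noiseRate spurious detections per detector per hour
#' @return a \linkS4class{SensorGeometry}
#' @export
sensorGeometry <- function(nDetectors = 5L, transitGap = 1, noiseRate = 0.5) {
  new("SensorGeometry", nDetectors = as.integer(nDetectors),
      transitGap = as.numeric(transitGap), noiseRate = as.numeric(noiseRate))
}

# run expr with a private RNG stream, restoring the caller's .Random.seed
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# circular distance between phases a and b (both in [0,1)), result in hours
# on a cycle of length `period`
circDistHours <- function(phi, center, period) {
  d <- (phi - center) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  d * period
}

#' Instantaneous clock-driven activity rate
#'
#' The deterministic rate (events per bin) underlying the Poisson event
#' counts:
#' \deqn{r(t) = b + D(t)\,[B_e(t) + B_l(t)]\,(1 - m I(t)/I_{max}) + S(t)}
#' where \eqn{b} is the baseline, \eqn{B_e, B_l} are Gaussian evening and
#' late-night bouts on circular circadian phase (truncated at 3 s.d.),
#' \eqn{D(t)} is exponential amplitude damping applied after the switch to
#' constant darkness, the masking term suppresses the clock-driven component
#' in proportion to relative light intensity, and \eqn{S(t)} is a square
#' startle pulse after each dark-to-light transition.  Before \code{ddOnset}
#' the internal phase is locked to the 24 h zeitgeber cycle; after it the
#' clock free-runs at period \code{tau}, continuous in phase at the
#' transition.
#'
#' @param params a \linkS4class{SimulationParams}
#' @param regime a \linkS4class{LightRegime}
#' @param t numeric vector, hours since the simulation start (midnight of
#'   day 0)
#' @param ddOnset hours since start at which constant darkness begins, or
#'   \code{NULL} if the whole span is under the light regime
#' @return numeric vector of rates, events per bin, always \eqn{\ge 0}
#' @export
clockRate <- function(params, regime, t, ddOnset = NULL) {
  stopifnot(is.numeric(t), all(t >= 0))
  inDD <- if (is.null(ddOnset)) rep(FALSE, length(t)) else t >= ddOnset
  dd0 <- if (is.null(ddOnset)) Inf else ddOnset

  # circadian phase: zeitgeber-locked before DD onset, free-running after
  phi <- ifelse(inDD, (dd0 / 24 + (t - dd0) / params@tau) %% 1,
                (t / 24) %% 1)
  period <- ifelse(inDD, params@tau, 24)

  bout <- function(center, gain) {
    dh <- circDistHours(phi, center, period)
    ifelse(abs(dh) <= 3 * params@boutWidth,
           gain * exp(-dh^2 / (2 * params@boutWidth^2)), 0)
  }
  circ <- bout(params@phaseEvening, params@gainEvening) +
          bout(params@phaseLateNight, params@gainLateNight)

  damp <- ifelse(inDD, 2^(-(t - dd0) / params@dampingHalflife), 1)

  # light reaches the animal only before DD onset
  rel <- ifelse(inDD, 0, lightIntensity(regime, t) / regime@peakIntensity)

  startle <- rep(0, length(t))
  if (params@startleGain > 0 && params@startleDuration > 0 &&
      regime@photoperiod > 0 && regime@photoperiod < 24) {
    since_on <- (t - lightsOn(regime)) %% 24
    startle <- ifelse(!inDD & since_on < params@startleDuration / 60,
                      params@startleGain, 0)
  }

  params@baselineRate + damp * circ * (1 - params@maskingCoeff * rel) + startle
}

#' Draw Poisson event counts per time bin
#'
#' Counts are Poisson with mean equal to the clock-driven rate averaged over
#' each bin (the rate is expressed per bin, so its within-bin average is the
#' integrated expectation).  Reproducible under a fixed seed; the caller's
#' RNG state is left untouched.
#'
#' @inheritParams clockRate
#' @param duration simulated span, hours
#' @param binWidth bin width in minutes (must divide 60)
#' @param seed integer seed; defaults to \code{params@seed}
#' @param nSub sub-steps per bin for the within-bin rate average
#' @return integer vector of per-bin counts, with attribute \code{time_h}
#'   giving bin start times in hours since start
#' @export
sampleEventCounts <- function(params, regime, duration, binWidth = 10,
                              ddOnset = NULL, seed = params@seed, nSub = 5) {
  stopifnot(duration > 0, 60 %% binWidth == 0)
  bw <- binWidth / 60
  nbin <- round(duration / bw)
  stopifnot(abs(nbin * bw - duration) < 1e-9)
  starts <- (seq_len(nbin) - 1) * bw
  sub <- (seq_len(nSub) - 0.5) / nSub * bw
  mu <- rowMeans(matrix(
    clockRate(params, regime, rep(starts, each = nSub) + sub, ddOnset),
    nrow = nbin, byrow = TRUE))
  counts <- withSeed(seed, stats::rpois(nbin, mu))
  attr(counts, "time_h") <- starts
  attr(counts, "mean") <- mu
  counts
}

#' Synthesize a raw beam-break event stream from per-bin transit counts
#'
#' Inverse of the upward-movement extraction: each counted upward movement
#' becomes one full transit of the column, i.e. an ordered run of detections
#' at detectors 1 to \code{nDetectors} separated by \code{transitGap}
#' seconds.  Within a bin the runs are placed uniformly at random but
#' without overlap and wholly inside the bin (interleaved transits would
#' break the adjacency chain that the downstream upward extraction counts,
#' and a straddling transit would blur bin totals).  Spurious detections are
#' superimposed as a homogeneous Poisson process per detector at
#' \code{noiseRate}.  The stream is sorted by timestamp, ties broken by
#' ascending detector index.
#'
#' @param counts non-negative integer vector of per-bin upward-transit counts
#' @param geometry a \linkS4class{SensorGeometry}
#' @param binWidth bin width in minutes
#' @param seed integer random seed
#' @param columnId identifier recorded in the \code{column_id} field
#' @param origin POSIXct (UTC) of the simulation start (midnight, day 0)
#' @return data.frame with columns \code{column_id}, \code{timestamp}
#'   (POSIXct, UTC), \code{detector_index}
#' @export
synthesizeBeamBreaks <- function(counts, geometry, binWidth = 10, seed = 1L,
                                 columnId = "col01",
                                 origin = as.POSIXct("2021-05-31 00:00:00",
                                                     tz = "UTC")) {
  if (any(counts < 0)) stop("'counts' must be non-negative")
  nd <- geometry@nDetectors
  bin_s <- binWidth * 60
  transit_s <- (nd - 1) * geometry@transitGap
  if (transit_s >= bin_s)
    stop("full transit duration exceeds the bin width")
  counts <- as.integer(counts)
  duration_s <- length(counts) * bin_s

  if (max(counts, 0) * transit_s >= bin_s)
    stop("too many transits per bin to place without overlap")
  withSeed(seed, {
    ntr <- sum(counts)
    if (ntr > 0) {
      start_s <- unlist(lapply(which(counts > 0), function(b) {
        k <- counts[b]
        u <- sort(stats::runif(k, 0, bin_s - k * transit_s))
        (b - 1) * bin_s + u + (seq_len(k) - 1) * transit_s
      }))
      tt <- rep(start_s, each = nd) +
        rep((seq_len(nd) - 1) * geometry@transitGap, times = ntr)
      det <- rep(seq_len(nd), times = ntr)
    } else {
      tt <- numeric(0); det <- integer(0)
    }
    if (geometry@noiseRate > 0) {
      nn <- stats::rpois(nd, geometry@noiseRate * duration_s / 3600)
      for (d in seq_len(nd)) {
        if (nn[d] > 0) {
          tt <- c(tt, stats::runif(nn[d], 0, duration_s))
          det <- c(det, rep(d, nn[d]))
        }
      }
    }
    ord <- order(tt, det)
    data.frame(column_id = rep(columnId, length(tt)),
               timestamp = origin + tt[ord],
               detector_index = as.integer(det[ord]))
  })
}

#' Simulate a cohort of krill columns down to raw beam-break events
#'
#' Convenience wrapper tying the rate model, Poisson sampling and sensor
#' synthesis together for \code{n} individuals sharing one light schedule
#' (\code{daysLD} days under the regime followed by \code{daysDD} days of
#' constant darkness).  Per-individual bout gains are jittered
#' log-normally (\code{gainCV}) and the free-running period can vary
#' (\code{tauSd}) to mimic inter-individual variability.
#'
#' @param n number of individuals (one per column)
#' @param params shared \linkS4class{SimulationParams} template
#' @param regime \linkS4class{LightRegime} for the LD phase
#' @param daysLD,daysDD days under the light regime / constant darkness
#' @param geometry \linkS4class{SensorGeometry}
#' @param binWidth bin width in minutes
#' @param seed master seed; per-individual streams are derived from it
#' @param tauSd s.d. of inter-individual free-running period, hours
#' @param gainCV coefficient of variation of the per-individual overall
#'   activity amplitude (one shared log-normal factor scales both bout
#'   gains, preserving the evening/late-night ratio)
#' @param sensors if \code{FALSE}, skip the sensor layer: no beam-break
#'   streams are synthesized (\code{events} is \code{NULL}) and only the
#'   ground-truth counts are returned, which is much faster for
#'   replicate-heavy simulation studies
#' @param origin POSIXct (UTC) experiment start (midnight, day 0)
#' @return list with \code{events} (combined beam-break data.frame),
#'   \code{truth} (an \linkS4class{ActivityExperiment} of ground-truth
#'   transit counts), \code{taus} (per-individual true periods) and
#'   \code{ddOnset} (hours)
#' @export
simulateCohort <- function(n, params = simulationParams(),
                           regime = lightRegime(5.5), daysLD = 3,
                           daysDD = 5, geometry = sensorGeometry(),
                           binWidth = 10, seed = params@seed, tauSd = 0,
                           gainCV = 0.2, sensors = TRUE,
                           origin = as.POSIXct("2021-05-31 00:00:00",
                                               tz = "UTC")) {
  stopifnot(n >= 1, daysLD >= 0, daysDD >= 0, daysLD + daysDD > 0)
  duration <- 24 * (daysLD + daysDD)
  ddOnset <- if (daysDD > 0) 24 * daysLD else NULL
  ids <- sprintf("krill%02d", seq_len(n))
  jit <- withSeed(seed, {
    amp <- exp(stats::rnorm(n, 0, gainCV) - gainCV^2 / 2)
    list(tau = stats::rnorm(n, params@tau, tauSd),
         ge = params@gainEvening * amp, gl = params@gainLateNight * amp)
  })
  events <- vector("list", n)
  cmat <- matrix(0L, nrow = round(duration * 60 / binWidth), ncol = n,
                 dimnames = list(NULL, ids))
  for (i in seq_len(n)) {
    p_i <- params
    p_i@tau <- jit$tau[i]
    p_i@gainEvening <- jit$ge[i]
    p_i@gainLateNight <- jit$gl[i]
    si <- seed * 1000 + i
    cnt <- sampleEventCounts(p_i, regime, duration, binWidth,
                             ddOnset = ddOnset, seed = si)
    cmat[, i] <- as.integer(cnt)
    if (sensors)
      events[[i]] <- synthesizeBeamBreaks(cnt, geometry, binWidth,
                                          seed = si + 500,
                                          columnId = ids[i], origin = origin)
  }
  ev <- NULL
  if (sensors) {
    ev <- do.call(rbind, events)
    ev <- ev[order(ev$timestamp, ev$column_id, ev$detector_index), ,
             drop = FALSE]
    rownames(ev) <- NULL
  }
  truth <- newActivityExperiment(cmat, binWidth = binWidth, origin = origin,
                                 ddOnset = ddOnset)
  list(events = ev, truth = truth, taus = jit$tau, ddOnset = ddOnset)
}
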