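#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowData colData
NULL

#' Triangular light regime
#'
#' Describes the daily light cycle of the activity monitor: intensity rises
#' linearly from 0 at lights-on to \code{peakIntensity} at solar noon and
#' falls linearly back to 0 at lights-off, with day length arranged
#' symmetrically around solar noon.  A photoperiod of 0 encodes constant
#' darkness (DD).
#'
#' @slot photoperiod hours of light per day, in [0, 24]
#' @slot solarNoon clock time of solar noon, hours since midnight
#' @slot peakIntensity maximal intensity at solar noon, mW/m^2
#' @slot samplingStep intensity profile resolution, minutes
#' @export
setClass("LightRegime",
  representation(photoperiod = "numeric", solarNoon = "numeric",
                 peakIntensity = "numeric", samplingStep = "numeric"))

setValidity("LightRegime", function(object) {
  msg <- character()
  if (length(object@photoperiod) != 1 || is.na(object@photoperiod) ||
      object@photoperiod < 0 || object@photoperiod > 24)
    msg <- c(msg, "'photoperiod' must be a single value in [0, 24] hours")
  if (length(object@solarNoon) != 1 || object@solarNoon < 0 ||
      object@solarNoon >= 24)
    msg <- c(msg, "'solarNoon' must be a clock time in [0, 24) hours")
  if (length(object@peakIntensity) != 1 || object@peakIntensity <= 0)
    msg <- c(msg, "'peakIntensity' must be > 0")
  if (length(object@samplingStep) != 1 || object@samplingStep <= 0)
    msg <- c(msg, "'samplingStep' must be > 0 minutes")
  if (length(msg)) msg else TRUE
})

#' Ground-truth parameters of the synthetic krill activity model
#'
#' Encodes the behavioural structure of krill swimming activity as reported
#' for Antarctic krill: a circadian clock driving two activity bouts per
#' cycle (evening and late night), multiplicative suppression (masking) of
#' the clock-driven component by light, a transient lights-on startle bout,
#' and exponential amplitude damping under constant darkness.
#'
#' @slot tau free-running period in hours (e.g. 24.2)
#' @slot phaseEvening circadian phase in [0,1) of the evening bout center
#' @slot phaseLateNight circadian phase in [0,1) of the late-night bout center
#' @slot boutWidth Gaussian s.d. of each bout, hours
#' @slot gainEvening,gainLateNight peak rate of each bout above baseline,
#'   events per bin
#' @slot baselineRate baseline activity, events per bin
#' @slot dampingHalflife amplitude halving time under DD, hours; \code{Inf}
#'   disables damping
#' @slot maskingCoeff fractional suppression of the clock-driven component at
#'   peak light intensity, in [0,1]
#' @slot startleGain added rate during the lights-on startle bout, events/bin
#' @slot startleDuration duration of the startle bout, minutes
#' @slot seed integer random seed
#' @export
setClass("SimulationParams",
  representation(tau = "numeric", phaseEvening = "numeric",
                 phaseLateNight = "numeric", boutWidth = "numeric",
                 gainEvening = "numeric", gainLateNight = "numeric",
                 baselineRate = "numeric", dampingHalflife = "numeric",
                 maskingCoeff = "numeric", startleGain = "numeric",
                 startleDuration = "numeric", seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@tau <= 0) msg <- c(msg, "'tau' must be > 0")
  for (s in c("phaseEvening", "phaseLateNight")) {
    v <- slot(object, s)
    if (v < 0 || v >= 1) msg <- c(msg, sprintf("'%s' must lie in [0, 1)", s))
  }
  if (object@boutWidth <= 0) msg <- c(msg, "'boutWidth' must be > 0 hours")
  for (s in c("gainEvening", "gainLateNight", "baselineRate", "startleGain"))
    if (slot(object, s) < 0) msg <- c(msg, sprintf("'%s' must be >= 0", s))
  if (object@dampingHalflife <= 0)
    msg <- c(msg, "'dampingHalflife' must be > 0 (Inf for no damping)")
  if (object@maskingCoeff < 0 || object@maskingCoeff > 1)
    msg <- c(msg, "'maskingCoeff' must lie in [0, 1]")
  if (object@startleDuration < 0)
    msg <- c(msg, "'startleDuration' must be >= 0 minutes")
  if (length(msg)) msg else TRUE
})

#' Geometry of the stacked-detector activity monitor column
#'
#' @slot nDetectors number of infrared detector modules, equally spaced over
#'   the column height (detector 1 at the bottom)
#' @slot transitGap seconds between consecutive detector crossings during one
#'   upward transit
#' @slot noiseRate spurious detections per detector per hour
#' @export
setClass("SensorGeometry",
  representation(nDetectors = "integer", transitGap = "numeric",
                 noiseRate = "numeric"))

setValidity("SensorGeometry", function(object) {
  msg <- character()
  if (object@nDetectors < 2L) msg <- c(msg, "'nDetectors' must be >= 2")
  if (object@transitGap <= 0) msg <- c(msg, "'transitGap' must be > 0 s")
  if (object@noiseRate < 0) msg <- c(msg, "'noiseRate' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Container for binned multi-individual activity time series
#'
#' A \linkS4class{SummarizedExperiment} with one column per individual
#' (experimental column) and one row per time bin on a strictly increasing,
#' gap-free grid.  Assays accumulate as the series is processed:
#' \code{"counts"} (raw upward-movement counts), then \code{"normalized"},
#' \code{"smoothed"} and \code{"detrended"}.  \code{rowData} carries
#' \code{time_h} (bin start, hours since the experiment-clock midnight
#' origin), \code{phase} (\code{"LD"} or \code{"DD"}) and \code{day}
#' (experiment day, 0-based, midnight to midnight).  \code{metadata} carries
#' \code{binWidth} (minutes), \code{origin} (POSIXct, UTC) and \code{state},
#' the name of the most recently added assay.
#'
#' @export
setClass("ActivityExperiment", contains = "SummarizedExperiment")

setValidity("ActivityExperiment", function(object) {
  msg <- character()
  rd <- rowData(object)
  if (!all(c("time_h", "phase", "day") %in% colnames(rd)))
    return("rowData must contain 'time_h', 'phase' and 'day'")
  bw <- metadata(object)$binWidth
  if (is.null(bw) || length(bw) != 1 || bw <= 0 || 60 %% bw != 0)
    msg <- c(msg, "metadata$binWidth must be a single divisor of 60 (minutes)")
  t <- rd$time_h
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) msg <- c(msg, "bin grid must be strictly increasing")
    if (!is.null(bw) && length(bw) == 1 && bw > 0 &&
        any(abs(dt - bw / 60) > 1e-8))
      msg <- c(msg, "bin grid must be gap-free at metadata$binWidth")
  }
  if (!all(rd$phase %in% c("LD", "DD")))
    msg <- c(msg, "phase labels must be 'LD' or 'DD'")
  st <- metadata(object)$state
  if (is.null(st) || !st %in% assayNames(object))
    msg <- c(msg, "metadata$state must name an existing assay")
  if (length(msg)) msg else TRUE
})

#' Lomb-Scargle periodogram result
#'
#' Variance-normalized (classical Scargle) periodogram over a period scan
#' range, with the significance of the peak from the independent-frequencies
#' approximation \eqn{p = 1 - (1 - e^{-P})^M}, M prorated from the
#' Horne-Baliunas estimate to the scanned frequency band.
#'
#' @slot period scanned periods, hours
#' @slot power normalized power at each scanned period
#' @slot peakPeriod period at maximal power, hours (parabolic refinement of
#'   the grid maximum)
#' @slot peakPower maximal normalized power over the grid
#' @slot pValue significance of the peak, in (0, 1]
#' @slot nEffective effective number of independent frequencies M
#' @slot n number of observations in the series
#' @export
setClass("PeriodogramResult",
  representation(period = "numeric", power = "numeric",
                 peakPeriod = "numeric", peakPower = "numeric",
                 pValue = "numeric", nEffective = "numeric", n = "integer"))

setValidity("PeriodogramResult", function(object) {
  msg <- character()
  if (length(object@period) != length(object@power))
    msg <- c(msg, "'period' and 'power' lengths differ")
  if (any(object@power < 0)) msg <- c(msg, "power must be >= 0")
  if (length(object@power) &&
      abs(object@peakPower - max(object@power)) > 1e-9)
    msg <- c(msg, "'peakPower' must equal max(power)")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "'pValue' must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
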