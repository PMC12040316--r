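#' Construct a triangular light regime
#'
#' The activity monitor ramps light linearly from 0 at lights-on to the
#' maximal intensity at solar noon and back to 0 at lights-off; day length is
#' symmetric around solar noon.  \code{photoperiod = 0} encodes constant
#' darkness.
#'
#' @param photoperiod hours of light per day, in [0, 24] (e.g. 5.5 for the
#'   short-day regime, 15 for the long-day regime)
#' @param solarNoon clock time of solar noon in hours since midnight
#' @param peakIntensity maximal intensity at solar noon, mW/m^2 (default 8.8)
#' @param samplingStep profile resolution in minutes
#' @return a \linkS4class{LightRegime}
#' @examples
#' reg <- lightRegime(5.5)
#' lightIntensity(reg, 12)      # 8.8 at solar noon
#' lightsOn(reg); lightsOff(reg)
#' @export
lightRegime <- function(photoperiod, solarNoon = 12, peakIntensity = 8.8,
                        samplingStep = 10) {
  if (!is.numeric(photoperiod) || length(photoperiod) != 1 ||
      is.na(photoperiod) || photoperiod < 0 || photoperiod > 24)
    stop("'photoperiod' must be a single value in [0, 24] hours")
  new("LightRegime", photoperiod = as.numeric(photoperiod),
      solarNoon = as.numeric(solarNoon),
      peakIntensity = as.numeric(peakIntensity),
      samplingStep = as.numeric(samplingStep))
}

#' @describeIn lightRegime photoperiod in hours
#' @param regime a \linkS4class{LightRegime}
#' @export
photoperiod <- function(regime) regime@photoperiod

#' @describeIn lightRegime clock time of lights-on (hours since midnight), or
#'   \code{NA} under constant darkness
#' @export
lightsOn <- function(regime) {
  if (regime@photoperiod == 0) return(NA_real_)
  regime@solarNoon - regime@photoperiod / 2
}

#' @describeIn lightRegime clock time of lights-off, or \code{NA} under DD
#' @export
lightsOff <- function(regime) {
  if (regime@photoperiod == 0) return(NA_real_)
  regime@solarNoon + regime@photoperiod / 2
}

#' Evaluate the light intensity profile
#'
#' Intensity at time \code{t} (hours; interpreted modulo 24 on the experiment
#' clock, so hours-since-start and clock time are interchangeable).  Zero
#' outside the photoperiod window, a linear ramp peaking at solar noon
#' inside it.
#'
#' @param regime a \linkS4class{LightRegime}
#' @param t numeric vector of times in hours
#' @return numeric vector of intensities, mW/m^2
#' @export
lightIntensity <- function(regime, t) {
  if (regime@photoperiod == 0) return(rep(0, length(t)))
  tod <- t %% 24
  half <- regime@photoperiod / 2
  # distance to solar noon on the 24 h circle
  d <- abs(tod - regime@solarNoon)
  d <- pmin(d, 24 - d)
  ifelse(d < half, regime@peakIntensity * (1 - d / half), 0)
}

setMethod("show", "LightRegime", function(object) {
  if (object@photoperiod == 0) {
    cat("LightRegime: constant darkness (DD)\n")
  } else {
    cat(sprintf(
      "LightRegime: LD %.2g:%.2g h, lights %05.2f-%05.2f, peak %.3g mW/m^2\n",
      object@photoperiod, 24 - object@photoperiod,
      lightsOn(object), lightsOff(object), object@peakIntensity))
  }
  invisible(NULL)
})
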