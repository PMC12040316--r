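#' Experiment configuration
#'
#' Bundles the light schedule and analysis parameters of one activity
#' experiment: either a light-dark phase followed by constant darkness
#' (design \code{"LD_DD"}, as in the short-day and long-day treatments) or
#' constant darkness only after field entrainment (design \code{"DD_only"},
#' as in the seasonal treatments).
#'
#' @param design \code{"LD_DD"} or \code{"DD_only"}
#' @param photoperiod hours of light per LD day (ignored under
#'   \code{"DD_only"})
#' @param daysLD,daysDD days under the light regime / constant darkness
#' @param binWidth bin width, minutes
#' @param smoothLD,smoothDD moving-average windows (points) for LD and DD
#' @param periodRange scanned period band for the periodogram, hours
#' @param ofac periodogram oversampling factor
#' @param criteria rhythmicity thresholds from \code{\link{rhythmCriteria}}
#' @param seed integer seed for any simulation attached to this config
#' @param origin ISO-8601 UTC timestamp of experiment-clock midnight, day 0
#' @param solarNoon clock time of solar noon, hours
#' @return validated list of class \code{"ExperimentConfig"}
#' @export
experimentConfig <- function(design = c("LD_DD", "DD_only"),
                             photoperiod = 5.5, daysLD = 3, daysDD = 5,
                             binWidth = 10, smoothLD = 6, smoothDD = 24,
                             periodRange = c(8, 32), ofac = 4,
                             criteria = rhythmCriteria(), seed = 1L,
                             origin = "2021-05-31T00:00:00",
                             solarNoon = 12) {
  design <- match.arg(design)
  cfg <- list(design = design, photoperiod = photoperiod,
              daysLD = as.integer(daysLD), daysDD = as.integer(daysDD),
              binWidth = binWidth, smoothLD = smoothLD, smoothDD = smoothDD,
              periodRange = periodRange, ofac = ofac, criteria = criteria,
              seed = as.integer(seed), origin = origin,
              solarNoon = solarNoon)
  class(cfg) <- "ExperimentConfig"
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  problems <- character()
  if (cfg$design == "DD_only" && cfg$daysLD != 0)
    problems <- c(problems, "design DD_only requires daysLD = 0")
  if (cfg$design == "LD_DD" && cfg$daysLD < 1)
    problems <- c(problems, "design LD_DD requires daysLD >= 1")
  if (cfg$daysDD < 0 || cfg$daysLD < 0)
    problems <- c(problems, "day counts must be >= 0")
  if (cfg$binWidth <= 0 || 60 %% cfg$binWidth != 0)
    problems <- c(problems, "binWidth must divide 60")
  if (cfg$smoothLD < 1 || cfg$smoothDD < 1)
    problems <- c(problems, "smoothing windows must be >= 1 point")
  cr <- cfg$criteria
  if (cr$periodMin <= 0 || cr$periodMax <= cr$periodMin ||
      cr$minPower <= 0 || cr$alpha <= 0 || cr$alpha >= 1)
    problems <- c(problems, "rhythm criteria thresholds must be positive")
  if (length(problems))
    stop("invalid experiment configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(cfg)
}

#' @describeIn experimentConfig read a configuration from a JSON document
#' @param path JSON file path
#' @export
readExperimentConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  crit <- if (is.null(raw$criteria)) rhythmCriteria() else
    do.call(rhythmCriteria,
            raw$criteria[intersect(names(raw$criteria),
                                   c("periodMin", "periodMax", "minPower",
                                     "alpha"))])
  args <- raw[intersect(names(raw),
                        c("design", "photoperiod", "daysLD", "daysDD",
                          "binWidth", "smoothLD", "smoothDD", "periodRange",
                          "ofac", "seed", "origin", "solarNoon"))]
  args$criteria <- crit
  do.call(experimentConfig, args)
}

#' @describeIn experimentConfig write a configuration as JSON
#' @param cfg an \code{ExperimentConfig}
#' @export
writeExperimentConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

configOrigin <- function(cfg) as.POSIXct(cfg$origin, tz = "UTC",
  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))

# process raw events into the full assay chain for a configured experiment
processEvents <- function(cfg, events, truncateDays = NULL) {
  origin <- configOrigin(cfg)
  days <- cfg$daysLD + cfg$daysDD
  span <- c(origin, origin + days * 86400)
  ddOnset <- if (cfg$daysDD > 0) 24 * cfg$daysLD else NULL
  cols <- sort(unique(events$column_id))
  if (length(cols) == 0) stop("event stream contains no columns")
  upward <- extractUpward(sortEvents(events))
  ae <- binCounts(upward, binWidth = cfg$binWidth, span = span,
                  origin = origin, ddOnset = ddOnset, columns = cols)
  if (!is.null(truncateDays))
    ae <- ae[rowData(ae)$time_h < 24 * truncateDays, ]
  ae <- normalizeActivity(ae)
  ae <- smoothActivity(ae, windowLD = cfg$smoothLD, windowDD = cfg$smoothDD)
  detrendActivity(ae)
}

runCore <- function(cfg, ae) {
  cls <- classifyGroup(ae, assay = "detrended", phase = "DD",
                       periodRange = cfg$periodRange, ofac = cfg$ofac,
                       criteria = cfg$criteria)
  corrected <- NULL; profile <- NULL; avgDD <- NULL
  if (any(cls$is_rhythmic)) {
    corrected <- frpCorrectGroup(ae, cls, assay = "detrended")
    profile <- groupMean(corrected, binWidth = cfg$binWidth,
                         smoothWindow = cfg$smoothDD)
    avgDD <- averageDay(corrected, binWidth = cfg$binWidth,
                        smoothWindow = cfg$smoothDD)
  } else {
    message("no rhythmic individuals: FRP-corrected group profiles skipped")
  }
  amps <- dailyAmplitudes(ae, assay = "detrended")
  list(classification = cls, corrected = corrected, groupProfile = profile,
       averageDayDD = avgDD, amplitudes = amps)
}

writeBundle <- function(bundle, cfg, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) if (!is.null(x))
    utils::write.csv(as.data.frame(x), file.path(outDir, f),
                     row.names = FALSE)
  wcsv(activityLong(bundle$activity, "detrended"), "activity_detrended.csv")
  wcsv(bundle$classification, "rhythm.csv")
  wcsv(bundle$groupProfile, "group_profile.csv")
  wcsv(bundle$averageDayDD, "average_day_dd.csv")
  wcsv(bundle$averageDayLD, "average_day_ld.csv")
  wcsv(bundle$amplitudes, "amplitudes.csv")
  if (!is.null(bundle$amplitudeTests))
    jsonlite::write_json(bundle$amplitudeTests,
                         file.path(outDir, "amplitude_tests.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfgPath <- file.path(outDir, "config.json")
  writeExperimentConfig(cfg, cfgPath)
  prov <- list(
    package = "krillclock",
    version = as.character(utils::packageVersion("krillclock")),
    config_md5 = unname(tools::md5sum(cfgPath)),
    written = names(Filter(Negate(is.null), bundle)))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Run the light-dark / constant-darkness experiment pipeline
#'
#' Full analysis of an LD-DD design: upward-movement extraction, binning,
#' normalization, phase-specific smoothing, detrending; rhythmicity
#' classification on the detrended DD segment; FRP correction of the
#' rhythmic individuals and group-mean and average-day profiles; daily
#' amplitudes and the LD-vs-DD and first-vs-last-DD-day amplitude tests.
#'
#' @param cfg an \code{ExperimentConfig} with design \code{"LD_DD"}
#' @param events raw beam-break event data.frame
#' @param outDir if non-NULL, all artifacts are written there (CSV/JSON)
#' @return list with \code{activity} (the processed
#'   \linkS4class{ActivityExperiment}), \code{classification},
#'   \code{corrected}, \code{groupProfile}, \code{averageDayLD},
#'   \code{averageDayDD}, \code{amplitudes}, \code{amplitudeTests}
#' @export
runExperiment1 <- function(cfg, events, outDir = NULL) {
  validateConfig(cfg)
  if (cfg$design != "LD_DD")
    stop("runExperiment1 requires an LD_DD design configuration")
  ae <- processEvents(cfg, events)
  core <- runCore(cfg, ae)
  avgLD <- averageDay(activityLong(ae, "smoothed", phase = "LD"),
                      binWidth = cfg$binWidth, smoothWindow = cfg$smoothLD)
  atests <- tryCatch(amplitudeTests(core$amplitudes), error = function(e) {
    message("amplitude tests skipped: ", conditionMessage(e)); NULL
  })
  bundle <- c(list(activity = ae), core,
              list(averageDayLD = avgLD, amplitudeTests = atests))
  if (!is.null(outDir)) writeBundle(bundle, cfg, outDir)
  bundle
}

#' Run the constant-darkness (seasonal) experiment pipeline
#'
#' Same processing as \code{\link{runExperiment1}} but for a DD-only design:
#' each series is truncated to the first \code{analysisDays} days before
#' classification and group/average-day analysis, to limit the influence of
#' amplitude damping late in the recording.
#'
#' @inheritParams runExperiment1
#' @param cfg an \code{ExperimentConfig} with design \code{"DD_only"}
#' @param analysisDays days of recording analysed (default 4); if the
#'   recording is shorter, the available span is used with a warning
#' @return list as in \code{\link{runExperiment1}} minus the LD average day
#'   and amplitude tests (no LD phase is present)
#' @export
runExperiment2 <- function(cfg, events, analysisDays = 4, outDir = NULL) {
  validateConfig(cfg)
  if (cfg$design != "DD_only")
    stop("runExperiment2 requires a DD_only design configuration")
  if (analysisDays < 1) stop("'analysisDays' must be >= 1")
  if (analysisDays > cfg$daysDD) {
    warning(sprintf("recording covers %d day(s) < analysisDays = %d; %s",
                    cfg$daysDD, analysisDays, "using the available span"))
    analysisDays <- cfg$daysDD
  }
  ae <- processEvents(cfg, events, truncateDays = analysisDays)
  core <- runCore(cfg, ae)
  bundle <- c(list(activity = ae), core,
              list(averageDayLD = NULL, amplitudeTests = NULL))
  if (!is.null(outDir)) writeBundle(bundle, cfg, outDir)
  bundle
}

# the packaged simulation scenarios: the two LD-DD treatments and the four
# field-entrained seasonal DD treatments (natural photoperiod sets the
# entrained bout phases; evening bout 1.25 h after lights-off)
fixtureScenarios <- function() {
  seas <- function(name, photo) {
    list(name = name, design = "DD_only", photoperiod = photo, n = 10,
         daysLD = 0, daysDD = 5)
  }
  list(
    list(name = "exp1_shortday", design = "LD_DD", photoperiod = 5.5,
         n = 11, daysLD = 3, daysDD = 5),
    list(name = "exp1_longday", design = "LD_DD", photoperiod = 15,
         n = 9, daysLD = 5, daysDD = 5),
    seas("exp2_summer", 17.5), seas("exp2_latesummer", 14.0),
    seas("exp2_autumn", 12.6), seas("exp2_winter", 5.9))
}

# evening bout tracks lights-off (1.25 h after it); the late-night bout sits
# at a season-stable clock time, as observed across the seasonal treatments
scenarioParams <- function(sc, seed) {
  off <- 12 + sc$photoperiod / 2
  simulationParams(phaseEvening = ((off + 1.25) %% 24) / 24,
                   phaseLateNight = 3.5 / 24, seed = seed)
}

#' Generate the packaged synthetic fixture battery
#'
#' Writes one deterministic synthetic data set per scenario (short-day and
#' long-day LD-DD treatments; summer, late-summer, autumn and winter
#' DD-only treatments): raw events (\code{events.csv}), ground-truth
#' transit counts (\code{truth_counts.csv}) and the experiment
#' configuration (\code{config.json}), plus a \code{checksums.json} of md5
#' sums over all files.  Identical seeds give identical checksums.
#'
#' @param dir output directory (one subdirectory per scenario)
#' @param seed master seed
#' @param scenarios names of scenarios to build (default: all six)
#' @return named list of per-file md5 checksums, invisibly written to
#'   \code{checksums.json}
#' @export
makeFixtures <- function(dir, seed = 1L,
                         scenarios = vapply(fixtureScenarios(), `[[`, "",
                                            "name")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sums <- list()
  for (sc in fixtureScenarios()) {
    if (!sc$name %in% scenarios) next
    sdir <- file.path(dir, sc$name)
    dir.create(sdir, showWarnings = FALSE)
    params <- scenarioParams(sc, seed)
    regime <- lightRegime(if (sc$design == "LD_DD") sc$photoperiod else 0)
    sim <- simulateCohort(sc$n, params, regime, daysLD = sc$daysLD,
                          daysDD = sc$daysDD, seed = seed)
    writeEvents(sim$events, file.path(sdir, "events.csv"))
    tl <- activityLong(sim$truth, "counts")
    utils::write.csv(
      data.frame(individual_id = tl$individual_id,
                 bin_start = format(metadata(sim$truth)$origin +
                                      tl$time_h * 3600,
                                    "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                 count = tl$value),
      file.path(sdir, "truth_counts.csv"), row.names = FALSE, quote = FALSE)
    cfg <- experimentConfig(design = sc$design,
                            photoperiod = if (sc$design == "LD_DD")
                              sc$photoperiod else 0,
                            daysLD = sc$daysLD, daysDD = sc$daysDD,
                            seed = seed)
    writeExperimentConfig(cfg, file.path(sdir, "config.json"))
    fl <- list.files(sdir, full.names = TRUE)
    sums[[sc$name]] <- as.list(stats::setNames(unname(tools::md5sum(fl)),
                                               basename(fl)))
  }
  jsonlite::write_json(sums, file.path(dir, "checksums.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sums)
}
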