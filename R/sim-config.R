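## Frozen moments of a Brief COPE scale score under the generator's item
## model (two items per scale, latent normal trait, within-pair latent
## correlation 0.6, quartile cutpoints -> items uniform on 1..4). Estimated
## once from 2e6 Monte Carlo draws; used to standardise the designated scale
## when modulating injected deviation magnitudes.
.copeScaleMean <- 5
.copeScaleSd <- 1.957

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions a generated cohort emulates: one year of
#' daily wearable streams per participant with day-of-week seasonality,
#' stationary lag-1 autocorrelated noise, day-level missingness, and -- for
#' responders -- an event-triggered step deviation decaying exponentially
#' over about two weeks, whose magnitude is modulated by a designated coping
#' scale.
#'
#' Defaults mirror the observable structure of the study this package
#' models: 45 participants followed for 365 days; resting heart rate around
#' 65 bpm, MVPA around 30 min/day, sleep around 7.5 h/night; weak day-of-week
#' effects (each summing to zero across the week, keeping the seasonal
#' component identifiable); lag-1 autocorrelation 0.3; about 62% responders
#' (28 of 45); injected deviations of roughly two marginal noise sds per
#' stream, halving every 7 days.
#'
#' @param nParticipants Number of participants.
#' @param studyDays Days of observation per participant.
#' @param startDate First calendar day of the study.
#' @param baselineMean,baselineSd Per-stream mean and between-participant sd
#'   of the baseline level, named `rhr` (bpm), `mvpa` (min), `sleep` (h).
#' @param weekdayEffect 7 x 3 matrix (rows Monday..Sunday, columns
#'   rhr/mvpa/sleep) of additive seasonal effects; each column must sum to 0.
#' @param arCoef Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param noiseSd Per-stream *marginal* (stationary) sd of the AR(1) noise;
#'   innovation sd is `noiseSd * sqrt(1 - arCoef^2)`.
#' @param crossStreamCor Correlation of innovations across streams
#'   (default 0: independent streams; nonzero values for stress tests).
#' @param responderFraction Probability that a participant's PB-state
#'   actually deviates after their event.
#' @param eventDayRange Integer interval for the index-event day; must leave
#'   at least 60 days before and 15 days (including the event day) after.
#' @param deviationMagnitude Per-stream deviation applied on the event day
#'   (stream units; sign free).
#' @param decayHalflifeDays Half-life of the exponential decay of the
#'   deviation, in days.
#' @param copeEffect Log-scale coefficient linking the standardized
#'   designated coping-scale score to deviation magnitude: magnitudes are
#'   scaled by `exp(copeEffect * z)`.
#' @param copeScale Name of the designated Brief COPE scale (one of
#'   `names(briefCopeKey())`).
#' @param missingDayRate Fraction of days where the device was effectively
#'   unworn: wear hours below 19 and all three stream values absent.
#' @param lowWearRate Fraction of days worn only part of the day: wear hours
#'   below 19 but stream values still recorded (non-compliant yet observed).
#' @param plantedFailureRates Named numeric vector with entries `valence`,
#'   `significance`, `confidence`, `cope`: fractions of participants whose
#'   index event (or COPE survey) is planted to fail the corresponding
#'   eligibility rule, making filter tests non-trivial. At most one failure
#'   is planted per participant.
#' @param extraEventRate Expected number of additional, always-ineligible
#'   (positive-valence) reported events per participant; these thin the
#'   no-event blocks available to the bootstrap null.
#' @param seed Integer seed from which all generator randomness derives.
#' @return A validated `SimConfig` (list).
#' @examples
#' cfg <- simConfig(nParticipants = 5, studyDays = 120,
#'                  eventDayRange = c(61, 100))
#' @export
simConfig <- function(nParticipants = 45,
                      studyDays = 365,
                      startDate = as.Date("2018-01-01"),
                      baselineMean = c(rhr = 65, mvpa = 30, sleep = 7.5),
                      baselineSd = c(rhr = 7, mvpa = 10, sleep = 0.7),
                      weekdayEffect = defaultWeekdayEffect(),
                      arCoef = 0.3,
                      noiseSd = c(rhr = 2.5, mvpa = 15, sleep = 0.9),
                      crossStreamCor = 0,
                      responderFraction = 28 / 45,
                      eventDayRange = c(100, 280),
                      deviationMagnitude = c(rhr = 5, mvpa = -25, sleep = -1.5),
                      decayHalflifeDays = 7,
                      copeEffect = -0.25,
                      copeScale = "active_coping",
                      missingDayRate = 0.05,
                      lowWearRate = 0.02,
                      plantedFailureRates = c(valence = 0, significance = 0,
                                              confidence = 0, cope = 0),
                      extraEventRate = 1,
                      seed = 1L) {
  cfg <- list(nParticipants = as.integer(nParticipants),
              studyDays = as.integer(studyDays),
              startDate = as.Date(startDate),
              baselineMean = baselineMean, baselineSd = baselineSd,
              weekdayEffect = weekdayEffect, arCoef = arCoef,
              noiseSd = noiseSd, crossStreamCor = crossStreamCor,
              responderFraction = responderFraction,
              eventDayRange = as.integer(eventDayRange),
              deviationMagnitude = deviationMagnitude,
              decayHalflifeDays = decayHalflifeDays,
              copeEffect = copeEffect, copeScale = copeScale,
              missingDayRate = missingDayRate, lowWearRate = lowWearRate,
              plantedFailureRates = plantedFailureRates,
              extraEventRate = extraEventRate,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' @rdname simConfig
#' @export
defaultWeekdayEffect <- function() {
  m <- cbind(rhr = c(0.3, 0.2, 0.1, 0, -0.1, -0.3, -0.2),
             mvpa = c(-2, -2, -2, -2, -2, 5, 5),
             sleep = c(-0.1, -0.1, -0.1, -0.1, -0.1, 0.25, 0.25))
  rownames(m) <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  m
}

validateSimConfig <- function(cfg) {
  st <- streamNames()
  if (cfg$nParticipants < 0) stop("nParticipants must be >= 0", call. = FALSE)
  for (f in c("baselineMean", "baselineSd", "noiseSd", "deviationMagnitude"))
    if (!all(st %in% names(cfg[[f]])))
      stop(sprintf("'%s' needs named entries %s", f,
                   paste(st, collapse = ", ")), call. = FALSE)
  if (any(cfg$baselineSd < 0) || any(cfg$noiseSd < 0))
    stop("sds must be non-negative", call. = FALSE)
  if (cfg$decayHalflifeDays <= 0)
    stop("decayHalflifeDays must be positive", call. = FALSE)
  assertScalarIn(cfg$arCoef, 0, 1, "arCoef", hiOpen = TRUE)
  assertScalarIn(cfg$responderFraction, 0, 1, "responderFraction")
  assertScalarIn(cfg$missingDayRate, 0, 1, "missingDayRate")
  assertScalarIn(cfg$lowWearRate, 0, 1, "lowWearRate")
  assertScalarIn(cfg$crossStreamCor, -1, 1, "crossStreamCor",
                 loOpen = TRUE, hiOpen = TRUE)
  we <- cfg$weekdayEffect
  if (!is.matrix(we) || nrow(we) != 7 || !all(st %in% colnames(we)))
    stop("weekdayEffect must be a 7 x 3 matrix with columns rhr/mvpa/sleep",
         call. = FALSE)
  if (any(abs(colSums(we[, st])) > 1e-8))
    stop("weekdayEffect columns must each sum to 0 (identifiable seasonality)",
         call. = FALSE)
  r <- cfg$eventDayRange
  if (length(r) != 2 || r[1] > r[2])
    stop("eventDayRange must be an increasing day-index interval",
         call. = FALSE)
  ## windows need 60 days before the event and 15 (incl. event day) after
  if (r[1] < 61 || r[2] > cfg$studyDays - 14)
    stop(sprintf(paste("eventDayRange must lie in [61, %d] so every event",
                       "leaves >= 60 prior and >= 15 posterior days"),
                 cfg$studyDays - 14L), call. = FALSE)
  pf <- cfg$plantedFailureRates
  need <- c("valence", "significance", "confidence", "cope")
  if (!all(need %in% names(pf)) || any(pf < 0) || sum(pf[need]) > 1)
    stop("plantedFailureRates needs valence/significance/confidence/cope,",
         " each >= 0, summing to <= 1", call. = FALSE)
  if (!cfg$copeScale %in% names(briefCopeKey()))
    stop("copeScale must be one of names(briefCopeKey())", call. = FALSE)
  invisible(cfg)
}
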