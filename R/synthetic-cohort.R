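#' Simulate one participant's daily three-stream series
#'
#' Builds a `studyDays`-long daily series per stream as
#' `baseline level + weekday effect + stationary AR(1) noise`, plus -- when
#' the participant is a responder -- an event-triggered deviation
#' `magnitude * 2^(-(d - eventDay)/halflife)` from the event day onward.
#' The injected magnitude is the configured per-stream deviation scaled by
#' `exp(copeEffect * z)` where `z` is the participant's standardized
#' designated coping-scale score, so that better copers deviate less when
#' `copeEffect < 0`. Sleep and MVPA are floored at zero (clips are counted
#' in the `nClipped` attribute of the series).
#'
#' @param config A [simConfig()].
#' @param participantId Identifier stored in the ground truth.
#' @param seed Integer seed for this participant.
#' @return list with `series` (data.frame: `day`, `date`, `weekday`, `rhr`,
#'   `mvpa`, `sleep`) and `truth` (list: `participant_id`, `is_responder`,
#'   `event_day`, `injected_magnitudes`, `cope_scores`, `cope_items`,
#'   `cluster_label_true`).
#' @examples
#' cfg <- simConfig(nParticipants = 1, studyDays = 120,
#'                  eventDayRange = c(61, 100))
#' ps <- simulateParticipantSeries(cfg, "P001", seed = 7)
#' head(ps$series)
#' @export
simulateParticipantSeries <- function(config, participantId, seed) {
  validateSimConfig(config)
  st <- streamNames()
  nd <- config$studyDays
  oldSeed <- globalSeedState()
  on.exit(restoreSeedState(oldSeed), add = TRUE)
  set.seed(seed)

  dates <- config$startDate + seq_len(nd) - 1
  wd <- as.integer(format(dates, "%u"))

  level <- config$baselineMean[st] + stats::rnorm(3) * config$baselineSd[st]

  ## stationary AR(1) noise; noiseSd is the marginal sd
  phi <- config$arCoef
  innovSd <- config$noiseSd[st] * sqrt(1 - phi^2)
  innov <- matrix(stats::rnorm(nd * 3), nd, 3)
  if (config$crossStreamCor != 0) {
    S <- matrix(config$crossStreamCor, 3, 3); diag(S) <- 1
    innov <- innov %*% chol(S)
  }
  innov <- sweep(innov, 2, innovSd, "*")
  noise <- matrix(0, nd, 3)
  noise[1, ] <- stats::rnorm(3) * config$noiseSd[st]
  for (d in 2:nd) noise[d, ] <- phi * noise[d - 1, ] + innov[d, ]

  isResponder <- stats::runif(1) < config$responderFraction
  eventDay <- if (config$eventDayRange[1] == config$eventDayRange[2])
    config$eventDayRange[1]
  else sample(config$eventDayRange[1]:config$eventDayRange[2], 1)

  copeItems <- simulateCopeItems(1)
  copeScores <- scoreBriefCope(copeItems)[1, ]
  zCope <- (copeScores[[config$copeScale]] - .copeScaleMean) / .copeScaleSd

  mag <- if (isResponder)
    config$deviationMagnitude[st] * exp(config$copeEffect * zCope)
  else c(rhr = 0, mvpa = 0, sleep = 0)

  dev <- matrix(0, nd, 3)
  if (isResponder) {
    d <- eventDay:nd
    decay <- 2^(-(d - eventDay) / config$decayHalflifeDays)
    dev[d, ] <- outer(decay, mag)
  }

  vals <- sweep(noise + dev, 2, level + 0, "+") +
    config$weekdayEffect[wd, st]
  colnames(vals) <- st
  nClipped <- sum(vals[, c("mvpa", "sleep")] < 0)
  vals[, "mvpa"] <- pmax(vals[, "mvpa"], 0)
  vals[, "sleep"] <- pmax(vals[, "sleep"], 0)

  series <- data.frame(day = seq_len(nd), date = dates, weekday = wd,
                       rhr = vals[, "rhr"], mvpa = vals[, "mvpa"],
                       sleep = vals[, "sleep"])
  attr(series, "nClipped") <- nClipped
  truth <- list(participant_id = participantId,
                is_responder = isResponder,
                event_day = eventDay,
                injected_magnitudes = mag,
                cope_scores = unlist(copeScores),
                cope_items = as.integer(copeItems[1, ]),
                cluster_label_true = as.integer(isResponder))
  list(series = series, truth = truth)
}

## Draw n participants' 28 Brief COPE item responses. The two items of each
## scale share a latent trait (latent correlation 0.6) discretised at
## quartile cutpoints, so scale scoring is meaningful.
simulateCopeItems <- function(n) {
  key <- briefCopeKey()
  items <- matrix(NA_integer_, n, 28,
                  dimnames = list(NULL, paste0("item_", 1:28)))
  cuts <- stats::qnorm(c(0.25, 0.5, 0.75))
  for (scale in names(key)) {
    z <- stats::rnorm(n)
    for (j in key[[scale]]) {
      u <- sqrt(0.6) * z + sqrt(0.4) * stats::rnorm(n)
      items[, j] <- findInterval(u, cuts) + 1L
    }
  }
  items
}

globalSeedState <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restoreSeedState <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Apply day-level missingness and wear-time to a simulated series
#'
#' Marks a `missingDayRate` fraction of days as effectively unworn (wear
#' hours drawn below 19, all three stream values removed) and a
#' `lowWearRate` fraction as worn only part of the day (wear below 19 but
#' values kept); all remaining days get wear hours in `[19, 24]`.
#'
#' @param series data.frame from [simulateParticipantSeries()].
#' @param config A [simConfig()].
#' @param seed Integer seed.
#' @return The series with a `wear` column and `NA` stream values on
#'   missing days.
#' @export
applyMissingness <- function(series, config, seed) {
  assertScalarIn(config$missingDayRate, 0, 1, "missingDayRate")
  assertScalarIn(config$lowWearRate, 0, 1, "lowWearRate")
  oldSeed <- globalSeedState()
  on.exit(restoreSeedState(oldSeed), add = TRUE)
  set.seed(seed)
  nd <- nrow(series)
  u <- stats::runif(nd)
  missing <- u < config$missingDayRate
  lowWear <- !missing & u < config$missingDayRate + config$lowWearRate
  wear <- stats::runif(nd, 19, 24)
  wear[missing | lowWear] <- stats::runif(sum(missing | lowWear), 2, 19 - 1e-6)
  series$wear <- wear
  series[missing, c("rhr", "mvpa", "sleep")] <- NA_real_
  series
}

#' Simulate the survey tables for a generated cohort
#'
#' Produces the life-event, Brief COPE and demographics tables consistent
#' with a set of participant ground truths. Each participant reports one
#' index event dated at their ground-truth event day; unless a failure was
#' planted, it is eligible (negative valence, at least high significance,
#' highest date confidence). Planted failures flip exactly one eligibility
#' rule so downstream consort counts are predictable. Additional
#' positive-valence (never eligible) events are added at rate
#' `extraEventRate` to thin the no-event blocks used by the bootstrap null.
#'
#' @param config A [simConfig()].
#' @param truths list of per-participant truth lists (see
#'   [simulateParticipantSeries()]).
#' @param seed Integer seed.
#' @return list with `events`, `cope`, `demographics` data.frames and
#'   `planted` (data.frame of per-participant planted failures, `"none"`
#'   when the index event is fully eligible).
#' @export
simulateSurveys <- function(config, truths, seed) {
  oldSeed <- globalSeedState()
  on.exit(restoreSeedState(oldSeed), add = TRUE)
  set.seed(seed)
  n <- length(truths)
  ids <- vapply(truths, `[[`, "", "participant_id")
  pf <- config$plantedFailureRates
  modes <- c("valence", "significance", "confidence", "cope", "none")
  planted <- if (n) sample(modes, n, replace = TRUE,
                           prob = c(pf["valence"], pf["significance"],
                                    pf["confidence"], pf["cope"],
                                    1 - sum(pf))) else character()

  descriptions <- c("death of a family member", "serious illness",
                    "financial issues", "marital problems",
                    "greatly increased work load", "injury")
  posDescriptions <- c("promotion at work", "birth of a child",
                       "bought a house", "family vacation")

  evList <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- truths[[i]]
    valence <- sample(6:7, 1)
    significance <- sample(6:7, 1)
    confidence <- 7L
    if (planted[i] == "valence") valence <- sample(1:4, 1)
    if (planted[i] == "significance") significance <- sample(1:5, 1)
    if (planted[i] == "confidence") confidence <- sample(1:6, 1)
    idx <- data.frame(participant_id = tr$participant_id,
                      event_date = config$startDate + tr$event_day - 1,
                      valence = valence, significance = significance,
                      date_confidence = confidence,
                      description = sample(descriptions, 1))
    nExtra <- stats::rpois(1, config$extraEventRate)
    if (nExtra > 0) {
      extra <- data.frame(participant_id = tr$participant_id,
                          event_date = config$startDate +
                            sample(seq_len(config$studyDays), nExtra) - 1,
                          valence = sample(1:3, nExtra, replace = TRUE),
                          significance = sample(1:7, nExtra, replace = TRUE),
                          date_confidence = sample(1:7, nExtra, replace = TRUE),
                          description = sample(posDescriptions, nExtra,
                                               replace = TRUE))
      idx <- rbind(idx, extra)
    }
    evList[[i]] <- idx
  }
  events <- if (n) do.call(rbind, evList) else
    data.frame(participant_id = character(), event_date = as.Date(character()),
               valence = integer(), significance = integer(),
               date_confidence = integer(), description = character())

  copeRows <- lapply(seq_len(n), function(i) {
    if (planted[i] == "cope") return(NULL)
    as.data.frame(c(list(participant_id = ids[i]),
                    as.list(stats::setNames(truths[[i]]$cope_items,
                                            paste0("item_", 1:28)))))
  })
  cope <- do.call(rbind, copeRows)
  if (is.null(cope))
    cope <- as.data.frame(c(list(participant_id = character()),
                            stats::setNames(rep(list(integer()), 28),
                                            paste0("item_", 1:28))))

  demographics <- data.frame(
    participant_id = ids,
    age = if (n) sample(23:63, n, replace = TRUE,
                        prob = stats::dnorm(23:63, 38, 10)) else integer(),
    gender = if (n) sample(c("female", "male"), n, replace = TRUE,
                           prob = c(0.57, 0.43)) else character())

  list(events = events, cope = cope, demographics = demographics,
       planted = data.frame(participant_id = ids,
                            planted_failure = planted))
}

#' Generate a full synthetic cohort
#'
#' Runs the per-participant series simulator, missingness model and survey
#' simulator under seeds derived from `config$seed`, assembles everything
#' into a [WearableCohort-class] carrying its ground truth, and (optionally)
#' writes the CSV bundle plus `truth.json` to disk. Identical config and
#' seed give byte-identical files.
#'
#' @param config A [simConfig()].
#' @param dir Optional output directory for the CSV bundle.
#' @return A [WearableCohort-class]; its `cohortTruth()` is a data.frame
#'   with one row per participant (responder flag, event day, injected
#'   magnitudes, the 14 scale scores, true cluster label, planted failure).
#' @examples
#' wc <- generateCohort(simConfig(nParticipants = 3, studyDays = 120,
#'                                eventDayRange = c(61, 100)))
#' cohortTruth(wc)[, c("participant_id", "is_responder", "event_day")]
#' @export
generateCohort <- function(config, dir = NULL) {
  validateSimConfig(config)
  n <- config$nParticipants
  ids <- sprintf("P%03d", seq_len(n))
  sims <- lapply(seq_len(n), function(i)
    simulateParticipantSeries(config, ids[i],
                              deriveSeed(config$seed, paste0("series", i))))
  dailyList <- lapply(seq_len(n), function(i) {
    s <- applyMissingness(sims[[i]]$series, config,
                          deriveSeed(config$seed, paste0("wear", i)))
    data.frame(participant_id = ids[i], date = s$date, rhr_bpm = s$rhr,
               mvpa_min = s$mvpa, sleep_h = s$sleep, wear_hours = s$wear)
  })
  daily <- if (n) do.call(rbind, dailyList) else
    data.frame(participant_id = character(), date = as.Date(character()),
               rhr_bpm = numeric(), mvpa_min = numeric(), sleep_h = numeric(),
               wear_hours = numeric())
  truths <- lapply(sims, `[[`, "truth")
  sv <- simulateSurveys(config, truths, deriveSeed(config$seed, "surveys"))

  truthDf <- do.call(rbind, lapply(truths, function(tr) {
    d <- data.frame(participant_id = tr$participant_id,
                    is_responder = tr$is_responder,
                    event_day = tr$event_day,
                    injected_rhr = tr$injected_magnitudes[["rhr"]],
                    injected_mvpa = tr$injected_magnitudes[["mvpa"]],
                    injected_sleep = tr$injected_magnitudes[["sleep"]],
                    cluster_label_true = tr$cluster_label_true)
    for (nm in names(tr$cope_scores)) d[[paste0("cope_", nm)]] <-
        tr$cope_scores[[nm]]
    d
  }))
  if (is.null(truthDf))
    truthDf <- data.frame(participant_id = character(),
                          is_responder = logical(), event_day = integer(),
                          injected_rhr = numeric(), injected_mvpa = numeric(),
                          injected_sleep = numeric(),
                          cluster_label_true = integer())
  truthDf <- merge(truthDf, sv$planted, by = "participant_id",
                   all.x = TRUE, sort = TRUE)

  wc <- WearableCohort(daily, sv$events, sv$cope, sv$demographics,
                       truth = truthDf)
  if (!is.null(dir)) writeCohort(wc, dir)
  wc
}
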