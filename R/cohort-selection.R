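#' Eligibility thresholds for index life events
#'
#' Numeric realisation of the verbal eligibility rules: an event is eligible
#' when it is negative (valence strictly above the scale midpoint, i.e.
#' `>= 5` on the 1 = Extremely Positive .. 7 = Extremely Negative scale), of
#' at least high significance (`>= 6`), and dated with highest confidence
#' (`= 7`). All three cuts are configurable.
#'
#' @param valence Minimum valence for an event to count as negative.
#' @param significance Minimum significance.
#' @param confidence Required date confidence (exact match).
#' @return list of thresholds.
#' @export
eligibilityThresholds <- function(valence = 5, significance = 6,
                                  confidence = 7) {
  stopifnot(valence %in% 1:7, significance %in% 1:7, confidence %in% 1:7)
  list(valence = valence, significance = significance,
       confidence = confidence)
}

#' Wear-time compliance rule
#'
#' A day counts as worn when the device was on for at least
#' `minHoursPerDay` of 24 hours; a window is compliant when at least
#' `minDayFraction` of its days were worn.
#'
#' @param minDayFraction Minimum fraction of worn days per window.
#' @param minHoursPerDay Minimum wear hours for a day to count as worn.
#' @return list rule.
#' @export
complianceRule <- function(minDayFraction = 0.8, minHoursPerDay = 19) {
  assertScalarIn(minDayFraction, 0, 1, "minDayFraction")
  assertScalarIn(minHoursPerDay, 0, 24, "minHoursPerDay")
  list(minDayFraction = minDayFraction, minHoursPerDay = minHoursPerDay)
}

#' Score a single life event against the eligibility rules
#'
#' @param event One-row data.frame (or list) with `valence`, `significance`
#'   and `date_confidence`, each an integer in 1..7.
#' @param thresholds An [eligibilityThresholds()].
#' @return list with `eligible` (logical) and `reason` (`"eligible"`, or the
#'   first failed rule among `"valence"`, `"significance"`,
#'   `"date_confidence"`).
#' @examples
#' scoreEventEligibility(list(valence = 6, significance = 7,
#'                            date_confidence = 7))
#' @export
scoreEventEligibility <- function(event, thresholds = eligibilityThresholds()) {
  v <- c(event$valence, event$significance, event$date_confidence)
  if (length(v) != 3 || any(is.na(v)) || any(v < 1 | v > 7 | v != round(v)))
    stop("valence, significance and date_confidence must be integers in 1..7",
         call. = FALSE)
  if (event$valence < thresholds$valence)
    return(list(eligible = FALSE, reason = "valence"))
  if (event$significance < thresholds$significance)
    return(list(eligible = FALSE, reason = "significance"))
  if (event$date_confidence != thresholds$confidence)
    return(list(eligible = FALSE, reason = "date_confidence"))
  list(eligible = TRUE, reason = "eligible")
}

#' Select a participant's index event
#'
#' Returns the earliest eligible event (the first significant negative life
#' event); the analysis requires a unique index event, so two eligible
#' events sharing the earliest date disqualify the participant (an error,
#' caught and logged by [filterCohort()]).
#'
#' @param events data.frame of one participant's reported events.
#' @param thresholds An [eligibilityThresholds()].
#' @return One-row data.frame, or `NULL` when no event is eligible.
#' @export
selectIndexEvent <- function(events, thresholds = eligibilityThresholds()) {
  if (!nrow(events)) return(NULL)
  ok <- vapply(seq_len(nrow(events)), function(i)
    scoreEventEligibility(events[i, ], thresholds)$eligible, logical(1))
  if (!any(ok)) return(NULL)
  el <- events[ok, , drop = FALSE]
  el <- el[order(as.Date(el$event_date)), , drop = FALSE]
  first <- as.Date(el$event_date[1])
  if (sum(as.Date(el$event_date) == first) > 1)
    stop("tie: multiple eligible events on the same date", call. = FALSE)
  el[1, , drop = FALSE]
}

#' Assess wear compliance around an index event
#'
#' Counts worn days (wear hours at or above the rule's cutoff) separately in
#' the 60-day pre-event and 15-day post-event windows; the participant is
#' compliant when worn days reach `ceiling(0.8 * 60) = 48` pre and
#' `ceiling(0.8 * 15) = 12` post (with defaults).
#'
#' @param series Participant daily series (needs `day` and `wear`).
#' @param eventDay Day index of the index event.
#' @param spec A [windowSpec()].
#' @param rule A [complianceRule()].
#' @return list with `compliant`, `wornDaysPre`, `wornDaysPost`.
#' @export
assessWearCompliance <- function(series, eventDay, spec = windowSpec(),
                                 rule = complianceRule()) {
  lo <- eventDay - spec$preDays
  hi <- eventDay + spec$postDays - 1
  if (lo < min(series$day) || hi > max(series$day))
    stop(sprintf("coverage: window [%d, %d] extends beyond observed span",
                 lo, hi), call. = FALSE)
  wear <- series$wear[match(lo:hi, series$day)]
  worn <- !is.na(wear) & wear >= rule$minHoursPerDay
  pre <- sum(worn[seq_len(spec$preDays)])
  post <- sum(worn[spec$preDays + seq_len(spec$postDays)])
  needPre <- ceiling(rule$minDayFraction * spec$preDays)
  needPost <- ceiling(rule$minDayFraction * spec$postDays)
  list(compliant = pre >= needPre && post >= needPost,
       wornDaysPre = pre, wornDaysPost = post)
}

#' Consort-style cohort filtering
#'
#' Applies the eligibility stages in order: completed the life-event survey,
#' has a negative event, has one of at least high significance, has one with
#' highest date confidence, wear-compliant around the index event, and
#' completed all 28 COPE items. Each participant is excluded at the first
#' failing stage; the returned [CohortReport-class] records remaining counts
#' after each stage.
#'
#' @param cohort A [WearableCohort-class].
#' @param thresholds An [eligibilityThresholds()].
#' @param rule A [complianceRule()].
#' @param spec A [windowSpec()].
#' @return list with `eligible` (data.frame: `participant_id`, `event_date`,
#'   `event_day`, `valence`, `significance`) and `report`
#'   ([CohortReport-class]).
#' @examples
#' wc <- generateCohort(simConfig(nParticipants = 4, studyDays = 120,
#'                                eventDayRange = c(61, 100),
#'                                missingDayRate = 0, lowWearRate = 0))
#' filterCohort(wc)$report
#' @export
filterCohort <- function(cohort, thresholds = eligibilityThresholds(),
                         rule = complianceRule(), spec = windowSpec()) {
  ids <- participantIds(cohort)
  ev <- lifeEvents(cohort)
  cp <- copeItems(cohort)
  startDate <- if (nrow(cohort)) min(rowData(cohort)$date) else NA

  reason <- stats::setNames(rep(NA_character_, length(ids)), ids)
  index <- stats::setNames(vector("list", length(ids)), ids)

  passes <- function(p, stageThr) {
    pe <- ev[ev$participant_id == p, , drop = FALSE]
    nrow(pe) > 0 && any(vapply(seq_len(nrow(pe)), function(i) {
      e <- pe[i, ]
      e$valence >= stageThr$valence &&
        e$significance >= stageThr$significance &&
        (is.na(stageThr$confidence) || e$date_confidence ==
           thresholds$confidence)
    }, logical(1)))
  }

  for (p in ids) {
    pe <- ev[ev$participant_id == p, , drop = FALSE]
    if (!nrow(pe)) { reason[p] <- "no_life_event_survey"; next }
    if (!passes(p, list(valence = thresholds$valence, significance = 1,
                        confidence = NA))) {
      reason[p] <- "valence"; next
    }
    if (!passes(p, list(valence = thresholds$valence,
                        significance = thresholds$significance,
                        confidence = NA))) {
      reason[p] <- "significance"; next
    }
    if (!passes(p, list(valence = thresholds$valence,
                        significance = thresholds$significance,
                        confidence = thresholds$confidence))) {
      reason[p] <- "date_confidence"; next
    }
    idx <- tryCatch(selectIndexEvent(pe, thresholds), error = function(e) e)
    if (inherits(idx, "error")) {
      warning("participant ", p, " excluded: ", conditionMessage(idx),
              call. = FALSE)
      reason[p] <- "index_event_tie"; next
    }
    eventDay <- as.integer(as.Date(idx$event_date) - startDate) + 1L
    comp <- tryCatch(
      assessWearCompliance(participantSeries(cohort, p), eventDay, spec, rule),
      error = function(e) list(compliant = FALSE))
    if (!isTRUE(comp$compliant)) { reason[p] <- "wear_compliance"; next }
    pc <- cp[cp$participant_id == p, paste0("item_", 1:28), drop = FALSE]
    if (nrow(pc) != 1 || anyNA(unlist(pc))) { reason[p] <- "cope_incomplete"; next }
    index[[p]] <- data.frame(participant_id = p,
                             event_date = as.Date(idx$event_date),
                             event_day = eventDay,
                             valence = idx$valence,
                             significance = idx$significance)
  }

  stageOrder <- c("no_life_event_survey", "valence", "significance",
                  "date_confidence", "index_event_tie", "wear_compliance",
                  "cope_incomplete")
  stageLabels <- c("enrolled", "life-event survey completed",
                   "has negative event", "at least high significance",
                   "highest date confidence", "unique index event",
                   "wear compliant", "COPE completed")
  remaining <- length(ids)
  counts <- remaining
  for (s in stageOrder) {
    remaining <- remaining - sum(reason == s, na.rm = TRUE)
    counts <- c(counts, remaining)
  }
  excl <- data.frame(participant_id = names(reason)[!is.na(reason)],
                     reason = reason[!is.na(reason)], row.names = NULL)
  report <- new("CohortReport",
                stages = data.frame(stage = stageLabels, remaining = counts),
                exclusions = excl)
  eligible <- do.call(rbind, index[!vapply(index, is.null, logical(1))])
  if (is.null(eligible))
    eligible <- data.frame(participant_id = character(),
                           event_date = as.Date(character()),
                           event_day = integer(), valence = integer(),
                           significance = integer())
  rownames(eligible) <- NULL
  list(eligible = eligible, report = report)
}
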