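#' Construct a WearableCohort from tidy tables
#'
#' Assembles the four input tables (daily streams, life events, Brief COPE
#' items, demographics) into a [WearableCohort-class] object. The daily table
#' is pivoted into day-by-participant assay matrices; every participant is
#' expected to cover the same calendar span (missing days are filled with
#' `NA` values and zero wear).
#'
#' @param daily data.frame with columns `participant_id`, `date`
#'   (ISO-8601 or `Date`), `rhr_bpm`, `mvpa_min`, `sleep_h`, `wear_hours`.
#' @param events data.frame with `participant_id`, `event_date`, `valence`,
#'   `significance`, `date_confidence`, `description`.
#' @param cope data.frame with `participant_id`, `item_1` .. `item_28`.
#' @param demographics data.frame with `participant_id`, `age`, `gender`.
#' @param truth optional generator ground truth (synthetic cohorts only).
#' @return A [WearableCohort-class] object.
#' @examples
#' cfg <- simConfig(nParticipants = 2, studyDays = 90,
#'                  eventDayRange = c(61, 75))
#' wc <- generateCohort(cfg)
#' wc
#' @export
WearableCohort <- function(daily, events, cope, demographics, truth = NULL) {
  stopifnot(is.data.frame(daily),
            all(c("participant_id", "date", "rhr_bpm", "mvpa_min",
                  "sleep_h", "wear_hours") %in% names(daily)))
  daily$date <- as.Date(daily$date)
  ids <- sort(unique(as.character(demographics$participant_id)))
  dates <- if (nrow(daily)) seq(min(daily$date), max(daily$date), by = "day")
           else as.Date(character())
  mk <- function(col) {
    m <- matrix(NA_real_, nrow = length(dates), ncol = length(ids),
                dimnames = list(format(dates), ids))
    if (nrow(daily)) {
      i <- match(daily$date, dates)
      j <- match(as.character(daily$participant_id), ids)
      keep <- !is.na(j)
      m[cbind(i[keep], j[keep])] <- as.numeric(daily[[col]][keep])
    }
    m
  }
  a <- SimpleList(rhr = mk("rhr_bpm"), mvpa = mk("mvpa_min"),
                  sleep = mk("sleep_h"), wear = mk("wear_hours"))
  a$wear[is.na(a$wear)] <- 0
  rd <- DataFrame(date = dates,
                  weekday = if (length(dates))
                    as.integer(format(dates, "%u")) else integer(0))
  cd <- DataFrame(row.names = ids)
  dm <- demographics[match(ids, as.character(demographics$participant_id)), ,
                     drop = FALSE]
  cd$age <- as.numeric(dm$age)
  cd$gender <- as.character(dm$gender)
  ev <- as.data.frame(events)
  if (nrow(ev)) ev$event_date <- as.Date(ev$event_date)
  se <- SummarizedExperiment(assays = a, rowData = rd, colData = cd)
  new("WearableCohort", se, events = ev, cope = as.data.frame(cope),
      truth = truth)
}

#' Accessors for WearableCohort components
#'
#' `wearHours()` returns the day-by-participant wear-time matrix,
#' `lifeEvents()` the reported life-event table, `copeItems()` the Brief COPE
#' item table, `cohortTruth()` the synthetic ground truth (or `NULL`), and
#' `participantIds()` the participant identifiers.
#'
#' @param x A [WearableCohort-class].
#' @return See individual descriptions.
#' @name WearableCohort-accessors
#' @aliases wearHours lifeEvents copeItems cohortTruth participantIds
NULL

#' @rdname WearableCohort-accessors
#' @export
setMethod("wearHours", "WearableCohort", function(x) assay(x, "wear"))

#' @rdname WearableCohort-accessors
#' @export
setMethod("lifeEvents", "WearableCohort", function(x) x@events)

#' @rdname WearableCohort-accessors
#' @export
setMethod("copeItems", "WearableCohort", function(x) x@cope)

#' @rdname WearableCohort-accessors
#' @export
setMethod("cohortTruth", "WearableCohort", function(x) x@truth)

#' @rdname WearableCohort-accessors
#' @export
setMethod("participantIds", "WearableCohort", function(x) colnames(x))

#' Extract one participant's daily series
#'
#' Returns a per-day data.frame for a single participant with day index
#' (1-based from study start), calendar date, weekday (1 = Monday), the three
#' streams and wear hours. This is the working format consumed by the
#' windowing, scoring and null-validation stages.
#'
#' @param x A [WearableCohort-class].
#' @param id Participant identifier.
#' @return data.frame with columns `day`, `date`, `weekday`, `rhr`, `mvpa`,
#'   `sleep`, `wear`.
#' @name participantSeries
#' @export
setMethod("participantSeries", "WearableCohort", function(x, id) {
  id <- as.character(id)
  if (!id %in% colnames(x)) stop("unknown participant: ", id, call. = FALSE)
  data.frame(day = seq_len(nrow(x)),
             date = rowData(x)$date,
             weekday = rowData(x)$weekday,
             rhr = assay(x, "rhr")[, id],
             mvpa = assay(x, "mvpa")[, id],
             sleep = assay(x, "sleep")[, id],
             wear = assay(x, "wear")[, id],
             row.names = NULL)
})

setMethod("show", "WearableCohort", function(object) {
  cat("WearableCohort:", ncol(object), "participants x", nrow(object),
      "days\n")
  cat("  assays:", paste(names(assays(object)), collapse = ", "), "\n")
  cat("  life events reported:", nrow(object@events), "\n")
  cat("  COPE surveys:", nrow(object@cope), "\n")
  cat("  synthetic truth:", if (is.null(object@truth)) "none" else "present",
      "\n")
})

setMethod("show", "CohortReport", function(object) {
  cat("CohortReport (consort-style filtering)\n")
  st <- object@stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-28s %d\n", st$stage[i], st$remaining[i]))
})

#' Read / write a cohort as CSV files
#'
#' `readCohort()` loads `daily.csv`, `events.csv`, `cope.csv` and
#' `demographics.csv` (plus `truth.json` when present) from a directory;
#' `writeCohort()` writes them. Empty CSV fields encode missing values.
#'
#' @param dir Directory path.
#' @param x A [WearableCohort-class].
#' @return `readCohort()`: a [WearableCohort-class]. `writeCohort()`: the
#'   directory path, invisibly.
#' @export
readCohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    as.data.frame(jsonlite::fromJSON(truthPath)) else NULL
  WearableCohort(rd("daily.csv"), rd("events.csv"), rd("cope.csv"),
                 rd("demographics.csv"), truth = truth)
}

#' @rdname readCohort
#' @export
writeCohort <- function(x, dir) {
  stopifnot(is(x, "WearableCohort"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  ids <- participantIds(x)
  daily <- do.call(rbind, c(list(
    data.frame(participant_id = character(), date = character(),
               rhr_bpm = numeric(), mvpa_min = numeric(),
               sleep_h = numeric(), wear_hours = numeric())),
    lapply(ids, function(id) {
      s <- participantSeries(x, id)
      data.frame(participant_id = id, date = format(s$date),
                 rhr_bpm = s$rhr, mvpa_min = s$mvpa, sleep_h = s$sleep,
                 wear_hours = s$wear)
    })))
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE,
                                        na = "")
  wr(daily, "daily.csv")
  ev <- x@events
  if (nrow(ev)) ev$event_date <- format(as.Date(ev$event_date))
  wr(ev, "events.csv")
  wr(x@cope, "cope.csv")
  wr(data.frame(participant_id = ids, age = colData(x)$age,
                gender = colData(x)$gender), "demographics.csv")
  if (!is.null(x@truth))
    jsonlite::write_json(x@truth, file.path(dir, "truth.json"),
                         dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(dir)
}
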