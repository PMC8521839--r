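#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay colData rowData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' WearableCohort: daily wearable streams plus surveys for a study cohort
#'
#' An S4 container extending \link[SummarizedExperiment]{SummarizedExperiment}.
#' Assays are day-by-participant matrices, one per stream: `rhr` (resting
#' heart rate, bpm), `mvpa` (moderate-to-vigorous physical activity, minutes),
#' `sleep` (nightly sleep, hours) and `wear` (device wear, hours; days with
#' `wear < 19` may carry missing stream values). `rowData` holds calendar
#' `date` and `weekday` (1 = Monday); `colData` holds participant-level
#' demographics (`age`, `gender`). Life-event reports and Brief COPE item
#' responses are carried in dedicated slots because they are not day-indexed.
#'
#' @slot events data.frame of reported life events with columns
#'   `participant_id`, `event_date`, `valence`, `significance`,
#'   `date_confidence` (all Likert 1-7) and `description`.
#' @slot cope data.frame with `participant_id` and `item_1` .. `item_28`
#'   (each 1-4); participants who skipped the survey have no row.
#' @slot truth `NULL` for real data; for synthetic cohorts, the generator's
#'   ground truth (see [generateCohort()]).
#'
#' @seealso [WearableCohort()] (constructor), [generateCohort()],
#'   [readCohort()], [filterCohort()]
#' @export
setClass("WearableCohort",
  contains = "SummarizedExperiment",
  slots = c(events = "data.frame", cope = "data.frame", truth = "ANY"))

setValidity("WearableCohort", function(object) {
  msg <- character()
  need <- c("rhr", "mvpa", "sleep", "wear")
  if (!all(need %in% names(assays(object))))
    msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
  if (!all(c("date", "weekday") %in% names(rowData(object))))
    msg <- c(msg, "rowData must include 'date' and 'weekday'")
  ev <- object@events
  if (nrow(ev)) {
    lik <- c("valence", "significance", "date_confidence")
    if (!all(lik %in% names(ev))) {
      msg <- c(msg, "events must have valence/significance/date_confidence")
    } else {
      v <- unlist(ev[lik])
      if (any(!is.na(v) & (v < 1 | v > 7 | v != round(v))))
        msg <- c(msg, "event Likert fields must be integers in 1..7")
    }
  }
  cp <- object@cope
  if (nrow(cp)) {
    itemCols <- paste0("item_", 1:28)
    if (!all(itemCols %in% names(cp))) {
      msg <- c(msg, "cope must have item_1..item_28")
    } else {
      v <- unlist(cp[itemCols])
      if (any(!is.na(v) & (v < 1 | v > 4)))
        msg <- c(msg, "COPE items must lie in 1..4")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CohortReport: consort-style accounting of eligibility filtering
#'
#' Records, for each filtering stage, how many participants remain, together
#' with one exclusion reason per removed participant. Stage counts are
#' non-increasing by construction.
#'
#' @slot stages data.frame with columns `stage` and `remaining`.
#' @slot exclusions data.frame with columns `participant_id` and `reason`.
#' @seealso [filterCohort()]
#' @export
setClass("CohortReport",
  slots = c(stages = "data.frame", exclusions = "data.frame"))

setValidity("CohortReport", function(object) {
  st <- object@stages
  if (!all(c("stage", "remaining") %in% names(st)))
    return("stages needs columns 'stage' and 'remaining'")
  if (nrow(st) > 1 && any(diff(st$remaining) > 0))
    return("stage counts must be non-increasing")
  if (anyDuplicated(object@exclusions$participant_id))
    return("a participant may be excluded at most once")
  TRUE
})

#' OcsvmBaseline: a participant's learned baseline PB-state
#'
#' One-class SVM (RBF kernel) fitted on the 60-day pre-event window. The
#' decision function is the dual form
#' \deqn{f(x) = \sum_i \alpha_i \exp(-\gamma \lVert x_i - x \rVert^2) - \rho,}
#' positive for days conforming to baseline (inliers), negative for deviating
#' days (outliers). Under the libsvm \eqn{\nu}-parameterisation used here the
#' dual coefficients are non-negative and sum to \eqn{\nu n}.
#'
#' @slot sv matrix of support vectors (rows of the training window).
#' @slot alpha non-negative dual coefficients, one per support vector.
#' @slot rho decision-function offset.
#' @slot gamma RBF bandwidth actually used.
#' @slot nu the training-error bound \eqn{\nu}.
#' @slot nTrain number of training rows.
#' @slot center column means of the training window (used by diagnostics).
#' @seealso [fitBaseline()], [scoreDays()]
#' @export
setClass("OcsvmBaseline",
  slots = c(sv = "matrix", alpha = "numeric", rho = "numeric",
            gamma = "numeric", nu = "numeric", nTrain = "integer",
            center = "numeric", tolerance = "numeric"))

setValidity("OcsvmBaseline", function(object) {
  msg <- character()
  if (length(object@alpha) != nrow(object@sv))
    msg <- c(msg, "one dual coefficient per support vector required")
  if (any(object@alpha < -1e-8))
    msg <- c(msg, "dual coefficients must be non-negative")
  if (abs(sum(object@alpha) - object@nu * object@nTrain) > 1e-6)
    msg <- c(msg, "dual coefficients must sum to nu * n (libsvm scaling)")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be positive")
  if (length(msg)) msg else TRUE
})
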