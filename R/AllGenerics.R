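#' @rdname WearableCohort-accessors
#' @export
setGeneric("wearHours", function(x) standardGeneric("wearHours"))

#' @rdname WearableCohort-accessors
#' @export
setGeneric("lifeEvents", function(x) standardGeneric("lifeEvents"))

#' @rdname WearableCohort-accessors
#' @export
setGeneric("copeItems", function(x) standardGeneric("copeItems"))

#' @rdname WearableCohort-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname WearableCohort-accessors
#' @export
setGeneric("participantIds", function(x) standardGeneric("participantIds"))

#' @rdname participantSeries
#' @export
setGeneric("participantSeries", function(x, id) standardGeneric("participantSeries"))

#' @rdname scoreDays
#' @export
setGeneric("decisionValues", function(model, x) standardGeneric("decisionValues"))
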