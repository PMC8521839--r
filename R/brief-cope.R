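#' Brief COPE scoring key
#'
#' The published item pairs of the 28-item Brief COPE inventory: each of the
#' 14 coping strategies is scored as the sum of its two designated items
#' (each 1-4), so scale scores range 2-8.
#'
#' @return Named list mapping scale name to its two item numbers.
#' @examples
#' briefCopeKey()$acceptance
#' @export
briefCopeKey <- function() {
  list(acceptance = c(20L, 24L),
       active_coping = c(2L, 7L),
       behavioral_disengagement = c(6L, 16L),
       denial = c(3L, 8L),
       humor = c(18L, 28L),
       planning = c(14L, 25L),
       positive_reframing = c(12L, 17L),
       religion = c(22L, 27L),
       self_blame = c(13L, 26L),
       self_distraction = c(1L, 19L),
       substance_use = c(4L, 11L),
       emotional_support = c(5L, 15L),
       instrumental_support = c(10L, 23L),
       venting = c(9L, 21L))
}

#' Score Brief COPE item responses into the 14 scale scores
#'
#' @param items A length-28 vector, or a matrix/data.frame with 28 item
#'   columns (named `item_1` .. `item_28` or in item order), one row per
#'   respondent. All items must lie in 1..4.
#' @return A one-row (or n-row) data.frame of the 14 scale scores, each in
#'   2..8.
#' @examples
#' scoreBriefCope(rep(1, 28))  # every scale at its minimum, 2
#' @export
scoreBriefCope <- function(items) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  itemCols <- paste0("item_", 1:28)
  if (!is.null(colnames(items)) && all(itemCols %in% colnames(items)))
    items <- items[, itemCols, drop = FALSE]
  if (ncol(items) != 28)
    stop("expected 28 COPE items", call. = FALSE)
  storage.mode(items) <- "numeric"
  if (anyNA(items) || any(items < 1 | items > 4 | items != round(items)))
    stop("COPE items must all be integers in 1..4", call. = FALSE)
  key <- briefCopeKey()
  out <- vapply(key, function(p) items[, p[1]] + items[, p[2]],
                numeric(nrow(items)))
  if (nrow(items) == 1) out <- matrix(out, nrow = 1,
                                      dimnames = list(NULL, names(key)))
  as.data.frame(out)
}
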