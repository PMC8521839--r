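#' Per-participant pre/post medians of the raw streams
#'
#' Medians of the interpolated but *unnormalised* streams over the 60
#' pre-event and 15 post-event days, so changes stay in interpretable units
#' (bpm, minutes, hours). The even-length pre-window median is the midpoint
#' of the two central order statistics (R's default convention).
#'
#' @param processed Named list of `WindowedSeries` (one per participant,
#'   see [preprocessParticipant()]), whose `rawPre`/`rawPost` matrices are
#'   used.
#' @return data.frame with one row per participant x stream: `
#'   participant_id`, `stream`, `pre_median`, `post_median`, `change`.
#' @export
medianPrePost <- function(processed) {
  rows <- lapply(names(processed), function(id) {
    p <- processed[[id]]
    data.frame(participant_id = id, stream = streamNames(),
               pre_median = apply(p$rawPre, 2, stats::median),
               post_median = apply(p$rawPost, 2, stats::median),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$change <- out$post_median - out$pre_median
  out
}

#' Per-cluster pre/post change table
#'
#' For each trajectory cluster and each raw measure: the mean paired change
#' (post-event median minus pre-event median) and a two-sided Wilcoxon
#' signed-rank p-value. Degenerate all-zero changes are reported with
#' `p = 1` and flagged rather than erroring.
#'
#' @param medians Output of [medianPrePost()].
#' @param labels Named integer vector of cluster labels (names =
#'   participant ids).
#' @return data.frame with one row per cluster x measure: `cluster`,
#'   `measure`, `mean_change`, `p_value`, `n`, `degenerate`.
#' @export
clusterChangeTable <- function(medians, labels) {
  stopifnot(!is.null(names(labels)))
  rows <- list()
  for (cl in sort(unique(labels))) {
    ids <- names(labels)[labels == cl]
    for (st in streamNames()) {
      d <- medians$change[medians$participant_id %in% ids &
                            medians$stream == st]
      res <- tryCatch(wilcoxonSignedRank(d), error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, measure = st, mean_change = mean(d),
        p_value = if (is.null(res)) 1 else res$pValue,
        n = length(d), degenerate = is.null(res))
    }
  }
  do.call(rbind, rows)
}
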