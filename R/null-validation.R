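#' Bootstrap null configuration
#'
#' @param blockLength Length of a no-event block (60 training + 15 scored
#'   days).
#' @param nBootstrap Number of bootstrap draws over valid blocks.
#' @param seed Integer seed for the bootstrap resampling.
#' @return list config.
#' @export
nullConfig <- function(blockLength = 75, nBootstrap = 10000, seed = 1L) {
  stopifnot(blockLength >= 2, nBootstrap >= 1)
  list(blockLength = as.integer(blockLength),
       nBootstrap = as.integer(nBootstrap), seed = as.integer(seed))
}

#' Enumerate valid no-event 75-day blocks
#'
#' Removes the participant's 75-day event window from their full series,
#' then slides a 75-day window day-by-day over each remaining contiguous
#' segment. A block is valid when it meets the same wear rule as the event
#' window (at least 80% of the first 60 and of the last 15 days worn, a day
#' counting as worn at 19+ hours) and contains no reported event date of
#' any valence.
#'
#' @param series Participant daily series (`day`, `wear`).
#' @param eventDay Day index of the index event (its window is removed).
#' @param eventDays Integer day indices of *all* reported events.
#' @param rule A [complianceRule()].
#' @param spec A [windowSpec()].
#' @return Integer vector of block start days (possibly empty).
#' @examples
#' s <- data.frame(day = 1:200, wear = 24)
#' length(enumerateValidBlocks(s, eventDay = 61, eventDays = 61))  # 51
#' @export
enumerateValidBlocks <- function(series, eventDay, eventDays = integer(),
                                 rule = complianceRule(),
                                 spec = windowSpec()) {
  len <- spec$preDays + spec$postDays
  evLo <- eventDay - spec$preDays
  evHi <- eventDay + spec$postDays - 1
  days <- series$day
  keep <- days < evLo | days > evHi
  worn <- !is.na(series$wear) & series$wear >= rule$minHoursPerDay
  needPre <- ceiling(rule$minDayFraction * spec$preDays)
  needPost <- ceiling(rule$minDayFraction * spec$postDays)

  kept <- days[keep]
  if (!length(kept)) return(integer())
  ## contiguous segments of the remaining day indices
  breaks <- c(0, which(diff(kept) != 1), length(kept))
  starts <- integer()
  for (s in seq_len(length(breaks) - 1)) {
    seg <- kept[(breaks[s] + 1):breaks[s + 1]]
    if (length(seg) < len) next
    for (st in seg[1]:(seg[length(seg)] - len + 1)) {
      idx <- match(st:(st + len - 1), days)
      w <- worn[idx]
      if (sum(w[seq_len(spec$preDays)]) < needPre) next
      if (sum(w[spec$preDays + seq_len(spec$postDays)]) < needPost) next
      if (any(eventDays >= st & eventDays <= st + len - 1)) next
      starts <- c(starts, st)
    }
  }
  starts
}

## Deterministic response curve of one no-event block: the block's 61st day
## acts as a pseudo-event day, the full preprocessing pipeline is re-applied
## inside the block, and the baseline model scores its last 15 days.
blockCurve <- function(series, startDay, preCfg = preprocessConfig(),
                       baseCfg = baselineConfig(), spec = windowSpec()) {
  w <- makeWindows(series, startDay + spec$preDays, spec)
  ## hundreds of blocks are preprocessed per participant; per-stream
  ## stationarity messages would swamp the log, and each block's flags are
  ## retained in its own WindowedSeries anyway
  p <- suppressMessages(preprocessParticipant(w, preCfg))
  scoreDays(fitBaseline(p$pre, baseCfg), p$post)
}

#' Bootstrap a participant's no-event null response curve
#'
#' Computes each valid block's response curve once (the curve of a block is
#' deterministic), then bootstraps blocks -- whole 75-day units, sampled
#' with replacement `nBootstrap` times -- and takes per-day medians over the
#' sampled curves, estimating the participant's generalized response to no
#' event.
#'
#' @param series Participant daily series.
#' @param blocks Integer block start days from [enumerateValidBlocks()].
#' @param preCfg A [preprocessConfig()].
#' @param baseCfg A [baselineConfig()].
#' @param config A [nullConfig()].
#' @param spec A [windowSpec()].
#' @return list with `median` (the 15-day null curve), `blockCurves`
#'   (nBlocks x 15 matrix), `nBlocks`, `nDraws`.
#' @export
bootstrapNullCurves <- function(series, blocks, preCfg = preprocessConfig(),
                                baseCfg = baselineConfig(),
                                config = nullConfig(),
                                spec = windowSpec()) {
  if (!length(blocks))
    stop("no valid no-event blocks: participant cannot be validated",
         call. = FALSE)
  curves <- t(vapply(blocks, function(st)
    blockCurve(series, st, preCfg, baseCfg, spec),
    numeric(spec$postDays)))
  oldSeed <- globalSeedState()
  on.exit(restoreSeedState(oldSeed), add = TRUE)
  set.seed(config$seed)
  draw <- sample.int(nrow(curves), config$nBootstrap, replace = TRUE)
  med <- apply(curves[draw, , drop = FALSE], 2, stats::median)
  names(med) <- colnames(curves)
  ## the null *cumulative* deviation aggregates after summing: the median
  ## over draws of each curve's 15-day sum. Summing the per-day median
  ## curve instead would be biased upward for left-skewed daily scores
  ## (the median suppresses each day's outlier tail) and would make the
  ## cumulative event-vs-null test anticonservative.
  cum <- stats::median(rowSums(curves)[draw])
  list(median = med, cumulative = cum, blockCurves = curves,
       nBlocks = nrow(curves), nDraws = config$nBootstrap)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided test; zero differences are dropped (the classical convention --
#' the Pratt signed-zero treatment would change p and is deliberately not
#' used). The exact distribution is used for 25 or fewer non-zero
#' differences without ties in their absolute values; otherwise the normal
#' approximation with continuity correction.
#'
#' @param d Numeric vector of paired differences.
#' @return list with `statistic` (V, the positive-rank sum), `pValue`, `n`
#'   (non-zero differences used), `method`.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5))$pValue  # exact: 2/2^5
#' @export
wilcoxonSignedRank <- function(d) {
  d <- as.numeric(d)
  d <- d[!is.na(d)]
  dz <- d[d != 0]
  if (!length(dz))
    stop("degenerate: all paired differences are zero", call. = FALSE)
  if (length(dz) < 5)
    warning("fewer than 5 non-zero differences; p-value is coarse",
            call. = FALSE)
  ties <- anyDuplicated(abs(dz)) > 0
  exact <- length(dz) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(dz, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), pValue = wt$p.value,
       n = length(dz),
       method = if (exact) "exact" else "normal approximation")
}

#' Compare event response curves against bootstrap null curves
#'
#' Runs the two internal-validation tests: (1) paired Wilcoxon on day-0
#' scores, event vs null ("immediate impact"); (2) paired Wilcoxon on the
#' 15-day cumulative deviations ("short-term trajectory"). For day 0 the
#' null value is the null curve's day-0 entry (identically the median of
#' day-0 scores over bootstrap draws). For the cumulative test the null
#' value should be the median of the draws' *sums*
#' (`bootstrapNullCurves()$cumulative`); when `nullCumulative` is not
#' supplied the sum of the per-day median curve is used instead, which is
#' upward-biased for left-skewed daily scores and makes the cumulative
#' test anticonservative. Raw signed scores are used by default;
#' `transformed = TRUE` compares impact-transformed day-0 deviations and
#' truncated sums instead.
#'
#' @param eventCurves n x 15 matrix of event response curves.
#' @param nullCurves n x 15 matrix of per-participant null median curves
#'   (same row order).
#' @param nullCumulative Optional length-n vector of per-participant null
#'   cumulative deviations (median over bootstrap draws of curve sums).
#' @param transformed Compare `impact_positive`-transformed day-0 values
#'   and truncated sums instead of raw scores.
#' @return list with `day0` and `cumulative`, each a [wilcoxonSignedRank()]
#'   result.
#' @export
compareEventVsNull <- function(eventCurves, nullCurves,
                               nullCumulative = NULL, transformed = FALSE) {
  eventCurves <- as.matrix(eventCurves)
  nullCurves <- as.matrix(nullCurves)
  stopifnot(all(dim(eventCurves) == dim(nullCurves)))
  if (nrow(eventCurves) < 5)
    stop("need paired curves for at least 5 participants", call. = FALSE)
  if (transformed) {
    e0 <- pmax(0, -eventCurves[, 1]); n0 <- pmax(0, -nullCurves[, 1])
    eS <- rowSums(pmin(0, eventCurves))
    nS <- if (is.null(nullCumulative)) rowSums(pmin(0, nullCurves))
          else nullCumulative
  } else {
    e0 <- eventCurves[, 1]; n0 <- nullCurves[, 1]
    eS <- rowSums(eventCurves)
    nS <- if (is.null(nullCumulative)) rowSums(nullCurves)
          else nullCumulative
  }
  list(day0 = wilcoxonSignedRank(e0 - n0),
       cumulative = wilcoxonSignedRank(eS - nS))
}
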