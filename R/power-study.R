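#' Monte Carlo power / type-I study of the internal validation tests
#'
#' Repeatedly generates small synthetic cohorts, computes each
#' participant's event response curve and bootstrap no-event null curve,
#' runs the two paired validation tests (day-0 deviation and cumulative
#' deviation), and records their p-values. With `effectSds > 0` the cohort
#' members are all responders with injected deviations of `effectSds`
#' marginal noise sds per stream, so the rejection rate estimates power;
#' with `effectSds = 0` no deviation is injected and the rejection rate
#' estimates the type-I error of the whole scoring-plus-validation chain.
#'
#' Each replicate uses a short study (fewer days than the default yearly
#' config) so only a handful of no-event blocks exist per participant;
#' this keeps a 100-replicate study affordable while exercising the full
#' block-enumeration, preprocessing and scoring path.
#'
#' @param nReplicates Number of simulated cohorts.
#' @param nParticipants Participants per cohort.
#' @param effectSds Injected event-day deviation, in units of each
#'   stream's marginal noise sd (0 = null cohorts).
#' @param nBootstrap Bootstrap draws per participant's null curve.
#' @param studyDays Days of observation per participant.
#' @param seed Integer seed.
#' @return data.frame with one row per replicate: `p_day0`,
#'   `p_cumulative`, `n_used` (participants with at least one valid
#'   block).
#' @export
validationPowerStudy <- function(nReplicates = 100, nParticipants = 40,
                                 effectSds = 2, nBootstrap = 200,
                                 studyDays = 200, seed = 1L) {
  spec <- windowSpec()
  preCfg <- preprocessConfig()
  baseCfg <- baselineConfig()
  rows <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    cfg <- simConfig(
      nParticipants = nParticipants, studyDays = studyDays,
      eventDayRange = c(100, 110),
      responderFraction = if (effectSds > 0) 1 else 0,
      deviationMagnitude = effectSds *
        c(rhr = 2.5, mvpa = 15, sleep = 0.9) * c(1, -1, -1),
      copeEffect = 0, missingDayRate = 0, lowWearRate = 0,
      extraEventRate = 0,
      seed = deriveSeed(seed, paste0("rep", r)))
    ev <- matrix(NA_real_, nParticipants, spec$postDays)
    nu <- matrix(NA_real_, nParticipants, spec$postDays)
    nuCum <- rep(NA_real_, nParticipants)
    for (i in seq_len(nParticipants)) {
      ps <- simulateParticipantSeries(cfg, sprintf("P%03d", i),
                                      deriveSeed(cfg$seed,
                                                 paste0("series", i)))
      s <- applyMissingness(ps$series, cfg,
                            deriveSeed(cfg$seed, paste0("wear", i)))
      eventDay <- ps$truth$event_day
      w <- makeWindows(s, eventDay, spec)
      p <- suppressMessages(preprocessParticipant(w, preCfg))
      ev[i, ] <- scoreDays(fitBaseline(p$pre, baseCfg), p$post)
      blocks <- enumerateValidBlocks(s, eventDay, eventDay,
                                     complianceRule(), spec)
      if (!length(blocks)) next
      nc <- nullConfig(nBootstrap = nBootstrap,
                       seed = deriveSeed(cfg$seed, paste0("boot", i)))
      bn <- bootstrapNullCurves(s, blocks, preCfg, baseCfg, nc, spec)
      nu[i, ] <- bn$median
      nuCum[i] <- bn$cumulative
    }
    keep <- !apply(is.na(nu), 1, any)
    cmp <- compareEventVsNull(ev[keep, , drop = FALSE],
                              nu[keep, , drop = FALSE], nuCum[keep])
    rows[[r]] <- data.frame(p_day0 = cmp$day0$pValue,
                            p_cumulative = cmp$cumulative$pValue,
                            n_used = sum(keep))
  }
  do.call(rbind, rows)
}
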