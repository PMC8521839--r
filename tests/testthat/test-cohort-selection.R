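# consort filtering: event eligibility, index-event choice, wear compliance,
# staged counts, monotonicity

test_that("event eligibility applies the three rules in order", {
  ok <- scoreEventEligibility(list(valence = 6, significance = 7,
                                   date_confidence = 7))
  expect_true(ok$eligible)
  lowConf <- scoreEventEligibility(list(valence = 6, significance = 7,
                                        date_confidence = 6))
  expect_false(lowConf$eligible)
  expect_equal(lowConf$reason, "date_confidence")
  positive <- scoreEventEligibility(list(valence = 3, significance = 7,
                                         date_confidence = 7))
  expect_false(positive$eligible)
  expect_equal(positive$reason, "valence")
  expect_error(scoreEventEligibility(list(valence = 8, significance = 7,
                                          date_confidence = 7)), "1..7")
})

test_that("the earliest eligible event is the index event", {
  ev <- data.frame(participant_id = "P",
                   event_date = as.Date("2018-01-01") + c(199, 99, 49),
                   valence = c(7, 6, 6), significance = c(7, 7, 7),
                   date_confidence = c(7, 7, 5))
  idx <- selectIndexEvent(ev)
  expect_equal(as.Date(idx$event_date), as.Date("2018-01-01") + 99)
  expect_null(selectIndexEvent(ev[ev$date_confidence == 5, , drop = FALSE]))
  tie <- ev[c(1, 1), ]
  expect_error(selectIndexEvent(tie), "tie")
})

test_that("wear compliance uses ceiling day counts at the 80% boundary", {
  s <- cleanSeries(200)
  full <- assessWearCompliance(s, eventDay = 100)
  expect_true(full$compliant)
  expect_equal(full$wornDaysPre, 60)
  expect_equal(full$wornDaysPost, 15)

  # exactly 47 worn pre days: 47 < ceiling(0.8*60) = 48, non-compliant
  s47 <- s; s47$wear[(100 - 60):(100 - 1)][1:13] <- 10
  r47 <- assessWearCompliance(s47, 100)
  expect_equal(r47$wornDaysPre, 47)
  expect_false(r47$compliant)

  # boundary: 48 pre and 12 post is compliant
  s48 <- s
  s48$wear[(100 - 60):(100 - 1)][1:12] <- 10
  s48$wear[100:114][1:3] <- 10
  r48 <- assessWearCompliance(s48, 100)
  expect_equal(c(r48$wornDaysPre, r48$wornDaysPost), c(48, 12))
  expect_true(r48$compliant)

  expect_error(assessWearCompliance(s, eventDay = 30), "coverage")
})

test_that("staged filtering matches planted-failure arithmetic exactly", {
  rates <- c(valence = 0.2, significance = 0.2, confidence = 0.2,
             cope = 0.1)
  cfg <- miniConfig(n = 40, seed = 321, missingDayRate = 0, lowWearRate = 0,
                    plantedFailureRates = rates, extraEventRate = 0)
  wc <- generateCohort(cfg)
  planted <- cohortTruth(wc)$planted_failure
  k <- table(factor(planted, levels = c("valence", "significance",
                                        "confidence", "cope", "none")))

  flt <- filterCohort(wc)
  st <- flt$report@stages
  counts <- setNames(st$remaining, st$stage)
  expect_equal(unname(counts["enrolled"]), 40)
  expect_equal(unname(counts["has negative event"]),
               40 - unname(k["valence"]))
  expect_equal(unname(counts["at least high significance"]),
               40 - sum(k[c("valence", "significance")]))
  expect_equal(unname(counts["highest date confidence"]),
               40 - sum(k[c("valence", "significance", "confidence")]))
  expect_equal(unname(counts["COPE completed"]), unname(k["none"]))
  expect_equal(nrow(flt$eligible), unname(k["none"]))

  # exclusion accounting: one reason per excluded participant, total adds up
  excl <- flt$report@exclusions
  expect_equal(nrow(excl) + nrow(flt$eligible), 40)
  expect_false(anyDuplicated(excl$participant_id) > 0)
})

test_that("a fully clean cohort passes every stage", {
  cfg <- miniConfig(n = 8, seed = 11, missingDayRate = 0, lowWearRate = 0,
                    extraEventRate = 0)
  wc <- generateCohort(cfg)
  flt <- filterCohort(wc)
  expect_equal(nrow(flt$eligible), 8)
  expect_true(all(flt$report@stages$remaining == 8))
})

test_that("relaxing a threshold never shrinks the eligible set", {
  cfg <- miniConfig(n = 30, seed = 55, extraEventRate = 0,
                    plantedFailureRates = c(valence = 0.25,
                                            significance = 0.25,
                                            confidence = 0.1, cope = 0))
  wc <- generateCohort(cfg)
  strict <- filterCohort(wc, eligibilityThresholds(5, 6, 7))
  relaxedSig <- filterCohort(wc, eligibilityThresholds(5, 1, 7))
  relaxedVal <- filterCohort(wc, eligibilityThresholds(1, 6, 7))
  expect_true(all(strict$eligible$participant_id %in%
                    relaxedSig$eligible$participant_id))
  expect_true(all(strict$eligible$participant_id %in%
                    relaxedVal$eligible$participant_id))
})
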