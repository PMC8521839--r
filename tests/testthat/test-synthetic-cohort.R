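# synthetic cohort generator: deterministic construction, decay arithmetic,
# coefficient recovery, missingness rates, survey structure

test_that("noise-free series equals baseline plus weekday effect exactly", {
  cfg <- miniConfig(n = 1, baselineSd = c(rhr = 0, mvpa = 0, sleep = 0),
                    noiseSd = c(rhr = 0, mvpa = 0, sleep = 0),
                    responderFraction = 0)
  ps <- simulateParticipantSeries(cfg, "P001", seed = 1)
  expected <- cfg$baselineMean["rhr"] +
    cfg$weekdayEffect[ps$series$weekday, "rhr"]
  expect_equal(ps$series$rhr, unname(expected), tolerance = 1e-12)
  expect_equal(ps$series$sleep,
               unname(cfg$baselineMean["sleep"] +
                        cfg$weekdayEffect[ps$series$weekday, "sleep"]),
               tolerance = 1e-12)
  expect_false(ps$truth$is_responder)
  expect_equal(unname(ps$truth$injected_magnitudes), c(0, 0, 0))
})

test_that("injected deviation follows the closed-form exponential decay", {
  cfg <- miniConfig(n = 1, baselineSd = c(rhr = 0, mvpa = 0, sleep = 0),
                    noiseSd = c(rhr = 0, mvpa = 0, sleep = 0),
                    responderFraction = 1, copeEffect = 0,
                    deviationMagnitude = c(rhr = 4, mvpa = 0, sleep = 0),
                    decayHalflifeDays = 7)
  ps <- simulateParticipantSeries(cfg, "P001", seed = 2)
  ev <- ps$truth$event_day
  seasonal <- function(d) cfg$baselineMean["rhr"] +
    cfg$weekdayEffect[ps$series$weekday[d], "rhr"]
  # one half-life after the event: half the injected magnitude remains
  expect_equal(ps$series$rhr[ev + 7] - unname(seasonal(ev + 7)), 2,
               tolerance = 1e-10)
  expect_equal(ps$series$rhr[ev] - unname(seasonal(ev)), 4,
               tolerance = 1e-10)
  expect_equal(ps$series$rhr[ev - 1] - unname(seasonal(ev - 1)), 0,
               tolerance = 1e-10)
})

test_that("regressing log magnitude on the standardized cope score recovers
           the generator coefficient", {
  cfg <- miniConfig(n = 1, responderFraction = 1, copeEffect = -0.25)
  logMag <- zc <- numeric(200)
  for (i in 1:200) {
    tr <- simulateParticipantSeries(cfg, sprintf("P%03d", i),
                                    seed = 5000 + i)$truth
    logMag[i] <- log(tr$injected_magnitudes[["rhr"]])
    zc[i] <- tr$cope_scores[["active_coping"]]
  }
  slope <- coef(lm(logMag ~ scale(zc)))[2]
  expect_lt(abs(slope - cfg$copeEffect), 0.05)
})

test_that("event-day margins are enforced at configuration time", {
  expect_error(miniConfig(eventDayRange = c(40, 120)), "eventDayRange")
  expect_error(miniConfig(eventDayRange = c(100, 190)), "eventDayRange")
  expect_error(simConfig(weekdayEffect = defaultWeekdayEffect() + 1),
               "sum to 0")
})

test_that("missingness rates behave at their extremes and in expectation", {
  s <- cleanSeries(200)[, c("day", "date", "weekday", "rhr", "mvpa", "sleep")]
  cfg0 <- miniConfig(missingDayRate = 0, lowWearRate = 0)
  out0 <- applyMissingness(s, cfg0, seed = 1)
  expect_true(all(out0$wear >= 19))
  expect_false(anyNA(out0[, c("rhr", "mvpa", "sleep")]))

  cfg1 <- miniConfig(missingDayRate = 1, lowWearRate = 0)
  out1 <- applyMissingness(s, cfg1, seed = 1)
  expect_true(all(out1$wear < 19))
  expect_true(all(is.na(out1$rhr)))

  big <- cleanSeries(10000)[, c("day", "date", "weekday", "rhr", "mvpa",
                                "sleep")]
  cfgR <- miniConfig(missingDayRate = 0.1, lowWearRate = 0)
  outR <- applyMissingness(big, cfgR, seed = 3)
  expect_lt(abs(mean(is.na(outR$rhr)) - 0.1), 0.01)
})

test_that("surveys respect eligibility planting and scoring identities", {
  cfg <- miniConfig(n = 12, plantedFailureRates = c(valence = 0,
                                                    significance = 0,
                                                    confidence = 0, cope = 0),
                    extraEventRate = 0)
  wc <- generateCohort(cfg)
  ev <- lifeEvents(wc)
  expect_true(all(ev$valence >= 5 & ev$significance >= 6 &
                    ev$date_confidence == 7))
  # every participant has at least one event row
  expect_setequal(unique(ev$participant_id), participantIds(wc))

  cfgC <- miniConfig(n = 30, seed = 77, extraEventRate = 0,
                     plantedFailureRates = c(valence = 0, significance = 0,
                                             confidence = 1, cope = 0))
  wcC <- generateCohort(cfgC)
  expect_true(all(lifeEvents(wcC)$date_confidence <= 6))
  flt <- filterCohort(wcC)
  expect_equal(nrow(flt$eligible), 0)
  expect_true(all(flt$report@exclusions$reason == "date_confidence"))

  # all-minimum item responses score every scale at its minimum of 2
  expect_true(all(scoreBriefCope(rep(1, 28)) == 2))
})

test_that("cohort generation is seed-deterministic, including files", {
  cfg <- miniConfig(n = 3, seed = 42)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  wc1 <- generateCohort(cfg, dir = d1)
  wc2 <- generateCohort(cfg, dir = d2)
  expect_equal(SummarizedExperiment::assay(wc1, "rhr"),
               SummarizedExperiment::assay(wc2, "rhr"))
  expect_equal(cohortTruth(wc1), cohortTruth(wc2))
  for (f in c("daily.csv", "events.csv", "cope.csv", "demographics.csv",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # and a cohort read back from disk reproduces the assays
  rt <- readCohort(d1)
  expect_equal(SummarizedExperiment::assay(rt, "rhr"),
               SummarizedExperiment::assay(wc1, "rhr"), tolerance = 1e-12)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("empty cohorts still produce valid tables with headers", {
  cfg <- miniConfig(n = 0)
  d <- file.path(tempdir(), "empty-cohort")
  wc <- generateCohort(cfg, dir = d)
  expect_equal(ncol(wc), 0)
  expect_equal(nrow(lifeEvents(wc)), 0)
  expect_match(readLines(file.path(d, "daily.csv"), n = 1),
               "participant_id")
  unlink(d, recursive = TRUE)
})

test_that("default-config rows and study span match the configuration", {
  cfg <- miniConfig(n = 4)
  wc <- generateCohort(cfg)
  expect_equal(dim(wc), c(200L, 4L))
  s <- participantSeries(wc, "P002")
  expect_equal(nrow(s), 200)
})

test_that("streams are only weakly correlated within participants", {
  cfg <- simConfig(nParticipants = 40, seed = 9)
  weak <- vapply(seq_len(40), function(i) {
    ps <- simulateParticipantSeries(cfg, "x", seed = 200 + i)
    m <- as.matrix(ps$series[, c("rhr", "mvpa", "sleep")])
    r <- cor(m)
    max(abs(r[upper.tri(r)])) < 0.3
  }, logical(1))
  expect_gte(mean(weak), 0.95)
})

test_that("deseasonalized generator output is stationary by ADF", {
  cfg <- simConfig(nParticipants = 40, arCoef = 0.5, seed = 10)
  ok <- vapply(seq_len(40), function(i) {
    ps <- simulateParticipantSeries(cfg, "x", seed = 400 + i)
    ds <- deseasonalize(as.matrix(ps$series[, c("rhr", "mvpa", "sleep")]),
                        ps$series$weekday)
    all(vapply(1:3, function(j)
      adfTest(ds$residuals[, j])$stationary, logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
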