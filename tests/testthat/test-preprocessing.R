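# windowing, interpolation, deseasonalization, ADF, z-normalization

test_that("windows cover the specified 75-day span", {
  s <- cleanSeries(200)
  w <- makeWindows(s, eventDay = 100)
  expect_equal(w$days, 40:114)
  expect_equal(nrow(w$pre) + nrow(w$post), 75)
  expect_equal(nrow(w$pre), 60)
  expect_equal(nrow(w$post), 15)
  expect_error(makeWindows(s, eventDay = 59), "coverage")
  expect_error(makeWindows(s, eventDay = 190), "coverage")
})

test_that("linear interpolation fills interior gaps and extends edges", {
  expect_equal(interpolateMissing(cbind(c(2, NA, 4)))[, 1], c(2, 3, 4))
  expect_equal(interpolateMissing(cbind(c(NA, 5, 5)))[, 1], c(5, 5, 5))
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(interpolateMissing(m), m)
  expect_error(interpolateMissing(cbind(rep(NA_real_, 5))),
               "unrecoverable")
})

test_that("weekday-mean removal leaves exactly zero weekday means", {
  # hand-computed example: two weeks Mon..Sun, Monday differs across weeks
  x <- c(1, 2, 3, 4, 5, 6, 7, 3, 2, 3, 4, 5, 6, 7)
  wd <- rep(1:7, 2)
  ds <- deseasonalize(cbind(x = x), wd)
  expect_equal(ds$residuals[c(1, 8)], c(-1, 1), ignore_attr = TRUE)
  expect_equal(ds$residuals[-c(1, 8)], rep(0, 12), ignore_attr = TRUE)

  # constant series and a pure Saturday effect both vanish
  expect_true(all(deseasonalize(cbind(rep(3, 14)), wd)$residuals == 0))
  sat <- ifelse(rep(1:7, 8) == 6, 2, 0)
  expect_true(all(abs(deseasonalize(cbind(sat),
                                    rep(1:7, 8))$residuals) < 1e-14))

  # exact zero per-weekday residual means on arbitrary data
  set.seed(1)
  y <- rnorm(75)
  wd75 <- ((0:74) %% 7) + 1
  r <- deseasonalize(cbind(y), wd75)$residuals[, 1]
  for (w in 1:7) expect_lt(abs(mean(r[wd75 == w])), 1e-12)
})

test_that("ADF distinguishes stationary noise from a random walk", {
  set.seed(21)
  rej <- mean(replicate(500, adfTest(rnorm(75))$stationary))
  # the reference implementation rejects 97.4% under AIC lag selection
  expect_gte(rej, 0.95)
  set.seed(22)
  rejRw <- mean(replicate(500, adfTest(cumsum(rnorm(75)))$stationary))
  expect_lte(rejRw, 0.20)
  expect_error(adfTest(rep(1, 50)), "degenerate")
  expect_error(adfTest(rnorm(10)), "short")
})

test_that("z-normalization is exact, idempotent, and errors on constants", {
  z <- zNormalize(cbind(c(1, 2, 3)))
  expect_equal(z$normalized[, 1], c(-1, 0, 1))
  z2 <- zNormalize(z$normalized)
  expect_equal(z2$normalized, z$normalized, tolerance = 1e-12)
  expect_error(zNormalize(cbind(rep(2, 10))), "degenerate")
})

test_that("full preprocessing is exact, deterministic, and affine-invariant", {
  cfg <- miniConfig(n = 1, missingDayRate = 0.1, seed = 31)
  ps <- simulateParticipantSeries(cfg, "P001", seed = 31)
  s <- applyMissingness(ps$series, cfg, seed = 32)
  w <- makeWindows(s, eventDay = 110)
  p <- suppressMessages(preprocessParticipant(w))

  expect_true(all(is.finite(p$pre)) && all(is.finite(p$post)))
  # estimation span (pre window) has mean 0 and sd 1 per stream
  expect_true(all(abs(colMeans(p$pre)) < 1e-12))
  expect_true(all(abs(apply(p$pre, 2, sd) - 1) < 1e-12))
  # per-weekday residual means over the estimation span are exactly zero
  res <- sweep(sweep(p$pre, 2, p$sd, "*"), 2, -p$mean)
  for (wd in unique(w$preWeekday))
    expect_true(all(abs(colMeans(res[w$preWeekday == wd, , drop = FALSE]))
                    < 1e-10))

  # determinism
  p2 <- suppressMessages(preprocessParticipant(w))
  expect_identical(p$pre, p2$pre)
  expect_identical(p$post, p2$post)

  # affine invariance: rescaling and shifting a raw stream changes nothing
  w3 <- w
  w3$pre[, "rhr"] <- 3.7 * w3$pre[, "rhr"] + 11
  w3$post[, "rhr"] <- 3.7 * w3$post[, "rhr"] + 11
  p3 <- suppressMessages(preprocessParticipant(w3))
  expect_equal(p3$pre, p$pre, tolerance = 1e-10)
  expect_equal(p3$post, p$post, tolerance = 1e-10)
})

test_that("a planted post-event step survives preprocessing at ~step/sd", {
  cfg <- miniConfig(n = 1, baselineSd = c(rhr = 0, mvpa = 0, sleep = 0),
                    responderFraction = 1, copeEffect = 0,
                    deviationMagnitude = c(rhr = 3, mvpa = 0, sleep = 0),
                    decayHalflifeDays = 1e6,  # effectively no decay
                    missingDayRate = 0, lowWearRate = 0, seed = 41)
  ps <- simulateParticipantSeries(cfg, "P001", seed = 41)
  ps$series$wear <- 24
  ev <- ps$truth$event_day
  w <- makeWindows(ps$series, ev)
  p <- suppressMessages(preprocessParticipant(w))
  shift <- mean(p$post[, "rhr"]) - mean(p$pre[, "rhr"])
  expect_gt(shift, 0)
  # normalized shift is approximately 3 / sd(pre-window rhr residuals)
  expect_lt(abs(shift - 3 / p$sd[["rhr"]]), 1)
})
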