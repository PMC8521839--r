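# one-class SVM baseline: dual-form contract, nu bound, transforms

test_that("dual-form scores match the solver's own decision values", {
  set.seed(61)
  for (rep in 1:10) {
    train <- matrix(rnorm(60), 20, 3)
    m <- fitBaseline(train)
    query <- matrix(rnorm(150, sd = 2), 50, 3)
    mine <- decisionValues(m, query)
    ref <- e1071::svm(x = train, type = "one-classification",
                      kernel = "radial", nu = 0.01, gamma = m@gamma,
                      scale = FALSE, tolerance = 1e-3)
    theirs <- attr(predict(ref, query, decision.values = TRUE),
                   "decision.values")
    expect_lt(max(abs(mine - as.numeric(theirs))), 1e-8)
  }
})

test_that("dual coefficients are a valid nu-parameterization", {
  set.seed(62)
  m <- fitBaseline(matrix(rnorm(180), 60, 3))
  expect_true(all(m@alpha > 0))
  expect_equal(sum(m@alpha), 0.01 * 60, tolerance = 1e-8)
  expect_gte(nrow(m@sv), 1)
})

test_that("training order permutation leaves the decision function invariant", {
  # the mathematical solution is permutation-invariant; the solver attains
  # it to within its tolerance, so verify at a tight tolerance
  set.seed(63)
  train <- matrix(rnorm(180), 60, 3)
  q <- matrix(rnorm(30), 10, 3)
  cfg <- baselineConfig(tolerance = 1e-10)
  m1 <- fitBaseline(train, cfg)
  m2 <- fitBaseline(train[sample(60), ], cfg)
  expect_lt(max(abs(decisionValues(m1, q) - decisionValues(m2, q))), 1e-8)
})

test_that("tightly clustered training data yields no training outliers and
           far points score below every inlier", {
  set.seed(64)
  train <- matrix(rnorm(180, sd = 0.1), 60, 3)
  m <- fitBaseline(train)
  trainScores <- decisionValues(m, train)
  expect_equal(trainingErrorFraction(m, train), 0)
  far <- matrix(10, 1, 3)
  farScore <- decisionValues(m, far)
  expect_lt(farScore, 0)
  expect_gt(abs(farScore), max(abs(trainScores[trainScores > 0])))
  # all kernel terms vanish at distance: the score approaches -rho
  expect_equal(farScore, -m@rho, tolerance = 1e-6)
})

test_that("nu = 0.01 bounds training errors over many synthetic baselines", {
  cfg <- miniConfig(n = 1, missingDayRate = 0, lowWearRate = 0)
  errFrac <- vapply(1:50, function(i) {
    ps <- simulateParticipantSeries(cfg, "x", seed = 700 + i)
    ps$series$wear <- 24
    w <- makeWindows(ps$series, 110)
    p <- suppressMessages(preprocessParticipant(w))
    m <- fitBaseline(p$pre)
    trainingErrorFraction(m, p$pre)
  }, numeric(1))
  expect_true(all(errFrac <= 1 / 60 + 1e-12))  # at most 1 of 60 days
  expect_lte(mean(errFrac), 0.01 + 1 / 60)
})

test_that("score is non-increasing as a day moves beyond the training range", {
  set.seed(65)
  train <- matrix(rnorm(180), 60, 3)
  m <- fitBaseline(train)
  grid <- seq(max(train[, 3]), max(train[, 3]) + 6, length.out = 25)
  pts <- cbind(matrix(rep(colMeans(train)[1:2], each = 25), 25),
               grid)
  sc <- decisionValues(m, pts)
  expect_true(all(diff(sc) <= 1e-12))
})

test_that("curve transforms implement the truncation conventions", {
  cv <- c(-0.3, 0.2, -0.1)
  expect_equal(transformCurve(cv, "impact_positive"), c(0.3, 0, 0.1))
  expect_equal(transformCurve(cv, "trajectory_signed"), c(-0.3, 0, -0.1))
  allIn <- c(0.2, 0.1, 0.05)
  expect_true(all(transformCurve(allIn, "impact_positive") == 0))
  expect_true(all(transformCurve(allIn, "trajectory_signed") == 0))
  expect_error(transformCurve(cv, "something"), "arg")

  expect_equal(immediateImpact(c(-0.4, 0.1)), 0.4)
  expect_equal(immediateImpact(c(0.2, -0.5)), 0)

  expect_equal(cumulativeDeviation(rep(0, 15)), 0)
  expect_equal(cumulativeDeviation(rep(1, 15)), 15)
  expect_equal(cumulativeDeviation(c(-2, rep(0.1, 14))), -0.6)
  expect_equal(cumulativeDeviation(c(-2, rep(0.1, 14)), truncated = TRUE),
               -2)
})

test_that("responders register positive immediate impact", {
  hits <- vapply(1:40, function(i) {
    cfg <- miniConfig(n = 1, responderFraction = 1, copeEffect = 0,
                      deviationMagnitude = c(rhr = 7.5, mvpa = -45,
                                             sleep = -2.7),
                      missingDayRate = 0, lowWearRate = 0)
    ps <- simulateParticipantSeries(cfg, "x", seed = 900 + i)
    ps$series$wear <- 24
    w <- makeWindows(ps$series, ps$truth$event_day)
    p <- suppressMessages(preprocessParticipant(w))
    immediateImpact(scoreDays(fitBaseline(p$pre), p$post)) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("identical windows produce identical curves", {
  set.seed(66)
  pre <- matrix(rnorm(180), 60, 3)
  post <- matrix(rnorm(45), 15, 3)
  c1 <- scoreDays(fitBaseline(pre), post)
  c2 <- scoreDays(fitBaseline(pre), post)
  expect_identical(c1, c2)
  expect_length(c1, 15)
  expect_named(c1, paste0("day", 0:14))
})
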