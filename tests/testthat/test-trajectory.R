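# lowess smoothing, shape-based distance, K-shape clustering, logistic ORs

test_that("lowess reproduces linear and constant curves exactly", {
  lin <- 2 - 0.3 * (0:14)
  expect_lt(max(abs(smoothLowess(lin) - lin)), 1e-10)
  expect_equal(smoothLowess(rep(1.5, 15)), rep(1.5, 15))
})

test_that("lowess recovers a noisy step-and-decay shape", {
  shape <- c(-2 * 2^(-(0:7) / 3), rep(0, 7))
  set.seed(91)
  rms <- vapply(1:100, function(i) {
    sm <- smoothLowess(shape + rnorm(15, 0, 0.1))
    sqrt(mean((sm - shape)^2))
  }, numeric(1))
  expect_lt(mean(rms), 0.15)
})

test_that("SBD matches the brute-force oracle on random curves", {
  set.seed(92)
  for (i in 1:25) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(sbdDistance(a, b), bruteSbd(a, b), tolerance = 1e-10)
    expect_equal(sbdDistance(a, b), sbdDistance(b, a), tolerance = 1e-10)
    expect_gte(sbdDistance(a, b), 0)
    expect_lte(sbdDistance(a, b), 2)
  }
})

test_that("SBD is zero for shape-identical curves and detects shifts", {
  a <- sin(seq(0, 3, length.out = 15))
  expect_equal(sbdDistance(a, a), 0, tolerance = 1e-12)
  expect_equal(sbdDistance(a, 5 + 2 * a), 0, tolerance = 1e-12)

  # a delayed copy (zero-padded) is re-aligned by the shift search
  b <- c(rep(0, 2), a[1:13])
  expect_equal(sbdDistance(a, b), bruteSbd(a, b), tolerance = 1e-10)
  al <- pbstate:::sbdAlign(a, b)
  expect_lte(al$shift, -1)  # b lags a
  expect_lt(al$distance, 0.35)

  # negation: the best-shift NCC equals -(min autocorrelation). It reaches
  # -1 (distance 2) only under a zero-shift convention; over all shifts
  # the distance equals 1 + min_s NCC(a, a)(s), verified via brute force
  az <- (a - mean(a)) / sd(a)
  expect_equal(sbdDistance(a, -a),
               1 + min(pbstate:::crossCorrelations(az, az) / sum(az^2)),
               tolerance = 1e-10)
  expect_equal(sbdDistance(a, -a), bruteSbd(a, -a), tolerance = 1e-10)

  expect_error(sbdDistance(rep(1, 15), a), "degenerate")
})

test_that("K-shape recovers a planted two-shape cohort exactly", {
  pc <- plantedCurves(nPerShape = 20, noiseSd = 0.05, seed = 93)
  sm <- t(apply(pc$curves, 1, smoothLowess))
  cl <- kshapeCluster(sm, seed = 93, rawCurves = pc$curves)
  expect_equal(cl$k, 2)
  expect_equal(adjustedRand(cl$labels, pc$truth), 1)
  # canonical label 0 = minimal-deviation cluster, for any seed
  for (s in c(7, 19)) {
    cl2 <- kshapeCluster(sm, seed = s, rawCurves = pc$curves)
    expect_equal(cl2$labels[1], 0L)
    expect_equal(cl2$labels[40], 1L)
  }
  expect_false(cl$unstable)
})

test_that("a duplicated single shape is flagged as unstable clustering", {
  set.seed(94)
  shape <- plantedShapes()$step
  curves <- t(replicate(24, shape + rnorm(15, 0, 0.01)))
  cl <- kshapeCluster(curves, kCandidates = 2:3, seed = 94)
  expect_lt(cl$silhouette[["2"]], 0.25)
  expect_true(cl$unstable)
})

test_that("zero-variance curves are held out and assigned to cluster 0", {
  pc <- plantedCurves(nPerShape = 15, seed = 95)
  curves <- rbind(matrix(0, 3, 15), pc$curves)
  cl <- kshapeCluster(curves, kCandidates = 2:3, seed = 95)
  expect_equal(cl$heldOut, 1:3)
  expect_true(all(cl$labels[1:3] == 0))
})

test_that("the K-shape objective never increases across iterations", {
  # the update rule keeps the best labeling, so the final objective is a
  # lower bound of any intermediate one; check via repeated restarts that
  # reported objectives are consistent with their own assignment
  pc <- plantedCurves(nPerShape = 12, noiseSd = 0.2, seed = 96)
  cl <- kshapeCluster(pc$curves, kCandidates = 2, seed = 96)
  D <- vapply(1:2, function(j)
    apply(pc$curves, 1, function(x) sbdDistance(x, cl$centroids[j, ])),
    numeric(24))
  expect_lt(abs(cl$objective - sum(D[cbind(1:24, cl$labels + 1L)])), 1e-8)
})

test_that("silhouette from the SBD matrix matches the direct reference", {
  pc <- plantedCurves(nPerShape = 10, noiseSd = 0.3, seed = 97)
  D <- sbdMatrix(pc$curves)
  lab <- pc$truth + 1L
  s <- cluster::silhouette(lab, dmatrix = D)
  expect_equal(mean(s[, "sil_width"]), silhouetteReference(lab, D),
               tolerance = 1e-10)
})

test_that("logistic regression recovers a planted odds ratio and inverts
           under relabeling", {
  set.seed(98)
  N <- 500
  x <- rnorm(N)
  y <- rbinom(N, 1, plogis(0.2 + log(0.5) * x))
  X <- cbind(intercept = 1, cope = x)
  cfg <- inferenceConfig(testMode = TRUE)
  fit <- fitBayesLogistic(y, X, cfg, seed = 98)
  orHat <- exp(median(fit$draws[, "cope"]))
  expect_gt(orHat, 0.40)
  expect_lt(orHat, 0.62)

  flip <- fitBayesLogistic(1 - y, X, cfg, seed = 98)
  orFlip <- exp(median(flip$draws[, "cope"]))
  expect_lt(abs(log(orFlip) + log(orHat)), 0.1)

  expect_error(fitBayesLogistic(rep(1, 20), cbind(1, rnorm(20))),
               "single-cluster")
})
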