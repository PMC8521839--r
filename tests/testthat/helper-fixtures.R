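# Shared fixtures: small configs and deterministic builders used across the
# unit tests. Everything is generated in code; no stored data.

# a compact cohort configuration: short study, early fixed-ish event window
miniConfig <- function(n = 6, studyDays = 200, seed = 101, ...) {
  simConfig(nParticipants = n, studyDays = studyDays,
            eventDayRange = c(100, 120), seed = seed, ...)
}

# a deterministic participant series with full wear and no missingness
cleanSeries <- function(days = 200, value = list(rhr = 65, mvpa = 30,
                                                 sleep = 7.5),
                        start = as.Date("2018-01-01")) {
  dates <- start + seq_len(days) - 1
  data.frame(day = seq_len(days), date = dates,
             weekday = as.integer(format(dates, "%u")),
             rhr = value$rhr, mvpa = value$mvpa, sleep = value$sleep,
             wear = 24)
}

# adjusted Rand index (independent reference for cluster-recovery checks)
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# brute-force two-sided exact Wilcoxon signed-rank p-value by enumerating
# all 2^n sign patterns (independent oracle; no ties assumed)
enumWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  patterns <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(patterns) %*% r
  pLe <- mean(vs <= v)
  pGe <- mean(vs >= v)
  min(1, 2 * min(pLe, pGe))
}

# brute-force SBD oracle: z-scale, enumerate every zero-padded shift
bruteSbd <- function(a, b) {
  z <- function(x) (x - mean(x)) / sd(x)
  a <- z(a); b <- z(b)
  m <- length(a)
  best <- -Inf
  for (s in -(m - 1):(m - 1)) {
    acc <- 0
    for (t in seq_len(m)) {
      tb <- t - s
      if (tb >= 1 && tb <= m) acc <- acc + a[t] * b[tb]
    }
    best <- max(best, acc / (sqrt(sum(a^2)) * sqrt(sum(b^2))))
  }
  1 - best
}

# two planted trajectory shapes: a shallow late dip (minimal deviation) and
# an immediate step-and-recover
plantedShapes <- function() {
  list(flat = c(rep(0, 8), seq(0, -0.5, length.out = 4),
                seq(-0.4, 0, length.out = 3)),
       step = c(seq(-2, 0, length.out = 8), rep(0, 7)))
}

plantedCurves <- function(nPerShape = 20, noiseSd = 0.05, seed = 1) {
  sh <- plantedShapes()
  set.seed(seed)
  curves <- rbind(
    t(replicate(nPerShape, sh$flat + rnorm(15, 0, noiseSd))),
    t(replicate(nPerShape, sh$step + rnorm(15, 0, noiseSd))))
  list(curves = curves, truth = rep(0:1, each = nPerShape))
}
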