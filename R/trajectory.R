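#' Lowess-smooth a signed response curve
#'
#' Locally weighted linear regression with tricube weights and no
#' robustifying iterations, over the day index 0..14. The default span of
#' 0.5 corresponds to roughly a 7-day local window on a 15-point curve.
#' Exactly linear curves are reproduced unchanged (local linear fits pass
#' through lines).
#'
#' @param curve Numeric curve (finite).
#' @param frac Lowess span (fraction of points in each local fit).
#' @return Smoothed curve of the same length.
#' @examples
#' smoothLowess(c(0, 0, -1, -0.8, -0.6, -0.4, -0.2, rep(0, 8)))
#' @export
smoothLowess <- function(curve, frac = 0.5) {
  stopifnot(all(is.finite(curve)), frac > 0)
  stats::lowess(seq_along(curve) - 1, curve, f = frac, iter = 0,
                delta = 0)$y
}

## z-scale a curve (sample sd); degenerate for (near-)constant input
zScale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate: zero-variance curve cannot be shape-compared",
         call. = FALSE)
  (x - mean(x)) / s
}

## cross-correlations of two equal-length vectors over all shifts
## -(m-1)..(m-1), zero-padded; returned in shift order
crossCorrelations <- function(a, b) {
  m <- length(a)
  vapply(-(m - 1):(m - 1), function(s) {
    ta <- seq_len(m)
    tb <- ta - s
    ok <- tb >= 1 & tb <= m
    sum(a[ta[ok]] * b[tb[ok]])
  }, numeric(1))
}

#' Shape-based distance between two curves
#'
#' The K-shape metric: curves are z-scaled, then
#' `SBD(a, b) = 1 - max_s NCCc(a, b)(s)` where NCCc is the
#' coefficient-normalised cross-correlation (normalised by the product of
#' the full vector norms) over all zero-padded shifts. Ranges over
#' `[0, 2]`; 0 for shape-identical curves (up to offset and positive
#' scaling).
#'
#' @param a,b Equal-length numeric curves, non-constant.
#' @return Distance in `[0, 2]`.
#' @examples
#' sbdDistance(sin(1:15), 2 + 3 * sin(1:15))  # 0: same shape
#' @export
sbdDistance <- function(a, b) {
  stopifnot(length(a) == length(b))
  sbdAlign(a, b)$distance
}

## distance plus the maximising shift (b shifted by s against a)
sbdAlign <- function(a, b) {
  az <- zScale(a)
  bz <- zScale(b)
  cc <- crossCorrelations(az, bz) / (sqrt(sum(az^2)) * sqrt(sum(bz^2)))
  i <- which.max(cc)
  list(distance = 1 - cc[i], shift = i - length(a))
}

## shift b by s (positions; zero-padded) to align with a
shiftCurve <- function(b, s) {
  m <- length(b)
  out <- numeric(m)
  src <- seq_len(m) - s
  ok <- src >= 1 & src <= m
  out[ok] <- b[src[ok]]
  out
}

## K-shape centroid (shape extraction): aligned, z-scaled members enter a
## Rayleigh-quotient problem; the centroid is the leading eigenvector of
## Q' S Q with S the sum of outer products and Q the centering projector.
shapeExtraction <- function(curves, reference) {
  m <- ncol(curves)
  A <- t(apply(curves, 1, function(x) {
    al <- sbdAlign(reference, x)
    shiftCurve(zScale(x), al$shift)
  }))
  if (nrow(curves) == 1) A <- matrix(A, nrow = 1)
  S <- crossprod(A)
  Q <- diag(m) - matrix(1 / m, m, m)
  M <- Q %*% S %*% Q
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  ## eigenvector sign is arbitrary; keep the orientation closer to members
  if (sum(A %*% v) < 0) v <- -v
  zScale(v)
}

#' K-shape clustering of smoothed response curves
#'
#' Iterates nearest-centroid assignment under the shape-based distance and
#' shape-extraction centroid updates until labels stabilise (or the
#' within-cluster SBD sum would increase, at which point the previous
#' solution is kept, making the objective non-increasing by construction).
#' The best of `nInit` seeded restarts is kept per candidate K; the chosen
#' K maximises the mean silhouette computed from the pairwise SBD matrix.
#' Labels are canonicalised so that cluster 0 is the minimal-deviation
#' cluster (smallest mean absolute cumulative signed deviation of the raw
#' curves).
#'
#' Curves with zero variance after smoothing (participants who never left
#' their baseline) cannot be z-scaled for shape comparison; they are held
#' out of the fit and assigned to the canonical minimal-deviation cluster.
#'
#' @param curves n x m matrix of smoothed signed curves.
#' @param kCandidates Candidate cluster counts.
#' @param nInit Random restarts per K.
#' @param seed Integer seed.
#' @param maxIter Maximum assignment/update iterations.
#' @param rawCurves Curves used for canonicalisation (default: `curves`).
#' @return list of class `ClusterResult`: `labels` (0-based, canonical),
#'   `k`, `silhouette` (named by candidate K), `centroids` (k x m),
#'   `objective`, `unstable` (TRUE when the chosen K's silhouette is below
#'   0.25, flagging weak cluster structure), `heldOut` (indices of
#'   zero-variance curves assigned directly to cluster 0).
#' @export
kshapeCluster <- function(curves, kCandidates = 2:6, nInit = 10, seed = 1L,
                          maxIter = 100, rawCurves = curves) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  variable <- apply(curves, 1, stats::sd) >= 1e-12
  heldOut <- which(!variable)
  fitIdx <- which(variable)
  X <- curves[fitIdx, , drop = FALSE]
  ## only candidate K with at least 2K non-degenerate curves are sensible
  kCandidates <- kCandidates[2 * kCandidates <= nrow(X)]
  if (!length(kCandidates))
    stop("need at least 4 non-degenerate curves to consider K = 2",
         call. = FALSE)
  D <- sbdMatrix(X)
  if (max(D) < 1e-10)
    stop("degenerate: all curves are shape-identical", call. = FALSE)

  oldSeed <- globalSeedState()
  on.exit(restoreSeedState(oldSeed), add = TRUE)

  best <- list()
  sil <- stats::setNames(rep(NA_real_, length(kCandidates)),
                         as.character(kCandidates))
  for (k in kCandidates) {
    runs <- lapply(seq_len(nInit), function(r) {
      set.seed(deriveSeed(seed, sprintf("kshape_k%d_init%d", k, r)))
      kshapeOnce(X, k, maxIter)
    })
    obj <- vapply(runs, `[[`, numeric(1), "objective")
    bestRun <- runs[[which.min(obj)]]
    s <- cluster::silhouette(bestRun$labels, dmatrix = D)
    sil[as.character(k)] <- mean(s[, "sil_width"])
    best[[as.character(k)]] <- bestRun
  }
  kChosen <- kCandidates[which.max(sil)]
  run <- best[[as.character(kChosen)]]

  ## canonical order: ascending mean |cumulative signed deviation|
  magn <- abs(rowSums(as.matrix(rawCurves)[fitIdx, , drop = FALSE]))
  clusterMag <- tapply(magn, run$labels, mean)
  ord <- order(clusterMag)
  relabel <- integer(kChosen)
  relabel[ord] <- seq_len(kChosen) - 1L
  labels <- integer(n)
  labels[fitIdx] <- relabel[run$labels]
  labels[heldOut] <- 0L

  structure(list(labels = labels, k = kChosen, silhouette = sil,
                 centroids = run$centroids[ord, , drop = FALSE],
                 objective = run$objective,
                 unstable = sil[as.character(kChosen)] < 0.25,
                 heldOut = heldOut),
            class = "ClusterResult")
}

## one K-shape run from a random label initialisation; keeps the objective
## non-increasing by reverting an update that would worsen it
kshapeOnce <- function(X, k, maxIter) {
  n <- nrow(X)
  labels <- sample(rep_len(seq_len(k), n))
  centroids <- matrix(0, k, ncol(X))
  kept <- list(labels = labels, centroids = centroids, objective = Inf)
  for (iter in seq_len(maxIter)) {
    for (j in seq_len(k)) {
      members <- which(labels == j)
      if (!length(members)) {  # re-seed an empty cluster
        members <- sample.int(n, 1)
        labels[members] <- j
      }
      ref <- if (iter == 1) X[members[1], ] else centroids[j, ]
      centroids[j, ] <- shapeExtraction(X[members, , drop = FALSE], ref)
    }
    Dc <- vapply(seq_len(k), function(j)
      apply(X, 1, function(x) sbdDistance(x, centroids[j, ])),
      numeric(n))
    if (n == 1) Dc <- matrix(Dc, nrow = 1)
    newLabels <- max.col(-Dc, ties.method = "first")
    newObjective <- sum(Dc[cbind(seq_len(n), newLabels)])
    if (newObjective > kept$objective + 1e-12) break  # keep previous solution
    converged <- all(newLabels == labels) && iter > 1
    labels <- newLabels
    kept <- list(labels = labels, centroids = centroids,
                 objective = newObjective)
    if (converged) break
  }
  kept
}

#' Pairwise shape-based distance matrix
#'
#' @param curves n x m matrix.
#' @return n x n symmetric matrix of [sbdDistance()] values.
#' @export
sbdMatrix <- function(curves) {
  n <- nrow(curves)
  D <- matrix(0, n, n)
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- sbdDistance(curves[i, ], curves[j, ])
  D
}

#' Mean silhouette from a dissimilarity matrix (reference implementation)
#'
#' Direct O(n^2) computation used to cross-check the silhouette values the
#' clustering stage obtains from the `cluster` package.
#'
#' @param labels Integer cluster labels.
#' @param D Symmetric dissimilarity matrix.
#' @return Mean silhouette width.
#' @export
silhouetteReference <- function(labels, D) {
  n <- length(labels)
  widths <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}
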