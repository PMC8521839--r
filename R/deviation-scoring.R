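#' One-class SVM baseline configuration
#'
#' Shared across every participant so that detected deviations reflect each
#' baseline's own distribution, never model-parameter variance. `nu` is the
#' upper bound on the fraction of training errors and is deliberately small
#' (0.01) so the model trains on essentially all pre-event days. When
#' `gamma` is `NULL` the RBF bandwidth follows the "scale" convention,
#' `1 / (nFeatures * var(training matrix))` with the population variance
#' over all entries -- for the three-stream windows,
#' `1 / (3 * var(pre))`.
#'
#' @param nu Training-error bound, in `(0, 1]`.
#' @param gamma RBF bandwidth, or `NULL` for the scale convention.
#' @param tolerance Solver tolerance (the contract is the dual-form decision
#'   function, not a particular solver path).
#' @return list config.
#' @export
baselineConfig <- function(nu = 0.01, gamma = NULL, tolerance = 1e-3) {
  assertScalarIn(nu, 0, 1, "nu", loOpen = TRUE)
  if (!is.null(gamma)) assertScalarIn(gamma, 0, Inf, "gamma", loOpen = TRUE)
  list(nu = nu, gamma = gamma, tolerance = tolerance)
}

#' Fit a participant's baseline PB-state model
#'
#' Trains a one-class SVM with RBF kernel on the processed pre-event window
#' (rows = days, columns = normalised streams). The returned
#' [OcsvmBaseline-class] carries the support vectors, dual coefficients,
#' offset and bandwidth; its decision function is evaluated in closed dual
#' form by [scoreDays()] / [decisionValues()].
#'
#' @param pre Numeric matrix of training days (e.g. 60 x 3), finite.
#' @param config A [baselineConfig()].
#' @return An [OcsvmBaseline-class].
#' @examples
#' set.seed(1)
#' m <- fitBaseline(matrix(rnorm(180), 60, 3))
#' m
#' @export
fitBaseline <- function(pre, config = baselineConfig()) {
  pre <- as.matrix(pre)
  if (!all(is.finite(pre)))
    stop("training window must be finite (impute first)", call. = FALSE)
  gamma <- if (is.null(config$gamma)) {
    v <- popVar(pre)
    if (v == 0) stop("degenerate training window: zero variance",
                     call. = FALSE)
    1 / (ncol(pre) * v)
  } else config$gamma
  fit <- e1071::svm(x = pre, type = "one-classification", kernel = "radial",
                    nu = config$nu, gamma = gamma, scale = FALSE,
                    tolerance = config$tolerance)
  new("OcsvmBaseline", sv = unname(as.matrix(fit$SV)),
      alpha = as.numeric(fit$coefs), rho = as.numeric(fit$rho),
      gamma = gamma, nu = config$nu, nTrain = nrow(pre),
      center = colMeans(pre), tolerance = config$tolerance)
}

#' Fraction of training days scored as errors
#'
#' A training day counts as an error when its decision value falls below
#' zero by more than the solver's KKT tolerance: free support vectors sit
#' exactly on the boundary (decision value 0) and their numerically
#' computed scores jitter by about the solver tolerance on either side of
#' zero, so a strict sign test would misreport boundary days as errors.
#' The \eqn{\nu}-property bounds this fraction by \eqn{\nu} (up to 1/n).
#'
#' @param model An [OcsvmBaseline-class].
#' @param x The training window the model was fitted on.
#' @return Fraction in `[0, 1]`.
#' @export
trainingErrorFraction <- function(model, x) {
  mean(decisionValues(model, x) < -model@tolerance)
}

#' Score days against a baseline model
#'
#' `decisionValues()` evaluates the dual-form decision function
#' \eqn{f(x) = \sum_i \alpha_i e^{-\gamma \lVert x_i - x\rVert^2} - \rho}
#' for each row of `x`; `scoreDays()` applies it to the 15-day post-event
#' window, yielding the response curve (day 0 = event day; positive =
#' inlier/conforms to baseline, negative = outlier/deviates).
#'
#' @param model An [OcsvmBaseline-class].
#' @param x,post Numeric matrix of days to score (columns matching the
#'   training streams).
#' @return `decisionValues()`: numeric vector of scores. `scoreDays()`: the
#'   response curve, named `day0` .. `day14`.
#' @name scoreDays
#' @export
setMethod("decisionValues", "OcsvmBaseline", function(model, x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("query days must be finite", call. = FALSE)
  if (ncol(x) != ncol(model@sv))
    stop("query has wrong number of streams", call. = FALSE)
  ## squared distances support-vectors x queries
  d2 <- outer(rowSums(model@sv^2), rowSums(x^2), "+") -
    2 * model@sv %*% t(x)
  d2[d2 < 0] <- 0
  as.numeric(colSums(model@alpha * exp(-model@gamma * d2)) - model@rho)
})

#' @rdname scoreDays
#' @export
scoreDays <- function(model, post) {
  post <- as.matrix(post)
  curve <- decisionValues(model, post)
  names(curve) <- paste0("day", seq_len(nrow(post)) - 1)
  curve
}

setMethod("show", "OcsvmBaseline", function(object) {
  cat("OcsvmBaseline (one-class SVM, RBF kernel)\n")
  cat(sprintf("  nu = %g, gamma = %.4g, %d support vectors of %d days\n",
              object@nu, object@gamma, nrow(object@sv), object@nTrain))
  cat(sprintf("  sum(alpha) = %.4g, rho = %.4g\n", sum(object@alpha),
              object@rho))
})

#' Transform a response curve for downstream modelling
#'
#' `impact_positive` truncates inliers to zero and flips outlier signs to
#' positive (`max(0, -score)`), giving the right-skewed non-negative
#' deviation used by the gamma-hurdle models; `trajectory_signed` truncates
#' inliers to zero but keeps outliers negative (`min(0, score)`), the form
#' whose shape is clustered.
#'
#' @param curve Numeric response curve.
#' @param mode `"impact_positive"` or `"trajectory_signed"`.
#' @return Transformed curve of the same length.
#' @examples
#' transformCurve(c(-0.3, 0.2, -0.1), "impact_positive")
#' @export
transformCurve <- function(curve, mode = c("impact_positive",
                                           "trajectory_signed")) {
  mode <- match.arg(mode)
  if (mode == "impact_positive") pmax(0, -curve) else pmin(0, curve)
}

#' Immediate impact of the event
#'
#' The deviation on the event day itself: 0 when day 0 was an inlier,
#' `|score|` when it was an outlier.
#'
#' @param curve Numeric response curve (day 0 first).
#' @return Non-negative scalar.
#' @export
immediateImpact <- function(curve) {
  unname(transformCurve(curve, "impact_positive")[1])
}

#' Cumulative deviation over the response curve
#'
#' By default the sum of the 15 raw signed scores; with
#' `truncated = TRUE`, the sum of the inlier-truncated signed curve
#' (outlier magnitudes only), provided because the "sum of deviations" can
#' be read either way.
#'
#' @param curve Numeric response curve.
#' @param truncated Use the inlier-truncated variant.
#' @return Scalar.
#' @export
cumulativeDeviation <- function(curve, truncated = FALSE) {
  if (truncated) sum(transformCurve(curve, "trajectory_signed"))
  else sum(curve)
}
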