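#' Derive a stage-specific random seed from a global seed
#'
#' Deterministically maps a global integer seed plus a stage label to a new
#' seed, so that every stochastic stage of the pipeline is reproducible and
#' isolated: changing the number of draws in one stage never perturbs another.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. `"bootstrap"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(1L, "bootstrap")
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage),
            length(stage) == 1)
  m <- 2147483629  # largest prime below 2^31; keeps seeds valid R integers
  h <- as.double(seed) %% m
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% m
  as.integer(h %% (m - 1L) + 1L)
}

## population variance over all entries of a numeric vector/matrix
## (the bandwidth convention for the RBF kernel divides by n, not n-1)
popVar <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}

## stream names used throughout: resting heart rate (bpm), MVPA minutes,
## nightly sleep hours
streamNames <- function() c("rhr", "mvpa", "sleep")

assertScalarIn <- function(x, lo, hi, name, loOpen = FALSE, hiOpen = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (loOpen) x > lo else x >= lo) && (if (hiOpen) x < hi else x <= hi)
  if (!ok) stop(sprintf("'%s' must be a finite scalar in %s%g, %g%s",
                        name, if (loOpen) "(" else "[", lo, hi,
                        if (hiOpen) ")" else "]"), call. = FALSE)
  invisible(TRUE)
}
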