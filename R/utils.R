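# Internal numeric helpers shared across modules.

#' Centered moving average with truncated windows at the trace ends
#'
#' For an even window the span is asymmetric by one sample
#' (\code{floor((w-1)/2)} samples to the left, \code{floor(w/2)} to the
#' right), so a window of 10 covers offsets -4..+5. Ends are truncated:
#' the divisor is the number of in-range, non-missing samples.
#'
#' @param x numeric vector, may contain NA (treated as missing, not zero).
#' @param window integer window length in samples.
#' @return numeric vector of the same length as \code{x}.
#' @export
movingAverage <- function(x, window) {
  stopifnot(is.numeric(x), length(window) == 1L, window >= 1)
  n <- length(x)
  if (n == 0L) return(x)
  left <- floor((window - 1) / 2)
  right <- floor(window / 2)
  xs <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  # cumulative-sum sliding window
  cx <- c(0, cumsum(xs))
  cc <- c(0, cumsum(cnt))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  s <- cx[hi + 1L] - cx[lo]
  m <- cc[hi + 1L] - cc[lo]
  out <- ifelse(m > 0, s / m, NA_real_)
  out
}

#' Round half away from zero to a whole number
#'
#' \code{round()} in R rounds half to even; printed percentages in the
#' connectome summaries use conventional half-up rounding (47.22 -> 47,
#' 45.83 -> 46, 6.5 -> 7).
#' @param x numeric.
#' @return numeric vector of integers.
#' @export
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Locate local maxima with a prominence threshold
#'
#' A sample is a candidate peak when strictly greater than its left
#' neighbour and at least its right neighbour (left edge of a plateau).
#' Prominence is the classical definition: the drop from the peak to the
#' higher of the two key saddles separating it from higher terrain.
#'
#' @param x numeric vector (no NA).
#' @param prominence minimum prominence; peaks below it are dropped.
#' @return integer vector of peak indices, increasing.
#' @export
findPeaks <- function(x, prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  if (anyNA(x)) stop("findPeaks: NA in trace")
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  keep <- vapply(cand, function(i) {
    h <- x[i]
    # walk left until higher ground or the end; track the lowest valley
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
    (h - max(lmin, rmin)) >= prominence
  }, logical(1))
  cand[keep]
}

#' Locate local minima with a prominence threshold
#' @inheritParams findPeaks
#' @return integer vector of minima indices.
#' @export
findValleys <- function(x, prominence = 0) findPeaks(-x, prominence)

# Classed error constructors so callers/tests can condition on failure mode.
undulaError <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "undulaError")))
}

#' Standard error of the mean (n - 1 denominator), NA-tolerant
#' @param x numeric vector.
#' @return scalar SEM, or NA if fewer than 2 non-missing samples.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Unwrap a sequence of angles
#'
#' Removes jumps larger than pi between consecutive samples by adding
#' multiples of 2*pi, so that tangent-angle profiles crossing the atan2
#' branch cut can be averaged and smoothed safely.
#' @param theta numeric vector of angles in radians.
#' @return unwrapped angles.
#' @export
unwrapAngles <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  corr <- cumsum(round(d / (2 * pi)))
  theta - c(0, corr * 2 * pi)
}

# linear resampling of (time, value) onto a uniform grid
resampleUniform <- function(time, x, dt) {
  grid <- seq(time[1], time[length(time)], by = dt)
  list(time = grid, x = stats::approx(time, x, xout = grid, rule = 2)$y)
}
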