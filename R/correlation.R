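# Event-wise cross-correlation of neural activity with body bending:
# smoothing, bending-event segmentation between angle minima, per-event
# normalized cross-correlograms over +/-100 lags at 10 samples/s,
# control-anchored signed-peak extraction, and reversal-epoch selection.

#' Smooth traces for correlation analysis
#'
#' Centered moving average over \code{smooth_frames} samples (default
#' 10), truncated at the trace ends.
#'
#' @param x numeric trace.
#' @param smooth_frames window length in samples.
#' @return smoothed trace.
#' @export
preprocessTrace <- function(x, smooth_frames = 10L) {
  if (length(x) <= smooth_frames)
    undulaError("trace shorter than the smoothing window", "inputError")
  movingAverage(x, smooth_frames)
}

#' Resample a trace to the 10 Hz analysis rate
#'
#' The lag grid of 100 lags spanning 10 s fixes an analysis rate of 10
#' samples/s; traces recorded at other rates are linearly interpolated
#' onto a 0.1-s grid before correlation.
#'
#' @param time_s sample times.
#' @param x trace values.
#' @param rate_hz analysis rate (default 10).
#' @return list(time, x) on the uniform grid.
#' @export
resampleForCorrelation <- function(time_s, x, rate_hz = 10) {
  resampleUniform(time_s, x, 1 / rate_hz)
}

#' Segment individual bending events between angle minima
#'
#' A bending event is one full undulation period: the segment of the
#' (smoothed) bending-angle trace between two consecutive local minima.
#' Minima are detected at a configurable prominence (default 10% of the
#' trace's peak-to-peak range); events shorter than \code{min_duration_s}
#' are dropped and counted.
#'
#' @param angle numeric bending-angle trace (already smoothed).
#' @param rate_hz sample rate of the trace.
#' @param prominence minima prominence; NULL = 0.1 * diff(range(angle)).
#' @param min_duration_s minimum event length (default 1 s).
#' @return data.frame(start, end) of sample indices (class
#'   "BendingEvents", attribute nDroppedShort); zero rows when fewer than
#'   two minima exist.
#' @export
segmentEvents <- function(angle, rate_hz = 10, prominence = NULL,
                          min_duration_s = 1) {
  if (is.null(prominence)) prominence <- 0.1 * diff(range(angle))
  mins <- findValleys(angle, prominence = prominence)
  if (length(mins) < 2L) {
    ev <- data.frame(start = integer(0), end = integer(0))
    attr(ev, "nDroppedShort") <- 0L
    class(ev) <- c("BendingEvents", class(ev))
    return(ev)
  }
  ev <- data.frame(start = mins[-length(mins)], end = mins[-1])
  short <- (ev$end - ev$start) / rate_hz < min_duration_s
  out <- ev[!short, , drop = FALSE]
  attr(out, "nDroppedShort") <- sum(short)
  class(out) <- c("BendingEvents", class(out))
  out
}

# Normalized cross-correlation of one event at signed lags.
# positive lag k: a leads b, i.e. it compares a[t] with b[t + k].
# "coeff": both segments centred on their event mean, zero-padded outside
# the event, normalized by the total event energies (the convention of
# common signal-processing cross-correlation routines); magnitudes
# attenuate as the overlap shrinks, so periodic signals keep a unique
# peak at the true lag. "pearson": per-lag Pearson correlation of the
# overlapping samples only (no attenuation); overlaps < 3 samples are NA.
eventXcorr <- function(a, b, start, end, lags,
                       normalization = c("pearson", "coeff")) {
  normalization <- match.arg(normalization)
  out <- rep(NA_real_, length(lags))
  if (normalization == "coeff") {
    va <- a[start:end] - mean(a[start:end])
    vb <- b[start:end] - mean(b[start:end])
    en <- sqrt(sum(va^2) * sum(vb^2))
    if (en == 0) return(out)
    n <- length(va)
    for (j in seq_along(lags)) {
      k <- lags[j]
      ov <- n - abs(k)
      out[j] <- if (ov < 1L) 0 else if (k >= 0)
        sum(va[1:ov] * vb[(1 + k):n]) / en
      else
        sum(va[(1 - k):n] * vb[1:ov]) / en
    }
    return(out)
  }
  for (j in seq_along(lags)) {
    k <- lags[j]
    if (end - start - abs(k) + 1L < 3L) next
    if (k >= 0) { ia <- start:(end - k); ib <- (start + k):end }
    else { ia <- (start - k):end; ib <- start:(end + k) }
    va <- a[ia]; vb <- b[ib]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    out[j] <- stats::cor(va, vb)
  }
  out
}

#' Event-wise normalized cross-correlograms
#'
#' For each bending event, the normalized cross-correlation of the two
#' signals at integer lags
#' -max_lags..+max_lags (at \code{rate_hz}, the default grid spans
#' +/-10 s in 0.1-s steps). Positive lag means \code{signal_a} leads
#' \code{signal_b}. The across-event mean and SEM are computed per lag.
#' The reported peak is the lag of maximum (positive) mean correlation,
#' i.e. where the two signals align best; an anticorrelated extremum is
#' deliberately not chosen here -- signed extrema (positive or negative)
#' are extracted with \code{\link{peakCorrelation}} inside a
#' control-anchored window, mirroring how conditions are compared.
#'
#' @param signal_a,signal_b numeric traces on a common uniform grid.
#' @param events a data.frame from \code{\link{segmentEvents}}.
#' @param rate_hz sample rate (default 10).
#' @param max_lags lags per side (default 100).
#' @param normalization "pearson" (default): per-lag Pearson correlation
#'   of the overlapping samples, the event-wise convention (no
#'   attenuation, so the peak lag of a lag-shifted copy is exact);
#'   "coeff": segments centred on the event mean, zero-padded and
#'   normalized by total event energy, the whole-trace convention whose
#'   attenuation gives strictly periodic signals a unique peak.
#' @return a \linkS4class{CorrelogramSet}.
#' @export
xcorrEvents <- function(signal_a, signal_b, events, rate_hz = 10,
                        max_lags = 100L,
                        normalization = c("pearson", "coeff")) {
  normalization <- match.arg(normalization)
  if (nrow(events) == 0L)
    undulaError("no bending events to correlate", "inputError")
  lags <- seq.int(-max_lags, max_lags)
  per <- matrix(NA_real_, nrow(events), length(lags))
  for (e in seq_len(nrow(events)))
    per[e, ] <- eventXcorr(signal_a, signal_b,
                           events$start[e], events$end[e], lags,
                           normalization)
  mu <- colMeans(per, na.rm = TRUE)
  mu[!is.finite(mu)] <- NA_real_
  se <- apply(per, 2, sem)
  npl <- colSums(!is.na(per))
  pk <- which.max(mu)
  methods::new("CorrelogramSet", lagS = lags / rate_hz, perEvent = per,
               mean = mu, semValues = se, nPerLag = as.integer(npl),
               peak = list(value = mu[pk], lagS = lags[pk] / rate_hz))
}

#' Signed peak correlation within a control-anchored window
#'
#' Returns the value of largest magnitude (sign preserved) of the mean
#' correlogram within a \code{window_s}-wide window centered on the peak
#' lag of the control mean correlogram, together with its lag. The window
#' is clipped (with a warning) where it leaves the lag grid.
#'
#' @param set \linkS4class{CorrelogramSet} under test.
#' @param control \linkS4class{CorrelogramSet} providing the anchor peak.
#' @param window_s window width in seconds (default 5).
#' @return list(value, lagS).
#' @export
peakCorrelation <- function(set, control, window_s = 5) {
  anchor <- control@peak$lagS
  lo <- anchor - window_s / 2; hi <- anchor + window_s / 2
  if (lo < min(set@lagS) || hi > max(set@lagS)) {
    warning("peak window clipped to the lag grid")
    lo <- max(lo, min(set@lagS)); hi <- min(hi, max(set@lagS))
  }
  sel <- which(set@lagS >= lo & set@lagS <= hi & is.finite(set@mean))
  if (length(sel) == 0L)
    undulaError("no finite correlogram values inside the window",
                "inputError")
  w <- sel[which.max(abs(set@mean[sel]))]
  list(value = set@mean[w], lagS = set@lagS[w])
}

#' Select reversal epochs of a minimum duration
#'
#' Maximal runs of "reverse" frames lasting at least
#' \code{min_duration_s}; shorter reversals are counted but excluded.
#'
#' @param state character per frame, "forward"/"reverse".
#' @param time_s frame times.
#' @param min_duration_s minimum reversal length (default 10 s).
#' @return data.frame(start, end, tStart, tEnd, duration_s) with
#'   attribute nShortExcluded.
#' @export
selectReversals <- function(state, time_s, min_duration_s = 10) {
  r <- rle(state == "reverse")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rev <- which(r$values)
  if (length(rev) == 0L) {
    out <- data.frame(start = integer(0), end = integer(0),
                      tStart = numeric(0), tEnd = numeric(0),
                      duration_s = numeric(0))
    attr(out, "nShortExcluded") <- 0L
    return(out)
  }
  dt <- stats::median(diff(time_s))
  dur <- (ends[rev] - starts[rev] + 1L) * dt
  keep <- dur >= min_duration_s
  out <- data.frame(start = starts[rev][keep], end = ends[rev][keep],
                    tStart = time_s[starts[rev][keep]],
                    tEnd = time_s[ends[rev][keep]],
                    duration_s = dur[keep])
  attr(out, "nShortExcluded") <- sum(!keep)
  out
}

#' End-to-end event-wise correlation of two trace tables
#'
#' Convenience wrapper: resamples both traces to the analysis rate,
#' smooths them, segments bending events on the angle trace, and returns
#' the correlogram set of activity vs angle.
#'
#' @param activity_time,activity activity trace and its time base.
#' @param angle_time,angle bending-angle trace and its time base.
#' @param rate_hz analysis rate (default 10).
#' @param smooth_frames smoothing window (default 10 samples).
#' @param max_lags lags per side (default 100).
#' @param min_duration_s minimum event length.
#' @return list(correlogram = CorrelogramSet, events, angleSmooth, grid).
#' @export
correlateActivityWithBending <- function(activity_time, activity,
                                         angle_time, angle, rate_hz = 10,
                                         smooth_frames = 10L,
                                         max_lags = 100L,
                                         min_duration_s = 1) {
  ok <- stats::complete.cases(activity_time, activity)
  ra <- resampleForCorrelation(activity_time[ok], activity[ok], rate_hz)
  ok <- stats::complete.cases(angle_time, angle)
  rb <- resampleForCorrelation(angle_time[ok], angle[ok], rate_hz)
  n <- min(length(ra$x), length(rb$x))
  a <- preprocessTrace(ra$x[seq_len(n)], smooth_frames)
  b <- preprocessTrace(rb$x[seq_len(n)], smooth_frames)
  ev <- segmentEvents(b, rate_hz, min_duration_s = min_duration_s)
  cs <- xcorrEvents(a, b, ev, rate_hz, max_lags)
  list(correlogram = cs, events = ev, angleSmooth = b,
       grid = list(time = ra$time[seq_len(n)], rate_hz = rate_hz))
}
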