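# Track-level quality control: speed computation, the speed/length frame
# filters, video exclusion, and per-window summary statistics.

#' Centroid speed from a track table
#'
#' Frame-to-frame centroid displacement times fps, smoothed with a
#' centered moving average. Speed is undefined for the first frame (NA).
#'
#' @param track data.frame with columns time_s, x_mm, y_mm.
#' @param fps frames per second.
#' @param smooth_window smoothing window in frames (default 15); 1
#'   disables smoothing.
#' @return numeric speed trace in mm/s, same length as the track.
#' @export
computeSpeed <- function(track, fps, smooth_window = 15L) {
  if (nrow(track) < 2L) undulaError("need at least 2 frames", "inputError")
  if (any(diff(track$time_s) <= 0))
    undulaError("time must be strictly increasing", "inputError")
  disp <- sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2)
  raw <- c(NA, disp * fps)
  out <- if (smooth_window > 1L) movingAverage(raw, smooth_window) else raw
  out[1] <- NA_real_  # speed is undefined for the first frame
  out
}

#' Apply the track quality filters
#'
#' A frame is discarded when its (smoothed) speed exceeds
#' \code{max_speed_mm_s} (worms do not move faster than 1.25 mm/s; faster
#' apparent motion is a tracking artifact) or when its body length
#' deviates from the baseline by more than \code{length_tol} (fractional).
#' The baseline L0 is the mean length over the first \code{baseline_s}
#' seconds. The whole video is excluded when strictly more than
#' \code{exclude_frac} of frames were discarded; a discard fraction
#' exactly at the threshold does not exclude.
#'
#' @param track data.frame with time_s, x_mm, y_mm, length_mm (and
#'   optionally a precomputed speed_mm_s column, else speed is computed).
#' @param fps frames per second.
#' @param max_speed_mm_s speed cap (default 1.25).
#' @param length_tol fractional length discrepancy cap (default 0.25).
#' @param exclude_frac video-exclusion fraction (default 0.15).
#' @param baseline_s baseline window for L0 (default 5 s).
#' @param smooth_window speed smoothing (default 15 frames); the cap is
#'   applied to the smoothed speed.
#' @return list(track, report): the track with columns speed_mm_s, valid,
#'   reason added, and a \linkS4class{QCReport}.
#' @export
filterTrack <- function(track, fps, max_speed_mm_s = 1.25,
                        length_tol = 0.25, exclude_frac = 0.15,
                        baseline_s = 5, smooth_window = 15L) {
  if (max(track$time_s) - min(track$time_s) < baseline_s)
    undulaError("track shorter than the baseline window", "baselineError")
  if (!"speed_mm_s" %in% names(track))
    track$speed_mm_s <- computeSpeed(track, fps, smooth_window)
  base <- track$time_s <= track$time_s[1] + baseline_s
  L0 <- mean(track$length_mm[base], na.rm = TRUE)
  badSpeed <- !is.na(track$speed_mm_s) & track$speed_mm_s > max_speed_mm_s
  badLen <- !is.na(track$length_mm) &
    abs(track$length_mm - L0) / L0 > length_tol
  reason <- rep("ok", nrow(track))
  reason[badSpeed] <- "speed"
  reason[badLen] <- "length"
  reason[badSpeed & badLen] <- "speed+length"
  track$valid <- !(badSpeed | badLen)
  track$reason <- reason
  nd <- sum(!track$valid)
  frac <- nd / nrow(track)
  report <- methods::new("QCReport", nFrames = nrow(track),
                         nDiscarded = as.integer(nd),
                         discardFraction = frac,
                         videoExcluded = frac > exclude_frac,
                         reasons = reason, baselineLengthMm = L0)
  list(track = track, report = report)
}

#' Per-window mean and SEM of a trace
#'
#' Typical use: comparing a trace before (e.g. 15-20 s) and during
#' (21-26 s) an illumination epoch. Masked/missing samples are excluded
#' from n; a window with no remaining samples is reported as missing, not
#' as zero.
#'
#' @param time_s sample times.
#' @param values trace values (NA = masked).
#' @param windows named list of c(t0, t1) windows in seconds (inclusive).
#' @return data.frame(window, t0, t1, n, mean, sem).
#' @export
windowStats <- function(time_s, values, windows) {
  for (w in names(windows))
    if (windows[[w]][1] < min(time_s) - 1e-9 ||
        windows[[w]][2] > max(time_s) + 1e-9)
      undulaError(sprintf("window '%s' outside the trace", w),
                  "protocolError")
  rows <- lapply(names(windows), function(w) {
    sel <- time_s >= windows[[w]][1] & time_s <= windows[[w]][2]
    v <- values[sel]
    v <- v[!is.na(v)]
    data.frame(window = w, t0 = windows[[w]][1], t1 = windows[[w]][2],
               n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sem = sem(v))
  })
  do.call(rbind, rows)
}
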