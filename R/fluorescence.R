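# ROI fluorescence extraction and normalization: background-subtracted
# traces, dF/F against the whole-trace mean, ratiometric dR/R for
# YFP/CFP (cameleon) recordings, and alignment to the first reference peak.

#' Extract a background-corrected ROI trace from an image stack
#'
#' Per frame: mean over the signal-ROI pixels minus mean over the
#' background-ROI pixels. Background ROIs are drawn with the same size as
#' the signal ROI; a mismatch beyond 1 px raises a warning (the means are
#' still well defined).
#'
#' @param video a \linkS4class{WormVideo} (single channel).
#' @param roi logical matrix, the signal ROI.
#' @param background_roi logical matrix, the background ROI.
#' @param roi_id,channel provenance labels.
#' @return a \linkS4class{Trace} with raw, background and corrected
#'   filled; normalized is NA until \code{\link{deltaFOverF}}.
#' @export
extractRoiTrace <- function(video, roi, background_roi, roi_id = "roi",
                            channel = "F") {
  d <- dim(video@frames)
  if (!identical(dim(roi), d[1:2]) || !identical(dim(background_roi), d[1:2]))
    undulaError("ROI masks must match the frame size", "geometryError")
  if (sum(roi) == 0L || sum(background_roi) == 0L)
    undulaError("zero-area ROI", "geometryError")
  if (abs(sum(roi) - sum(background_roi)) > 1L)
    warning("background ROI area differs from signal ROI by more than 1 px")
  n <- d[3]
  flat <- matrix(video@frames, d[1] * d[2], n)
  raw <- colMeans(flat[as.vector(roi), , drop = FALSE])
  bg <- colMeans(flat[as.vector(background_roi), , drop = FALSE])
  t <- (seq_len(n) - 1L) / video@fps
  methods::new("Trace", time = t, raw = raw, background = bg,
               corrected = raw - bg, normalized = rep(NA_real_, n),
               roi = roi_id, channel = channel)
}

#' Normalize a trace to dF/F
#'
#' dF/F = (F_i - Fbar) / Fbar where F_i is the background-corrected
#' intensity at frame i and Fbar the mean of the entire corrected trace.
#' By construction mean(dF/F) = 0 and the result is invariant to positive
#' rescaling of the corrected trace (it is not invariant to additive
#' offsets, which is why background subtraction must come first).
#'
#' @param trace a \linkS4class{Trace} (or a bare numeric vector of
#'   corrected values, for which the numeric dF/F vector is returned).
#' @return the Trace with the normalized slot filled, or a numeric vector.
#' @export
deltaFOverF <- function(trace) {
  x <- if (methods::is(trace, "Trace")) trace@corrected else trace
  fbar <- mean(x, na.rm = TRUE)
  if (!is.finite(fbar) || fbar == 0)
    undulaError("whole-trace mean is zero: dF/F undefined",
                "normalizationError")
  dff <- (x - fbar) / fbar
  if (!methods::is(trace, "Trace")) return(dff)
  trace@normalized <- dff
  trace
}

#' Ratiometric dR/R from YFP and CFP traces
#'
#' R_i = YFP_i / CFP_i per frame; dR/R = (R_i - Rbar)/Rbar. Rbar defaults
#' to the mean over the full trace; \code{span = "window"} restricts the
#' normalization mean to \code{window} (e.g. the blue-light stimulation
#' period), matching the alternative convention for stimulated
#' recordings. The ratio cancels any per-frame factor common to both
#' channels, so uniform bleaching leaves dR/R unchanged.
#'
#' @param yfp,cfp background-corrected channel traces (numeric vectors or
#'   \linkS4class{Trace}s of equal length).
#' @param time_s sample times (taken from the traces when omitted).
#' @param span "full" or "window".
#' @param window c(t0, t1) seconds, required for span = "window".
#' @return a \linkS4class{RatioTrace}.
#' @export
deltaROverR <- function(yfp, cfp, time_s = NULL,
                        span = c("full", "window"), window = NULL) {
  span <- match.arg(span)
  if (methods::is(yfp, "Trace")) { time_s <- yfp@time; yfp <- yfp@corrected }
  if (methods::is(cfp, "Trace")) {
    if (is.null(time_s)) time_s <- cfp@time
    cfp <- cfp@corrected
  }
  if (length(yfp) != length(cfp))
    undulaError("channel traces differ in length", "inputError")
  if (is.null(time_s)) time_s <- seq_along(yfp) - 1
  bad <- which(cfp <= 0)
  if (length(bad))
    undulaError(paste("CFP <= 0 at frames:",
                      paste(utils::head(bad, 10), collapse = ", ")),
                "ratioError")
  r <- yfp / cfp
  sel <- if (span == "window") {
    if (is.null(window)) undulaError("window required", "inputError")
    time_s >= window[1] & time_s <= window[2]
  } else rep(TRUE, length(r))
  rbar <- mean(r[sel])
  methods::new("RatioTrace", time = time_s, yfp = yfp, cfp = cfp, ratio = r,
               normalized = (r - rbar) / rbar, normalizationSpan = span)
}

#' Align a set of traces to the first peak of a reference trace
#'
#' Finds the first local maximum of the reference trace with at least
#' \code{min_prominence} (default 2 SD of the reference) and shifts the
#' time axis of every trace of that animal so the peak sits at t = 0.
#' Animals whose reference contains no qualifying peak are excluded and
#' reported, not silently dropped.
#'
#' @param traces named list of numeric vectors (one animal's ROIs), all
#'   sampled at \code{fps}.
#' @param reference name of the reference trace within \code{traces}
#'   (e.g. the dorsal muscle trace).
#' @param fps sampling rate.
#' @param min_prominence peak prominence threshold; NULL = 2 * sd(ref).
#' @return list(time_s, traces, peakTime_s, excluded): shifted common time
#'   axis and the input traces, or excluded = TRUE with a reason when no
#'   peak was found.
#' @export
alignToFirstPeak <- function(traces, reference, fps, min_prominence = NULL) {
  ref <- traces[[reference]]
  if (is.null(ref)) undulaError("reference trace not found", "inputError")
  if (is.null(min_prominence)) min_prominence <- 2 * stats::sd(ref)
  pk <- findPeaks(ref, prominence = min_prominence)
  if (length(pk) == 0L)
    return(list(time_s = NULL, traces = traces, peakTime_s = NA_real_,
                excluded = TRUE, reason = "no reference peak at prominence"))
  t0 <- (pk[1] - 1L) / fps
  list(time_s = (seq_along(ref) - 1L) / fps - t0, traces = traces,
       peakTime_s = t0, excluded = FALSE)
}
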