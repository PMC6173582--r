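# S4 containers for the pipeline. Conventions used throughout:
#   * image frames are numeric matrices in [0, 1], indexed [row, col],
#     stacks are [row, col, frame] arrays;
#   * pixel coordinates are 1-based (row, col);
#   * generator (world) coordinates are mm, columns (x, y), with y mapped
#     to image rows so that larger y = larger row;
#   * angles are radians internally, degrees in reported posture metrics.

#' WormVideo: a grayscale frame stack with acquisition metadata
#'
#' @slot frames numeric array [height, width, nFrames] in [0, 1].
#' @slot fps frames per second.
#' @slot mmPerPx spatial calibration, millimetres per pixel.
#' @slot protocol data.frame of named illumination epochs
#'   (columns name, tStart, tEnd, seconds).
#' @slot meta free-form list (seed, world origin in mm, channel label, ...).
#' @export
setClass("WormVideo", representation(
  frames = "array", fps = "numeric", mmPerPx = "numeric",
  protocol = "data.frame", meta = "list"
))

setValidity("WormVideo", function(object) {
  if (length(dim(object@frames)) != 3L) return("frames must be [row, col, frame]")
  if (object@fps <= 0) return("fps must be positive")
  if (object@mmPerPx <= 0) return("mmPerPx must be positive")
  if (nrow(object@protocol) &&
      !all(c("name", "tStart", "tEnd") %in% names(object@protocol)))
    return("protocol needs columns name, tStart, tEnd")
  TRUE
})

#' GroundTruth: known locomotion state underlying a synthetic video
#'
#' @slot time seconds, one per frame.
#' @slot midlineMm array [nPoints, 2(x, y), nFrames], millimetres.
#' @slot theta matrix [nPoints - 1, nFrames], segment tangent angles (rad).
#' @slot centroidMm matrix [nFrames, 2].
#' @slot arcLengthMm numeric per frame.
#' @slot state character per frame: "forward" or "reverse".
#' @slot traces data.frame of true per-ROI fluorescence traces (may be empty).
#' @slot params the generating parameter list, seed included.
#' @export
setClass("GroundTruth", representation(
  time = "numeric", midlineMm = "array", theta = "matrix",
  centroidMm = "matrix", arcLengthMm = "numeric", state = "character",
  traces = "data.frame", params = "list"
))

setValidity("GroundTruth", function(object) {
  n <- length(object@time)
  if (dim(object@midlineMm)[3] != n) return("midlineMm frame count mismatch")
  if (nrow(object@theta) != dim(object@midlineMm)[1] - 1L)
    return("theta must have one entry per inter-point segment")
  if (ncol(object@theta) != n) return("theta frame count mismatch")
  if (length(object@arcLengthMm) != n) return("arcLengthMm length mismatch")
  TRUE
})

#' MidlineSeries: per-frame ordered midlines extracted from a video
#'
#' Index 1 of the point axis is the head once the series is oriented.
#' Invalid frames carry NA coordinates plus a reason code
#' ("no_worm", "skeleton_too_small", "branching_unresolved").
#'
#' @slot points array [nPoints, 2(row, col), nFrames], pixels, NA if invalid.
#' @slot theta matrix [nPoints - 1, nFrames], tangent angles (rad).
#' @slot valid logical per frame.
#' @slot invalidReason character per frame (NA when valid).
#' @slot arcLengthPx numeric per frame.
#' @slot oriented logical flag: head/tail assignment has been applied.
#' @export
setClass("MidlineSeries", representation(
  points = "array", theta = "matrix", valid = "logical",
  invalidReason = "character", arcLengthPx = "numeric", oriented = "logical"
))

setValidity("MidlineSeries", function(object) {
  n <- length(object@valid)
  if (dim(object@points)[3] != n) return("points frame count mismatch")
  if (nrow(object@theta) != dim(object@points)[1] - 1L)
    return("theta length must be nPoints - 1")
  if (length(object@invalidReason) != n) return("invalidReason length mismatch")
  if (length(object@arcLengthPx) != n) return("arcLengthPx length mismatch")
  TRUE
})

#' Trace: a single-ROI fluorescence time series
#'
#' @slot time seconds.
#' @slot raw per-frame ROI mean, arbitrary fluorescence units.
#' @slot background per-frame background-ROI mean.
#' @slot corrected raw - background.
#' @slot normalized dF/F, (F_i - Fbar)/Fbar with Fbar the whole-trace mean
#'   of the corrected signal; NA-filled until computed.
#' @slot roi,channel provenance labels.
#' @export
setClass("Trace", representation(
  time = "numeric", raw = "numeric", background = "numeric",
  corrected = "numeric", normalized = "numeric",
  roi = "character", channel = "character"
))

setValidity("Trace", function(object) {
  n <- length(object@time)
  if (length(object@raw) != n || length(object@background) != n ||
      length(object@corrected) != n || length(object@normalized) != n)
    return("all trace vectors must share one length")
  TRUE
})

#' RatioTrace: ratiometric (YFP/CFP cameleon) time series
#'
#' @slot time seconds.
#' @slot yfp,cfp per-frame background-corrected channel means.
#' @slot ratio R_i = YFP_i / CFP_i.
#' @slot normalized dR/R = (R_i - Rbar)/Rbar, Rbar over the normalization span.
#' @slot normalizationSpan "full" or "window".
#' @export
setClass("RatioTrace", representation(
  time = "numeric", yfp = "numeric", cfp = "numeric",
  ratio = "numeric", normalized = "numeric", normalizationSpan = "character"
))

#' EigenwormBasis: principal components of tangent-angle posture space
#'
#' @slot center mean posture vector (length 99 for a 100-point spine).
#' @slot components k x 99 orthonormal rows, leading variance first.
#' @slot varianceExplained fraction of variance per component.
#' @export
setClass("EigenwormBasis", representation(
  center = "numeric", components = "matrix", varianceExplained = "numeric"
))

setValidity("EigenwormBasis", function(object) {
  if (ncol(object@components) != length(object@center))
    return("components and center disagree on posture dimension")
  g <- object@components %*% t(object@components)
  if (max(abs(g - diag(nrow(g)))) > 1e-8)
    return("components must be orthonormal within 1e-8")
  if (sum(object@varianceExplained) > 1 + 1e-8)
    return("variance fractions cannot exceed 1")
  TRUE
})

#' CorrelogramSet: per-event normalized cross-correlograms
#'
#' Positive lag means the first signal leads the second.
#'
#' @slot lagS lag grid in seconds, symmetric about 0.
#' @slot perEvent matrix [nEvents, nLags] of Pearson correlations on the
#'   overlapping lag-shifted samples of each event; NA where the overlap
#'   is too short.
#' @slot mean,semValues across-event mean and SEM per lag.
#' @slot nPerLag events contributing per lag.
#' @slot peak list(value, lagS): maximum positive mean correlation and
#'   its lag (best positive alignment of the two signals).
#' @export
setClass("CorrelogramSet", representation(
  lagS = "numeric", perEvent = "matrix", mean = "numeric",
  semValues = "numeric", nPerLag = "integer", peak = "list"
))

setValidity("CorrelogramSet", function(object) {
  v <- object@perEvent[is.finite(object@perEvent)]
  if (length(v) && max(abs(v)) > 1 + 1e-9)
    return("correlations must lie in [-1, 1]")
  if (length(object@mean) != length(object@lagS))
    return("mean length must match lag grid")
  TRUE
})

#' SpotTrackSet: linked fluorescent-spot tracks across frames
#'
#' @slot tracks data.frame (frame, label, row, col, raw, background,
#'   corrected, missing).
#' @slot labels identity labels in tracking order.
#' @slot roiRadiusPx,bgWidthPx ROI geometry used for intensity extraction.
#' @export
setClass("SpotTrackSet", representation(
  tracks = "data.frame", labels = "character",
  roiRadiusPx = "numeric", bgWidthPx = "numeric"
))

#' QCReport: outcome of the track-level quality filters
#'
#' @slot nFrames,nDiscarded counts.
#' @slot discardFraction nDiscarded / nFrames.
#' @slot videoExcluded TRUE when strictly more than the exclusion fraction
#'   of frames was discarded.
#' @slot reasons character per frame ("ok", "speed", "length", or
#'   "speed+length").
#' @slot baselineLengthMm the first-5-s mean length used for the length rule.
#' @export
setClass("QCReport", representation(
  nFrames = "integer", nDiscarded = "integer", discardFraction = "numeric",
  videoExcluded = "logical", reasons = "character", baselineLengthMm = "numeric"
))

setValidity("QCReport", function(object) {
  if (!identical(object@videoExcluded, object@discardFraction > 0.15))
    return("videoExcluded must equal discardFraction > 0.15")
  TRUE
})
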