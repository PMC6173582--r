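# Generics and accessors. Slot access from user code goes through these.

#' @rdname WormVideo-class
#' @param object,x a package object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname WormVideo-class
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))
#' @rdname WormVideo-class
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))
#' @rdname WormVideo-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname MidlineSeries-class
#' @export
setGeneric("midlinePoints", function(x) standardGeneric("midlinePoints"))
#' @rdname MidlineSeries-class
#' @export
setGeneric("thetaAngles", function(x) standardGeneric("thetaAngles"))
#' @rdname MidlineSeries-class
#' @export
setGeneric("validFrames", function(x) standardGeneric("validFrames"))

#' @rdname Trace-class
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname Trace-class
#' @export
setGeneric("corrected", function(x) standardGeneric("corrected"))
#' @rdname Trace-class
#' @export
setGeneric("normalized", function(x) standardGeneric("normalized"))

#' @export
#' @rdname WormVideo-class
setMethod("frames", "WormVideo", function(x) x@frames)
#' @export
#' @rdname WormVideo-class
setMethod("fps", "WormVideo", function(x) x@fps)
#' @export
#' @rdname WormVideo-class
setMethod("mmPerPx", "WormVideo", function(x) x@mmPerPx)
#' @export
#' @rdname WormVideo-class
setMethod("nFrames", "WormVideo", function(x) dim(x@frames)[3])
#' @export
#' @rdname GroundTruth-class
#' @param x a \linkS4class{GroundTruth}.
setMethod("nFrames", "GroundTruth", function(x) length(x@time))
#' @export
#' @rdname MidlineSeries-class
#' @param x a \linkS4class{MidlineSeries}.
setMethod("nFrames", "MidlineSeries", function(x) length(x@valid))

#' @export
#' @rdname MidlineSeries-class
setMethod("midlinePoints", "MidlineSeries", function(x) x@points)
#' @export
#' @rdname MidlineSeries-class
setMethod("thetaAngles", "MidlineSeries", function(x) x@theta)
#' @export
#' @rdname MidlineSeries-class
setMethod("validFrames", "MidlineSeries", function(x) x@valid)

#' @export
#' @rdname Trace-class
setMethod("traceTime", "Trace", function(x) x@time)
#' @export
#' @rdname Trace-class
setMethod("corrected", "Trace", function(x) x@corrected)
#' @export
#' @rdname Trace-class
setMethod("normalized", "Trace", function(x) x@normalized)
#' @export
#' @rdname RatioTrace-class
#' @param x a \linkS4class{RatioTrace}.
setMethod("traceTime", "RatioTrace", function(x) x@time)
#' @export
#' @rdname RatioTrace-class
setMethod("normalized", "RatioTrace", function(x) x@normalized)

setMethod("show", "WormVideo", function(object) {
  d <- dim(object@frames)
  cat(sprintf("WormVideo: %d frames of %d x %d px, %.3g fps, %.4g mm/px\n",
              d[3], d[1], d[2], object@fps, object@mmPerPx))
  if (nrow(object@protocol))
    cat("  protocol epochs:", paste(object@protocol$name, collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d frames, %.3g s, body %.3g mm\n",
              length(object@time), max(object@time),
              stats::median(object@arcLengthMm)))
})

setMethod("show", "MidlineSeries", function(object) {
  cat(sprintf("MidlineSeries: %d frames (%d valid), %d points%s\n",
              length(object@valid), sum(object@valid), dim(object@points)[1],
              if (object@oriented) ", oriented" else ""))
  bad <- table(object@invalidReason[!object@valid])
  if (length(bad))
    cat("  invalid:", paste(names(bad), bad, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace [%s/%s]: %d samples, %.3g s%s\n", object@roi,
              object@channel, length(object@time),
              diff(range(object@time)),
              if (all(is.na(object@normalized))) "" else ", dF/F computed"))
})

setMethod("show", "CorrelogramSet", function(object) {
  cat(sprintf(
    "CorrelogramSet: %d events, lags %.3g..%.3g s, peak %.3f at %+.2f s\n",
    nrow(object@perEvent), min(object@lagS), max(object@lagS),
    object@peak$value, object@peak$lagS))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d/%d frames discarded (%.1f%%) -> %s\n",
              object@nDiscarded, object@nFrames, 100 * object@discardFraction,
              if (object@videoExcluded) "video EXCLUDED" else "video kept"))
})
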