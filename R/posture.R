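# Posture metrics from midline series: normalized 2-point-angle kymographs,
# eleven signed 3-point angles, dorso-ventral ratio, differential bending,
# eigenworm decomposition, body length and centroid.

#' Normalized 2-point-angle kymograph
#'
#' Per frame, the 99 segment tangent angles minus their frame mean
#' ("normalized"): subtracting the mean removes the global heading, so a
#' straight worm gives zeros at any orientation and each row sums to zero.
#' Rows of the returned matrix are frames (time), columns run head to
#' tail; stripes advancing along the columns visualize the traveling
#' bending wave.
#'
#' @param series an oriented \linkS4class{MidlineSeries}.
#' @return matrix [nFrames, nPoints - 1]; invalid frames are NA rows.
#' @export
twoPointKymograph <- function(series) {
  if (!series@oriented)
    warning("midline series is not oriented; head/tail may be inconsistent")
  # unwrap along the body so the frame mean is well defined when the
  # heading crosses the atan2 branch cut (idempotent on continuous theta)
  th <- t(apply(series@theta, 2, unwrapAngles))
  sweep(th, 1, rowMeans(th), `-`)
}

# interior 3-point angle with dorso-ventral sign.
# vulvaSide "dorsal_up": dorsal = decreasing image row.
signedThreePointAngle <- function(p1, p2, p3, dorsalUp = TRUE) {
  v1 <- p1 - p2; v2 <- p3 - p2
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  interior <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  # cross product in (x = col, y = row) screen coordinates; a middle point
  # deviating toward smaller row (up) gives a negative z component
  cz <- v1[2] * v2[1] - v1[1] * v2[2]
  s <- if (dorsalUp) -sign(cz) else sign(cz)
  s * (180 - interior)
}

sampleSpine <- function(pts, fractions) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  cbind(stats::approx(cs, pts[, 1], xout = fractions * L)$y,
        stats::approx(cs, pts[, 2], xout = fractions * L)$y)
}

#' Eleven signed 3-point bending angles along the spine
#'
#' Thirteen points are sampled at equal arc-length fractions 0, 1/12, ...,
#' 1 of the midline; angle i (i = 1..11, head to tail) is 180 degrees
#' minus the interior angle at point i+1 formed with points i and i+2,
#' signed positive when the middle point deviates toward the dorsal side.
#'
#' @param series an oriented \linkS4class{MidlineSeries} (or a single
#'   "Midline" list).
#' @param vulva_side "dorsal_up", "ventral_up" or "unknown" ("unknown"
#'   keeps the dorsal_up convention and attaches attribute
#'   \code{signConvention = "arbitrary"}).
#' @return matrix [nFrames, 11] of signed angles in degrees; invalid
#'   frames are NA rows.
#' @export
threePointAngles <- function(series, vulva_side = c("dorsal_up",
                                                    "ventral_up",
                                                    "unknown")) {
  vulva_side <- match.arg(vulva_side)
  dorsalUp <- vulva_side != "ventral_up"
  if (inherits(series, "Midline")) {
    pts <- series$points
    out <- matrix(threePointAnglesOne(pts, dorsalUp), 1L)
  } else {
    n <- nFrames(series)
    out <- matrix(NA_real_, n, 11L)
    for (i in which(series@valid))
      out[i, ] <- threePointAnglesOne(series@points[, , i], dorsalUp)
  }
  if (vulva_side == "unknown") attr(out, "signConvention") <- "arbitrary"
  out
}

threePointAnglesOne <- function(pts, dorsalUp) {
  p13 <- sampleSpine(pts, (0:12) / 12)
  vapply(1:11, function(i)
    signedThreePointAngle(p13[i, ], p13[i + 1, ], p13[i + 2, ], dorsalUp),
    0)
}

#' Dorso-ventral bending ratio
#'
#' Mean of the dorsal (positive) samples of a signed bending-angle trace
#' divided by the magnitude of the mean of the ventral (negative) samples.
#' Conventionally evaluated on the second of the eleven 3-point angles
#' (just behind the head), where steering is expressed.
#'
#' @param angles numeric vector of signed angles (degrees).
#' @return scalar ratio (> 1 means dorsal bias).
#' @export
dorsoventralRatio <- function(angles) {
  angles <- angles[!is.na(angles)]
  pos <- angles[angles > 0]; neg <- angles[angles < 0]
  if (length(pos) == 0L || length(neg) == 0L)
    undulaError("ratio undefined: need both dorsal and ventral samples",
                "undefinedRatioError")
  mean(pos) / abs(mean(neg))
}

#' Differential bending activity between protocol epochs
#'
#' Each of the eleven 3-point-angle traces is smoothed with a centered
#' moving average (\code{smooth_window} frames), the absolute
#' frame-to-frame difference is taken, and that bending activity is
#' averaged within the dark and light epochs. DeltaDelta = light - dark
#' per angle, then averaged over anterior angles (1-5) and posterior
#' angles (6-11).
#'
#' @param angle_series matrix [nFrames, 11] of signed angles (degrees).
#' @param time_s frame times.
#' @param protocol list(dark = c(t0, t1), light = c(t0, t1)) in seconds.
#' @param smooth_window temporal smoothing window in frames (default 15).
#' @return list(perAngle: data.frame(angle, meanAbsDeltaDark,
#'   meanAbsDeltaLight, deltaDelta), anteriorDeltaDelta,
#'   posteriorDeltaDelta). Units: degrees per frame.
#' @export
differentialBending <- function(angle_series, time_s, protocol,
                                smooth_window = 15L) {
  stopifnot(ncol(angle_series) == 11L, nrow(angle_series) == length(time_s))
  for (w in c("dark", "light"))
    if (protocol[[w]][1] < time_s[1] - 1e-9 ||
        protocol[[w]][2] > time_s[length(time_s)] + 1e-9)
      undulaError(sprintf("%s epoch outside the recording", w),
                  "protocolError")
  inWin <- function(w) time_s >= protocol[[w]][1] & time_s <= protocol[[w]][2]
  dark <- inWin("dark"); light <- inWin("light")
  res <- t(vapply(1:11, function(a) {
    sm <- movingAverage(angle_series[, a], smooth_window)
    d <- c(NA, abs(diff(sm)))
    c(mean(d[dark], na.rm = TRUE), mean(d[light], na.rm = TRUE))
  }, c(0, 0)))
  perAngle <- data.frame(angle = 1:11, meanAbsDeltaDark = res[, 1],
                         meanAbsDeltaLight = res[, 2],
                         deltaDelta = res[, 2] - res[, 1])
  list(perAngle = perAngle,
       anteriorDeltaDelta = mean(perAngle$deltaDelta[1:5]),
       posteriorDeltaDelta = mean(perAngle$deltaDelta[6:11]))
}

#' Fit an eigenworm basis from a posture library
#'
#' Principal components of a library of frame-mean-normalized tangent
#' angles. A handful of components captures most of the posture variance
#' of crawling worms; the projections serve as a low-dimensional posture
#' description.
#'
#' @param posture_library matrix [nFrames, 99] of normalized theta (rad),
#'   e.g. a \code{\link{twoPointKymograph}}.
#' @param k number of components to keep.
#' @return an \linkS4class{EigenwormBasis}.
#' @export
fitEigenworms <- function(posture_library, k = 4L) {
  posture_library <- posture_library[stats::complete.cases(posture_library), ,
                                     drop = FALSE]
  if (nrow(posture_library) < k)
    undulaError("library has fewer frames than components requested",
                "rankError")
  pc <- stats::prcomp(posture_library, center = TRUE, scale. = FALSE)
  if (k > sum(pc$sdev > 1e-12))
    undulaError("k exceeds the rank of the posture library", "rankError")
  methods::new("EigenwormBasis",
               center = as.numeric(pc$center),
               components = t(pc$rotation[, seq_len(k), drop = FALSE]),
               varianceExplained =
                 (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Project postures onto an eigenworm basis
#'
#' @param theta matrix [nFrames, 99] (or a single vector) of normalized
#'   tangent angles.
#' @param basis an \linkS4class{EigenwormBasis}.
#' @return matrix [nFrames, k] of projection coefficients.
#' @export
projectEigenworms <- function(theta, basis) {
  if (is.null(dim(theta))) theta <- matrix(theta, 1L)
  sweep(theta, 2, basis@center) %*% t(basis@components)
}

#' Reconstruct postures from eigenworm coefficients
#' @param coefficients matrix [nFrames, k].
#' @param basis an \linkS4class{EigenwormBasis}.
#' @return matrix [nFrames, 99] of tangent angles.
#' @export
reconstructEigenworms <- function(coefficients, basis) {
  if (is.null(dim(coefficients))) coefficients <- matrix(coefficients, 1L)
  sweep(coefficients %*% basis@components, 2, basis@center, `+`)
}

#' Body length and centroid traces from a midline series
#'
#' @param series a \linkS4class{MidlineSeries}.
#' @param mm_per_px spatial calibration.
#' @param fps frames per second.
#' @return data.frame(frame, time_s, length_mm, centroid_row_mm,
#'   centroid_col_mm); invalid frames carry NA.
#' @export
bodyMetrics <- function(series, mm_per_px, fps) {
  n <- nFrames(series)
  cent <- t(apply(series@points, 3, colMeans))
  data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1L) / fps,
             length_mm = series@arcLengthPx * mm_per_px,
             centroid_row_mm = cent[, 1] * mm_per_px,
             centroid_col_mm = cent[, 2] * mm_per_px)
}
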