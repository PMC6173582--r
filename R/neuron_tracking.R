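# Tracking of fluorescent neuron cell bodies in moving animals: per-frame
# spot detection on the marker channel, nearest-neighbour identity
# linkage, circular-ROI minus donut-background intensity on the activity
# channel, and the AS6-vulva-AS7 bending angle.

detectSpots <- function(frame, min_area_px = 4L) {
  thr <- tryCatch(otsuThreshold(frame), undulaError = function(e) NA_real_)
  if (is.na(thr)) return(matrix(numeric(0), 0L, 2L))
  lab <- EBImage::bwlabel(EBImage::Image(t(frame > thr)))
  labM <- t(EBImage::imageData(lab))
  k <- max(labM)
  if (k == 0L) return(matrix(numeric(0), 0L, 2L))
  out <- matrix(NA_real_, k, 2L)
  for (j in seq_len(k)) {
    idx <- which(labM == j, arr.ind = TRUE)
    if (nrow(idx) >= min_area_px) out[j, ] <- colMeans(idx)
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

diskAnnulusMeans <- function(frame, row, col, roiR, bgW) {
  h <- nrow(frame); w <- ncol(frame)
  outR <- roiR + bgW
  r0 <- max(1L, floor(row - outR)); r1 <- min(h, ceiling(row + outR))
  c0 <- max(1L, floor(col - outR)); c1 <- min(w, ceiling(col + outR))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  patch <- frame[rr, cc, drop = FALSE]
  c(roi = mean(patch[d2 <= roiR^2]),
    bg = mean(patch[d2 > roiR^2 & d2 <= outR^2]))
}

#' Track neuron cell bodies across a dual-channel movie
#'
#' Spots are detected per frame by Otsu binarization of the marker
#' channel and connected-component centroids. Identities are carried by
#' greedy nearest-neighbour linkage to each track's last known position,
#' gated by \code{gate_px}; a track with no detection inside the gate is
#' missing for that frame and resumes when the spot reappears (its last
#' known position keeps serving as the linkage reference for up to
#' \code{gap_tolerance} consecutive missing frames, after which the
#' track only reattaches if a detection falls inside the gate again).
#' Intensity is measured on the activity channel as the mean over a
#' circular ROI centred on the (offset-corrected) centroid minus the
#' mean over the surrounding donut-shaped background annulus.
#'
#' @param activity,marker \linkS4class{WormVideo}s of equal length.
#' @param init named list of c(row, col) seed positions in frame 1, one
#'   per identity (e.g. AS6 / vulva / AS7, as clicked by the user); NULL
#'   labels detections spot1..spotN left to right.
#' @param channel_offset c(dr, dc) translation from marker to activity
#'   coordinates (dual-view alignment).
#' @param roi_radius_px circular ROI radius (default 18 px).
#' @param bg_width_px annulus width (default 5 px).
#' @param gate_px linkage gate radius (default 20 px).
#' @param gap_tolerance frames a lost spot may stay missing while keeping
#'   its linkage reference (default 5).
#' @return a \linkS4class{SpotTrackSet}.
#' @export
trackNeurons <- function(activity, marker, init = NULL,
                         channel_offset = c(0, 0), roi_radius_px = 18,
                         bg_width_px = 5, gate_px = 20, gap_tolerance = 5L) {
  n <- nFrames(marker)
  if (nFrames(activity) != n)
    undulaError("activity and marker stacks differ in length", "inputError")
  det1 <- detectSpots(marker@frames[, , 1])
  if (nrow(det1) == 0L) undulaError("no spots in frame 1", "noWormError")
  if (is.null(init)) {
    ord <- order(det1[, 2])
    init <- lapply(seq_len(nrow(det1)), function(i) det1[ord[i], ])
    names(init) <- paste0("spot", seq_along(init))
  }
  labels <- names(init)
  nT <- length(labels)
  pos <- matrix(NA_real_, nT, 2L)
  for (k in seq_len(nT)) {
    d <- sqrt(colSums((t(det1) - init[[k]])^2))
    if (min(d) > gate_px)
      undulaError(sprintf("no detection near init position '%s'", labels[k]),
                  "ambiguityError")
    pos[k, ] <- det1[which.min(d), ]
  }
  missRun <- integer(nT)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    det <- if (i == 1L) det1 else detectSpots(marker@frames[, , i])
    assigned <- rep(NA_integer_, nT)
    if (nrow(det) > 0L) {
      D <- matrix(NA_real_, nT, nrow(det))
      for (k in seq_len(nT))
        D[k, ] <- sqrt(colSums((t(det) - pos[k, ])^2))
      # greedy assignment by increasing distance, gated
      repeat {
        m <- suppressWarnings(min(D, na.rm = TRUE))
        if (!is.finite(m) || m > gate_px) break
        w <- which(D == m, arr.ind = TRUE)[1, ]
        assigned[w[1]] <- w[2]
        D[w[1], ] <- NA; D[, w[2]] <- NA
      }
    }
    fr <- data.frame(frame = i, label = labels,
                     row = NA_real_, col = NA_real_, raw = NA_real_,
                     background = NA_real_, corrected = NA_real_,
                     missing = TRUE)
    for (k in seq_len(nT)) {
      if (!is.na(assigned[k])) {
        pos[k, ] <- det[assigned[k], ]
        missRun[k] <- 0L
        v <- diskAnnulusMeans(activity@frames[, , i],
                              pos[k, 1] + channel_offset[1],
                              pos[k, 2] + channel_offset[2],
                              roi_radius_px, bg_width_px)
        fr$row[k] <- pos[k, 1]; fr$col[k] <- pos[k, 2]
        fr$raw[k] <- v["roi"]; fr$background[k] <- v["bg"]
        fr$corrected[k] <- v["roi"] - v["bg"]
        fr$missing[k] <- FALSE
      } else {
        missRun[k] <- missRun[k] + 1L
      }
    }
    rows[[i]] <- fr
  }
  methods::new("SpotTrackSet", tracks = do.call(rbind, rows),
               labels = labels, roiRadiusPx = roi_radius_px,
               bgWidthPx = bg_width_px)
}

#' Per-identity trace from a SpotTrackSet
#' @param set a \linkS4class{SpotTrackSet}.
#' @param label identity label.
#' @param fps frames per second (for the time axis).
#' @return a \linkS4class{Trace} (missing frames NA).
#' @export
spotTrace <- function(set, label, fps) {
  tr <- set@tracks[set@tracks$label == label, ]
  tr <- tr[order(tr$frame), ]
  methods::new("Trace", time = (tr$frame - 1) / fps, raw = tr$raw,
               background = tr$background, corrected = tr$corrected,
               normalized = rep(NA_real_, nrow(tr)),
               roi = label, channel = "activity")
}

#' Vulva bending angle from three spot tracks
#'
#' Interior angle at the vulva between the vectors to the two flanking
#' neurons (180 degrees = locally straight body; smaller = deeper bend),
#' plus the AS6-AS7 distance. Frames where any spot is missing, or where
#' points coincide, are NA.
#'
#' @param set a \linkS4class{SpotTrackSet} containing the three labels.
#' @param as6,vulva,as7 identity labels (defaults "AS6", "vulva", "AS7").
#' @return data.frame(frame, angle_deg, dist_px).
#' @export
vulvaAngle <- function(set, as6 = "AS6", vulva = "vulva", as7 = "AS7") {
  tr <- set@tracks
  get <- function(l) {
    d <- tr[tr$label == l, ]
    d[order(d$frame), c("frame", "row", "col", "missing")]
  }
  a <- get(as6); v <- get(vulva); b <- get(as7)
  n <- nrow(v)
  ang <- rep(NA_real_, n); dst <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (a$missing[i] || v$missing[i] || b$missing[i]) next
    v1 <- c(a$row[i] - v$row[i], a$col[i] - v$col[i])
    v2 <- c(b$row[i] - v$row[i], b$col[i] - v$col[i])
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0) next
    ang[i] <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
    dst[i] <- sqrt((a$row[i] - b$row[i])^2 + (a$col[i] - b$col[i])^2)
  }
  data.frame(frame = v$frame, angle_deg = ang, dist_px = dst)
}
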