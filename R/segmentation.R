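# Worm segmentation and 100-point midline skeletonization.
# Pipeline per frame: Otsu threshold -> drop components touching the image
# border -> keep the largest blob -> morphological cleanup (thicken, remove
# spurs, majority, fill holes) -> thin to a 1-px skeleton -> longest
# endpoint-to-endpoint geodesic path -> resample to 100 points.

#' Global Otsu threshold of a grayscale image
#'
#' Exhaustive maximization of the between-class variance over the level
#' histogram: values in [0, 1] are binned into \code{levels} equal bins
#' and every cut k (class 1 = bins 1..k, class 2 = bins k+1..levels) is
#' scored by w1*w2*(mu1 - mu2)^2. The returned threshold is the bin
#' boundary of the optimal cut (the midpoint boundary of the first and
#' last optimum under ties); pixels strictly above it are foreground.
#'
#' @param x numeric matrix/vector with values in [0, 1].
#' @param levels histogram resolution (default 256).
#' @return scalar threshold in (0, 1).
#' @export
otsuThreshold <- function(x, levels = 256L) {
  h <- graphics::hist(as.vector(x),
                      breaks = seq(0, 1, length.out = levels + 1),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  m1 <- cumsum(p * mids)
  mT <- m1[levels]
  k <- seq_len(levels - 1L)
  num <- (mT * w1[k] - m1[k])^2
  den <- w1[k] * (1 - w1[k])
  v <- ifelse(den > 0, num / den, NA_real_)
  if (!any(is.finite(v)))
    undulaError("degenerate histogram: no threshold exists",
                "thresholdError")
  best <- which(abs(v - max(v, na.rm = TRUE)) < 1e-15)
  (min(best) + max(best)) / 2 / levels
}

shiftMat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neighborCount8 <- function(m) {
  s <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) s <- s + shiftMat(m, dr, dc)
  s
}

# Zhang-Suen thinning to a 1-px-wide 8-connected skeleton.
thinMask <- function(mask, maxIter = 500L) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  # neighbour order P2..P9 clockwise from north; shift (dr, dc) moves the
  # neighbour's value onto the centre pixel
  offs <- list(c(1, 0), c(1, -1), c(0, -1), c(-1, -1),
               c(-1, 0), c(-1, 1), c(0, 1), c(1, 1))
  for (iter in seq_len(maxIter)) {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offs, function(o) shiftMat(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        nxt <- P[[if (k == 8) 1 else k + 1]]
        A <- A + (P[[k]] == 0L & nxt == 1L)
      }
      if (step == 1) {
        c1 <- P[[1]] * P[[3]] * P[[5]] == 0L
        c2 <- P[[3]] * P[[5]] * P[[7]] == 0L
      } else {
        c1 <- P[[1]] * P[[3]] * P[[7]] == 0L
        c2 <- P[[1]] * P[[5]] * P[[7]] == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

removeSpurs <- function(mask, iter = 5L) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  for (i in seq_len(iter)) {
    nc <- neighborCount8(m)
    spur <- m == 1L & nc <= 1L
    if (!any(spur)) break
    m[spur] <- 0L
  }
  m == 1L
}

majorityFilter <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  (neighborCount8(m) + m) >= 5L
}

#' Segment the worm in a grayscale frame
#'
#' Applies a global Otsu threshold, discards connected components that
#' contain border pixels, keeps the largest remaining blob, then runs the
#' morphological cleanup chain: thicken (one constrained dilation), spur
#' removal, majority filter, hole filling.
#'
#' @param frame numeric matrix in [0, 1].
#' @param invert TRUE when the worm is darker than the background.
#' @param spur_iter spur-removal iterations.
#' @param min_area_px blobs smaller than this are not considered worms.
#' @return list of class "WormMask": mask (logical matrix), areaPx,
#'   touchesBorder (always FALSE for a returned mask), thresholdValue.
#' @export
segmentWorm <- function(frame, invert = FALSE, spur_iter = 5L,
                        min_area_px = 25L) {
  if (length(unique(as.vector(frame))) < 2L)
    undulaError("constant image: no threshold exists", "thresholdError")
  thr <- otsuThreshold(frame)
  bin <- if (invert) frame < thr else frame > thr
  lab <- EBImage::bwlabel(EBImage::Image(t(bin)))
  labM <- t(EBImage::imageData(lab))
  h <- nrow(labM); w <- ncol(labM)
  border <- unique(c(labM[1, ], labM[h, ], labM[, 1], labM[, w]))
  border <- border[border > 0]
  tab <- tabulate(labM[labM > 0])
  keep <- setdiff(which(tab >= min_area_px), border)
  if (length(keep) == 0L)
    undulaError("no worm-sized component away from the border", "noWormError")
  wormLab <- keep[which.max(tab[keep])]
  m <- labM == wormLab
  # cleanup chain in the stated order
  m <- t(EBImage::imageData(
    EBImage::dilate(EBImage::Image(t(m)), EBImage::makeBrush(3, "diamond")))) > 0
  m <- removeSpurs(m, spur_iter)
  m <- majorityFilter(m)
  m <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(m))))) > 0
  structure(list(mask = m, areaPx = sum(m), touchesBorder = FALSE,
                 thresholdValue = as.numeric(thr)),
            class = "WormMask")
}

# --- skeleton path extraction -------------------------------------------

skeletonGraph <- function(px) {
  # px: matrix [n, 2] of (row, col); returns igraph + an id lookup
  key <- paste(px[, 1], px[, 2])
  idx <- seq_len(nrow(px))
  names(idx) <- key
  edges <- NULL; wts <- NULL
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nk <- paste(px[, 1] + o[1], px[, 2] + o[2])
    hit <- !is.na(idx[nk])
    if (any(hit)) {
      edges <- rbind(edges, cbind(idx[hit], idx[nk[hit]]))
      wts <- c(wts, rep(sqrt(sum(o^2)), sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n = nrow(px), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges), weight = wts)
  g
}

invalidMidline <- function(reason, nPoints) {
  structure(list(points = matrix(NA_real_, nPoints, 2L),
                 theta = rep(NA_real_, nPoints - 1L),
                 arcLengthPx = NA_real_, valid = FALSE,
                 invalidReason = reason),
            class = "Midline")
}

resamplePolyline <- function(pts, nPoints) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  tt <- seq(0, L, length.out = nPoints)
  cbind(stats::approx(cs, pts[, 1], xout = tt)$y,
        stats::approx(cs, pts[, 2], xout = tt)$y)
}

#' Extract an ordered midline from a worm mask
#'
#' Thins the mask to a skeleton, takes the longest geodesic path between
#' skeleton endpoints as the spine, extends both spine tips along their
#' local tangent to the mask boundary (thinning retracts from tapered
#' ends), and resamples to \code{n_points} equally spaced in arc length.
#' Tangent angles theta are atan2 of successive segment vectors in
#' (x = col, y = row) image coordinates.
#'
#' @param wormMask result of \code{\link{segmentWorm}} (or any list with a
#'   logical \code{mask}).
#' @param n_points points on the midline (default 100).
#' @param min_skeleton_px paths shorter than this are rejected as
#'   "skeleton_too_small".
#' @param prune_px side branches up to this geodesic length are ignored;
#'   longer branches give "branching_unresolved".
#' @return list of class "Midline": points (n_points x 2, row/col), theta
#'   (n_points - 1 rad), arcLengthPx, valid, invalidReason.
#' @export
midlineFromMask <- function(wormMask, n_points = 100L,
                            min_skeleton_px = 20, prune_px = 10) {
  mask <- wormMask$mask
  skel <- thinMask(mask)
  px <- which(skel, arr.ind = TRUE)
  if (nrow(px) < 3L) return(invalidMidline("skeleton_too_small", n_points))
  g <- skeletonGraph(px)
  deg <- igraph::degree(g)
  ends <- which(deg == 1L)
  if (length(ends) < 2L)
    return(invalidMidline(
      if (nrow(px) < min_skeleton_px) "skeleton_too_small"
      else "branching_unresolved", n_points))
  d <- igraph::distances(g, v = ends, to = ends)
  d[!is.finite(d)] <- -1
  best <- which(d == max(d), arr.ind = TRUE)[1, ]
  if (max(d) < min_skeleton_px)
    return(invalidMidline("skeleton_too_small", n_points))
  path <- igraph::shortest_paths(g, from = ends[best[1]],
                                 to = ends[best[2]])$vpath[[1]]
  path <- as.integer(path)
  # side branches: every other endpoint must be near the chosen path
  others <- setdiff(ends, c(ends[best[1]], ends[best[2]]))
  if (length(others)) {
    db <- igraph::distances(g, v = others, to = path)
    if (any(apply(db, 1, min) > prune_px))
      return(invalidMidline("branching_unresolved", n_points))
  }
  pts <- px[path, , drop = FALSE]
  # suppress the pixel staircase of the skeleton (it inflates arc length),
  # then extend the smoothed spine to the mask boundary (thinning retracts
  # from the tapered head and tail)
  pts <- cbind(movingAverage(pts[, 1], 7L), movingAverage(pts[, 2], 7L))
  pts <- extendToBoundary(pts, mask)
  pts <- resamplePolyline(pts, n_points)
  dseg <- diff(pts)
  theta <- atan2(dseg[, 1], dseg[, 2])  # y = row, x = col
  structure(list(points = pts, theta = theta,
                 arcLengthPx = sum(sqrt(rowSums(dseg^2))),
                 valid = TRUE, invalidReason = NA_character_),
            class = "Midline")
}

# extend both ends of the spine along the local tangent until leaving the
# mask; compensates the retraction of thinning at the tapered head/tail
extendToBoundary <- function(pts, mask, step = 0.4, maxPx = 20) {
  h <- nrow(mask); w <- ncol(mask)
  inside <- function(p) {
    r <- round(p[1]); c <- round(p[2])
    r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]
  }
  extendOne <- function(tip, ref) {
    v <- tip - ref
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NULL)
    v <- v / nv
    last <- NULL
    for (k in seq_len(round(maxPx / step))) {
      p <- tip + v * step * k
      if (!inside(p)) break
      last <- p
    }
    last
  }
  k <- min(5L, nrow(pts) - 1L)
  head_ext <- extendOne(pts[1, ], pts[1 + k, ])
  tail_ext <- extendOne(pts[nrow(pts), ], pts[nrow(pts) - k, ])
  if (!is.null(head_ext)) pts <- rbind(head_ext, pts)
  if (!is.null(tail_ext)) pts <- rbind(pts, tail_ext)
  pts
}

#' Segment a whole video into a MidlineSeries
#'
#' Runs \code{\link{segmentWorm}} and \code{\link{midlineFromMask}} on
#' every frame. Frames that fail segmentation or skeletonization are
#' recorded as invalid (missing data), never as zero-filled midlines.
#'
#' @param video a \linkS4class{WormVideo}.
#' @param invert,n_points,min_skeleton_px,prune_px passed through.
#' @return an un-oriented \linkS4class{MidlineSeries}; pass it to
#'   \code{\link{orientAndSmooth}} before posture analysis.
#' @export
extractMidlines <- function(video, invert = FALSE, n_points = 100L,
                            min_skeleton_px = 20, prune_px = 10) {
  n <- nFrames(video)
  pts <- array(NA_real_, c(n_points, 2L, n))
  th <- matrix(NA_real_, n_points - 1L, n)
  valid <- logical(n)
  reason <- rep(NA_character_, n)
  arc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ml <- tryCatch({
      wm <- segmentWorm(video@frames[, , i], invert = invert)
      midlineFromMask(wm, n_points, min_skeleton_px, prune_px)
    }, undulaError = function(e) {
      invalidMidline(
        if (inherits(e, "noWormError")) "no_worm" else "no_worm", n_points)
    })
    valid[i] <- ml$valid
    reason[i] <- ml$invalidReason
    if (ml$valid) {
      pts[, , i] <- ml$points
      th[, i] <- ml$theta
      arc[i] <- ml$arcLengthPx
    }
  }
  methods::new("MidlineSeries", points = pts, theta = th, valid = valid,
               invalidReason = reason, arcLengthPx = arc, oriented = FALSE)
}

flipMidline <- function(p) p[rev(seq_len(nrow(p))), , drop = FALSE]

#' Orient midlines head-first and smooth tangent angles along the body
#'
#' Frame-to-frame orientation is chosen to minimize the summed
#' point-to-point distance to the previous oriented frame. The global
#' head/tail choice comes from \code{head_hint} (a c(row, col) point near
#' the head in the first valid frame, or "auto"): with "auto", the end
#' whose displacement projects onto the centroid motion direction over the
#' first second wins, replacing the manual head check of interactive
#' trackers. Theta is then smoothed along the 100-point body axis with a
#' centered moving average (window \code{smooth_window} body points,
#' truncated at head and tail). Invalid frames stay missing.
#'
#' @param series a \linkS4class{MidlineSeries}.
#' @param fps frames per second (for the first-second motion window).
#' @param head_hint "auto" or c(row, col).
#' @param smooth_window body-point smoothing window (default 15).
#' @return oriented, smoothed \linkS4class{MidlineSeries}.
#' @export
orientAndSmooth <- function(series, fps, head_hint = "auto",
                            smooth_window = 15L) {
  vi <- which(series@valid)
  if (length(vi) == 0L)
    undulaError("all frames invalid: nothing to orient", "emptySeriesError")
  pts <- series@points
  prev <- NULL
  for (i in vi) {
    p <- pts[, , i]
    if (!is.null(prev)) {
      dKeep <- sum(sqrt(rowSums((p - prev)^2)))
      dFlip <- sum(sqrt(rowSums((flipMidline(p) - prev)^2)))
      if (dFlip < dKeep) p <- flipMidline(p)
    }
    pts[, , i] <- p
    prev <- p
  }
  flipAll <- FALSE
  if (is.numeric(head_hint)) {
    p1 <- pts[, , vi[1]]
    dHead <- sum((p1[1, ] - head_hint)^2)
    dTail <- sum((p1[nrow(p1), ] - head_hint)^2)
    flipAll <- dTail < dHead
  } else {
    # head leads motion: project end offsets onto centroid velocity
    w <- vi[vi <= vi[1] + max(2, round(fps))]
    if (length(w) >= 2L) {
      cent <- t(apply(pts[, , w, drop = FALSE], 3, colMeans))
      vel <- colMeans(diff(cent))
      nP <- dim(pts)[1]
      sc <- 0
      for (i in w) {
        sc <- sc + sum((pts[1, , i] - colMeans(pts[, , i])) * vel) -
          sum((pts[nP, , i] - colMeans(pts[, , i])) * vel)
      }
      flipAll <- sc < 0
    }
  }
  if (flipAll) for (i in vi) pts[, , i] <- flipMidline(pts[, , i])
  th <- series@theta
  for (i in vi) {
    d <- diff(pts[, , i])
    th[, i] <- movingAverage(unwrapAngles(atan2(d[, 1], d[, 2])),
                             smooth_window)
  }
  methods::new("MidlineSeries", points = pts, theta = th,
               valid = series@valid, invalidReason = series@invalidReason,
               arcLengthPx = series@arcLengthPx, oriented = TRUE)
}
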