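# Synthetic worm locomotion, silhouette rendering and fluorescence movies.
# Every downstream stage of the pipeline is validated against the ground
# truth these generators return.

#' Locomotion parameters for the synthetic worm
#'
#' The body wave is a single spatial harmonic of the tangent angle along
#' normalized arc length s in [0, 1]:
#'   theta(s, t) = A(t) * sin(2*pi*s/lambda - 2*pi*f*t) + B(t)
#' A is the peak tangent-angle amplitude (rad), lambda the wavelength as a
#' fraction of body length, f the undulation frequency (Hz; freely crawling
#' animals undulate at roughly 0.5 Hz), and B a constant dorsal bias (rad).
#' Perturbation epochs rescale A, B, the crawling speed v and the body
#' length multiplicatively, emulating optogenetic stimulation windows
#' (deeper bends, dorsal bias, slowing, contraction).
#'
#' @param duration_s recording length, seconds.
#' @param fps frames per second.
#' @param body_length_mm resting body length (adult hermaphrodite ~1 mm).
#' @param wave_amplitude_rad peak tangent-angle amplitude A.
#' @param wavelength_fraction wavelengths per body length, lambda.
#' @param wave_freq_hz undulation frequency f.
#' @param dorsal_bias_rad constant angular offset B (dorsal positive).
#' @param body_curvature_rad static body curvature as the total tangent
#'   rotation along the body, C * (s - 1/2) added to theta; nonzero values
#'   emulate the curved posture of circling (dorsally biased) animals.
#' @param wave_phase_jitter cycle-to-cycle phase noise: SD (rad per
#'   square-root second) of a seeded Gaussian random walk added to the
#'   wave phase. 0 gives a perfectly periodic wave; real undulation shows
#'   period variability, and a nonzero value makes lead/lag relations
#'   identifiable beyond one period.
#' @param speed_mm_s crawling speed v; negative values are reversals.
#' @param perturbation_epochs list of lists with fields tStart, tEnd and
#'   optional multipliers amplitude, bias, speed, length (default 1).
#' @param seed integer seed recorded with the output.
#' @return a validated parameter list of class "LocomotionParams".
#' @export
locomotionParams <- function(duration_s = 30, fps = 20, body_length_mm = 1,
                             wave_amplitude_rad = 0.45,
                             wavelength_fraction = 0.8,
                             wave_freq_hz = 0.5, dorsal_bias_rad = 0,
                             body_curvature_rad = 0, wave_phase_jitter = 0,
                             speed_mm_s = 0.15,
                             perturbation_epochs = list(), seed = 1L) {
  if (duration_s <= 0) undulaError("duration_s must be > 0", "parameterError")
  if (fps <= 0) undulaError("fps must be > 0", "parameterError")
  if (body_length_mm <= 0)
    undulaError("body_length_mm must be > 0", "parameterError")
  ep <- lapply(perturbation_epochs, function(e) {
    e <- utils::modifyList(
      list(amplitude = 1, bias = 1, speed = 1, length = 1), e)
    if (is.null(e$tStart) || is.null(e$tEnd) || e$tEnd <= e$tStart ||
        e$tStart < 0 || e$tEnd > duration_s)
      undulaError(sprintf("invalid epoch [%s, %s]", e$tStart, e$tEnd),
                  "parameterError")
    e
  })
  if (length(ep) > 1L) {
    o <- order(vapply(ep, `[[`, 0, "tStart"))
    ep <- ep[o]
    st <- vapply(ep, `[[`, 0, "tStart"); en <- vapply(ep, `[[`, 0, "tEnd")
    if (any(st[-1] < en[-length(en)]))
      undulaError("perturbation epochs overlap", "parameterError")
  }
  structure(list(duration_s = duration_s, fps = fps,
                 body_length_mm = body_length_mm,
                 wave_amplitude_rad = wave_amplitude_rad,
                 wavelength_fraction = wavelength_fraction,
                 wave_freq_hz = wave_freq_hz,
                 dorsal_bias_rad = dorsal_bias_rad,
                 body_curvature_rad = body_curvature_rad,
                 wave_phase_jitter = wave_phase_jitter,
                 speed_mm_s = speed_mm_s, perturbation_epochs = ep,
                 seed = as.integer(seed)),
            class = "LocomotionParams")
}

epochMultiplier <- function(epochs, t, field) {
  m <- rep(1, length(t))
  for (e in epochs) m[t >= e$tStart & t < e$tEnd] <- e[[field]]
  m
}

#' Generate ground-truth worm locomotion
#'
#' Evaluates the traveling-wave posture model on a 100-point midline.
#' Tangent angles are evaluated at the 99 segment midpoints and the
#' midline is reconstructed by integrating unit tangents from the head, so
#' the arc length equals the (epoch-scaled) body length exactly. The
#' centroid advances head-first along the x axis at the instantaneous
#' speed v(t).
#'
#' @param params a \code{\link{locomotionParams}} list.
#' @param n_points midline points (default 100).
#' @return a \linkS4class{GroundTruth}.
#' @export
generateLocomotion <- function(params, n_points = 100L) {
  stopifnot(inherits(params, "LocomotionParams"))
  n <- max(1L, round(params$duration_s * params$fps))
  t <- (seq_len(n) - 1L) / params$fps
  ep <- params$perturbation_epochs
  A <- params$wave_amplitude_rad * epochMultiplier(ep, t, "amplitude")
  B <- params$dorsal_bias_rad * epochMultiplier(ep, t, "bias")
  v <- params$speed_mm_s * epochMultiplier(ep, t, "speed")
  L <- params$body_length_mm * epochMultiplier(ep, t, "length")
  sMid <- (seq_len(n_points - 1L) - 0.5) / (n_points - 1L)
  # accumulated path of the centroid; the head is the low-x end of the
  # integrated midline, so forward motion advances along -x (head first)
  dt <- 1 / params$fps
  xc <- -cumsum(c(0, v[-n] * dt))
  phiNoise <- rep(0, n)
  if (params$wave_phase_jitter > 0) {
    set.seed(params$seed)
    phiNoise <- cumsum(stats::rnorm(n, 0,
                                    params$wave_phase_jitter * sqrt(dt)))
  }
  midline <- array(NA_real_, c(n_points, 2L, n))
  theta <- matrix(NA_real_, n_points - 1L, n)
  centroid <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    th <- A[i] * sin(2 * pi * sMid / params$wavelength_fraction -
                       2 * pi * params$wave_freq_hz * t[i] - phiNoise[i]) +
      B[i] + params$body_curvature_rad * (sMid - 0.5)
    ds <- L[i] / (n_points - 1L)
    x <- cumsum(c(0, ds * cos(th)))
    y <- cumsum(c(0, ds * sin(th)))
    # translate so the midline centroid sits on the commanded path
    x <- x - mean(x) + xc[i]
    y <- y - mean(y)
    midline[, 1L, i] <- x
    midline[, 2L, i] <- y
    theta[, i] <- th
    centroid[i, ] <- c(xc[i], 0)
  }
  methods::new("GroundTruth", time = t, midlineMm = midline, theta = theta,
               centroidMm = centroid, arcLengthMm = L,
               state = ifelse(v >= 0, "forward", "reverse"),
               traces = data.frame(), params = unclass(params))
}

# radius profile (px): smooth taper to ~0 at head and tail
wormRadiusPx <- function(sFrac, peakWidthMm, mmPerPx, exponent) {
  (peakWidthMm / 2 / mmPerPx) * sin(pi * sFrac)^exponent
}

drawDisk <- function(img, row, col, r, value) {
  if (r < 0.5) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  r0 <- max(1L, floor(row - r)); r1 <- min(h, ceiling(row + r))
  c0 <- max(1L, floor(col - r)); c1 <- min(w, ceiling(col + r))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  patch <- img[rr, cc, drop = FALSE]
  patch[d2 <= r^2] <- value
  img[rr, cc] <- patch
  img
}

addGaussianSpot <- function(img, row, col, sigma, amp) {
  h <- dim(img)[1]; w <- dim(img)[2]
  e <- ceiling(4 * sigma)
  r0 <- max(1L, floor(row - e)); r1 <- min(h, ceiling(row + e))
  c0 <- max(1L, floor(col - e)); c1 <- min(w, ceiling(col + e))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  img[rr, cc] <- img[rr, cc] + amp * exp(-d2 / (2 * sigma^2))
  img
}

#' Render a ground-truth midline as a silhouette video
#'
#' Each frame is the union of filled disks centred on the midline points,
#' with radius following a sin^p taper (connected blob, near-zero width at
#' head and tail). World mm coordinates map to pixels as
#' row = (y - originMm[2]) / mmPerPx + 1, col = (x - originMm[1]) / mmPerPx + 1.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param image_size c(height, width) pixels.
#' @param mm_per_px spatial calibration.
#' @param peak_width_mm full body width at midbody (adult ~0.07-0.09 mm).
#' @param width_exponent taper exponent p of sin(pi*s)^p.
#' @param fg,bg foreground/background intensities in [0, 1]; the worm is
#'   bright on dark by default, set \code{invert = TRUE} for the opposite.
#' @param invert flag for dark-worm videos.
#' @param noise_sd Gaussian pixel noise SD (after clipping to [0, 1]).
#' @param clutter optional list(row, col, radius) for a disk that touches
#'   the image border (tests the border-object rejection rule).
#' @param origin_mm world position of pixel (1, 1); NULL auto-centres the
#'   whole trajectory in the frame.
#' @param seed noise seed.
#' @return a \linkS4class{WormVideo}; meta carries originMm and seed.
#' @export
renderWormVideo <- function(truth, image_size = c(200L, 200L),
                            mm_per_px = 0.01, peak_width_mm = 0.08,
                            width_exponent = 0.5, fg = 0.9, bg = 0.1,
                            invert = FALSE, noise_sd = 0, clutter = NULL,
                            origin_mm = NULL, seed = 1L) {
  n <- nFrames(truth)
  nP <- dim(truth@midlineMm)[1]
  sFrac <- (seq_len(nP) - 1L) / (nP - 1L)
  rad <- wormRadiusPx(sFrac, peak_width_mm, mm_per_px, width_exponent)
  if (is.null(origin_mm)) {
    xr <- range(truth@midlineMm[, 1L, ]); yr <- range(truth@midlineMm[, 2L, ])
    origin_mm <- c(mean(xr) - (image_size[2] / 2) * mm_per_px,
                   mean(yr) - (image_size[1] / 2) * mm_per_px)
  }
  if (invert) { tmp <- fg; fg <- bg; bg <- tmp }
  set.seed(seed)
  stack <- array(bg, c(image_size[1], image_size[2], n))
  maxR <- max(rad)
  for (i in seq_len(n)) {
    col <- (truth@midlineMm[, 1L, i] - origin_mm[1]) / mm_per_px + 1
    row <- (truth@midlineMm[, 2L, i] - origin_mm[2]) / mm_per_px + 1
    if (any(row - maxR < 1 | row + maxR > image_size[1] |
            col - maxR < 1 | col + maxR > image_size[2]))
      undulaError(sprintf("worm leaves the frame at frame %d", i),
                  "renderError", frame = i)
    img <- stack[, , i]
    for (j in seq_len(nP)) img <- drawDisk(img, row[j], col[j], rad[j], fg)
    if (!is.null(clutter))
      img <- drawDisk(img, clutter$row, clutter$col, clutter$radius, fg)
    stack[, , i] <- img
  }
  if (noise_sd > 0) {
    stack <- stack + stats::rnorm(length(stack), 0, noise_sd)
    stack[stack < 0] <- 0; stack[stack > 1] <- 1
  }
  methods::new("WormVideo", frames = stack, fps = truth@params$fps,
               mmPerPx = mm_per_px, protocol = data.frame(),
               meta = list(originMm = origin_mm, seed = seed,
                           invert = invert, widthExponent = width_exponent,
                           peakWidthMm = peak_width_mm))
}

#' Ground-truth midline in pixel coordinates of a rendered video
#'
#' Convenience for round-trip tests: applies the renderer's world-to-pixel
#' mapping to the true midline.
#' @param truth a \linkS4class{GroundTruth}.
#' @param video the \linkS4class{WormVideo} rendered from it.
#' @return array [nPoints, 2(row, col), nFrames] in pixels.
#' @export
truthMidlinePx <- function(truth, video) {
  o <- video@meta$originMm
  mpp <- video@mmPerPx
  out <- array(NA_real_, dim(truth@midlineMm))
  out[, 1L, ] <- (truth@midlineMm[, 2L, ] - o[2]) / mpp + 1
  out[, 2L, ] <- (truth@midlineMm[, 1L, ] - o[1]) / mpp + 1
  out
}

#' Synthetic dorso-ventral muscle fluorescence movie
#'
#' Places n ROIs per side as bright disks in a dorsal and a ventral band.
#' Dorsal intensity follows base + amp * w(2*pi*f*t), the ventral band the
#' same waveform phase-shifted by pi when \code{antiphase}, mirroring the
#' reciprocity of spontaneous dorso-ventral muscle activity. The waveform w
#' is a sinusoid by default; \code{rectified = TRUE} uses max(0, sin) for
#' spiky, burst-like traces. A photostimulation epoch adds constant steps
#' to each side (dorsal up / ventral down emulates selective cholinergic
#' drive onto dorsal muscle).
#'
#' @param n_rois_per_side ROIs per band (>= 1).
#' @param duration_s,fps movie timing.
#' @param freq_hz oscillation frequency (spontaneous muscle activity,
#'   ~0.25 Hz in immobilized preparations).
#' @param antiphase ventral band phase-shifted by pi when TRUE.
#' @param rectified use max(0, sin) instead of sin as the waveform.
#' @param base,amp ROI baseline intensity and oscillation amplitude.
#' @param photostim NULL or list(tStart, tEnd, dorsalStep, ventralStep).
#' @param noise_sd Gaussian pixel noise SD.
#' @param image_size c(height, width).
#' @param roi_radius_px disk radius.
#' @param seed noise seed.
#' @return list(video, rois, background, truth): the movie, a list of
#'   logical ROI masks named dorsal1..n / ventral1..n, one equal-area
#'   background mask, and a data.frame of true per-ROI intensity traces.
#' @export
generateMuscleMovie <- function(n_rois_per_side = 4L, duration_s = 30,
                                fps = 10, freq_hz = 0.25, antiphase = TRUE,
                                rectified = FALSE, base = 0.35, amp = 0.25,
                                photostim = NULL, noise_sd = 0,
                                image_size = c(120L, 160L),
                                roi_radius_px = 8, seed = 1L) {
  if (n_rois_per_side < 1L)
    undulaError("need at least one ROI per side", "parameterError")
  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1L) / fps
  if (!is.null(photostim) &&
      (photostim$tStart < 0 || photostim$tEnd > duration_s))
    undulaError("photostim epoch outside movie duration", "parameterError")
  wave <- function(phase) {
    s <- sin(2 * pi * freq_hz * t + phase)
    if (rectified) pmax(0, s) else s
  }
  dor <- base + amp * wave(0)
  ven <- base + amp * wave(if (antiphase) pi else 0)
  if (!is.null(photostim)) {
    on <- t >= photostim$tStart & t < photostim$tEnd
    dor[on] <- dor[on] + photostim$dorsalStep
    ven[on] <- ven[on] + photostim$ventralStep
  }
  bgLevel <- 0.05
  h <- image_size[1]; w <- image_size[2]
  cols <- round(seq(w * 0.2, w * 0.9, length.out = n_rois_per_side))
  rowD <- round(h * 0.25); rowV <- round(h * 0.75)
  mkMask <- function(row, col) {
    m <- matrix(FALSE, h, w)
    rr <- seq_len(h); cc <- seq_len(w)
    d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
    m[d2 <= roi_radius_px^2] <- TRUE
    m
  }
  rois <- list()
  for (k in seq_len(n_rois_per_side)) {
    rois[[paste0("dorsal", k)]] <- mkMask(rowD, cols[k])
    rois[[paste0("ventral", k)]] <- mkMask(rowV, cols[k])
  }
  bgMask <- mkMask(round(h / 2), round(w * 0.06))
  set.seed(seed)
  stack <- array(bgLevel, c(h, w, n))
  for (i in seq_len(n)) {
    img <- stack[, , i]
    for (k in seq_len(n_rois_per_side)) {
      img[rois[[paste0("dorsal", k)]]] <- dor[i]
      img[rois[[paste0("ventral", k)]]] <- ven[i]
    }
    stack[, , i] <- img
  }
  if (noise_sd > 0) {
    stack <- stack + stats::rnorm(length(stack), 0, noise_sd)
    stack[stack < 0] <- 0; stack[stack > 1] <- 1
  }
  video <- methods::new("WormVideo", frames = stack, fps = fps,
                        mmPerPx = 1, protocol = if (is.null(photostim))
                          data.frame() else
                          data.frame(name = "photostim",
                                     tStart = photostim$tStart,
                                     tEnd = photostim$tEnd),
                        meta = list(seed = seed, channel = "GCaMP"))
  truth <- data.frame(time_s = t, dorsal = dor, ventral = ven)
  list(video = video, rois = rois, background = bgMask, truth = truth)
}

#' Synthetic dual-channel neuron-tracking movie (AS6 / vulva / AS7)
#'
#' Three Gaussian spots ride the moving midline at fixed arc-length
#' fractions. The marker channel shows all three at constant brightness
#' (the vulva spot emulates the vulval-muscle GFP landmark used for stage
#' tracking); the activity channel shows AS6 and AS7 with brightness
#' following the true vulva bending angle, time-advanced by
#' \code{activity_lead_s} (AS6) and by \code{activity_lead_s -
#' inter_neuron_lag_s} (AS7). Frames are rendered in a stage-compensated
#' reference (centroid held at the image centre), as produced by a
#' tracking stage that keeps the fluorescent marker in view.
#'
#' @param truth \linkS4class{GroundTruth}; NULL builds a default slowed
#'   (under-coverslip) scenario: 0.25 Hz wave, 0.05 mm/s.
#' @param as6_s,vulva_s,as7_s arc-length fractions, ordered
#'   0 <= as6_s < vulva_s < as7_s <= 1 (AS6 anterior to the vulva).
#' @param activity_lead_s seconds by which AS6 activity leads the vulva
#'   angle (the anterior neuron fires ahead of the local bend).
#' @param inter_neuron_lag_s seconds by which AS7 activity trails AS6.
#' @param duration_s,seed scenario length and noise seed (used when
#'   truth is NULL).
#' @param image_size,mm_per_px,spot_sigma_px rendering geometry.
#' @param marker_amp,activity_base,activity_amp spot brightness.
#' @param noise_sd Gaussian pixel noise SD.
#' @return list(activity, marker, truth) where truth holds time,
#'   positionsPx [label, (row, col), frame], activity traces, the true
#'   vulva angle (degrees) and the locomotion state per frame.
#' @export
generateNeuronMovie <- function(truth = NULL, as6_s = 0.30, vulva_s = 0.50,
                                as7_s = 0.70, activity_lead_s = 2.0,
                                inter_neuron_lag_s = 1.0, duration_s = 60,
                                image_size = c(240L, 240L), mm_per_px = 0.005,
                                spot_sigma_px = 3, marker_amp = 0.7,
                                activity_base = 0.45, activity_amp = 0.25,
                                noise_sd = 0, seed = 1L) {
  if (!(as6_s >= 0 && as6_s < vulva_s && vulva_s < as7_s && as7_s <= 1))
    undulaError("need 0 <= as6_s < vulva_s < as7_s <= 1", "parameterError")
  if (is.null(truth)) {
    # slowed under-coverslip scenario; the static curvature keeps the
    # interior vulva angle oscillating at the undulation fundamental (a
    # straight mean posture would rectify it to twice the wave frequency,
    # since a constant tangent offset cancels between the two arms)
    truth <- generateLocomotion(locomotionParams(
      duration_s = duration_s, fps = 20, wave_freq_hz = 0.25,
      speed_mm_s = 0.05, wave_amplitude_rad = 0.45,
      body_curvature_rad = 2.0, wave_phase_jitter = 0.3, seed = seed))
  }
  n <- nFrames(truth)
  t <- truth@time
  nP <- dim(truth@midlineMm)[1]
  sGrid <- (seq_len(nP) - 1L) / (nP - 1L)
  posMm <- array(NA_real_, c(3L, 2L, n),
                 dimnames = list(c("AS6", "vulva", "AS7"), c("x", "y"), NULL))
  for (i in seq_len(n)) {
    for (d in 1:2) {
      posMm[1L, d, i] <- stats::approx(sGrid, truth@midlineMm[, d, i], as6_s)$y
      posMm[2L, d, i] <- stats::approx(sGrid, truth@midlineMm[, d, i], vulva_s)$y
      posMm[3L, d, i] <- stats::approx(sGrid, truth@midlineMm[, d, i], as7_s)$y
    }
  }
  # true vulva bending angle from the spot geometry
  ang <- vapply(seq_len(n), function(i) {
    v1 <- posMm[1L, , i] - posMm[2L, , i]
    v2 <- posMm[3L, , i] - posMm[2L, , i]
    acos(pmin(1, pmax(-1, sum(v1 * v2) /
                        sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }, 0)
  z <- if (stats::sd(ang) > 0) (ang - mean(ang)) / stats::sd(ang) else ang * 0
  shift <- function(lead) stats::approx(t, z, xout = t + lead, rule = 2)$y
  act6 <- activity_base + activity_amp * shift(activity_lead_s)
  act7 <- activity_base +
    activity_amp * shift(activity_lead_s - inter_neuron_lag_s)
  # stage compensation: centroid pinned to the image centre
  ctr <- c(image_size[1] / 2, image_size[2] / 2)
  posPx <- array(NA_real_, c(3L, 2L, n),
                 dimnames = list(c("AS6", "vulva", "AS7"),
                                 c("row", "col"), NULL))
  posPx[, 1L, ] <- (posMm[, 2L, ] -
                      matrix(truth@centroidMm[, 2L], 3L, n, byrow = TRUE)) /
    mm_per_px + ctr[1]
  posPx[, 2L, ] <- (posMm[, 1L, ] -
                      matrix(truth@centroidMm[, 1L], 3L, n, byrow = TRUE)) /
    mm_per_px + ctr[2]
  pad <- 6 * spot_sigma_px
  if (any(posPx[, 1L, ] < pad | posPx[, 1L, ] > image_size[1] - pad |
          posPx[, 2L, ] < pad | posPx[, 2L, ] > image_size[2] - pad))
    undulaError("spots leave the usable frame; enlarge image_size",
                "renderError")
  set.seed(seed)
  bgLevel <- 0.05
  mk <- array(bgLevel, c(image_size[1], image_size[2], n))
  ac <- array(bgLevel, c(image_size[1], image_size[2], n))
  for (i in seq_len(n)) {
    img <- mk[, , i]
    for (k in 1:3)
      img <- addGaussianSpot(img, posPx[k, 1L, i], posPx[k, 2L, i],
                             spot_sigma_px, marker_amp)
    mk[, , i] <- img
    img <- ac[, , i]
    img <- addGaussianSpot(img, posPx[1L, 1L, i], posPx[1L, 2L, i],
                           spot_sigma_px, act6[i])
    img <- addGaussianSpot(img, posPx[3L, 1L, i], posPx[3L, 2L, i],
                           spot_sigma_px, act7[i])
    ac[, , i] <- img
  }
  if (noise_sd > 0) {
    mk <- mk + stats::rnorm(length(mk), 0, noise_sd)
    mk[mk < 0] <- 0; mk[mk > 1] <- 1
    ac <- ac + stats::rnorm(length(ac), 0, noise_sd)
    ac[ac < 0] <- 0; ac[ac > 1] <- 1
  }
  fpsv <- truth@params$fps
  mkV <- methods::new("WormVideo", frames = mk, fps = fpsv,
                      mmPerPx = mm_per_px, protocol = data.frame(),
                      meta = list(seed = seed, channel = "marker"))
  acV <- methods::new("WormVideo", frames = ac, fps = fpsv,
                      mmPerPx = mm_per_px, protocol = data.frame(),
                      meta = list(seed = seed, channel = "activity"))
  list(activity = acV, marker = mkV,
       truth = list(time = t, positionsPx = posPx,
                    activity = data.frame(time_s = t, AS6 = act6, AS7 = act7),
                    vulvaAngleDeg = ang, state = truth@state,
                    params = list(activity_lead_s = activity_lead_s,
                                  inter_neuron_lag_s = inter_neuron_lag_s,
                                  as6_s = as6_s, vulva_s = vulva_s,
                                  as7_s = as7_s)))
}
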