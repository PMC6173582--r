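# Shared fixtures, built once per test run and memoized.

.fixtureCache <- new.env(parent = emptyenv())

memoize <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# 20 noise-free rendered frames of a freely crawling worm, plus truth
roundTripFixture <- function() {
  memoize("roundTrip", function() {
    p <- locomotionParams(duration_s = 2, fps = 10, seed = 7)
    truth <- generateLocomotion(p)
    video <- renderWormVideo(truth, image_size = c(230L, 230L),
                             mm_per_px = 0.01, noise_sd = 0)
    series <- orientAndSmooth(extractMidlines(video), fps(video))
    list(params = p, truth = truth, video = video, series = series,
         truthPx = truthMidlinePx(truth, video))
  })
}

# the dual-neuron tracking scenario (slowed, curved, jittered wave) with
# a 2-s activity lead, tracked end to end
neuronScenarioTracked <- function() {
  memoize("neuronScenario", function() {
    sc <- generateNeuronMovie(activity_lead_s = 2.0, duration_s = 60,
                              seed = 11L, noise_sd = 0.01)
    init <- list(AS6 = sc$truth$positionsPx[1, , 1],
                 vulva = sc$truth$positionsPx[2, , 1],
                 AS7 = sc$truth$positionsPx[3, , 1])
    tracks <- trackNeurons(sc$activity, sc$marker, init = init)
    list(scenario = sc, tracks = tracks, fps = 20,
         angle = vulvaAngle(tracks))
  })
}

# naive exhaustive between-class-variance maximizer over 256 histogram
# levels (direct per-cut class means, no cumulative-sum shortcuts);
# returns the set of argmax cuts (ties possible on discrete histograms)
bruteForceOtsuBins <- function(x, levels = 256L) {
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- hist(as.vector(x), breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  v <- rep(NA_real_, levels - 1L)
  for (k in seq_len(levels - 1L)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v[k] <- w0 * w1 * (m0 - m1)^2
  }
  which(abs(v - max(v, na.rm = TRUE)) < 1e-15)
}

# a two-value image with a worm-like blob away from the border
simpleWormImage <- function(h = 120L, w = 260L, rows = 56:65, cols = 31:230,
                            fg = 0.9, bg = 0.1) {
  img <- matrix(bg, h, w)
  img[rows, cols] <- fg
  img
}

# MidlineSeries built directly from ground-truth midlines (mm -> px),
# bypassing rendering/segmentation
truthMidlineSeries <- function(truth, mm_per_px = 0.01) {
  n <- nFrames(truth)
  nP <- dim(truth@midlineMm)[1]
  pts <- array(NA_real_, c(nP, 2L, n))
  pts[, 1L, ] <- truth@midlineMm[, 2L, ] / mm_per_px
  pts[, 2L, ] <- truth@midlineMm[, 1L, ] / mm_per_px
  th <- matrix(NA_real_, nP - 1L, n)
  arc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- diff(pts[, , i])
    th[, i] <- atan2(d[, 1], d[, 2])
    arc[i] <- sum(sqrt(rowSums(d^2)))
  }
  methods::new("MidlineSeries", points = pts, theta = th,
               valid = rep(TRUE, n), invalidReason = rep(NA_character_, n),
               arcLengthPx = arc, oriented = TRUE)
}

rigidTransform <- function(pts, angle, shift) {
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2L)
  sweep(pts %*% t(R), 2, shift, `+`)
}
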