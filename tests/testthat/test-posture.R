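# Posture metrics: kymograph normalization, 3-point angles, dorso-ventral
# ratio, differential bending, eigenworms, body metrics.

straightSeries <- function(angle, n = 3L) {
  # straight worm at a global orientation, several frames
  pts <- array(NA_real_, c(100, 2, n))
  for (i in seq_len(n)) {
    s <- seq(0, 99, length.out = 100)
    pts[, 1, i] <- 50 + s * sin(angle)
    pts[, 2, i] <- 50 + s * cos(angle)
  }
  th <- matrix(angle, 99, n)
  methods::new("MidlineSeries", points = pts, theta = th,
               valid = rep(TRUE, n), invalidReason = rep(NA_character_, n),
               arcLengthPx = rep(99, n), oriented = TRUE)
}

test_that("kymograph normalization removes global orientation", {
  for (ang in c(0, 0.7, -2.1)) {
    k <- twoPointKymograph(straightSeries(ang))
    expect_lt(max(abs(k)), 1e-12)
  }
  # every frame's normalized angles sum to zero
  fx <- roundTripFixture()
  k <- twoPointKymograph(fx$series)
  expect_lt(max(abs(rowSums(k))), 1e-9)
})

test_that("quarter-circle posture gives angles linear in body index", {
  t <- seq(0, pi / 2, length.out = 100)
  pts <- array(NA_real_, c(100, 2, 1))
  pts[, 1, 1] <- 200 - 100 * cos(t)
  pts[, 2, 1] <- 100 * sin(t)
  d <- diff(pts[, , 1])
  s <- methods::new("MidlineSeries", points = pts,
                    theta = matrix(atan2(d[, 1], d[, 2]), 99, 1),
                    valid = TRUE, invalidReason = NA_character_,
                    arcLengthPx = sum(sqrt(rowSums(d^2))), oriented = TRUE)
  k <- twoPointKymograph(s)[1, ]
  fit <- stats::lm(k ~ seq_along(k))
  expect_gt(summary(fit)$r.squared, 0.9999)
  expect_lt(abs(k[50]), 0.02)  # zero at the midpoint
})

test_that("kymograph stripes travel at lambda * f body lengths per second", {
  p <- locomotionParams(duration_s = 10, fps = 20, wave_freq_hz = 0.5,
                        wavelength_fraction = 0.8, seed = 1)
  tr <- generateLocomotion(p)
  k <- twoPointKymograph(truthMidlineSeries(tr))
  # expected delay between body points 30 and 70 (0.4 body lengths):
  # dt = ds / (lambda * f) = 0.4 / 0.4 = 1 s = 20 frames
  a <- k[, 30]; b <- k[, 70]
  cc <- vapply(0:40, function(l)
    stats::cor(a[1:(length(a) - l)], b[(1 + l):length(b)]), 0)
  expect_equal(which.max(cc) - 1L, 20L, tolerance = 1)
})

test_that("3-point angles match trigonometric oracles and sign rules", {
  prim <- undulaR:::signedThreePointAngle
  # collinear
  expect_equal(prim(c(0, 0), c(0, 1), c(0, 2)), 0)
  # right angle: P1 (0,0), P2 (1, 0) -> rows, cols: use (row, col)
  expect_equal(abs(prim(c(0, 0), c(0, 1), c(1, 1))), 90)
  # middle point deviating up (smaller row) is dorsal-positive
  expect_gt(prim(c(10, 0), c(9, 1), c(10, 2), dorsalUp = TRUE), 0)
  expect_lt(prim(c(10, 0), c(9, 1), c(10, 2), dorsalUp = FALSE), 0)
})

test_that("mirror antisymmetry: reflected worm with flipped side matches", {
  fx <- roundTripFixture()
  s <- fx$series
  ang <- threePointAngles(s, "dorsal_up")
  m <- s
  m@points[, 1, ] <- -m@points[, 1, ]  # reflect rows
  angMirror <- threePointAngles(m, "ventral_up")
  expect_equal(ang, angMirror, tolerance = 1e-9)
  angNoFlip <- threePointAngles(m, "dorsal_up")
  expect_equal(ang, -angNoFlip, tolerance = 1e-9)
})

recomputeTheta <- function(s) {
  for (i in seq_len(nFrames(s))) {
    d <- diff(s@points[, , i])
    s@theta[, i] <- atan2(d[, 1], d[, 2])
  }
  s
}

test_that("angle metrics are invariant under rigid motion", {
  fx <- roundTripFixture()
  s <- recomputeTheta(fx$series)
  ang <- threePointAngles(s, "dorsal_up")
  k <- twoPointKymograph(s)
  set.seed(42)
  for (r in 1:10) {
    a <- stats::runif(1, 0, 2 * pi)
    shift <- stats::runif(2, -30, 30)
    # rotation in (row, col) preserves handedness, so signs must hold
    s2 <- s
    for (i in seq_len(nFrames(s)))
      s2@points[, , i] <- rigidTransform(s@points[, , i], a, shift)
    s2 <- recomputeTheta(s2)
    expect_equal(threePointAngles(s2, "dorsal_up"), ang,
                 tolerance = 1e-6 * 180 / pi)
    expect_equal(twoPointKymograph(s2), k, tolerance = 1e-6)
  }
})

test_that("dorsoventral ratio follows its defining arithmetic", {
  expect_equal(dorsoventralRatio(rep(c(10, -10), 20)), 1.0)
  expect_equal(dorsoventralRatio(c(20, 20, -10, -10)), 2.0)
  expect_error(dorsoventralRatio(c(5, 10, 15)),
               class = "undefinedRatioError")
})

test_that("differential bending: static, ramp, and freeze scenarios", {
  tm <- (0:399) / 20
  protocol <- list(dark = c(0, 10), light = c(10, 19.9))
  constAng <- matrix(5, 400, 11)
  r <- differentialBending(constAng, tm, protocol)
  expect_true(all(r$perAngle$meanAbsDeltaDark == 0))
  expect_equal(r$anteriorDeltaDelta, 0)
  # linear ramp 1 deg/frame is invariant to centered smoothing
  ramp <- matrix(rep(seq_len(400), 11), 400, 11)
  r2 <- differentialBending(ramp, tm, protocol)
  # the truncated centered smoother halves the slope over its ~7 edge
  # frames, so the epoch means sit within 2% of the 1 deg/frame ramp
  expect_equal(mean(r2$perAngle$meanAbsDeltaDark), 1, tolerance = 0.02)
  expect_equal(r2$posteriorDeltaDelta, 0, tolerance = 0.02)
  # freezing the wave during the light epoch reduces posterior bending
  p <- locomotionParams(duration_s = 20, fps = 20,
                        perturbation_epochs = list(
                          list(tStart = 10, tEnd = 20, amplitude = 0)))
  tr <- generateLocomotion(p)
  ang <- threePointAngles(truthMidlineSeries(tr), "ventral_up")
  r3 <- differentialBending(ang, tr@time,
                            list(dark = c(0, 10), light = c(10, 19.9)))
  expect_lt(r3$posteriorDeltaDelta, 0)
  expect_lt(r3$anteriorDeltaDelta, 0)
  # epochs outside the recording are protocol errors
  expect_error(
    differentialBending(constAng, tm, list(dark = c(0, 10),
                                           light = c(15, 30))),
    class = "protocolError")
})

test_that("eigenworm basis identities hold", {
  # library of sinusoid postures over two phases
  s <- (0:98) / 98
  set.seed(3)
  phases <- stats::runif(300, 0, 2 * pi)
  lib <- t(vapply(phases, function(ph) sin(2 * pi * s / 0.8 + ph), s))
  lib <- lib - rowMeans(lib)
  # a phase-shifted sinusoid family spans exactly two components
  basis <- fitEigenworms(lib, k = 2)
  expect_gt(sum(basis@varianceExplained[1:2]), 0.95)
  # projecting component j gives the unit vector e_j
  proj <- projectEigenworms(
    sweep(basis@components, 2, basis@center, `+`), basis)
  expect_equal(proj, diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  # the rank-2 library reconstructs exactly from its two components
  rec <- reconstructEigenworms(projectEigenworms(lib, basis), basis)
  expect_lt(max(abs(rec - lib)), 1e-8)
  expect_error(fitEigenworms(lib[1:3, ], k = 5), class = "rankError")
  expect_error(fitEigenworms(lib, k = 50), class = "rankError")
})

test_that("body metrics convert pixels to millimetres", {
  img <- simpleWormImage(120L, 260L, rows = 56:65, cols = 31:230)
  wm <- segmentWorm(img)
  ml <- midlineFromMask(wm)
  pts <- array(ml$points, c(100, 2, 1))
  s <- methods::new("MidlineSeries", points = pts,
                    theta = matrix(ml$theta, 99, 1), valid = TRUE,
                    invalidReason = NA_character_,
                    arcLengthPx = ml$arcLengthPx, oriented = TRUE)
  bm <- bodyMetrics(s, mm_per_px = 0.005, fps = 10)
  expect_equal(nrow(bm), 1L)
  expect_equal(bm$length_mm, 1.0, tolerance = 0.02)
  # generator length multiplier shows up as a proportional dip
  p <- locomotionParams(duration_s = 10, fps = 5,
                        perturbation_epochs = list(
                          list(tStart = 4, tEnd = 8, length = 0.9)))
  tr <- generateLocomotion(p)
  bm2 <- bodyMetrics(truthMidlineSeries(tr, 0.01), 0.01, 5)
  inEpoch <- bm2$time_s >= 4 & bm2$time_s < 8
  expect_equal(mean(bm2$length_mm[inEpoch]) / mean(bm2$length_mm[!inEpoch]),
               0.9, tolerance = 0.001)
})
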