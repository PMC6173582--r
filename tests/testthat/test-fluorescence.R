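# ROI extraction, dF/F, ratiometric dR/R, and first-peak alignment.

uniformVideo <- function(values, h = 20L, w = 30L, fps = 10) {
  st <- array(NA_real_, c(h, w, length(values)))
  for (i in seq_along(values)) st[, , i] <- values[i]
  methods::new("WormVideo", frames = st, fps = fps, mmPerPx = 1,
               protocol = data.frame(), meta = list())
}

diskMask <- function(h, w, row, col, r) {
  m <- matrix(FALSE, h, w)
  m[outer((seq_len(h) - row)^2, (seq_len(w) - col)^2, `+`) <= r^2] <- TRUE
  m
}

test_that("ROI extraction subtracts the background ROI mean per frame", {
  v <- uniformVideo(rep(100 / 255, 5))
  roi <- diskMask(20, 30, 10, 8, 4)
  bg <- diskMask(20, 30, 10, 22, 4)
  tr <- extractRoiTrace(v, roi, bg)
  expect_equal(corrected(tr), rep(0, 5))
  # distinct ROI and background levels
  st <- array(50 / 255, c(20, 30, 3))
  for (i in 1:3) { f <- st[, , i]; f[roi] <- 150 / 255; st[, , i] <- f }
  v2 <- methods::new("WormVideo", frames = st, fps = 10, mmPerPx = 1,
                     protocol = data.frame(), meta = list())
  tr2 <- extractRoiTrace(v2, roi, bg)
  expect_equal(corrected(tr2), rep(100 / 255, 3))
  expect_error(extractRoiTrace(v, matrix(FALSE, 20, 30), bg),
               class = "geometryError")
  expect_error(extractRoiTrace(v, diskMask(5, 5, 2, 2, 1), bg),
               class = "geometryError")
  expect_warning(extractRoiTrace(v, roi, diskMask(20, 30, 10, 22, 6)),
                 "area")
})

test_that("muscle movie round trip matches the generator truth", {
  mm <- generateMuscleMovie(n_rois_per_side = 2, duration_s = 20, fps = 10,
                            noise_sd = 0)
  trD <- extractRoiTrace(mm$video, mm$rois$dorsal1, mm$background, "d1")
  trV <- extractRoiTrace(mm$video, mm$rois$ventral1, mm$background, "v1")
  expect_gt(stats::cor(corrected(trD), mm$truth$dorsal), 0.99)
  expect_gt(stats::cor(corrected(trV), mm$truth$ventral), 0.99)
  # antiphase reciprocity in dF/F
  dD <- normalized(deltaFOverF(trD))
  dV <- normalized(deltaFOverF(trV))
  expect_lte(stats::cor(dD, dV), -0.9)
})

test_that("photostimulation steps move dorsal and ventral dF/F oppositely", {
  mm <- generateMuscleMovie(duration_s = 30, fps = 10, noise_sd = 0.005,
                            photostim = list(tStart = 15, tEnd = 25,
                                             dorsalStep = 0.5,
                                             ventralStep = -0.3), seed = 2)
  dD <- deltaFOverF(extractRoiTrace(mm$video, mm$rois$dorsal1,
                                    mm$background))
  dV <- deltaFOverF(extractRoiTrace(mm$video, mm$rois$ventral1,
                                    mm$background))
  on <- traceTime(dD) >= 15 & traceTime(dD) < 25
  expect_gt(mean(normalized(dD)[on]), mean(normalized(dD)[!on]))
  expect_lt(mean(normalized(dV)[on]), mean(normalized(dV)[!on]))
})

test_that("a flat movie yields dF/F of zero within noise tolerance", {
  mm <- generateMuscleMovie(duration_s = 10, fps = 10, amp = 0,
                            noise_sd = 0)
  d <- deltaFOverF(extractRoiTrace(mm$video, mm$rois$dorsal1,
                                   mm$background))
  expect_lt(max(abs(normalized(d))), 1e-12)
})

test_that("dF/F follows its printed formula and identities", {
  expect_equal(deltaFOverF(c(1, 2, 3)), c(-0.5, 0, 0.5))
  expect_equal(deltaFOverF(c(2, 2, 2)), c(0, 0, 0))
  set.seed(1)
  x <- stats::runif(500, 0.5, 2)
  expect_lt(abs(mean(deltaFOverF(x))), 1e-12)
  # scale invariance, offset sensitivity
  expect_equal(deltaFOverF(3.7 * x), deltaFOverF(x), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(deltaFOverF(x + 1), deltaFOverF(x))))
  expect_error(deltaFOverF(c(-1, 1)), class = "normalizationError")
})

test_that("dR/R cancels common factors and honors the normalization span", {
  expect_equal(normalized(deltaROverR(c(2, 4, 6), c(1, 2, 3))), c(0, 0, 0))
  rt <- deltaROverR(c(2, 4), c(1, 1))
  expect_equal(rt@ratio, c(2, 4))
  expect_equal(normalized(rt), c(-1 / 3, 1 / 3))
  # uniform bleaching of both channels leaves dR/R unchanged
  t <- seq(0, 10, by = 0.1)
  yfp <- 2 + sin(t); cfp <- 1.5 + 0.3 * cos(t)
  bleach <- exp(-0.1 * t)
  r1 <- normalized(deltaROverR(yfp, cfp, t))
  r2 <- normalized(deltaROverR(yfp * bleach, cfp * bleach, t))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(deltaROverR(c(1, 2), c(1, 0)), class = "ratioError")
  # window span normalizes to the stimulation-period mean
  rw <- deltaROverR(yfp, cfp, t, span = "window", window = c(2, 4))
  sel <- t >= 2 & t <= 4
  expect_lt(abs(mean(normalized(rw)[sel])), 1e-9)
  expect_gt(abs(mean(normalized(rw))), 1e-4)
})

test_that("alignment shifts the first reference peak to t = 0", {
  fps <- 10
  t <- seq(0, 10, by = 1 / fps)
  ref <- exp(-((t - 3)^2) / 0.1)
  other <- exp(-((t - 5)^2) / 0.1)
  al <- alignToFirstPeak(list(d = ref, v = other), "d", fps)
  expect_false(al$excluded)
  expect_equal(al$peakTime_s, 3, tolerance = 0.11)
  expect_equal(al$time_s[which.max(ref)], 0, tolerance = 1e-9)
  # the first peak anchors the shift: a second peak is ignored
  ref2 <- exp(-((t - 3)^2) / 0.1) + 0.8 * exp(-((t - 7)^2) / 0.1)
  al2 <- alignToFirstPeak(list(d = ref2), "d", fps)
  expect_equal(al2$peakTime_s, 3, tolerance = 0.11)
  # no qualifying peak: excluded with a reason, not dropped
  alno <- alignToFirstPeak(list(d = rep(1, 50)), "d", fps,
                           min_prominence = 0.1)
  expect_true(alno$excluded)
  expect_match(alno$reason, "peak")
})

test_that("dorsal-peak alignment puts the ventral minimum near t = 0", {
  mm <- generateMuscleMovie(duration_s = 20, fps = 10, antiphase = TRUE,
                            noise_sd = 0)
  dD <- normalized(deltaFOverF(extractRoiTrace(mm$video, mm$rois$dorsal1,
                                               mm$background)))
  dV <- normalized(deltaFOverF(extractRoiTrace(mm$video, mm$rois$ventral1,
                                               mm$background)))
  al <- alignToFirstPeak(list(dorsal = dD, ventral = dV), "dorsal", 10)
  expect_false(al$excluded)
  # antiphase: at the dorsal peak (t = 0) the ventral trace is at its
  # trough (all troughs of the noise-free sinusoid are equal)
  v0 <- al$traces$ventral[which.min(abs(al$time_s))]
  expect_lt(v0, min(al$traces$ventral) +
              0.02 * diff(range(al$traces$ventral)))
})
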