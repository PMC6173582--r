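# Event-wise cross-correlation: smoothing, event segmentation, lag
# conventions, peak rules, reversal selection.

test_that("preprocessing is a truncated centered 10-sample average", {
  expect_equal(preprocessTrace(rep(3, 50)), rep(3, 50))
  x <- rep(0, 50); x[25] <- 1
  sm <- preprocessTrace(x)
  expect_equal(sum(sm > 0), 10L)
  expect_equal(max(sm), 0.1)
  set.seed(2)
  n <- stats::rnorm(500)
  expect_lt(stats::var(preprocessTrace(n)), stats::var(n))
  expect_error(preprocessTrace(1:5), class = "inputError")
})

test_that("bending events span consecutive minima of the angle trace", {
  expect_identical(nrow(segmentEvents(rep(1, 100))), 0L)
  t <- seq(0, 20, by = 0.1)
  x <- sin(2 * pi * t / 5)
  ev <- segmentEvents(x, rate_hz = 10)
  expect_identical(nrow(ev), 3L)
  expect_equal((ev$end - ev$start) / 10, rep(5, 3), tolerance = 0.02)
  # robust to noise below the prominence threshold
  set.seed(8)
  xn <- x + stats::rnorm(length(x), 0, 0.03)
  evn <- segmentEvents(xn, rate_hz = 10, prominence = 0.3)
  expect_identical(nrow(evn), 3L)
  # sub-second events are dropped and counted
  f <- sin(2 * pi * t / 0.8)
  evf <- segmentEvents(f, rate_hz = 10)
  expect_identical(nrow(evf), 0L)
  expect_gt(attr(evf, "nDroppedShort"), 0L)
})

test_that("autocorrelation peaks at exactly 1 at lag zero", {
  set.seed(3)
  x <- stats::rnorm(300)
  cs <- xcorrEvents(x, x, data.frame(start = 20L, end = 250L))
  expect_equal(cs@peak$value, 1.0)
  expect_equal(cs@peak$lagS, 0)
  expect_true(all(abs(cs@perEvent[is.finite(cs@perEvent)]) <= 1 + 1e-12))
})

test_that("a 2-s shift is recovered at +2.0 s with the lead convention", {
  t <- seq(0, 20, by = 0.1)
  a <- sin(2 * pi * t / 5)
  b <- sin(2 * pi * (t - 2) / 5)  # b lags a by 2 s
  # whole-trace correlation: energy normalization makes the periodic
  # peak unique (overlap attenuation)
  cs <- xcorrEvents(a, b, data.frame(start = 1L, end = length(t)),
                    normalization = "coeff")
  expect_equal(cs@peak$lagS, 2.0, tolerance = 0.1001)
  expect_gt(cs@peak$value, 0.8)
})

test_that("lag symmetry: xcorr(a, b) at +k equals xcorr(b, a) at -k", {
  set.seed(12)
  a <- stats::rnorm(200); b <- stats::rnorm(200)
  ev <- data.frame(start = c(10L, 90L), end = c(80L, 190L))
  for (nm in c("pearson", "coeff")) {
    ab <- xcorrEvents(a, b, ev, max_lags = 30, normalization = nm)
    ba <- xcorrEvents(b, a, ev, max_lags = 30, normalization = nm)
    expect_equal(ab@perEvent, ba@perEvent[, rev(seq_len(61))])
  }
})

test_that("independent noise produces a flat correlogram", {
  set.seed(5)
  x <- stats::rnorm(2500); y <- stats::rnorm(2500)
  st <- seq(1L, by = 49L, length.out = 50L)
  ev <- data.frame(start = st, end = st + 48L)
  # energy normalization: every lag of every event is defined
  cs <- xcorrEvents(x, y, ev, normalization = "coeff")
  expect_identical(nrow(ev), 50L)
  expect_lt(max(abs(cs@mean), na.rm = TRUE), 0.2)
  expect_lt(cs@peak$value, 0.2)
  # per-lag Pearson agrees over the well-sampled core of the lag grid
  cp <- xcorrEvents(x, y, ev, normalization = "pearson")
  core <- abs(cp@lagS) <= 2.5
  expect_lt(max(abs(cp@mean[core]), na.rm = TRUE), 0.2)
})

test_that("pearson mode marks too-short overlaps as missing", {
  a <- sin(seq(0, 6, by = 0.1)); b <- cos(seq(0, 6, by = 0.1))
  cs <- xcorrEvents(a, b, data.frame(start = 10L, end = 30L),
                    max_lags = 40, normalization = "pearson")
  expect_true(is.na(cs@perEvent[1, 1]))   # lag -40 exceeds the event
  expect_true(is.finite(cs@perEvent[1, 41]))  # lag 0
})

test_that("signed peak in the control window follows the magnitude rule", {
  mkSet <- function(mu, lags = seq(-10, 10, by = 0.1)) {
    methods::new("CorrelogramSet", lagS = lags,
                 perEvent = matrix(mu, 1), mean = mu,
                 semValues = rep(0, length(mu)),
                 nPerLag = rep(1L, length(mu)),
                 peak = list(value = max(mu), lagS = lags[which.max(mu)]))
  }
  lags <- seq(-10, 10, by = 0.1)
  ctrl <- mkSet(0.5 * exp(-lags^2))
  # simple positive peak at 0
  expect_equal(peakCorrelation(mkSet(0.5 * exp(-lags^2)), ctrl),
               list(value = 0.5, lagS = 0))
  # -0.6 at -1 s beats +0.3 at +1 s on magnitude, sign preserved
  mu <- 0.3 * exp(-(lags - 1)^2 / 0.1) - 0.6 * exp(-(lags + 1)^2 / 0.1)
  pk <- peakCorrelation(mkSet(mu), ctrl)
  expect_equal(pk$value, -0.6, tolerance = 1e-6)
  expect_equal(pk$lagS, -1)
  # control anchored at +4 s: lags outside [1.5, 6.5] are ignored
  ctrl4 <- mkSet(0.5 * exp(-(lags - 4)^2 / 0.1))
  mu2 <- -0.9 * exp(-(lags + 5)^2 / 0.1) + 0.4 * exp(-(lags - 3)^2 / 0.1)
  pk2 <- peakCorrelation(mkSet(mu2), ctrl4)
  expect_equal(pk2$value, 0.4, tolerance = 1e-6)
  expect_equal(pk2$lagS, 3)
  # window reaching past the lag grid is clipped with a warning
  ctrl9 <- mkSet(0.5 * exp(-(lags - 9)^2 / 0.1))
  expect_warning(peakCorrelation(mkSet(mu2), ctrl9), "clipped")
})

test_that("reversal selection keeps only runs of at least 10 s", {
  t <- seq(0, 40, by = 0.1)
  st <- rep("forward", length(t))
  expect_identical(nrow(selectReversals(st, t)), 0L)
  st[t >= 2 & t < 10] <- "reverse"    # 8 s: too short
  st[t >= 20 & t < 32] <- "reverse"   # 12 s: kept
  rv <- selectReversals(st, t)
  expect_identical(nrow(rv), 1L)
  expect_equal(rv$duration_s, 12, tolerance = 0.11)
  expect_identical(attr(rv, "nShortExcluded"), 1L)
  # a trace that is reverse throughout is one spanning epoch
  st2 <- rep("reverse", 151)
  rv2 <- selectReversals(st2, seq(0, 15, by = 0.1))
  expect_identical(nrow(rv2), 1L)
  expect_equal(rv2$tStart, 0)
  expect_equal(rv2$tEnd, 15)
})

test_that("the generator's reversal epochs are recovered from state", {
  p <- locomotionParams(duration_s = 40, fps = 10,
                        perturbation_epochs = list(
                          list(tStart = 5, tEnd = 11, speed = -1),
                          list(tStart = 20, tEnd = 32, speed = -1)))
  tr <- generateLocomotion(p)
  rv <- selectReversals(tr@state, tr@time, min_duration_s = 10)
  expect_identical(nrow(rv), 1L)
  expect_equal(rv$tStart, 20, tolerance = 0.2)
})
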