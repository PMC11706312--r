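fs_std <- 1 / 0.229

test_that("scaled-MAD outlier removal flags spikes and interpolates them", {
  x <- c(rep(1, 9), 100)
  r <- remove_outliers(x)
  expect_identical(r$outliers, 10L)
  expect_equal(r$values[10], 1)       # rule-2 extrapolation from neighbours
  # constant series: zero MAD, no exact deviants, nothing flagged
  expect_identical(remove_outliers(rep(5, 12))$outliers, integer(0))
  # zero-MAD guard: a single exact deviant is still caught
  x2 <- c(rep(5, 11), 7)
  expect_identical(remove_outliers(x2)$outliers, 12L)
  # a pure sinusoid has max |dev| / scaledMAD < 3: nothing flagged
  s <- sin(seq(0, 20 * pi, length.out = 400))
  expect_identical(remove_outliers(s)$outliers, integer(0))
  # idempotence
  set.seed(7)
  y <- c(rnorm(50), 25)
  r1 <- remove_outliers(y)
  r2 <- remove_outliers(r1$values)
  expect_identical(r2$outliers, integer(0))
  expect_error(remove_outliers(c(0, rep(c(1, 100), 5))[1:9]), "length")
})

test_that("band conditioning attenuates the opposite band by >= 20 dB", {
  t <- (0:496) * 0.229
  x <- 1.0 * cos(2 * pi * 0.25 * t) + 0.8 * cos(2 * pi * 1.0 * t)
  amp_at <- function(y, f) {
    n <- length(y)
    2 * abs(sum(y * exp(-2i * pi * f * (0:(n - 1)) / fs_std))) / n
  }
  lo <- bandpass_condition(x, "respiratory", fs_std)
  expect_lt(amp_at(lo, 1.0) / 0.8, 10^(-20 / 20))        # >= 20 dB down
  expect_lt(abs(amp_at(lo, 0.25) - 1.0), 0.02)           # passband intact
  hi <- bandpass_condition(x, "cardiac", fs_std)
  expect_lt(amp_at(hi, 0.25) / 1.0, 10^(-20 / 20))
  # the 1.0 Hz component sits near the 0.8 Hz corner: the forward-backward
  # 4th-order digital Butterworth leaves ~91% of its amplitude there
  expect_gt(amp_at(hi, 1.0) / 0.8, 0.85)
  expect_lt(amp_at(hi, 1.0) / 0.8, 1.02)
  # a DC-only series is annihilated by the high-pass (edge transients only)
  dc <- bandpass_condition(rep(7, 300), "cardiac", fs_std)
  expect_lt(max(abs(dc)) / 7, 0.005)
  expect_error(bandpass_condition(x, "respiratory", fs = 1), "twice")
})

test_that("zero-phase filtering induces no lag", {
  t <- (0:496) * 0.229
  x <- cos(2 * pi * 0.25 * t)
  y <- bandpass_condition(x, "respiratory", fs_std)
  n <- length(x)
  cc <- vapply(0:16, function(l) cor(y[(l + 1):n], x[1:(n - l)]), numeric(1))
  expect_identical(which.max(cc) - 1L, 0L)
})

test_that("dominant frequency is found to within one spectral bin", {
  t <- (0:496) * 0.229
  x <- cos(2 * pi * 0.25 * t)
  f <- dominant_frequency(x, fs_std, "respiratory")
  expect_lt(abs(as.numeric(f) - 0.25), fs_std / 497 + 1e-12)
  expect_false(attr(f, "low_confidence"))
  # ties break toward the lower frequency
  x2 <- cos(2 * pi * 0.20 * t) + cos(2 * pi * 0.40 * t)
  f2 <- dominant_frequency(x2, fs_std, "respiratory")
  expect_lt(as.numeric(f2), 0.3)
  # a flat (peakless) band spectrum flags low confidence: equal-amplitude
  # tones at every band bin leave peak ~ spectral median
  set.seed(42)
  n <- length(t)
  flat_f <- (4:63) * fs_std / n            # exact DFT bins inside the band
  xf <- rowSums(vapply(flat_f, function(fk)
    cos(2 * pi * fk * t + runif(1, 0, 2 * pi)), numeric(n)))
  fn <- dominant_frequency(xf, fs_std, "respiratory")
  expect_true(attr(fn, "low_confidence"))
  expect_error(dominant_frequency(x, fs = 1.2, "cardiac"), "empty")
})

test_that("navigator extraction averages the ROI and respects bounds", {
  s <- dynamic_series(array(rep(1:20, times = 64), c(20, 8, 8)), 0.229)
  roi <- list(rows = 2:4, cols = 3:5)
  expect_equal(extract_navigator(s, roi), as.numeric(1:20))
  roi1 <- list(rows = 3, cols = 3)
  expect_equal(extract_navigator(s, roi1), s$frames[, 3, 3])
  expect_error(extract_navigator(s, list(rows = 5:20, cols = 1:2)), "bounds")
})

test_that("conditioned navigator is normalized, banded, and scale-invariant", {
  t <- (0:496) * 0.229
  raw <- 500 * (1 + 0.2 * cos(2 * pi * 0.25 * t) + 0.02 * cos(2 * pi * 1.1 * t))
  sig <- condition_signal(raw, fs_std, "respiratory")
  expect_equal(median(sig$values), 100)
  expect_lt(abs(sig$dominant_freq_hz - 0.25), fs_std / 497 + 1e-12)
  expect_identical(sig$band, "respiratory")
  # relative signal: positive rescaling of the raw series changes nothing
  sig2 <- condition_signal(raw * 37.1, fs_std, "respiratory")
  expect_equal(sig$values, sig2$values, tolerance = 1e-12)
})

test_that("cardiac reference extraction validates the band", {
  p <- fixture("phantom_clean")
  ser <- dynamic_series(p$series$frames[16:512, , ], 0.229)
  ref <- extract_cardiac_reference(ser, p$truth$cardiac_roi)
  expect_identical(ref$band, "cardiac")
  expect_lt(abs(ref$dominant_freq_hz - 1.08), fs_std / 497 + 1e-12)
  # static background ROI carries no cardiac signal
  expect_error(extract_cardiac_reference(ser, list(rows = 1:3, cols = 1:3)),
               "no cardiac signal")
})
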