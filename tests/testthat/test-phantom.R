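test_that("phantom configuration enforces its physical invariants", {
  expect_error(phantom_config(resp_freq_hz = 0.7), "0.6")
  expect_error(phantom_config(cardiac_freq_hz = 0.5), "0.8")
  expect_error(phantom_config(frame_interval_s = 0.6), "aliasing")
  expect_error(phantom_config(matrix = c(32, 32)), "too small")
  expect_error(phantom_config(lag_frac = 1.2), "\\[0, 1\\)")
})

test_that("identical configurations generate bit-identical phantoms", {
  cfg <- phantom_config(n_frames = 96, rng_seed = 7)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$series$frames, p2$series$frames)
  expect_identical(p1$truth$diaphragm_trace, p2$truth$diaphragm_trace)
})

test_that("noiseless navigator has its spectral peak at the respiratory frequency", {
  p <- fixture("phantom_clean")
  tr <- p$truth
  # drop the steady-state window to match the analysed 497-frame series
  nav <- apply(p$series$frames[16:512, tr$nav_roi$rows, tr$nav_roi$cols],
               1, mean)
  n <- length(nav)
  fs <- 1 / 0.229
  # oracle: direct DFT magnitude spectrum
  mag <- Mod(fft(nav - mean(nav)))[2:(n %/% 2)]
  freqs <- (1:(n %/% 2 - 1)) * fs / n
  expect_lt(abs(freqs[which.max(mag)] - 0.25), fs / n + 1e-9)

  # spectral separation: >= 99% of sub-0.6 Hz power concentrated in the
  # respiratory line (Hann window; its mainlobe spans +/- 2 bins, which is
  # what bounds the concentration for the non-integer cycle count here)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  magw <- Mod(fft((nav - mean(nav)) * w))[2:(n %/% 2)]
  sub <- freqs < 0.6
  peak_band <- sub & abs(freqs - 0.25) <= 2 * fs / n + 1e-9
  expect_gt(sum(magw[peak_band]^2) / sum(magw[sub]^2), 0.99)
})

test_that("cardiac component survives the 0.8 Hz high-pass with < 5% amplitude error", {
  p <- fixture("phantom_clean")
  tr <- p$truth
  fs <- 1 / 0.229
  ves <- apply(p$series$frames[, tr$cardiac_roi$rows, tr$cardiac_roi$cols],
               1, mean)
  hp <- bandpass_condition(ves, "cardiac", fs)
  # vessel modulation is 30% of its baseline intensity
  truth_amp <- 0.30 * median(ves)
  est_amp <- sqrt(2) * sd(hp[20:(length(hp) - 20)])
  expect_lt(abs(est_amp - truth_amp) / truth_amp, 0.05)
})

test_that("zero-gradient lungs leave no respiratory-band variance beyond noise", {
  p <- generate_phantom(phantom_config(n_frames = 128, noise_sigma = 0,
                                       ventilation_gradient = 0,
                                       cardiac_amplitude_frac = 0))
  idx <- which(p$truth$lung_mask & !is.na(p$truth$lung_mask), arr.ind = TRUE)
  # interior voxel (away from the moving diaphragm boundary)
  v <- p$series$frames[, 20, 20]
  expect_lt(sd(v), 1e-9)
})

test_that("an injected regional lag is recoverable by brute-force cross-correlation", {
  p <- fixture("phantom_clean")
  tr <- p$truth
  def <- fixture("defects")
  period <- 1 / (0.25 * 0.229)              # frames per respiratory cycle
  r0 <- c(def$lag30$rows[3], def$lag30$cols[3])
  v <- p$series$frames[, r0[1], r0[2]]
  ref <- 100 * (1 + tr$delta)
  n <- length(v)
  cc <- vapply(0:(round(period) - 1), function(l)
    cor(v[(l + 1):n], ref[1:(n - l)]), numeric(1))
  lag_best <- which.max(cc) - 1
  expect_lt(abs(lag_best - 0.3 * period), 1)
})

test_that("Rician noise is reproducible and leaves intensities non-negative", {
  cfg <- phantom_config(n_frames = 64, noise_sigma = 5, rng_seed = 11)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$series$frames, p2$series$frames)
  expect_true(all(p1$series$frames >= 0))
  # generation must not disturb the session RNG stream
  set.seed(1); a <- runif(1)
  invisible(generate_phantom(cfg))
  set.seed(1); b <- runif(1)
  expect_identical(a, b)
})

test_that("phantom round-trips through its NIfTI writer", {
  p <- generate_phantom(phantom_config(n_frames = 48, noise_sigma = 0))
  d <- withr::local_tempdir()
  write_phantom(p, phantom_config(n_frames = 48, noise_sigma = 0), d)
  s2 <- load_series(file.path(d, "series.nii.gz"))
  expect_identical(as.numeric(s2$frames), as.numeric(p$series$frames))
  expect_equal(s2$frame_interval_s, 0.229, tolerance = 1e-6)
  side <- jsonlite::read_json(file.path(d, "phantom.json"))
  expect_equal(side$config$resp_freq_hz, 0.25)
})
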