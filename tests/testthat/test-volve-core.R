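# independent oracle: minimize the errors-in-variables misfit
# S(b) = sum_i W_i(b) (y_i - a - b x_i)^2 numerically over the slope
york_misfit_slope <- function(x, y, sx = 1, sy = 1) {
  wx <- rep_len(1 / sx^2, length(x)); wy <- rep_len(1 / sy^2, length(x))
  S <- function(b) {
    W <- wx * wy / (wx + b^2 * wy)
    a <- sum(W * y) / sum(W) - b * sum(W * x) / sum(W)
    sum(W * (y - a - b * x)^2)
  }
  # S(b) has finite asymptotes, so bracket the global minimum on a grid
  # before refining
  grid <- seq(-10, 10, by = 0.01)
  i <- which.min(vapply(grid, S, numeric(1)))
  optimize(S, grid[c(max(1, i - 2), min(length(grid), i + 2))],
           tol = 1e-12)$minimum
}

test_that("lagged cross-correlation recovers identity, delay and sign structure", {
  t <- (0:496) * 0.229
  ref <- cos(2 * pi * 0.25 * t)
  r <- lagged_xcc(ref, ref, period_frames = 17)
  expect_equal(r$xcc, 1)
  expect_identical(r$lag_frames, 0L)
  expect_equal(r$cc0, 1)
  # half-cycle delay: cc0 ~ -1, xcc ~ +1 at lag ~ period/2
  per <- 1 / (0.25 * 0.229)
  lagged <- cos(2 * pi * 0.25 * (t - 2))     # 2 s = half of the 4 s cycle
  r2 <- lagged_xcc(lagged, ref, period_frames = 17)
  expect_lt(r2$cc0, -0.95)
  expect_gt(r2$xcc, 0.95)
  expect_lt(abs(r2$lag_frames - per / 2), 1)
  # zero-variance input is undefined
  r3 <- lagged_xcc(rep(1, 497), ref, period_frames = 17)
  expect_true(is.na(r3$xcc))
})

test_that("lag recovery matches a brute-force correlation oracle on the phantom", {
  p <- fixture("phantom_clean")
  def <- fixture("defects")
  v <- p$series$frames[, def$lag50$rows[3], def$lag50$cols[3]]
  ref <- 100 * (1 + p$truth$delta)
  r <- lagged_xcc(v, ref, period_frames = 17)
  n <- length(v)
  cc_oracle <- vapply(0:16, function(l)
    cor(v[(l + 1):n], ref[1:(n - l)]), numeric(1))
  expect_identical(r$lag_frames, which.max(cc_oracle) - 1L)
  expect_lt(abs(r$lag_frames - 0.5 / (0.25 * 0.229)), 1)
})

test_that("York regression fits exact lines and reduces to OLS as sx -> 0", {
  set.seed(5)
  x <- rnorm(30); y <- 2 * x + 1
  f <- york_regression(x, y, sx = 0.3, sy = 0.3)
  expect_equal(f$slope, 2, tolerance = 1e-8)
  expect_equal(f$intercept, 1, tolerance = 1e-8)
  expect_true(f$converged)
  # sx -> 0 limit equals ordinary least squares of y on x
  yn <- y + rnorm(30, 0, 0.5)
  f2 <- york_regression(x, yn, sx = 1e-9 * 0.5, sy = 0.5)
  ols <- coef(lm(yn ~ x))[[2]]
  expect_equal(f2$slope, ols, tolerance = 1e-6 * abs(ols))
  expect_error(york_regression(rep(1, 10), rnorm(10), 1, 1), "zero variance")
})

test_that("York slope equals the brute-force misfit minimizer with equal errors", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(20); y <- 0.8 * x + rnorm(20, 0, 0.4)
    f <- york_regression(x, y, sx = 1, sy = 1)
    expect_equal(f$slope, york_misfit_slope(x, y), tolerance = 1e-6)
  }
})

test_that("the vectorized map regression equals per-voxel iterative York", {
  r <- fixture("run_snr20_V")
  p <- fixture("phantom_snr20")
  maps <- r$maps
  keep <- setdiff(seq_len(dim(r$registered$frames)[1]),
                  r$registered$excluded_frames)
  ref <- r$reference$values[keep]
  fs <- 1 / 0.229
  idx <- which(r$mask$mask, arr.ind = TRUE)
  set.seed(2); pick <- idx[sample(nrow(idx), 8), , drop = FALSE]
  for (k in seq_len(nrow(pick))) {
    rr <- pick[k, 1]; cc <- pick[k, 2]
    raw <- r$registered$frames[keep, rr, cc]
    lp <- bandpass_condition(raw, "respiratory", fs)
    y <- 100 * lp / median(lp)
    sy <- volve:::.noise_scale(100 * raw / median(lp))
    sx <- volve:::.noise_scale(ref)
    f <- york_regression(ref, y, sx = sx, sy = sy)
    expect_equal(maps$grad[rr, cc], f$slope, tolerance = 1e-6)
  }
})

test_that("voxel maps respect XCC dominance and lag ranges", {
  m <- fixture("run_snr20_V")$maps
  ok <- is.finite(m$xcc)
  expect_true(all(m$xcc[ok] >= m$cc0[ok] - 1e-12))
  expect_true(all(m$xcc[ok] <= 1 + 1e-12))
  lag_ok <- is.finite(m$lag)
  expect_true(all(m$lag[lag_ok] >= 0 & m$lag[lag_ok] < 100))
  # where lag is zero the maximum equals the zero-lag correlation
  zero_lag <- ok & lag_ok & m$lag == 0
  expect_true(all(abs(m$xcc[zero_lag] - m$cc0[zero_lag]) < 1e-12))
})

test_that("fractional ventilation matches the two-phase definition", {
  p <- fixture("phantom_clean")
  r <- fixture("run_clean_V")
  fv <- r$fv
  expect_false(is.null(fv))
  # noiseless voxel with peak-to-peak fractional change f has FV close to f
  msk <- r$mask$mask & p$truth$true_lag_frac == 0 & p$truth$true_grad == 1
  alpha <- p$truth$alpha
  f_expected <- 2 * alpha / (1 + alpha)   # (S_exp - S_insp) / S_exp
  expect_lt(abs(median(fv[msk], na.rm = TRUE) - f_expected) / f_expected, 0.1)
  # paradoxical voxels (brighter at inspiration) have FV < 0
  pv <- r$mask$mask & p$truth$true_grad == -1
  expect_lt(median(fv[pv], na.rm = TRUE), 0)
  # constant signal gives FV = 0
  reg <- r$registered
  reg$frames[] <- 50
  mask0 <- r$mask
  fv0 <- fractional_ventilation(reg, mask0, r$navigator)
  expect_true(all(abs(fv0[mask0$mask]) < 1e-12))
})
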