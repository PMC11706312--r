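# build a lung_mask-like container around arbitrary values for summary tests
values_as_map <- function(vals, ncol = 100) {
  n <- length(vals)
  nr <- ceiling(n / ncol)
  map <- matrix(NA_real_, nr, ncol)
  map[seq_len(n)] <- vals
  mask <- structure(list(mask = !is.na(map),
                         side_labels = matrix("right", nr, ncol),
                         vessel_exclusions = matrix(FALSE, nr, ncol),
                         quadrant_labels = matrix(
                           rep(c("RU", "RL", "LU", "LL"), length.out = nr * ncol),
                           nr, ncol),
                         orientation = "radiological"),
                    class = "lung_mask")
  mask$quadrant_labels[!mask$mask] <- NA_character_
  list(map = map, mask = mask)
}

test_that("map summaries report median, skewness and quadrant medians", {
  set.seed(1)
  sym <- values_as_map(rnorm(1e4))
  s <- summarize_map(sym$map, sym$mask, "sym")
  expect_lt(abs(s$skewness), 0.05)
  expect_equal(s$median, median(sym$map, na.rm = TRUE))
  expect_identical(s$n_voxels, 10000L)
  # long left tail gives negative skewness (healthy XCC-like shape)
  lt <- values_as_map(1 - rexp(1e4, 2))
  expect_lt(summarize_map(lt$map, lt$mask, "lt")$skewness, -0.5)
  # pooled median lies within the quadrant medians
  expect_true(s$median >= min(s$quadrant_medians) - 1e-12 &&
                s$median <= max(s$quadrant_medians) + 1e-12)
  # degenerate distribution: skewness absent with a warning
  eq <- values_as_map(rep(2, 500))
  expect_warning(se <- summarize_map(eq$map, eq$mask, "eq"), "degenerate")
  expect_identical(se$median, 2)
  expect_true(is.na(se$skewness))
  few <- values_as_map(rnorm(50))
  expect_error(summarize_map(few$map, few$mask, "few"), "too few")
})

test_that("two-component EM recovers mixture weights and PAR", {
  set.seed(10)
  x <- c(rnorm(9000, 1, 0.2), rnorm(1000, -1, 0.2))
  f <- fit_gmm_par(x)
  expect_lt(abs(f$par - 1 / 9), 0.02)
  expect_equal(sum(f$gmm$weights), 1, tolerance = 1e-9)
  # orientation flip inverts the ratio
  f2 <- fit_gmm_par(x, par_orientation = "pos_over_neg")
  expect_equal(f2$par, 1 / f$par, tolerance = 1e-9)
  # unimodal sample: negative component weight collapses
  xu <- rnorm(1e4, 1, 0.2)
  expect_lte(fit_gmm_par(xu)$par, 0.05)
  # symmetric 50/50 mixture
  xs <- c(rnorm(5000, 1, 0.2), rnorm(5000, -1, 0.2))
  expect_lt(abs(fit_gmm_par(xs)$par - 1), 0.1)
  expect_error(fit_gmm_par(rnorm(100)), "200")
})

test_that("PAR is monotone in the negative-mode fraction and duplication-invariant", {
  set.seed(20)
  pars <- vapply(c(0.05, 0.10, 0.20, 0.50), function(fr) {
    n <- 1e4
    x <- c(rnorm(round((1 - fr) * n), 1, 0.2), rnorm(round(fr * n), -1, 0.2))
    fit_gmm_par(x)$par
  }, numeric(1))
  expect_true(all(diff(pars) > 0))
  x <- c(rnorm(1800, 1, 0.2), rnorm(200, -1, 0.2))
  f1 <- fit_gmm_par(x)
  f2 <- fit_gmm_par(sample(rep(x, 2)))
  expect_equal(f2$par, f1$par, tolerance = 0.02)
})

test_that("EM agrees with an independent mixture fitter", {
  set.seed(30)
  x <- c(rnorm(7000, 1, 0.25), rnorm(3000, -1, 0.25))
  f <- fit_gmm_par(x)
  suppressMessages(library(mclust))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  w_mc <- mc$parameters$pro[order(mc$parameters$mean)]
  expect_equal(f$par, w_mc[1] / w_mc[2], tolerance = 0.02)
})
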