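#' Lagged cross-correlation between a voxel and a reference time course
#'
#' For each integer shift `l` in `0 .. period_frames - 1`, computes the
#' Pearson correlation between `parenchyma(t)` and `reference(t - l)` over
#' the overlapping frames. Returns the maximum (XCC), the lag at which it is
#' attained, and the zero-lag correlation (CC). Ties break toward the
#' smallest lag. With `refine = TRUE`, the peak is refined to sub-frame
#' precision by parabolic interpolation over its two neighbours when the
#' peak is interior.
#'
#' @param parenchyma,reference numeric series of equal length (>= 32).
#' @param period_frames number of frames in one cycle of the reference
#'   (search covers one full cycle).
#' @param refine logical; parabolic sub-frame refinement of the peak.
#' @param min_overlap_frac minimum overlap as a fraction of the series
#'   length for a shift to be evaluated.
#' @return List with `xcc`, `lag_frames`, `cc0`. `NA`s if either series has
#'   zero variance over the overlap.
#' @export
lagged_xcc <- function(parenchyma, reference, period_frames,
                       refine = FALSE, min_overlap_frac = 0.75) {
  n <- length(parenchyma)
  stopifnot(length(reference) == n, n >= 32, period_frames >= 2)
  lags <- 0:(period_frames - 1)
  lags <- lags[n - lags >= min_overlap_frac * n]
  cc <- rep(NA_real_, length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]
    p <- parenchyma[(l + 1):n]
    r <- reference[1:(n - l)]
    if (sd(p) == 0 || sd(r) == 0) next
    cc[i] <- cor(p, r)
  }
  if (all(is.na(cc))) return(list(xcc = NA_real_, lag_frames = NA_real_,
                                  cc0 = NA_real_))
  best <- which(cc == max(cc, na.rm = TRUE))[1]
  lag <- lags[best]
  xcc <- cc[best]
  if (refine && best > 1 && best < length(lags) &&
      !is.na(cc[best - 1]) && !is.na(cc[best + 1])) {
    y1 <- cc[best - 1]; y2 <- cc[best]; y3 <- cc[best + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      delta <- 0.5 * (y1 - y3) / den
      lag <- lag + delta
      xcc <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  list(xcc = xcc, lag_frames = lag, cc0 = cc[1])
}

#' York errors-in-variables straight-line fit
#'
#' Iterative least-squares line fit with errors in both coordinates:
#' point weights `W_i = wx_i wy_i / (wx_i + b^2 wy_i - 2 b r_xy
#' sqrt(wx_i wy_i))` with `w = 1/s^2`, slope iterated to `|db| < tol`,
#' intercept from the weighted means, and the slope standard error evaluated
#' at the least-squares-adjusted points. With equal errors this is the
#' major-axis (Deming) solution; in the limit `sx -> 0` it reduces to
#' ordinary least squares of y on x.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param sx,sy per-point standard errors (scalar or vector, > 0).
#' @param r_xy per-point error correlation (scalar or vector, default 0).
#' @param tol convergence tolerance on the slope.
#' @param max_iter maximum iterations.
#' @return List of class `york_fit`: `slope`, `intercept`, `slope_se`,
#'   `n_iter`, `converged`.
#' @export
york_regression <- function(x, y, sx, sy, r_xy = 0, tol = 1e-10,
                            max_iter = 50L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3, all(sx > 0), all(sy > 0))
  if (sd(x) == 0) stop("zero variance in x: slope undefined")
  wx <- 1 / rep_len(sx, n)^2
  wy <- 1 / rep_len(sy, n)^2
  r_xy <- rep_len(r_xy, n)
  alpha <- sqrt(wx * wy)
  b <- coef(lm(y ~ x))[[2]]
  if (!is.finite(b)) b <- 1
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    W <- wx * wy / (wx + b^2 * wy - 2 * b * r_xy * alpha)
    Xb <- sum(W * x) / sum(W)
    Yb <- sum(W * y) / sum(W)
    U <- x - Xb; V <- y - Yb
    beta <- W * (U / wy + b * V / wx - (b * U + V) * r_xy / alpha)
    b_new <- sum(W * beta * V) / sum(W * beta * U)
    if (!is.finite(b_new)) break
    done <- abs(b_new - b) < tol
    b <- b_new
    if (done) { converged <- TRUE; break }
  }
  W <- wx * wy / (wx + b^2 * wy - 2 * b * r_xy * alpha)
  Xb <- sum(W * x) / sum(W)
  Yb <- sum(W * y) / sum(W)
  a <- Yb - b * Xb
  beta <- W * ((x - Xb) / wy + b * (y - Yb) / wx -
                 (b * (x - Xb) + (y - Yb)) * r_xy / alpha)
  x_adj <- Xb + beta
  xbar_adj <- sum(W * x_adj) / sum(W)
  u <- x_adj - xbar_adj
  se <- sqrt(1 / sum(W * u^2))
  if (!converged)
    warning("York regression did not converge; returning last iterate")
  structure(list(slope = b, intercept = a, slope_se = se,
                 n_iter = it, converged = converged),
            class = "york_fit")
}

# Closed-form York slope when each series has a single (scalar) error level:
# the weights are then constant across points and the iteration collapses to
# the Deming solution with lambda = sy^2 / sx^2. Vectorized over voxels.
.deming_slope <- function(Sxx, Syy, Sxy, lambda) {
  b <- ifelse(abs(Sxy) > 0,
              ((Syy - lambda * Sxx) +
                 sqrt((Syy - lambda * Sxx)^2 + 4 * lambda * Sxy^2)) / (2 * Sxy),
              0)
  b
}

# difference-based noise scale of a series: robust second differences
# (Gasser-type), which cancel locally linear signal so slow physiological
# oscillations leak far less than with first differences
.noise_scale <- function(x) {
  d <- diff(x, differences = 2)
  s <- 1.4826 * median(abs(d - median(d))) / sqrt(6)
  if (!is.finite(s) || s <= 0) s <- sd(d) / sqrt(6)
  if (!is.finite(s) || s <= 0) s <- 1
  s
}

#' Compute voxel-wise XCC, Lag and Grad maps
#'
#' For every voxel in the lung mask: the registered time course is expressed
#' as a percentage of its temporal median, band-conditioned with the
#' modality's zero-phase filter (ventilation: low-pass; perfusion:
#' high-pass), cross-correlated against the reference over one full cycle of
#' integer lags, and fitted against the unshifted reference by York
#' regression (per-series difference-based noise estimates; equal weights on
#' request). Lags are converted to modality units: ventilation as % of the
#' respiratory cycle (`lag_frames * dt * f_resp * 100`), perfusion as
#' milliseconds (`lag_frames * dt * 1000`). Sub-frame parabolic lag
#' refinement defaults to on for perfusion (cardiac period of only a few
#' frames) and off for ventilation.
#'
#' @param registered a [register_series()] result.
#' @param mask a [segment_lungs()] result (defined on the target frame).
#' @param reference a `navigator_signal` conditioned for the modality.
#' @param modality `"V"` or `"Q"`.
#' @param config a [run_config()].
#' @param frame_interval_s frame interval (seconds).
#' @return An object of class `volve_maps` with matrices `xcc`, `lag`,
#'   `grad`, `cc0` (NA outside the mask or where undefined), the
#'   `undefined_mask`, `modality`, `lag_units`, `period_frames` and the
#'   reference frequency.
#' @export
compute_voxel_maps <- function(registered, mask, reference,
                               modality = c("V", "Q"), config = run_config(),
                               frame_interval_s) {
  modality <- match.arg(modality)
  stopifnot(inherits(registered, "registered_series"),
            inherits(mask, "lung_mask"),
            inherits(reference, "navigator_signal"))
  fs <- 1 / frame_interval_s
  keep <- setdiff(seq_len(dim(registered$frames)[1]), registered$excluded_frames)
  nT <- length(keep)
  f0 <- reference$dominant_freq_hz
  period <- max(2L, round(1 / (f0 * frame_interval_s)))
  refine <- if (identical(config$refine_subframe, "auto")) modality == "Q"
            else isTRUE(config$refine_subframe)

  idx <- which(mask$mask)
  nV <- length(idx)
  if (nV == 0) stop("empty lung mask")
  d <- dim(registered$frames)
  P_raw <- matrix(registered$frames[keep, , ], nrow = nT)[, idx, drop = FALSE]

  # the per-voxel normalization scale is the median of the low-pass
  # (baseline) component, so band-limited oscillations (cardiac pulsation,
  # breathing) cannot shift the % scale
  LP <- apply(P_raw, 2, function(z)
    tryCatch(bandpass_condition(z, band = "respiratory", fs = fs,
                                lowpass_hz = config$lowpass_hz),
             error = function(e) rep(NA_real_, nT)))
  scale_v <- apply(LP, 2, median)
  undef <- !is.finite(scale_v) | scale_v <= 0 |
    apply(P_raw, 2, function(z) sd(z) == 0)
  scale_safe <- ifelse(undef, 1, scale_v)
  P <- if (modality == "V") {
    sweep(LP, 2, scale_safe, "/") * 100
  } else {
    HP <- apply(P_raw, 2, function(z)
      tryCatch(bandpass_condition(z, band = "cardiac", fs = fs,
                                  highpass_hz = config$highpass_hz),
               error = function(e) rep(NA_real_, nT)))
    sweep(HP, 2, scale_safe, "/") * 100
  }
  ref <- reference$values[keep]

  # noise scales for the York/Deming weights, from the raw % courses
  P_pct <- sweep(P_raw, 2, scale_safe, "/") * 100
  sx <- if (isTRUE(config$equal_weights)) 1 else .noise_scale(ref)
  sy <- if (isTRUE(config$equal_weights)) rep(1, nV)
        else apply(P_pct, 2, .noise_scale)

  xcc <- lagf <- cc0 <- grad <- rep(NA_real_, nV)
  sdP <- apply(P, 2, sd)
  undef <- undef | !is.finite(sdP) | sdP == 0
  if (sd(ref) == 0) undef[] <- TRUE

  if (!all(undef)) {
    sub <- which(!undef)
    # correlations for all integer lags, vectorized across voxels
    lags <- 0:(period - 1)
    # truncated-overlap correlation; overlap never below 75% of the series
    lags <- lags[nT - lags >= max(32, ceiling(0.75 * nT))]
    CC <- matrix(NA_real_, length(lags), length(sub))
    for (i in seq_along(lags)) {
      l <- lags[i]
      pr <- P[(l + 1):nT, sub, drop = FALSE]
      rr <- ref[1:(nT - l)]
      pr <- scale(pr)
      rr <- (rr - mean(rr)) / sd(rr)
      CC[i, ] <- as.numeric(crossprod(pr, rr)) / (nT - l - 1)
    }
    best <- apply(CC, 2, which.max)
    xcc[sub] <- CC[cbind(best, seq_along(sub))]
    lagf[sub] <- lags[best]
    cc0[sub] <- CC[1, ]
    if (refine) {
      interior <- best > 1 & best < length(lags)
      if (any(interior)) {
        ii <- which(interior)
        y1 <- CC[cbind(best[ii] - 1L, ii)]
        y2 <- CC[cbind(best[ii], ii)]
        y3 <- CC[cbind(best[ii] + 1L, ii)]
        den <- y1 - 2 * y2 + y3
        ok <- den < 0
        delta <- ifelse(ok, 0.5 * (y1 - y3) / den, 0)
        lagf[sub[ii]] <- lagf[sub[ii]] + delta
        xcc[sub[ii]] <- ifelse(ok, y2 - 0.25 * (y1 - y3) * delta, y2)
      }
    }

    # York (Deming closed form; per-series scalar errors) on the unshifted
    # pair, or at the XCC-optimal integer lag on request
    for_grad_lag <- if (isTRUE(config$grad_at_lag)) round(lagf[sub]) else
      rep(0L, length(sub))
    for (l in unique(for_grad_lag)) {
      g <- sub[for_grad_lag == l]
      pr <- P[(l + 1):nT, g, drop = FALSE]
      rr <- ref[1:(nT - l)]
      U <- rr - mean(rr)
      Vm <- sweep(pr, 2, colMeans(pr))
      Sxx <- sum(U^2)
      Syy <- colSums(Vm^2)
      Sxy <- as.numeric(crossprod(Vm, U))
      lambda <- (sy[g] / sx)^2
      grad[g] <- .deming_slope(Sxx, Syy, Sxy, lambda)
    }
  }
  if (mean(undef) > 0.5)
    stop("more than 50% of mask voxels undefined: data quality insufficient")

  to_map <- function(v) {
    m <- matrix(NA_real_, d[2], d[3]); m[idx] <- v; m
  }
  lag_units <- if (modality == "V") "% cycle" else "ms"
  lag_conv <- if (modality == "V") frame_interval_s * f0 * 100 else
    frame_interval_s * 1000
  lag_max <- if (modality == "V") 100 else 1000 / f0
  lagu <- (lagf * lag_conv) %% lag_max

  structure(list(xcc = to_map(xcc), lag = to_map(lagu),
                 grad = to_map(grad), cc0 = to_map(cc0),
                 undefined_mask = to_map(as.numeric(undef)) > 0,
                 modality = modality, lag_units = lag_units,
                 period_frames = period, reference_freq_hz = f0,
                 frame_interval_s = frame_interval_s),
            class = "volve_maps")
}

#' Classical fractional ventilation map
#'
#' The two-phase comparison metric `FV = (SI_exp - SI_insp) / SI_exp`, with
#' end-expiration frames identified as navigator local maxima and
#' end-inspiration frames as local minima, each averaged over respiratory
#' cycles.
#'
#' @param registered a [register_series()] result.
#' @param mask a [segment_lungs()] result.
#' @param navigator the respiratory `navigator_signal`.
#' @return Matrix of per-voxel FV (NA outside the mask).
#' @export
fractional_ventilation <- function(registered, mask, navigator) {
  v <- navigator$values
  n <- length(v)
  interior <- 2:(n - 1)
  peaks <- interior[v[interior] > v[interior - 1] & v[interior] >= v[interior + 1]]
  troughs <- interior[v[interior] < v[interior - 1] & v[interior] <= v[interior + 1]]
  if (length(peaks) < 3 || length(troughs) < 3)
    stop("fewer than 3 respiratory cycles detected")
  keep <- setdiff(seq_len(dim(registered$frames)[1]), registered$excluded_frames)
  peaks <- intersect(peaks, keep); troughs <- intersect(troughs, keep)
  d <- dim(registered$frames)
  idx <- which(mask$mask)
  Pe <- matrix(registered$frames[peaks, , ], nrow = length(peaks))[, idx, drop = FALSE]
  Pi <- matrix(registered$frames[troughs, , ], nrow = length(troughs))[, idx, drop = FALSE]
  si_exp <- colMeans(Pe); si_insp <- colMeans(Pi)
  fv <- ifelse(si_exp != 0, (si_exp - si_insp) / si_exp, NA_real_)
  out <- matrix(NA_real_, d[2], d[3])
  out[idx] <- fv
  out
}
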