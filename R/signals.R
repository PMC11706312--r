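#' Extract the raw navigator time course
#'
#' One value per frame: the arithmetic mean of the voxel intensities inside
#' the rectangular navigator ROI.
#'
#' @param series a [dynamic_series()].
#' @param roi a [place_navigator_roi()] result, or any list with integer
#'   vectors `rows` and `cols`.
#' @return Numeric vector, one value per frame.
#' @export
extract_navigator <- function(series, roi) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$frames)
  if (min(roi$rows) < 1 || max(roi$rows) > d[2] ||
      min(roi$cols) < 1 || max(roi$cols) > d[3])
    stop("ROI outside image bounds")
  apply(series$frames[, roi$rows, roi$cols, drop = FALSE], 1, mean)
}

#' Flag and replace outliers by the scaled-MAD rule
#'
#' Frames deviating from the series median by more than `k` scaled median
#' absolute deviations (scaled MAD = 1.4826 x median absolute deviation) are
#' flagged and replaced by linear interpolation from their neighbours, so the
#' uniform time base needed by lag and frequency analysis is preserved. If
#' the scaled MAD is zero, only values that differ from the median at all are
#' candidates.
#'
#' @param x numeric series of length >= 10.
#' @param k threshold in scaled MADs (default 3).
#' @return List with `values` (outliers interpolated) and integer `outliers`.
#' @export
remove_outliers <- function(x, k = 3) {
  stopifnot(is.numeric(x), length(x) >= 10)
  med <- median(x)
  dev <- abs(x - med)
  smad <- 1.4826 * median(dev)
  out <- if (smad > 0) which(dev > k * smad) else which(dev > 0)
  if (length(out) == length(x)) stop("all frames flagged as outliers")
  vals <- x
  if (length(out)) {
    keep <- setdiff(seq_along(x), out)
    vals[out] <- stats::approx(keep, x[keep], xout = out, rule = 2)$y
  }
  list(values = vals, outliers = out)
}

# zero-phase Butterworth with odd-reflection edge padding (scipy-style),
# so that filter transients do not leak into the lag estimates
.filtfilt_padded <- function(x, b_a) {
  n <- length(x)
  ord <- length(b_a$a) - 1
  pad <- min(n - 1, max(3 * ord, 12))
  if (n <= 3 * ord) stop("series too short for the filter order")
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(b_a, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase band conditioning of a physiological series
#'
#' Applies a 4th-order Butterworth filter forward and backward (zero phase,
#' so no group delay biases downstream lag estimates): the respiratory band
#' is low-passed at `lowpass_hz` (default 0.6 Hz, removing cardiac
#' contributions); the cardiac band is high-passed at `highpass_hz`
#' (default 0.8 Hz, removing respiratory contributions).
#'
#' @param x numeric series.
#' @param band `"respiratory"` or `"cardiac"`.
#' @param fs sampling frequency (Hz); must exceed twice the cutoff.
#' @param lowpass_hz,highpass_hz cutoffs in Hz.
#' @param order filter order.
#' @return Filtered series, same length as `x`.
#' @export
bandpass_condition <- function(x, band = c("respiratory", "cardiac"), fs,
                               lowpass_hz = 0.6, highpass_hz = 0.8,
                               order = 4) {
  band <- match.arg(band)
  cutoff <- if (band == "respiratory") lowpass_hz else highpass_hz
  if (fs <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  ba <- signal::butter(order, cutoff / (fs / 2),
                       type = if (band == "respiratory") "low" else "high")
  .filtfilt_padded(x, ba)
}

#' Dominant frequency of a series within a physiological band
#'
#' Frequency of the maximum magnitude-spectrum bin within the admissible
#' range: respiratory `(0, 0.6]` Hz, cardiac `[0.8, Nyquist)` Hz. Ties break
#' toward the lower frequency. The result carries a `low_confidence`
#' attribute set when the winning peak is below twice the spectral median of
#' the band (e.g. broadband noise).
#'
#' @param x numeric series of length >= 64.
#' @param fs sampling frequency (Hz).
#' @param band `"respiratory"` or `"cardiac"`.
#' @param lowpass_hz,highpass_hz band edges (Hz).
#' @return Frequency in Hz with attribute `low_confidence`.
#' @export
dominant_frequency <- function(x, fs, band = c("respiratory", "cardiac"),
                               lowpass_hz = 0.6, highpass_hz = 0.8) {
  band <- match.arg(band)
  stopifnot(length(x) >= 64)
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  mag <- Mod(fft(x - mean(x)))
  half <- freqs <= fs / 2
  sel <- if (band == "respiratory") half & freqs > 0 & freqs <= lowpass_hz
         else half & freqs >= highpass_hz & freqs < fs / 2
  if (!any(sel)) stop("empty frequency band at this sampling rate")
  f <- freqs[sel]; m <- mag[sel]
  i <- which(m == max(m))[1]  # ties -> lowest frequency (freqs ascending)
  out <- f[i]
  attr(out, "low_confidence") <- m[i] < 2 * median(m)
  out
}

#' Condition a raw reference time course into a navigator signal
#'
#' Applies, in order: scaled-MAD outlier removal (with interpolation),
#' expression as a percentage of the median (a proxy for relative lung
#' volume change), zero-phase band filtering, re-normalization to median
#' 100%, and Fourier estimation of the dominant band frequency.
#'
#' @param raw raw ROI-mean series.
#' @param fs sampling frequency (Hz).
#' @param band `"respiratory"` or `"cardiac"`.
#' @param mad_k outlier threshold in scaled MADs.
#' @param lowpass_hz,highpass_hz filter cutoffs (Hz).
#' @return An object of class `navigator_signal`: `values` (% of median),
#'   `band`, `dominant_freq_hz`, `outlier_frames`, `filter_spec`.
#' @export
condition_signal <- function(raw, fs, band = c("respiratory", "cardiac"),
                             mad_k = 3, lowpass_hz = 0.6, highpass_hz = 0.8) {
  band <- match.arg(band)
  ro <- remove_outliers(raw, k = mad_k)
  # the normalization scale is the median of the low-pass (baseline)
  # component, so band-limited oscillations cannot shift the scale
  lp <- bandpass_condition(ro$values, band = "respiratory", fs = fs,
                           lowpass_hz = lowpass_hz)
  med <- median(lp)
  if (!is.finite(med) || med <= 0) stop("non-positive navigator median")
  filt <- if (band == "respiratory") 100 * lp / med else {
    hp <- bandpass_condition(ro$values, band = "cardiac", fs = fs,
                             highpass_hz = highpass_hz)
    # high-passed series fluctuates about 0; report about the 100% baseline
    100 * hp / med + 100
  }
  f0 <- dominant_frequency(filt, fs = fs, band = band,
                           lowpass_hz = lowpass_hz, highpass_hz = highpass_hz)
  structure(list(values = filt, band = band,
                 dominant_freq_hz = as.numeric(f0),
                 low_confidence = isTRUE(attr(f0, "low_confidence")),
                 outlier_frames = ro$outliers,
                 filter_spec = list(
                   type = if (band == "respiratory") "lowpass" else "highpass",
                   cutoff_hz = if (band == "respiratory") lowpass_hz else highpass_hz,
                   order = 4, zero_phase = TRUE)),
            class = "navigator_signal")
}

#' Extract and condition a cardiac reference signal
#'
#' The perfusion analogue of the diaphragm navigator: the mean time course of
#' a user-supplied vessel ROI (aorta or main pulmonary vessel), high-pass
#' conditioned. Errors if no cardiac-band signal is present in the ROI.
#'
#' @param series a [dynamic_series()].
#' @param roi list with integer vectors `rows` and `cols`.
#' @param mad_k outlier threshold in scaled MADs.
#' @param highpass_hz cardiac high-pass cutoff (Hz).
#' @return A `navigator_signal` with `band = "cardiac"`.
#' @export
extract_cardiac_reference <- function(series, roi, mad_k = 3,
                                      highpass_hz = 0.8) {
  raw <- extract_navigator(series, roi)
  if (sd(raw) == 0) stop("no cardiac signal in ROI: constant time course")
  sig <- condition_signal(raw, fs = 1 / series$frame_interval_s,
                          band = "cardiac", mad_k = mad_k,
                          highpass_hz = highpass_hz)
  fs <- 1 / series$frame_interval_s
  if (sig$low_confidence ||
      sig$dominant_freq_hz < highpass_hz || sig$dominant_freq_hz >= fs / 2)
    stop("no cardiac signal in ROI: dominant frequency outside the cardiac band")
  sig
}
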