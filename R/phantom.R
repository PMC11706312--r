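#' Configuration for the synthetic dynamic lung phantom
#'
#' Builds the parameter set for [generate_phantom()]. The phantom emulates a
#' single coronal slice acquired during free breathing: a bright body oval,
#' two dark lung fields whose basal boundary (the diaphragm) oscillates at the
#' respiratory frequency, parenchymal signal co-varying with lung volume, a
#' superimposed cardiac-frequency component, a bright mediastinal vessel
#' carrying a strong cardiac modulation (the perfusion reference), and Rician
#' magnitude noise.
#'
#' Regional "defects" (reduced, zero or negative ventilation gradient, and/or
#' lagged response) are injected via `defects`, each a list with integer index
#' ranges `rows`, `cols` and any of `grad`, `lag_frac` (fraction of the
#' respiratory cycle in `[0,1)`) and `lag_q_ms` (cardiac arrival delay).
#'
#' @param n_frames number of frames acquired.
#' @param frame_interval_s frame interval in seconds.
#' @param matrix image size as `c(rows, cols)`; at least 48 x 48.
#' @param resp_freq_hz respiratory frequency (must be < 0.6 Hz so the
#'   low-pass band separates it from the cardiac band).
#' @param cardiac_freq_hz cardiac frequency (must be > 0.8 Hz and below the
#'   Nyquist frequency `1/(2*frame_interval_s)`).
#' @param resp_amplitude_vox diaphragm excursion amplitude in voxels.
#' @param tissue_signal_mean mean lung parenchyma intensity (arbitrary units).
#' @param ventilation_gradient true dimensionless ventilation slope; scalar or
#'   `rows x cols` matrix. Healthy parenchyma is 1 by construction.
#' @param lag_frac true ventilation lag as a fraction of the respiratory
#'   cycle in `[0,1)`; scalar or matrix.
#' @param cardiac_amplitude_frac cardiac signal amplitude as a fraction of
#'   `tissue_signal_mean` in the parenchyma.
#' @param noise_sigma noise scale in intensity units (0 disables noise).
#'   The default gives SNR 20 relative to the parenchyma mean.
#' @param noise_model `"rician"` (magnitude MRI, default) or `"gaussian"`.
#' @param resp_jitter_frac per-cycle uniform amplitude jitter (e.g. 0.1 for
#'   +/-10%); 0 (default) gives an exactly periodic raised-cosine waveform.
#' @param cardiac_waveform `"cosine"` (default) or `"pulse"` (sharpened
#'   systolic peaks).
#' @param defects list of regional defect descriptors (see Details).
#' @param rng_seed integer seed; identical configurations produce
#'   bit-identical phantoms.
#'
#' @return An object of class `phantom_config`.
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(n_frames = 512L,
                           frame_interval_s = 0.229,
                           matrix = c(64L, 64L),
                           resp_freq_hz = 0.25,
                           cardiac_freq_hz = 1.08,
                           resp_amplitude_vox = 4,
                           tissue_signal_mean = 60,
                           ventilation_gradient = 1,
                           lag_frac = 0,
                           cardiac_amplitude_frac = 0.05,
                           noise_sigma = 3,
                           noise_model = c("rician", "gaussian"),
                           resp_jitter_frac = 0,
                           cardiac_waveform = c("cosine", "pulse"),
                           defects = list(),
                           rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  cardiac_waveform <- match.arg(cardiac_waveform)
  stopifnot(.is_count(n_frames), frame_interval_s > 0, length(matrix) == 2)
  if (resp_freq_hz >= 0.6)
    stop("resp_freq_hz must be < 0.6 Hz (below the ventilation low-pass cutoff)")
  if (cardiac_freq_hz <= 0.8)
    stop("cardiac_freq_hz must be > 0.8 Hz (above the perfusion high-pass cutoff)")
  fs <- 1 / frame_interval_s
  if (fs <= 2 * cardiac_freq_hz)
    stop("frame rate must exceed twice the cardiac frequency (aliasing)")
  if (any(matrix < 48))
    stop("matrix too small to contain two lungs and a diaphragm navigator ROI (need >= 48 x 48)")
  lf <- lag_frac
  if (any(lf < 0 | lf >= 1)) stop("lag_frac values must lie in [0, 1)")
  cfg <- list(
    n_frames = as.integer(n_frames), frame_interval_s = frame_interval_s,
    matrix = as.integer(matrix), resp_freq_hz = resp_freq_hz,
    cardiac_freq_hz = cardiac_freq_hz, resp_amplitude_vox = resp_amplitude_vox,
    tissue_signal_mean = tissue_signal_mean,
    ventilation_gradient = ventilation_gradient, lag_frac = lag_frac,
    cardiac_amplitude_frac = cardiac_amplitude_frac,
    noise_sigma = noise_sigma, noise_model = noise_model,
    resp_jitter_frac = resp_jitter_frac, cardiac_waveform = cardiac_waveform,
    defects = defects, rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "phantom_config"
  cfg
}

# Fixed anatomical proportions of the phantom slice, in voxel units.
# Intensities: background 0, body soft tissue 200, sub-diaphragm abdomen 240,
# mediastinal vessel 250; lung parenchyma is cfg$tissue_signal_mean.
.phantom_geometry <- function(rows, cols) {
  list(
    body = list(rc = 0.50 * rows, cc = 0.50 * cols,
                sr = 0.48 * rows, sc = 0.44 * cols, val = 200),
    lungs = list(
      right = list(rc = 0.40 * rows, cc = 0.32 * cols,
                   sr = 0.29 * rows, sc = 0.10 * cols),
      left  = list(rc = 0.40 * rows, cc = 0.68 * cols,
                   sr = 0.29 * rows, sc = 0.10 * cols)
    ),
    base_row = round(0.58 * rows),
    abdomen_val = 240,
    vessel = list(rows = round(0.25 * rows):round(0.55 * rows),
                  cols = (floor(0.5 * cols)):(floor(0.5 * cols) + 1),
                  val = 250, amp = 0.30)
  )
}

.ellipse_mask <- function(rows, cols, rc, cc, sr, sc) {
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((r - rc) / sr)^2 + ((c - cc) / sc)^2 <= 1
}

# Respiratory waveform: unit-amplitude raised cosine, maximum at
# end-expiration (t = 0), optional per-cycle amplitude jitter.
.resp_waveform <- function(t, freq, jitter_frac = 0, jitter_amp = NULL) {
  base <- cos(2 * pi * freq * t)
  if (jitter_frac <= 0) return(base)
  cyc <- pmax(0L, floor(t * freq)) + 1L
  jitter_amp[pmin(cyc, length(jitter_amp))] * base
}

.cardiac_waveform <- function(t, freq, shape = "cosine") {
  if (shape == "cosine") return(cos(2 * pi * t * freq))
  # pulse: sharpened, zero-mean, unit peak-to-trough-normalized systolic train
  p <- cos(pi * t * freq)^8
  p <- p - mean(cos(pi * seq(0, 1, length.out = 4096) * 1)^8)
  p / max(abs(p))
}

# Per-column description of one lung: ellipse top/bottom row (integer voxel
# centres) for each column the ellipse crosses.
.lung_columns <- function(rows, cols, lung) {
  cs <- seq_len(cols)
  inside <- abs(cs - lung$cc) <= lung$sc
  cs <- cs[inside]
  h <- lung$sr * sqrt(pmax(0, 1 - ((cs - lung$cc) / lung$sc)^2))
  list(cols = cs, top = pmax(1L, ceiling(lung$rc - h)),
       bot = pmin(rows, floor(lung$rc + h)))
}

# Render the frame stack. delta_fun(tsec) returns the relative respiratory
# modulation waveform (vectorized over time); NULL means no parenchymal
# respiratory modulation (calibration pass). col_subset restricts rendering
# to the given columns (fast navigator calibration).
.render_phantom <- function(cfg, geom, d_trace, delta_fun, card_fun,
                            grad_map, lagf_map, lagq_map, col_subset = NULL,
                            with_cardiac = TRUE, with_vessel = TRUE) {
  rows <- cfg$matrix[1]; cols <- cfg$matrix[2]
  nt <- cfg$n_frames
  tsec <- (seq_len(nt) - 1) * cfg$frame_interval_s
  keep_cols <- if (is.null(col_subset)) seq_len(cols) else col_subset

  base <- matrix(0, rows, cols)
  base[.ellipse_mask(rows, cols, geom$body$rc, geom$body$cc,
                     geom$body$sr, geom$body$sc)] <- geom$body$val
  lung_cols <- lapply(geom$lungs, .lung_columns, rows = rows, cols = cols)
  # abdomen fills the whole lung ellipse; the lung overlay replaces its top
  for (lc in lung_cols)
    for (i in seq_along(lc$cols)) {
      cc <- lc$cols[i]
      if (cc %in% keep_cols) base[lc$top[i]:lc$bot[i], cc] <- geom$abdomen_val
    }
  if (with_vessel) base[geom$vessel$rows, geom$vessel$cols] <- geom$vessel$val

  # flat per-voxel list of all lung-ellipse voxels (row, col, linear index)
  vr <- integer(0); vc <- integer(0)
  for (lc in lung_cols)
    for (i in seq_along(lc$cols)) {
      cc <- lc$cols[i]
      if (!(cc %in% keep_cols)) next
      rr <- lc$top[i]:lc$bot[i]
      vr <- c(vr, rr); vc <- c(vc, rep.int(cc, length(rr)))
    }
  vidx <- cbind(vr, vc)
  lidx <- (vc - 1L) * rows + vr
  g_v <- grad_map[vidx]
  lagf_v <- lagf_map[vidx]
  lagq_v <- lagq_map[vidx] / 1000  # seconds

  frames <- array(0, dim = c(nt, rows, cols))
  SL <- cfg$tissue_signal_mean
  qa <- cfg$cardiac_amplitude_frac
  has_lag <- any(lagf_v > 0)
  for (t in seq_len(nt)) {
    img <- base
    if (with_vessel)
      img[geom$vessel$rows, geom$vessel$cols] <-
        geom$vessel$val * (1 + geom$vessel$amp * card_fun(tsec[t]))
    d <- d_trace[t]
    if (is.null(delta_fun)) {
      sig <- rep.int(SL, length(lidx))
    } else {
      if (has_lag) {
        dv <- delta_fun(tsec[t] - lagf_v / cfg$resp_freq_hz)
      } else {
        dv <- delta_fun(tsec[t])
      }
      sig <- SL * (1 + g_v * dv)
    }
    if (with_cardiac && qa != 0)
      sig <- sig + SL * qa * card_fun(tsec[t] - lagq_v)
    # partial-volume blend at the moving diaphragm boundary: voxel i spans
    # rows [i-0.5, i+0.5); rows above d are lung, below are abdomen
    frac <- pmin(1, pmax(0, d - (vr - 0.5)))
    img[lidx] <- frac * sig + (1 - frac) * geom$abdomen_val
    frames[t, , ] <- img
  }
  frames
}

# Analytic navigator ROI placement on the phantom's own geometry: centred on
# the right hemidiaphragm, one third of the way from the costophrenic
# (lateral) toward the costocardiac (medial) angle.
.phantom_nav_roi <- function(cfg, geom) {
  rows <- cfg$matrix[1]; cols <- cfg$matrix[2]
  lc <- .lung_columns(rows, cols, geom$lungs$right)
  c_lat <- min(lc$cols); c_med <- max(lc$cols)
  c0 <- c_lat + round((c_med - c_lat) / 3)
  r0 <- geom$base_row
  list(rows = (r0 - 14L):(r0 + 15L), cols = (c0 - 2L):(c0 + 2L),
       center = c(r0, c0))
}

#' Generate a synthetic free-breathing dynamic lung-MRI series
#'
#' Renders a 2D+t phantom whose lung voxels carry a signal
#' `S(t) = S0 * (1 + grad * delta(t - lag) + q * c(t - lag_q))` where
#' `delta(t)` is the relative (fractional) respiratory modulation actually
#' exhibited by the phantom's own diaphragm navigator ROI, `c(t)` the cardiac
#' waveform, and `grad`, `lag`, `lag_q` per-voxel ground-truth maps. Because
#' the parenchymal modulation is calibrated to the rendered navigator (by a
#' short fixed-point iteration over noiseless renders), the true regression
#' slope between voxel and navigator signals, both expressed as % of their
#' medians, equals `grad` by construction, and injected lags are recoverable.
#'
#' @param config a [phantom_config()].
#' @return A list with components `series` (a [dynamic_series()]) and `truth`
#'   (class `phantom_truth`: `true_grad`, `true_lag_frac`, `true_lag_q_ms`,
#'   `lung_mask`, `diaphragm_trace`, plus the navigator/cardiac ROIs used,
#'   the calibrated relative respiratory waveform and its amplitude `alpha`).
#' @examples
#' p <- generate_phantom(phantom_config(n_frames = 64, noise_sigma = 0))
#' dim(p$series$frames)
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  rows <- cfg$matrix[1]; cols <- cfg$matrix[2]
  geom <- .phantom_geometry(rows, cols)
  nt <- cfg$n_frames
  tsec <- (seq_len(nt) - 1) * cfg$frame_interval_s

  # truth maps (full-image grids; meaningful inside the lung mask)
  expand_map <- function(x) if (is.matrix(x)) x else matrix(x, rows, cols)
  grad_map <- expand_map(cfg$ventilation_gradient)
  lagf_map <- expand_map(cfg$lag_frac)
  lagq_map <- expand_map(0)
  for (d in cfg$defects) {
    if (!is.null(d$grad)) grad_map[d$rows, d$cols] <- d$grad
    if (!is.null(d$lag_frac)) lagf_map[d$rows, d$cols] <- d$lag_frac
    if (!is.null(d$lag_q_ms)) lagq_map[d$rows, d$cols] <- d$lag_q_ms
  }
  if (any(lagf_map < 0 | lagf_map >= 1)) stop("lag fractions must lie in [0, 1)")

  # waveforms and diaphragm trace (end-expiration = diaphragm high = low row)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(cfg$rng_seed)
  n_cycles <- ceiling(max(tsec) * cfg$resp_freq_hz) + 2L
  jit <- 1 + cfg$resp_jitter_frac * (2 * runif(n_cycles) - 1)
  r_fun <- function(t) .resp_waveform(t, cfg$resp_freq_hz,
                                      cfg$resp_jitter_frac, jit)
  card_fun <- function(t) .cardiac_waveform(t, cfg$cardiac_freq_hz,
                                            cfg$cardiac_waveform)
  d_trace <- geom$base_row - cfg$resp_amplitude_vox * r_fun(tsec)

  # the ROI the calibration targets is placed by the same rule the analysis
  # uses (segmentation of the temporal-median image), so the ground-truth
  # gain is defined at the navigator actually measured downstream; the
  # analytic placement is the fallback for degenerate geometries
  fr0 <- .render_phantom(cfg, geom, geom$base_row - cfg$resp_amplitude_vox *
                           r_fun(tsec), NULL, card_fun,
                         grad_map, lagf_map, lagq_map,
                         with_cardiac = FALSE)
  med_img <- apply(fr0, c(2, 3), median)
  roi <- tryCatch({
    seg <- segment_lungs(med_img, orientation = "radiological")
    place_navigator_roi(seg, med_img)
  }, error = function(e) .phantom_nav_roi(cfg, geom))
  resp_period <- 1 / cfg$resp_freq_hz

  # calibrate the relative parenchymal modulation to the rendered navigator:
  # delta_hat is measured from noiseless, cardiac-free renders of the ROI
  # columns only, and fed back until self-consistent
  delta_fun <- NULL
  for (pass in 1:3) {
    fr <- .render_phantom(cfg, geom, d_trace, delta_fun, card_fun,
                          grad_map, lagf_map, lagq_map,
                          col_subset = roi$cols, with_cardiac = FALSE,
                          with_vessel = FALSE)
    nav <- apply(fr[, roi$rows, roi$cols, drop = FALSE], 1, mean)
    delta <- nav / median(nav) - 1
    sf <- stats::splinefun(tsec, delta, method = "fmm")
    delta_fun <- local({
      sf_ <- sf; t0 <- tsec[1]; per <- resp_period; j <- cfg$resp_jitter_frac
      function(t) {
        # periodic extension before t0 (exact when jitter is off)
        tt <- ifelse(t < t0, t + per * ceiling((t0 - t) / per), t)
        sf_(tt)
      }
    })
  }
  alpha <- {
    rv <- r_fun(tsec)
    sum((nav / median(nav) - 1) * rv) / sum(rv^2)
  }

  frames <- .render_phantom(cfg, geom, d_trace, delta_fun, card_fun,
                            grad_map, lagf_map, lagq_map)
  if (cfg$noise_sigma > 0) {
    n <- length(frames)
    if (cfg$noise_model == "rician") {
      frames[] <- sqrt((frames + rnorm(n, 0, cfg$noise_sigma))^2 +
                         rnorm(n, 0, cfg$noise_sigma)^2)
    } else {
      frames[] <- frames + rnorm(n, 0, cfg$noise_sigma)
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv()))
    rm(".Random.seed", envir = globalenv())

  # ground-truth lung mask at the reference (mid-position) diaphragm row
  lung_mask <- matrix(FALSE, rows, cols)
  for (lc in lapply(geom$lungs, .lung_columns, rows = rows, cols = cols))
    for (i in seq_along(lc$cols)) {
      bot <- min(lc$bot[i], geom$base_row)
      if (lc$top[i] <= bot) lung_mask[lc$top[i]:bot, lc$cols[i]] <- TRUE
    }

  series <- dynamic_series(frames, frame_interval_s = cfg$frame_interval_s)
  truth <- structure(list(
    true_grad = grad_map, true_lag_frac = lagf_map, true_lag_q_ms = lagq_map,
    lung_mask = lung_mask, diaphragm_trace = d_trace,
    nav_roi = roi, cardiac_roi = list(rows = geom$vessel$rows,
                                      cols = geom$vessel$cols),
    alpha = alpha, delta = delta_fun(tsec), times_s = tsec
  ), class = "phantom_truth")
  list(series = series, truth = truth)
}

#' Canonical regional defects for validation phantoms
#'
#' Four rectangular regions placed well inside the lung fields of the
#' standard phantom geometry: a 30%-of-cycle ventilation lag, a
#' 50%-of-cycle ventilation lag, a paradoxical region (gradient -1, which
#' for a sinusoidal drive is equivalent to an inverted, half-cycle-lagged
#' response), and a delayed-perfusion region (cardiac arrival delayed by
#' one frame interval, 229 ms by default).
#'
#' @param matrix image size `c(rows, cols)`.
#' @param lag_q_ms cardiac arrival delay of the perfusion defect (ms).
#' @return Named list of defect descriptors for [phantom_config()]; each
#'   also carries its row/col ranges for truth comparisons.
#' @export
phantom_study_defects <- function(matrix = c(64L, 64L), lag_q_ms = 229) {
  R <- matrix[1]; C <- matrix[2]
  rr1 <- round(0.22 * R):round(0.32 * R)
  rr2 <- round(0.41 * R):round(0.50 * R)
  cr <- round(0.25 * C):round(0.39 * C)   # inside the right lung
  cl <- round(0.61 * C):round(0.75 * C)   # inside the left lung
  list(
    lag30 = list(rows = rr1, cols = cr, lag_frac = 0.3),
    lag50 = list(rows = rr2, cols = cr, lag_frac = 0.5),
    paradox = list(rows = rr1, cols = cl, grad = -1),
    qdelay = list(rows = rr2, cols = cl, lag_q_ms = lag_q_ms)
  )
}

#' Write a phantom to disk as NIfTI plus JSON sidecars
#'
#' Writes the dynamic series (`series.nii.gz`), the ground-truth maps
#' (`truth_*.nii.gz`), and a JSON sidecar with the configuration and ROIs.
#'
#' @param phantom result of [generate_phantom()].
#' @param config the [phantom_config()] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_series(phantom$series, file.path(dir, "series.nii.gz"))
  tr <- phantom$truth
  for (nm in c("true_grad", "true_lag_frac", "true_lag_q_ms"))
    .write_map_nifti(tr[[nm]], file.path(dir, paste0("truth_", nm, ".nii.gz")))
  .write_map_nifti(tr$lung_mask * 1, file.path(dir, "truth_lung_mask.nii.gz"))
  side <- unclass(config)
  side$defects <- NULL
  jsonlite::write_json(list(config = side,
                            nav_roi = unclass(tr$nav_roi),
                            cardiac_roi = unclass(tr$cardiac_roi),
                            alpha = tr$alpha,
                            diaphragm_trace = tr$diaphragm_trace),
                       file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
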