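#' Construct a dynamic 2D+t image series
#'
#' The container for a single-slice free-breathing acquisition: a uniformly
#' sampled stack of frames with its frame interval and in-plane spacing.
#'
#' @param frames numeric array with dimensions (time, rows, cols).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param voxel_spacing_mm in-plane spacing `c(row, col)` in mm.
#' @param orientation `"radiological"` (image left = anatomical right,
#'   default) or `"neurological"`.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, frame_interval_s,
                           voxel_spacing_mm = c(1, 1),
                           orientation = c("radiological", "neurological")) {
  orientation <- match.arg(orientation)
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("frame_interval_s must be > 0")
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 voxel_spacing_mm = voxel_spacing_mm,
                 orientation = orientation),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("dynamic_series: %d frames of %d x %d voxels, dt = %.4g s (%s)\n",
              d[1], d[2], d[3], x$frame_interval_s, x$orientation))
  invisible(x)
}

#' Load a dynamic series from disk
#'
#' Reads a 2D+t NIfTI volume (dims rows x cols x 1 x time, or rows x cols x
#' time) written by [write_series()] or an external tool. The frame interval
#' is taken from the time-axis pixdim; if absent, a default of 1 s is used
#' with a warning.
#'
#' @param path path to a NIfTI file.
#' @param format `"nifti"`; `"dicom"` is recognized but not supported in this
#'   build and raises an informative error.
#' @return A [dynamic_series()].
#' @export
load_series <- function(path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom")
    stop("DICOM input is not supported by this build; convert to NIfTI first")
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  arr <- as.array(img)
  if (length(d) == 4) {
    nt <- d[4]
    arr <- array(arr, dim = c(d[1], d[2], d[4]))  # drop singleton slice dim
  } else if (length(d) == 3) {
    nt <- d[3]
  } else stop("time series required: input has no time axis")
  if (nt < 2) stop("time series required: single-frame input")
  pd <- RNifti::pixdim(img)
  dt <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else {
    warning("no frame interval recorded; defaulting to 1 s")
    1
  }
  sp <- if (all(is.finite(pd[1:2])) && all(pd[1:2] > 0)) pd[1:2] else {
    warning("missing voxel spacing; defaulting to 1 mm")
    c(1, 1)
  }
  frames <- aperm(arr, c(3, 1, 2))
  dynamic_series(frames, frame_interval_s = dt, voxel_spacing_mm = sp)
}

#' Write a dynamic series as NIfTI
#'
#' The series is stored as rows x cols x 1 x time with the frame interval in
#' the fourth pixdim, so that [load_series()] round-trips it exactly.
#'
#' @param series a [dynamic_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  fr <- series$frames
  d <- dim(fr)
  arr <- array(aperm(fr, c(2, 3, 1)), dim = c(d[2], d[3], 1, d[1]))
  hdr <- RNifti::asNifti(arr)
  RNifti::pixdim(hdr) <- c(series$voxel_spacing_mm, 1, series$frame_interval_s)
  # double datatype for a lossless round trip
  img <- RNifti::asNifti(arr, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

.write_map_nifti <- function(map, path, spacing = c(1, 1)) {
  arr <- array(map, dim = c(nrow(map), ncol(map), 1))
  hdr <- RNifti::asNifti(arr)
  RNifti::pixdim(hdr) <- c(spacing, 1)
  img <- RNifti::asNifti(arr, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Analysis run configuration
#'
#' Collects every pipeline constant with its standard default: 15 discarded
#' steady-state frames, 0.6 Hz ventilation low-pass, 0.8 Hz perfusion
#' high-pass, a 30 x 5 voxel diaphragm navigator ROI, outlier removal at 3
#' scaled median absolute deviations, full-cycle lag search and a
#' two-component Gaussian mixture for the gradient histogram.
#'
#' @param n_discard_frames initial frames removed to reach steady state.
#' @param lowpass_hz ventilation band cutoff (Hz).
#' @param highpass_hz perfusion band cutoff (Hz).
#' @param nav_roi_fh_vox navigator ROI extent, foot-head (voxels).
#' @param nav_roi_rl_vox navigator ROI extent, right-left (voxels).
#' @param mad_k outlier threshold in scaled MADs.
#' @param lag_search lag search range as a fraction-of-cycle interval;
#'   the default spans one full cycle.
#' @param gmm_components mixture components for the gradient histogram.
#' @param vessel_factor parenchyma-median multiple above which bright voxels
#'   are excluded as large vessels.
#' @param mask_erode_vox voxels eroded off the analysis-mask boundary
#'   (partial-volume rim; see [erode_mask()]).
#' @param register logical; run demons registration (default TRUE).
#' @param grad_at_lag logical; compute the gradient at the lag of maximum
#'   cross-correlation instead of at zero lag (default FALSE).
#' @param refine_subframe `"auto"` (parabolic sub-frame lag refinement for
#'   perfusion only), `TRUE` or `FALSE`.
#' @param equal_weights logical; use unit equal errors in the York fit
#'   instead of difference-based noise estimates.
#' @param par_orientation `"neg_over_pos"` (default) or `"pos_over_neg"`
#'   for the peak-area ratio.
#' @param seed integer seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_discard_frames = 15L, lowpass_hz = 0.6,
                       highpass_hz = 0.8, nav_roi_fh_vox = 30L,
                       nav_roi_rl_vox = 5L, mad_k = 3,
                       lag_search = c(0, 1), gmm_components = 2L,
                       vessel_factor = 3, mask_erode_vox = 1L,
                       register = TRUE,
                       grad_at_lag = FALSE,
                       refine_subframe = "auto",
                       equal_weights = FALSE,
                       par_orientation = c("neg_over_pos", "pos_over_neg"),
                       seed = 1L) {
  par_orientation <- match.arg(par_orientation)
  stopifnot(n_discard_frames >= 0, lowpass_hz > 0, highpass_hz > 0,
            nav_roi_fh_vox > 0, nav_roi_rl_vox > 0, mad_k > 0)
  if (lowpass_hz >= highpass_hz)
    stop("lowpass_hz must be below highpass_hz (band separation)")
  structure(list(n_discard_frames = as.integer(n_discard_frames),
                 lowpass_hz = lowpass_hz, highpass_hz = highpass_hz,
                 nav_roi_fh_vox = as.integer(nav_roi_fh_vox),
                 nav_roi_rl_vox = as.integer(nav_roi_rl_vox),
                 mad_k = mad_k, lag_search = lag_search,
                 gmm_components = as.integer(gmm_components),
                 vessel_factor = vessel_factor,
                 mask_erode_vox = as.integer(mask_erode_vox),
                 register = register,
                 grad_at_lag = grad_at_lag,
                 refine_subframe = refine_subframe,
                 equal_weights = equal_weights,
                 par_orientation = par_orientation,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#' @param path config file; keys are [run_config()] arguments.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' Run the full analysis pipeline
#'
#' Executes, in order: steady-state frame discard, global intensity
#' normalization, lung segmentation (temporal-median image) and navigator ROI
#' placement, navigator extraction and conditioning, mid-respiratory target
#' selection, demons registration of all frames to the target, segmentation
#' of the target frame (analysis mask with vessel exclusion and quadrants),
#' voxel-wise conditioning and lagged cross-correlation / York regression,
#' and histogram summaries. The pipeline is a pure function of
#' `(series, config, modality)`.
#'
#' @param series a [dynamic_series()].
#' @param config a [run_config()].
#' @param modality `"V"` (ventilation; diaphragm navigator reference) or
#'   `"Q"` (perfusion; cardiac vessel reference, requires `cardiac_roi`).
#' @param cardiac_roi for `modality = "Q"`: list with integer vectors `rows`
#'   and `cols` delimiting a vessel ROI.
#' @param mask optional precomputed `lung_mask` (skips segmentation).
#' @return A list of class `volve_result`: `maps` ([compute_voxel_maps()]
#'   output), `summaries` (one [summarize_map()] per map), `navigator`,
#'   `mask`, `nav_roi`, `target_index`, `registered`, `fv` (ventilation only)
#'   and a per-stage `log` data frame.
#' @export
run_pipeline <- function(series, config = run_config(),
                         modality = c("V", "Q"), cardiac_roi = NULL,
                         mask = NULL) {
  modality <- match.arg(modality)
  stopifnot(inherits(series, "dynamic_series"), inherits(config, "run_config"))
  log <- list()
  tick <- function(stage, note = "") {
    log[[length(log) + 1]] <<- data.frame(stage = stage, note = note,
                                          time = as.numeric(Sys.time()))
  }

  # -- discard steady-state frames, normalize global intensity scale --------
  nt <- dim(series$frames)[1]
  if (nt <= config$n_discard_frames + 1)
    .stage_stop("discard", "series shorter than the steady-state discard")
  frames <- series$frames[(config$n_discard_frames + 1):nt, , , drop = FALSE]
  gmed <- median(frames)
  if (!is.finite(gmed) || gmed <= 0)
    .stage_stop("normalize", "non-positive global median intensity")
  frames <- frames / gmed
  work <- dynamic_series(frames, series$frame_interval_s,
                         series$voxel_spacing_mm, series$orientation)
  fs <- 1 / work$frame_interval_s
  tick("discard+normalize", sprintf("%d -> %d frames", nt, dim(frames)[1]))

  # -- provisional segmentation on the temporal-median image for ROI --------
  med_img <- apply(frames, c(2, 3), median)
  seg0 <- tryCatch(segment_lungs(med_img, orientation = work$orientation,
                                 vessel_factor = config$vessel_factor),
                   error = function(e) .stage_stop("segment", conditionMessage(e)))
  roi <- tryCatch(place_navigator_roi(seg0, med_img,
                                      fh = config$nav_roi_fh_vox,
                                      rl = config$nav_roi_rl_vox),
                  error = function(e) .stage_stop("navigator-roi",
                                                  conditionMessage(e)))
  tick("segment-provisional")

  # -- navigator (respiratory reference; from unregistered frames) ----------
  raw_nav <- extract_navigator(work, roi)
  navigator <- condition_signal(raw_nav, fs = fs, band = "respiratory",
                                mad_k = config$mad_k,
                                lowpass_hz = config$lowpass_hz,
                                highpass_hz = config$highpass_hz)
  tick("navigator", sprintf("f_resp = %.3f Hz", navigator$dominant_freq_hz))

  # -- modality reference ----------------------------------------------------
  if (modality == "Q") {
    if (is.null(cardiac_roi))
      .stage_stop("cardiac-reference", "cardiac navigator unavailable: supply cardiac_roi")
    reference <- tryCatch(
      extract_cardiac_reference(work, cardiac_roi, mad_k = config$mad_k,
                                highpass_hz = config$highpass_hz),
      error = function(e) .stage_stop("cardiac-reference", conditionMessage(e)))
  } else {
    reference <- navigator
  }

  # -- registration to a mid-respiratory target ------------------------------
  target <- select_target(navigator)
  registered <- if (isTRUE(config$register)) {
    tryCatch(register_series(work, target),
             error = function(e) .stage_stop("register", conditionMessage(e)))
  } else {
    structure(list(frames = work$frames, target_index = target,
                   deformation_norms = rep(0, dim(work$frames)[1]),
                   excluded_frames = integer(0),
                   method_spec = list(algorithm = "none")),
              class = "registered_series")
  }
  tick("register", sprintf("target frame %d", target))

  # -- analysis mask on the registration target ------------------------------
  if (is.null(mask)) {
    mask <- tryCatch(segment_lungs(registered$frames[target, , ],
                                   orientation = work$orientation,
                                   vessel_factor = config$vessel_factor),
                     error = function(e) .stage_stop("segment", conditionMessage(e)))
    mask <- erode_mask(mask, config$mask_erode_vox)
  }
  mask <- quadrant_split(mask)
  tick("segment-target", sprintf("%d lung voxels", sum(mask$mask)))

  # -- voxel-wise regression and maps ----------------------------------------
  maps <- tryCatch(
    compute_voxel_maps(registered, mask, reference, modality = modality,
                       config = config, frame_interval_s = work$frame_interval_s),
    error = function(e) .stage_stop("voxel-maps", conditionMessage(e)))
  tick("voxel-maps")

  fv <- if (modality == "V")
    tryCatch(fractional_ventilation(registered, mask, navigator),
             error = function(e) NULL) else NULL

  summaries <- summarize_maps(maps, mask,
                              par_orientation = config$par_orientation)
  tick("summaries")

  structure(list(maps = maps, summaries = summaries, navigator = navigator,
                 reference = reference, mask = mask, nav_roi = roi,
                 target_index = target, registered = registered, fv = fv,
                 n_analysed = dim(frames)[1], config = config,
                 modality = modality, log = do.call(rbind, log)),
            class = "volve_result")
}

#' @export
print.volve_result <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("VOLVE %s analysis: %d frames, %d lung voxels\n",
              x$modality, x$n_analysed, sum(x$mask$mask)))
  cat(sprintf("  reference frequency: %.3f Hz (target frame %d)\n",
              x$reference$dominant_freq_hz, x$target_index))
  cat(sprintf("  %s median %.3f (skewness %.2f)\n", s$xcc$map_name,
              s$xcc$median, s$xcc$skewness))
  cat(sprintf("  %s median %.1f %s\n", s$lag$map_name, s$lag$median,
              x$maps$lag_units))
  cat(sprintf("  %s median %.3f%s\n", s$grad$map_name, s$grad$median,
              if (!is.null(s$grad$par) && is.finite(s$grad$par))
                sprintf(" (PAR %.3f)", s$grad$par) else ""))
  invisible(x)
}

#' Write the maps and summaries of a pipeline run
#'
#' Maps are written as NIfTI, scalar summaries as a JSON sidecar and a CSV
#' (one row per map per region).
#'
#' @param result a `volve_result` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- result$maps
  tag <- m$modality
  for (nm in c("xcc", "lag", "grad", "cc0"))
    .write_map_nifti(m[[nm]], file.path(dir, sprintf("%s_%s.nii.gz", nm, tag)))
  .write_map_nifti(result$mask$mask * 1, file.path(dir, "lung_mask.nii.gz"))
  jsonlite::write_json(summaries_as_list(result$summaries),
                       file.path(dir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(summaries_as_table(result$summaries),
            file.path(dir, "summaries.csv"), row.names = FALSE)
  invisible(dir)
}
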