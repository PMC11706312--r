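#' Select the mid-respiratory registration target
#'
#' Returns the index of the frame whose navigator value is closest to the
#' median navigator value, i.e. a frame at an intermediate level of lung
#' inflation (minimizing the deformations the registration must resolve).
#' Ties break toward the earliest frame.
#'
#' @param navigator a `navigator_signal` or numeric vector.
#' @return Integer frame index.
#' @export
select_target <- function(navigator) {
  v <- if (inherits(navigator, "navigator_signal")) navigator$values else navigator
  which.min(abs(v - median(v)))[1]
}

#' Register every frame to a target frame (demons)
#'
#' Non-rigid, intensity-driven (demons) registration of each frame onto the
#' target, with Gaussian regularization of the displacement field and a
#' 3-level coarse-to-fine pyramid; intensities are resampled with bilinear
#' interpolation. The target frame itself is returned untouched. Frames
#' whose mean displacement exceeds a quarter of the image extent are flagged
#' divergent and excluded (with a warning) rather than interpolated.
#'
#' @param series a [dynamic_series()] with at least 2 frames.
#' @param target_index index of the target frame.
#' @param levels pyramid levels.
#' @param max_iter maximum demons iterations per level (cold start).
#' @param max_iter_warm iteration cap for warm-started frames (consecutive
#'   frames differ by well under a voxel of motion).
#' @param sigma_field Gaussian regularization of the displacement field
#'   (voxels).
#' @param sigma_pre pre-smoothing of the moving frame (voxels).
#' @return An object of class `registered_series`: aligned `frames`,
#'   `target_index`, per-frame `deformation_norms` (mean displacement, mm),
#'   `excluded_frames`, `method_spec`.
#' @export
register_series <- function(series, target_index, levels = 3L,
                            max_iter = 50L, max_iter_warm = 30L,
                            sigma_field = 1.0, sigma_pre = 0.5) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$frames)
  if (d[1] < 2) stop("at least 2 frames required")
  if (any(!is.finite(series$frames))) stop("non-finite values in input series")
  stopifnot(target_index >= 1, target_index <= d[1])
  fixed <- series$frames[target_index, , ]
  out <- array(0, dim = d)
  norms <- numeric(d[1])
  excluded <- integer(0)
  limit <- max(d[2], d[3]) / 4
  mm <- mean(series$voxel_spacing_mm)
  # consecutive frames differ little (breathing is slow relative to the
  # frame rate), so each solve warm-starts from the previous frame's field
  ur_prev <- NULL; uc_prev <- NULL
  for (t in seq_len(d[1])) {
    if (t == target_index) { out[t, , ] <- fixed; next }
    warm <- !is.null(ur_prev)
    reg <- .demons_register_cpp(fixed, series$frames[t, , ],
                                levels = levels,
                                max_iter = if (warm) max_iter_warm else max_iter,
                                sigma_field = sigma_field,
                                sigma_pre = sigma_pre,
                                ur_init = ur_prev, uc_init = uc_prev)
    ur_prev <- reg$ur; uc_prev <- reg$uc
    if (reg$mean_displacement_vox > limit) {
      excluded <- c(excluded, t)
      out[t, , ] <- NA_real_
    } else {
      out[t, , ] <- reg$warped
    }
    norms[t] <- reg$mean_displacement_vox * mm
  }
  if (length(excluded))
    warning(sprintf("%d frame(s) excluded for registration divergence",
                    length(excluded)))
  structure(list(frames = out, target_index = as.integer(target_index),
                 deformation_norms = norms, excluded_frames = excluded,
                 method_spec = list(algorithm = "demons",
                                    levels = levels, max_iter = max_iter,
                                    sigma_field = sigma_field,
                                    sigma_pre = sigma_pre,
                                    interpolation = "bilinear")),
            class = "registered_series")
}

#' Register a single frame pair (demons)
#'
#' Low-level access to the registration backend; mainly for QC and testing.
#'
#' @param fixed,moving 2D numeric matrices of equal size.
#' @inheritParams register_series
#' @return List with `warped`, displacement components `ur`, `uc` (voxels)
#'   and `mean_displacement_vox`.
#' @export
register_pair <- function(fixed, moving, levels = 3L, max_iter = 50L,
                          sigma_field = 1.0, sigma_pre = 0.5) {
  stopifnot(is.matrix(fixed), is.matrix(moving), all(dim(fixed) == dim(moving)))
  .demons_register_cpp(fixed, moving, levels = levels, max_iter = max_iter,
                       sigma_field = sigma_field, sigma_pre = sigma_pre)
}
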