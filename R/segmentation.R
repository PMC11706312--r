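#' Segment the lungs by seeded region growing
#'
#' The thoracic cavity is segmented on a single reference frame: the body is
#' separated from background by an Otsu threshold, dark regions inside the
#' (hole-filled) body are labelled, and the lungs are grown from seeds placed
#' at the centroids of the two largest dark components (or from user-supplied
#' seeds). Bright voxels inside the lungs exceeding `vessel_factor` times the
#' parenchyma median are excluded as large pulmonary vessels. An optional
#' manual-correction overlay is applied with XOR semantics.
#'
#' @param frame 2D numeric matrix (a single image).
#' @param seeds optional list/matrix of `(row, col)` seed voxels, one per lung.
#' @param orientation `"radiological"` (image left = anatomical right) or
#'   `"neurological"`; determines the side labels.
#' @param vessel_factor multiple of the parenchyma median intensity above
#'   which lung voxels are excluded as vessels.
#' @param min_area minimum component area (voxels) for auto-seeding.
#' @param overlay optional logical matrix XOR-ed onto the grown mask
#'   (manual correction).
#' @return An object of class `lung_mask`: logical `mask`, character matrix
#'   `side_labels` (`"right"`/`"left"`), logical `vessel_exclusions`, and
#'   `quadrant_labels` (filled by [quadrant_split()]).
#' @export
segment_lungs <- function(frame, seeds = NULL,
                          orientation = c("radiological", "neurological"),
                          vessel_factor = 3, min_area = NULL,
                          overlay = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(frame))
  rows <- nrow(frame); cols <- ncol(frame)
  if (is.null(min_area)) min_area <- max(25, round(0.004 * rows * cols))
  rng <- range(frame)
  if (diff(rng) <= 0) stop("auto-seeding failed: image is uniform; supply seeds")
  xn <- (frame - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))

  body <- xn > thr
  lab <- EBImage::bwlabel(EBImage::Image(body))
  tabs <- tabulate(as.integer(lab))
  if (!length(tabs)) stop("auto-seeding failed: no body detected; supply seeds")
  body_main <- matrix(as.integer(lab) == which.max(tabs), rows, cols)
  body_filled <- as.array(EBImage::fillHull(EBImage::Image(body_main))) > 0

  dark <- body_filled & (xn <= thr)
  dlab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(dark))), rows, cols)

  if (is.null(seeds)) {
    sizes <- tabulate(dlab)
    ok <- which(sizes >= min_area)
    if (length(ok) < 2)
      stop("auto-seeding failed: fewer than two dark components of sufficient size; supply seeds")
    ok <- ok[order(sizes[ok], decreasing = TRUE)][1:2]
    comp_ids <- ok
  } else {
    seeds <- if (is.matrix(seeds)) split(seeds, row(seeds)) else seeds
    comp_ids <- vapply(seeds, function(s) dlab[s[1], s[2]], numeric(1))
    if (any(comp_ids == 0))
      stop("a seed does not fall on a dark region; adjust seeds")
    comp_ids <- unique(comp_ids)
    if (length(comp_ids) < 2) stop("seeds must fall in two distinct lungs")
  }
  mask <- matrix(dlab %in% comp_ids, rows, cols)

  if (!is.null(overlay)) {
    stopifnot(is.matrix(overlay), all(dim(overlay) == dim(mask)))
    mask <- xor(mask, overlay > 0)
    # recompute the two components after manual correction
    mlab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask))), rows, cols)
    sizes <- tabulate(mlab)
    comp_ids <- order(sizes, decreasing = TRUE)[seq_len(min(2, sum(sizes > 0)))]
    dlab <- mlab
  }

  # side labels: smaller mean column is the image-left lung
  side_labels <- matrix(NA_character_, rows, cols)
  mean_cols <- vapply(comp_ids, function(id) mean(col(dlab)[dlab == id]),
                      numeric(1))
  img_left_id <- comp_ids[which.min(mean_cols)]
  img_right_id <- comp_ids[which.max(mean_cols)]
  if (orientation == "radiological") {
    side_labels[dlab == img_left_id] <- "right"
    side_labels[dlab == img_right_id] <- "left"
  } else {
    side_labels[dlab == img_left_id] <- "left"
    side_labels[dlab == img_right_id] <- "right"
  }

  vessels <- matrix(FALSE, rows, cols)
  pmed <- median(xn[mask])
  if (is.finite(pmed) && pmed > 0)
    vessels <- mask & (xn > vessel_factor * pmed)
  mask <- mask & !vessels
  side_labels[!mask] <- NA_character_

  structure(list(mask = mask, side_labels = side_labels,
                 vessel_exclusions = vessels,
                 quadrant_labels = matrix(NA_character_, rows, cols),
                 orientation = orientation),
            class = "lung_mask")
}

# diaphragm boundary: for each column, the largest-row lung voxel of a side
.diaphragm_boundary <- function(mask_side) {
  cols_with <- which(colSums(mask_side) > 0)
  bnd <- vapply(cols_with, function(cc) max(which(mask_side[, cc])), integer(1))
  list(cols = cols_with, rows = bnd)
}

#' Place the diaphragm navigator ROI
#'
#' The ROI (default 30 foot-head x 5 right-left voxels) is centred on the
#' right hemidiaphragm boundary, at one third of the horizontal distance from
#' the costophrenic (lateral) angle toward the costocardiac (medial) angle of
#' the right lung. If the ROI would cross an image border it is shifted
#' inward, size preserved, with a warning.
#'
#' @param mask a [segment_lungs()] result with a right lung.
#' @param frame the reference frame (used only for bounds; placement depends
#'   on the mask geometry alone, so it is invariant to intensity scaling).
#' @param fh,rl ROI extent in the foot-head and right-left directions.
#' @return An object of class `navigator_roi` with integer vectors `rows`,
#'   `cols`, the `anchor` (diaphragm centre point) and `size`.
#' @export
place_navigator_roi <- function(mask, frame, fh = 30L, rl = 5L) {
  stopifnot(inherits(mask, "lung_mask"))
  rows <- nrow(mask$mask); cols <- ncol(mask$mask)
  right <- !is.na(mask$side_labels) & mask$side_labels == "right"
  if (!any(right)) stop("right lung missing from mask")
  bnd <- .diaphragm_boundary(right)
  if (any(bnd$rows >= rows))
    stop("diaphragm boundary not found: right lung touches the image border")
  # lateral = outer edge of the right lung (image side depends on orientation)
  lateral_is_min_col <- mask$orientation == "radiological"
  c_lat <- if (lateral_is_min_col) min(bnd$cols) else max(bnd$cols)
  c_med <- if (lateral_is_min_col) max(bnd$cols) else min(bnd$cols)
  c0 <- as.integer(c_lat + round((c_med - c_lat) / 3))
  r0 <- bnd$rows[match(c0, bnd$cols)]
  if (is.na(r0)) r0 <- as.integer(round(stats::approx(bnd$cols, bnd$rows,
                                                      xout = c0)$y))

  rr <- (r0 - ceiling(fh / 2) + 1L):(r0 + floor(fh / 2))
  cc <- (c0 - ceiling(rl / 2) + 1L):(c0 + floor(rl / 2))
  shift_in <- function(v, n) {
    if (v[1] < 1) v <- v - v[1] + 1L
    if (v[length(v)] > n) v <- v - (v[length(v)] - n)
    v
  }
  rr2 <- shift_in(rr, rows); cc2 <- shift_in(cc, cols)
  if (!identical(rr2, rr) || !identical(cc2, cc))
    warning("navigator ROI clipped at the image border; shifted inward")
  structure(list(rows = as.integer(rr2), cols = as.integer(cc2),
                 anchor = c(row = r0, col = c0),
                 size = c(fh = fh, rl = rl)),
            class = "navigator_roi")
}

#' Erode the parenchyma mask
#'
#' Peels `n` voxels off the mask boundary. Used as analysis-mask hygiene:
#' the outermost voxel layer is dominated by partial-volume mixing with
#' chest-wall/mediastinal tissue and by residual registration effects at
#' static edges, which invert or dilute the parenchymal signal.
#'
#' @param mask a [segment_lungs()] result.
#' @param n erosion radius in voxels.
#' @return The eroded `lung_mask`.
#' @export
erode_mask <- function(mask, n = 1L) {
  stopifnot(inherits(mask, "lung_mask"))
  if (n <= 0) return(mask)
  kern <- EBImage::makeBrush(2 * n + 1, shape = "box")
  m <- as.array(EBImage::erode(EBImage::Image(mask$mask * 1), kern)) > 0
  mask$mask <- m
  mask$side_labels[!m] <- NA_character_
  mask$quadrant_labels[!m] <- NA_character_
  mask
}

#' Split the lung mask into quadrants
#'
#' Cuts the mask at the row midway between the apex (minimum row) and base
#' (maximum row) of the right lung, labelling voxels RU/RL/LU/LL (right/left
#' x upper/lower). The labels partition the parenchyma mask exactly.
#'
#' @param mask a [segment_lungs()] result with both lungs.
#' @return The mask with `quadrant_labels` filled.
#' @export
quadrant_split <- function(mask) {
  stopifnot(inherits(mask, "lung_mask"))
  right <- !is.na(mask$side_labels) & mask$side_labels == "right"
  left <- !is.na(mask$side_labels) & mask$side_labels == "left"
  if (!any(right) || !any(left)) stop("both lungs required for quadrant split")
  rr <- range(which(rowSums(right) > 0))
  cut <- (rr[1] + rr[2]) / 2
  rowm <- row(mask$mask)
  q <- matrix(NA_character_, nrow(mask$mask), ncol(mask$mask))
  q[right & rowm < cut] <- "RU"
  q[right & rowm >= cut] <- "RL"
  q[left & rowm < cut] <- "LU"
  q[left & rowm >= cut] <- "LL"
  mask$quadrant_labels <- q
  mask$cut_row <- cut
  mask
}
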