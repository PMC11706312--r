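#' Histogram summary of a parameter map
#'
#' Reduces a map to the scalar summaries used for group comparison: the
#' median over defined voxels, the moment-based Fisher-Pearson skewness g1,
#' per-quadrant medians, and (for gradient maps) a two-component Gaussian
#' mixture with its peak-area ratio.
#'
#' @param map numeric matrix (NA where undefined).
#' @param mask a [quadrant_split()] lung mask.
#' @param map_name label, e.g. `"Grad_V"`.
#' @param gmm logical; fit the two-component mixture and PAR.
#' @param min_voxels minimum number of defined voxels.
#' @param par_orientation `"neg_over_pos"` or `"pos_over_neg"`.
#' @return An object of class `histogram_summary`: `map_name`, `median`,
#'   `skewness` (NA with a warning when degenerate), `quadrant_medians`,
#'   `n_voxels`, and `gmm`/`par` when requested.
#' @export
summarize_map <- function(map, mask, map_name = "map", gmm = FALSE,
                          min_voxels = 100,
                          par_orientation = "neg_over_pos") {
  stopifnot(is.matrix(map), inherits(mask, "lung_mask"))
  sel <- mask$mask & is.finite(map)
  vals <- map[sel]
  if (length(vals) < min_voxels)
    stop("too few defined voxels for a histogram summary")
  m2 <- mean((vals - mean(vals))^2)
  skew <- if (m2 > 0) mean((vals - mean(vals))^3) / m2^1.5 else {
    warning("degenerate distribution: skewness undefined")
    NA_real_
  }
  quads <- c("RU", "RL", "LU", "LL")
  qmed <- vapply(quads, function(q) {
    s <- sel & !is.na(mask$quadrant_labels) & mask$quadrant_labels == q
    if (any(s)) median(map[s]) else NA_real_
  }, numeric(1))
  out <- list(map_name = map_name, median = median(vals), skewness = skew,
              quadrant_medians = qmed, n_voxels = length(vals))
  if (gmm) {
    fit <- tryCatch(fit_gmm_par(vals, par_orientation = par_orientation),
                    error = function(e) NULL)
    out$gmm <- fit$gmm
    out$par <- fit$par
  }
  structure(out, class = "histogram_summary")
}

#' Two-component Gaussian mixture and peak-area ratio of a gradient sample
#'
#' Fits a two-component univariate Gaussian mixture by
#' expectation-maximization, initialized at the modes observed in healthy
#' and paradoxically ventilating parenchyma (means +1 and -1, sds 0.5,
#' weights 0.5/0.5), to log-likelihood tolerance 1e-6 within 500 iterations.
#' The peak-area ratio (PAR) is the mixture weight of the component with the
#' more negative mean divided by the weight of the more positive one (so PAR
#' grows with the paradoxical mode), or the reciprocal under
#' `par_orientation = "pos_over_neg"`. Collapsing components (sd below
#' 1e-4) are refit with an sd floor; persistent failure returns `par = NA`.
#'
#' @param grad_values numeric sample (>= 200 values).
#' @param par_orientation `"neg_over_pos"` (default) or `"pos_over_neg"`.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return List with `gmm` (means, sds, weights, loglik, n_iter) and `par`.
#' @export
fit_gmm_par <- function(grad_values, par_orientation = "neg_over_pos",
                        tol = 1e-6, max_iter = 500L) {
  x <- grad_values[is.finite(grad_values)]
  if (length(x) < 200) stop("at least 200 values required for the mixture fit")
  run_em <- function(sd_floor) {
    mu <- c(1, -1); sig <- c(0.5, 0.5); w <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(x, mu[1], sig[1])
      d2 <- w[2] * dnorm(x, mu[2], sig[2])
      tot <- d1 + d2
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      g1 <- d1 / tot
      g2 <- 1 - g1
      n1 <- sum(g1); n2 <- sum(g2)
      if (n1 < 1e-8 || n2 < 1e-8) break
      mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
      sig <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                    sum(g2 * (x - mu[2])^2) / n2))
      sig <- pmax(sig, sd_floor)
      w <- c(n1, n2) / length(x)
      ll <- sum(log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol) {
        return(list(mu = mu, sig = sig, w = w, ll = ll, n_iter = it,
                    collapsed = any(sig <= 1.0001 * sd_floor & sd_floor > 1e-8)))
      }
      ll_old <- ll
    }
    list(mu = mu, sig = sig, w = w, ll = ll_old, n_iter = max_iter,
         collapsed = any(sig < 1e-4))
  }
  fit <- run_em(sd_floor = 0)
  if (any(fit$sig < 1e-4) || any(!is.finite(fit$sig)))
    fit <- run_em(sd_floor = 0.01)
  par <- NA_real_
  if (all(is.finite(fit$mu)) && all(is.finite(fit$w))) {
    ineg <- which.min(fit$mu); ipos <- which.max(fit$mu)
    if (fit$w[ipos] > 0) {
      par <- fit$w[ineg] / fit$w[ipos]
      if (par_orientation == "pos_over_neg")
        par <- if (fit$w[ineg] > 0) fit$w[ipos] / fit$w[ineg] else NA_real_
    }
  }
  list(gmm = list(means = fit$mu, sds = fit$sig, weights = fit$w,
                  loglik = fit$ll, n_iter = fit$n_iter),
       par = par)
}

#' Summaries for every map of a pipeline run
#'
#' One [summarize_map()] per map (XCC, Lag, Grad), with the Gaussian mixture
#' and PAR computed on the gradient map.
#'
#' @param maps a [compute_voxel_maps()] result.
#' @param mask a [quadrant_split()] lung mask.
#' @param par_orientation passed to [fit_gmm_par()].
#' @return Named list of `histogram_summary` objects.
#' @export
summarize_maps <- function(maps, mask, par_orientation = "neg_over_pos") {
  stopifnot(inherits(maps, "volve_maps"))
  tag <- maps$modality
  list(
    xcc = summarize_map(maps$xcc, mask, paste0("XCC_", tag)),
    lag = summarize_map(maps$lag, mask, paste0("Lag_", tag)),
    grad = summarize_map(maps$grad, mask, paste0("Grad_", tag), gmm = TRUE,
                         par_orientation = par_orientation)
  )
}

#' @rdname summarize_maps
#' @param summaries result of [summarize_maps()].
#' @export
summaries_as_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(map = s$map_name, median = s$median, skewness = s$skewness,
               par = if (is.null(s$par)) NA_real_ else s$par,
               RU = s$quadrant_medians[["RU"]], RL = s$quadrant_medians[["RL"]],
               LU = s$quadrant_medians[["LU"]], LL = s$quadrant_medians[["LL"]],
               n_voxels = s$n_voxels, row.names = NULL)
  }))
}

#' @rdname summarize_maps
#' @export
summaries_as_list <- function(summaries) {
  lapply(summaries, function(s) {
    s <- unclass(s)
    s$quadrant_medians <- as.list(s$quadrant_medians)
    s
  })
}
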