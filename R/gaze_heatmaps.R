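#' Construct a gaze heatmap
#'
#' A heatmap is a gridded, non-negative gaze density at a declared resolution.
#' `grid[i, j]` covers the cell with x in `origin[1] + (j-1, j] / px_per_deg`
#' and y in `origin[2] + (i-1, i] / px_per_deg`: row index grows with y from
#' the lower-left corner `origin`. Before smoothing, total mass equals the
#' number of accumulated 1-ms samples, i.e. dwell time in ms.
#'
#' @param grid numeric matrix, `round(extent * px_per_deg)` cells per axis
#'   (rows = height, cols = width), all values finite and `>= 0` unless
#'   `signed = TRUE`.
#' @param px_per_deg grid resolution in pixels per degree of visual angle.
#' @param origin `c(x, y)` dva coordinate of the grid's lower-left corner.
#' @param extent `c(width, height)` in dva.
#' @param signed allow negative values (difference maps).
#' @return object of class `gm_heatmap`.
#' @export
gm_heatmap <- function(grid, px_per_deg, origin, extent, signed = FALSE) {
  grid <- as.matrix(grid)
  nx <- as.integer(round(extent[1] * px_per_deg))
  ny <- as.integer(round(extent[2] * px_per_deg))
  if (nrow(grid) != ny || ncol(grid) != nx)
    stop("grid is ", nrow(grid), " x ", ncol(grid), " but extent x resolution requires ",
         ny, " x ", nx)
  if (!signed && any(grid < 0)) stop("heatmap values must be non-negative")
  structure(list(grid = unname(grid), px_per_deg = px_per_deg,
                 origin = as.numeric(origin), extent = as.numeric(extent),
                 signed = signed),
            class = "gm_heatmap")
}

#' @export
print.gm_heatmap <- function(x, ...) {
  cat(sprintf("<gm_heatmap> %d x %d px, %g px/deg, extent %g x %g dva, mass %.4g\n",
              nrow(x$grid), ncol(x$grid), x$px_per_deg, x$extent[1], x$extent[2],
              sum(x$grid)))
  invisible(x)
}

same_grid <- function(u, v) {
  identical(dim(u$grid), dim(v$grid)) &&
    isTRUE(all.equal(u$px_per_deg, v$px_per_deg)) &&
    isTRUE(all.equal(u$origin, v$origin))
}

# Bin (x, y) dva points into a fresh grid; returns list(grid, n_dropped).
bin_points <- function(x, y, px_per_deg, origin, extent) {
  nx <- as.integer(round(extent[1] * px_per_deg))
  ny <- as.integer(round(extent[2] * px_per_deg))
  jx <- floor((x - origin[1]) * px_per_deg) + 1L
  iy <- floor((y - origin[2]) * px_per_deg) + 1L
  ok <- jx >= 1L & jx <= nx & iy >= 1L & iy <= ny
  g <- matrix(0, ny, nx)
  if (any(ok)) {
    tab <- table((jx[ok] - 1L) * ny + iy[ok])
    g[as.integer(names(tab))] <- as.numeric(tab)
  }
  list(grid = g, n_dropped = sum(!ok))
}

#' Build a fixation heatmap from one trial
#'
#' Samples falling inside detected saccades larger than `exclude_amp_dva` are
#' removed from the trace; the remaining on-image samples are accumulated one
#' count per 1-ms sample and the grid is smoothed with an isotropic Gaussian
#' (unit-sum kernel, zero-padded borders), so total mass approximates dwell
#' time in ms for interior gaze.
#'
#' @param trial a [gm_trial()].
#' @param saccades [detect_saccades()] output for the trial.
#' @param sigma_dva Gaussian SD in dva (default 0.25).
#' @param exclude_amp_dva saccade-amplitude exclusion threshold (default 1).
#' @param px_per_deg native display resolution (default 20).
#' @return a [gm_heatmap()] with attributes `mass` (retained sample count)
#'   and `n_dropped` (off-grid samples).
#' @export
build_fixation_heatmap <- function(trial, saccades, sigma_dva = 0.25,
                                   exclude_amp_dva = 1.0, px_per_deg = 20) {
  s <- retained_samples(trial, saccades, exclude_amp_dva)
  if (nrow(s) == 0) stop("trial ", trial$trial_id, ": no usable samples for heatmap")
  ext <- trial$image_extent
  org <- -ext / 2
  b <- bin_points(s$x, s$y, px_per_deg, org, ext)
  hm <- gm_heatmap(smooth_gauss2d(b$grid, sigma_dva * px_per_deg),
                   px_per_deg, org, ext)
  attr(hm, "mass") <- nrow(s) - b$n_dropped
  attr(hm, "n_dropped") <- b$n_dropped
  hm
}

# On-image post-onset samples with large-saccade intervals removed.
retained_samples <- function(trial, saccades, exclude_amp_dva = 1.0) {
  s <- trial$samples
  keep <- s$t_ms >= 0 & s$on_image & !is.na(s$x)
  big <- saccades[saccades$A_dva > exclude_amp_dva, , drop = FALSE]
  if (nrow(big)) for (k in seq_len(nrow(big)))
    keep <- keep & !(s$t_ms >= big$onset_ms[k] & s$t_ms <= big$offset_ms[k])
  s[keep, , drop = FALSE]
}

#' Resample a heatmap to the analysis resolution
#'
#' Mass-preserving down-sampling (each source cell's mass goes to the target
#' cell containing its center) followed by Gaussian smoothing in target
#' pixels. For the standard 28 x 21 dva image at 5 px/deg the result is a
#' 140 x 105 grid.
#'
#' @param hm a [gm_heatmap()].
#' @param px_per_deg target resolution (default 5; must not exceed source).
#' @param sigma_px Gaussian SD in target pixels (default 2.5).
#' @return the resampled [gm_heatmap()].
#' @export
resample_for_analysis <- function(hm, px_per_deg = 5, sigma_px = 2.5) {
  if (px_per_deg > hm$px_per_deg)
    stop("target resolution (", px_per_deg, " px/deg) finer than source (",
         hm$px_per_deg, " px/deg)")
  nx <- as.integer(round(hm$extent[1] * px_per_deg))
  ny <- as.integer(round(hm$extent[2] * px_per_deg))
  src <- hm$grid
  cx <- hm$origin[1] + (seq_len(ncol(src)) - 0.5) / hm$px_per_deg
  cy <- hm$origin[2] + (seq_len(nrow(src)) - 0.5) / hm$px_per_deg
  jx <- pmin(pmax(floor((cx - hm$origin[1]) * px_per_deg) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((cy - hm$origin[2]) * px_per_deg) + 1L, 1L), ny)
  # accumulate source cells into target bins (rows, then columns)
  tmp <- rowsum(src, group = iy)
  tmp_full <- matrix(0, ny, ncol(src))
  tmp_full[as.integer(rownames(tmp)), ] <- tmp
  tt <- rowsum(t(tmp_full), group = jx)
  g <- matrix(0, ny, nx)
  g[, as.integer(rownames(tt))] <- t(tt)
  hm2 <- gm_heatmap(smooth_gauss2d(g, sigma_px), px_per_deg, hm$origin, hm$extent,
                    signed = hm$signed)
  attr(hm2, "mass") <- attr(hm, "mass")
  hm2
}

#' Euclidean distance between two heatmaps
#'
#' `d(u, v) = sqrt(sum((u_i - v_i)^2))` over the flattened grids.
#'
#' @param u,v [gm_heatmap()] objects on identical grids.
#' @return non-negative scalar.
#' @export
heatmap_distance <- function(u, v) {
  if (!same_grid(u, v)) stop("heatmap grids do not match")
  sqrt(sum((u$grid - v$grid)^2))
}

#' Weighted mean of a stack of heatmaps
#' @param hms list of [gm_heatmap()] on identical grids.
#' @param weights optional non-negative weights (default uniform).
#' @return the average [gm_heatmap()].
#' @export
average_heatmaps <- function(hms, weights = NULL) {
  if (!length(hms)) stop("average_heatmaps: empty input")
  for (h in hms[-1]) if (!same_grid(hms[[1]], h)) stop("heatmap grids do not match")
  w <- weights %||% rep(1, length(hms))
  if (length(w) != length(hms) || any(w < 0) || sum(w) == 0)
    stop("invalid weights")
  w <- w / sum(w)
  g <- Reduce(`+`, Map(function(h, wi) wi * h$grid, hms, w))
  gm_heatmap(g, hms[[1]]$px_per_deg, hms[[1]]$origin, hms[[1]]$extent,
             signed = any(vapply(hms, `[[`, logical(1), "signed")))
}

#' Rescale a heatmap to unit total mass
#'
#' Pattern-level comparisons (e.g. the pattern change index) are blind to how
#' long a trial lasted only if per-trial dwell mass is divided out; this
#' helper performs that normalization.
#'
#' @param hm a [gm_heatmap()] with positive total mass.
#' @return the unit-mass [gm_heatmap()].
#' @export
normalize_heatmap <- function(hm) {
  tot <- sum(hm$grid)
  if (tot <= 0) stop("cannot normalize a heatmap with non-positive mass")
  gm_heatmap(hm$grid / tot, hm$px_per_deg, hm$origin, hm$extent,
             signed = hm$signed)
}

#' Signed difference of two heatmaps (post minus baseline)
#' @param post_avg,base_avg [gm_heatmap()] objects on identical grids.
#' @return a signed [gm_heatmap()].
#' @export
difference_heatmap <- function(post_avg, base_avg) {
  if (!same_grid(post_avg, base_avg)) stop("heatmap grids do not match")
  gm_heatmap(post_avg$grid - base_avg$grid, post_avg$px_per_deg,
             post_avg$origin, post_avg$extent, signed = TRUE)
}
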