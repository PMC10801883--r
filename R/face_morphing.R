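#' Average face shape from landmark correspondences
#'
#' The mean shape is the pointwise arithmetic mean of the corresponding
#' landmark coordinates across images; it defines the common frame into
#' which all gaze data are morphed.
#'
#' @param landmark_sets list of [gm_landmarks()] with identical label order.
#' @return object of class `gm_mean_shape`: `points` (26 x 2), `labels`,
#'   `source_ids`.
#' @export
compute_mean_shape <- function(landmark_sets) {
  if (!length(landmark_sets)) stop("compute_mean_shape: no landmark sets")
  labels <- landmark_sets[[1]]$labels
  for (lm in landmark_sets) if (!identical(lm$labels, labels))
    stop("landmark label order differs between images (correspondence broken): ",
         lm$image_id)
  pts <- Reduce(`+`, lapply(landmark_sets, `[[`, "points")) / length(landmark_sets)
  structure(list(points = pts, labels = labels,
                 source_ids = vapply(landmark_sets, `[[`, "", "image_id")),
            class = "gm_mean_shape")
}

#' Delaunay triangulation of the mean shape
#'
#' The triangulation is computed once on the mean shape; its vertex-index
#' topology is reused on every individual face so triangles correspond across
#' images. Triangle vertex triples are sorted and ordered for determinism.
#'
#' @param shape a `gm_mean_shape` (or any list with a `points` matrix).
#' @return object of class `gm_mesh`: `triangles` (k x 3 index matrix into
#'   the 26 points), `n_points`.
#' @export
triangulate <- function(shape) {
  p <- shape$points
  if (nrow(p) < 3) stop("triangulate needs at least 3 points")
  if (qr(cbind(1, p))$rank < 3) stop("points are collinear; triangulation is degenerate")
  dd <- deldir::deldir(p[, 1], p[, 2], suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  if (!is.matrix(tri)) tri <- matrix(tri, ncol = 3)
  if (nrow(tri) == 0) stop("triangulation failed")
  tri <- t(apply(tri, 1, sort))
  tri <- tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
  structure(list(triangles = unname(tri), n_points = nrow(p)), class = "gm_mesh")
}

#' Affine map sending one triangle onto another
#'
#' Solves the six-unknown linear system `D = T S` where `S` and `D` hold the
#' homogeneous source and destination vertices column-wise, yielding the
#' 3 x 3 homogeneous transform (bottom row 0, 0, 1) that maps the source
#' vertices exactly onto the destination vertices.
#'
#' @param src_tri,dst_tri 3 x 2 matrices of triangle vertices (rows = points).
#' @return 3 x 3 transform matrix.
#' @export
triangle_affine <- function(src_tri, dst_tri) {
  S <- rbind(t(src_tri), 1)
  D <- rbind(t(dst_tri), 1)
  det_s <- det(S)
  if (abs(det_s) < 1e-12)
    stop("source triangle is degenerate (zero area); affine map is singular")
  T <- D %*% solve(S)
  T[3, ] <- c(0, 0, 1)
  T
}

# Barycentric coordinates of points (n x 2) w.r.t. triangle (3 x 2).
# Returns n x 3 matrix; rows sum to 1.
barycentric_coords <- function(points, tri) {
  M <- rbind(t(tri), 1)              # 3 x 3
  lam <- solve(M, rbind(t(points), 1))
  t(lam)
}

#' Warp points from a source face into the mean-face frame
#'
#' Each point is assigned to the source-face triangle containing it (mesh
#' topology from the mean shape, vertex coordinates from the source
#' landmarks) and mapped by that triangle's affine transform. Points on a
#' shared edge go to the lowest-index containing triangle; points outside the
#' source convex hull are flagged and returned unwarped.
#'
#' @param points n x 2 matrix of (x, y) dva in source-image coordinates.
#' @param src_landmarks [gm_landmarks()] of the source image.
#' @param mesh [triangulate()] output (topology from the mean shape).
#' @param dst_shape the `gm_mean_shape` (destination vertex coordinates).
#' @param tol containment tolerance on barycentric coordinates.
#' @return list: `points` (n x 2, warped where in-mesh), `in_mesh` (logical),
#'   `triangle` (index or NA).
#' @export
warp_points <- function(points, src_landmarks, mesh, dst_shape, tol = 1e-9) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  src <- src_landmarks$points
  dst <- dst_shape$points
  if (!identical(src_landmarks$labels, dst_shape$labels))
    stop("source landmarks and mean shape have different label order")
  out <- points
  tri_idx <- rep(NA_integer_, n)
  unassigned <- rep(TRUE, n)
  for (k in seq_len(nrow(mesh$triangles))) {
    if (!any(unassigned)) break
    v <- mesh$triangles[k, ]
    lam <- barycentric_coords(points[unassigned, , drop = FALSE], src[v, , drop = FALSE])
    inside <- lam[, 1] >= -tol & lam[, 2] >= -tol & lam[, 3] >= -tol
    if (any(inside)) {
      idx <- which(unassigned)[inside]
      # affine image = barycentric re-evaluation at destination vertices
      Tk <- triangle_affine(src[v, , drop = FALSE], dst[v, , drop = FALSE])
      ph <- cbind(points[idx, , drop = FALSE], 1) %*% t(Tk)
      out[idx, ] <- ph[, 1:2, drop = FALSE]
      tri_idx[idx] <- k
      unassigned[idx] <- FALSE
    }
  }
  list(points = out, in_mesh = !is.na(tri_idx), triangle = tri_idx)
}

#' Warp a trial's gaze trace into the mean-face frame
#'
#' Applies [warp_points()] to the trial's retained samples (on-image,
#' post-onset, large-saccade intervals removed — the same selection used for
#' fixation heatmaps). Timestamps are preserved, so dwell time is conserved
#' for in-mesh samples.
#'
#' @param trial a [gm_trial()].
#' @param saccades [detect_saccades()] output for the trial.
#' @param landmarks named list of [gm_landmarks()] keyed by image id, or a
#'   single [gm_landmarks()] for the trial's image.
#' @param mesh mean-shape [triangulate()] output.
#' @param mean_shape the `gm_mean_shape`.
#' @param exclude_amp_dva saccade-amplitude exclusion threshold (default 1).
#' @return data.frame `t_ms`, `x`, `y` (mean-face dva where in-mesh,
#'   original coordinates otherwise), `in_mesh`, `triangle`; attribute
#'   `frac_out_of_mesh`.
#' @export
warp_trial_gaze <- function(trial, saccades, landmarks, mesh, mean_shape,
                            exclude_amp_dva = 1.0) {
  lm <- if (inherits(landmarks, "gm_landmarks")) landmarks
        else landmarks[[trial$image_id]]
  if (is.null(lm)) stop("no landmarks for image ", trial$image_id)
  s <- retained_samples(trial, saccades, exclude_amp_dva)
  if (nrow(s) == 0) {
    out <- data.frame(t_ms = integer(), x = numeric(), y = numeric(),
                      in_mesh = logical(), triangle = integer())
    attr(out, "frac_out_of_mesh") <- NA_real_
    return(out)
  }
  w <- warp_points(cbind(s$x, s$y), lm, mesh, mean_shape)
  out <- data.frame(t_ms = s$t_ms, x = w$points[, 1], y = w$points[, 2],
                    in_mesh = w$in_mesh, triangle = w$triangle)
  attr(out, "frac_out_of_mesh") <- mean(!w$in_mesh)
  out
}
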