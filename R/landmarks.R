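#' Construct a facial landmark set
#'
#' A landmark set holds the 26 corresponding points annotated on one face
#' image, in a canonical label order shared by every image (the
#' correspondence), plus a simple polygon bounding the face region. All
#' coordinates are screen-centered dva.
#'
#' @param image_id stimulus identifier.
#' @param points 26 x 2 numeric matrix of (x, y) dva coordinates.
#' @param labels character vector of 26 semantic names (`left_*`/`right_*`
#'   prefixes are observer-referenced: `left_*` lies at negative x).
#' @param face_polygon k x 2 matrix of ordered polygon vertices (dva).
#' @return An object of class `gm_landmarks`.
#' @export
gm_landmarks <- function(image_id, points, labels, face_polygon) {
  points <- as.matrix(points)
  if (nrow(points) != 26 || ncol(points) != 2)
    stop("landmark set for image ", image_id, ": expected 26 (x, y) points, got ",
         nrow(points))
  if (length(labels) != 26) stop("landmark set for image ", image_id,
                                 ": expected 26 labels")
  face_polygon <- as.matrix(face_polygon)
  if (!polygon_is_simple(face_polygon))
    stop("landmark set for image ", image_id, ": face polygon self-intersects")
  structure(list(image_id = as.character(image_id), points = unname(points),
                 labels = as.character(labels), face_polygon = unname(face_polygon)),
            class = "gm_landmarks")
}

# Proper-crossing test for non-adjacent polygon edges.
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  idx <- seq_len(n)
  nxt <- c(idx[-1], 1L)
  for (i in idx) for (j in idx) {
    if (j <= i) next
    # skip adjacent edges (shared vertex), including the wrap-around pair
    if (j == i + 1L || (i == 1L && j == n)) next
    if (segments_cross(poly[i, ], poly[nxt[i], ], poly[j, ], poly[nxt[j], ]))
      return(FALSE)
  }
  TRUE
}

#' Read landmark sets from a tab-separated file
#'
#' Expected columns: `image_id`, `point_index` (0-25 for landmarks, any order
#' index for polygon vertices), `label`, `x_dva`, `y_dva`, `role`
#' (`landmark` or `face_polygon`).
#'
#' @param path input file.
#' @return named list of [gm_landmarks()] keyed by `image_id`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("image_id", "point_index", "label", "x_dva", "y_dva", "role")
  for (col in req) if (!col %in% names(d)) stop("landmark file missing column: ", col)
  out <- list()
  for (id in unique(d$image_id)) {
    di <- d[d$image_id == id, ]
    lm <- di[di$role == "landmark", ]
    lm <- lm[order(lm$point_index), ]
    if (nrow(lm) != 26)
      stop("image ", id, ": expected 26 landmark points, found ", nrow(lm))
    pg <- di[di$role == "face_polygon", ]
    pg <- pg[order(pg$point_index), ]
    out[[as.character(id)]] <- gm_landmarks(
      image_id = id, points = cbind(lm$x_dva, lm$y_dva), labels = lm$label,
      face_polygon = cbind(pg$x_dva, pg$y_dva))
  }
  out
}

#' Write landmark sets to a tab-separated file
#' @param landmarks named list of [gm_landmarks()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- lapply(landmarks, function(lm) {
    rbind(
      data.frame(image_id = lm$image_id, point_index = 0:25, label = lm$labels,
                 x_dva = lm$points[, 1], y_dva = lm$points[, 2], role = "landmark"),
      data.frame(image_id = lm$image_id,
                 point_index = seq_len(nrow(lm$face_polygon)) - 1L,
                 label = "face_polygon", x_dva = lm$face_polygon[, 1],
                 y_dva = lm$face_polygon[, 2], role = "face_polygon"))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Mirror a landmark set about the image's vertical midline
#'
#' Reflects x coordinates about `axis_x` (the image center in the package's
#' screen-centered convention) and swaps `left_*`/`right_*` semantic labels,
#' re-ordering points so the canonical label order — and hence the
#' cross-image correspondence — is preserved for the mirrored image.
#' Applying the operation twice is the identity.
#'
#' @param lm a [gm_landmarks()].
#' @param axis_x x coordinate of the mirror axis in dva (default 0).
#' @param suffix appended to the image id of the mirrored set (default "_m";
#'   an existing suffix is stripped so double mirroring restores the id).
#' @return the mirrored [gm_landmarks()].
#' @export
mirror_landmarks <- function(lm, axis_x = 0, suffix = "_m") {
  swap <- function(l) {
    out <- l
    out[startsWith(l, "left_")] <- sub("^left_", "right_", l[startsWith(l, "left_")])
    out[startsWith(l, "right_")] <- sub("^right_", "left_", l[startsWith(l, "right_")])
    out
  }
  mirrored <- cbind(2 * axis_x - lm$points[, 1], lm$points[, 2])
  new_labels <- swap(lm$labels)
  idx <- match(lm$labels, new_labels)
  if (anyNA(idx)) stop("labels are not mirror-consistent (unpaired left_/right_ name)")
  new_id <- if (endsWith(lm$image_id, suffix))
    substr(lm$image_id, 1, nchar(lm$image_id) - nchar(suffix))
  else paste0(lm$image_id, suffix)
  gm_landmarks(image_id = new_id, points = mirrored[idx, , drop = FALSE],
               labels = lm$labels,
               face_polygon = cbind(2 * axis_x - rev(lm$face_polygon[, 1]),
                                    rev(lm$face_polygon[, 2])))
}
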