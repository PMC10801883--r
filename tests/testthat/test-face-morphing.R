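test_that("mean shape is the pointwise mean and respects correspondence", {
  a <- random_landmarks("a", 1)
  expect_equal(compute_mean_shape(list(a))$points, a$points)
  sets <- lapply(1:3, function(i) random_landmarks(paste0("s", i), i))
  ms <- compute_mean_shape(sets)
  oracle <- (sets[[1]]$points + sets[[2]]$points + sets[[3]]$points) / 3
  expect_equal(ms$points, oracle, tolerance = 1e-12)
  # a set and its mirror average to a laterally symmetric shape
  sym <- compute_mean_shape(list(a, mirror_landmarks(a)))
  i_l <- match("left_eye_center", sym$labels)
  i_r <- match("right_eye_center", sym$labels)
  expect_equal(sym$points[i_l, 1], -sym$points[i_r, 1], tolerance = 1e-12)
  expect_equal(sym$points[i_l, 2], sym$points[i_r, 2], tolerance = 1e-12)
  bad <- a; bad$labels <- rev(bad$labels)
  expect_error(compute_mean_shape(list(a, bad)), "label order")
})

test_that("triangulation covers the points and satisfies the empty-circumcircle test", {
  tri3 <- triangulate(list(points = rbind(c(0, 0), c(1, 0), c(0, 1))))
  expect_identical(nrow(tri3$triangles), 1L)
  sq <- triangulate(list(points = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  expect_identical(nrow(sq$triangles), 2L)
  expect_error(triangulate(list(points = rbind(c(0, 0), c(1, 1), c(2, 2)))),
               "collinear")
  # brute-force Delaunay check on a 26-point mean shape
  ms <- compute_mean_shape(lapply(1:4, function(i) random_landmarks(paste0("s", i), i)))
  mesh <- triangulate(ms)
  p <- ms$points
  circumcircle <- function(v) {
    ax <- p[v[1], 1]; ay <- p[v[1], 2]; bx <- p[v[2], 1]; by <- p[v[2], 2]
    cx <- p[v[3], 1]; cy <- p[v[3], 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  for (k in seq_len(nrow(mesh$triangles))) {
    v <- mesh$triangles[k, ]
    cc <- circumcircle(v)
    others <- setdiff(seq_len(nrow(p)), v)
    dist <- sqrt((p[others, 1] - cc[1])^2 + (p[others, 2] - cc[2])^2)
    expect_true(all(dist > cc[3] - 1e-8))
  }
})

test_that("triangle affine maps solve the vertex correspondence exactly", {
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(triangle_affine(src, src), diag(3))
  shifted <- src + rep(c(2, 3), each = 3)
  Tt <- triangle_affine(src, shifted)
  expect_equal(Tt, matrix(c(1, 0, 0, 0, 1, 0, 2, 3, 1), 3, 3), tolerance = 1e-12)
  Ts <- triangle_affine(src, 2 * src)
  expect_equal(Ts[1:2, 1:2], 2 * diag(2), tolerance = 1e-12)
  expect_error(triangle_affine(rbind(c(0, 0), c(1, 1), c(2, 2)), src), "degenerate")
  # exactness on a random pair
  set.seed(2)
  s <- matrix(rnorm(6), 3, 2); d <- matrix(rnorm(6), 3, 2)
  Tr <- triangle_affine(s, d)
  expect_equal(t(Tr %*% t(cbind(s, 1)))[, 1:2], d, tolerance = 1e-12)
})

test_that("warping is exact at landmarks and agrees with a barycentric oracle", {
  sets <- lapply(1:4, function(i) random_landmarks(paste0("s", i), i))
  ms <- compute_mean_shape(sets)
  mesh <- triangulate(ms)
  src <- sets[[1]]
  w <- warp_points(src$points, src, mesh, ms)
  expect_true(all(w$in_mesh))
  expect_lt(max(abs(w$points - ms$points)), 1e-9)
  # interior random points vs an independent barycentric oracle, using the
  # mean shape as the source (a proper triangulation, so containment is
  # unambiguous) and an individual face as the destination
  ms_lm <- gm_landmarks("mean", ms$points, ms$labels, face_template()$face_polygon)
  dst <- list(points = sets[[2]]$points, labels = sets[[2]]$labels)
  set.seed(7)
  n <- 1000
  tri_pick <- sample(nrow(mesh$triangles), n, replace = TRUE)
  lam <- matrix(stats::rexp(3 * n), ncol = 3)
  lam <- lam / rowSums(lam)
  pts <- t(vapply(seq_len(n), function(i) {
    v <- mesh$triangles[tri_pick[i], ]
    colSums(lam[i, ] * ms$points[v, ])
  }, numeric(2)))
  expected <- t(vapply(seq_len(n), function(i) {
    v <- mesh$triangles[tri_pick[i], ]
    colSums(lam[i, ] * dst$points[v, ])
  }, numeric(2)))
  w2 <- warp_points(pts, ms_lm, mesh, dst)
  expect_true(all(w2$in_mesh))
  expect_lt(max(abs(w2$points - expected)), 1e-9)
  # triangle centroids map to destination triangle centroids
  cent_src <- t(apply(mesh$triangles, 1, function(v) colMeans(ms$points[v, ])))
  cent_dst <- t(apply(mesh$triangles, 1, function(v) colMeans(dst$points[v, ])))
  wc <- warp_points(cent_src, ms_lm, mesh, dst)
  expect_lt(max(abs(wc$points - cent_dst)), 1e-9)
})

test_that("warping is continuous across shared edges and flags out-of-hull points", {
  sets <- lapply(1:3, function(i) random_landmarks(paste0("s", i), 10 + i))
  ms <- compute_mean_shape(sets)
  mesh <- triangulate(ms)
  # source = the mean shape itself so containment is unambiguous at edges
  src <- gm_landmarks("mean", ms$points, ms$labels, face_template()$face_polygon)
  ms <- list(points = sets[[2]]$points, labels = sets[[2]]$labels)
  # shared edges: pairs of triangles sharing two vertices
  tri <- mesh$triangles
  for (k1 in seq_len(nrow(tri) - 1)) for (k2 in (k1 + 1):nrow(tri)) {
    shared <- intersect(tri[k1, ], tri[k2, ])
    if (length(shared) != 2) next
    mid <- colMeans(src$points[shared, ])
    # approach the edge midpoint from both triangle interiors
    off1 <- colMeans(src$points[tri[k1, ], ]) - mid
    off2 <- colMeans(src$points[tri[k2, ], ]) - mid
    eps <- 1e-7
    w <- warp_points(rbind(mid + eps * off1, mid + eps * off2), src, mesh, ms)
    expect_lt(max(abs(w$points[1, ] - w$points[2, ])), 1e-5)
  }
  far <- rbind(c(100, 100), c(-50, 0))
  wf <- warp_points(far, src, mesh, ms)
  expect_false(any(wf$in_mesh))
  expect_equal(wf$points, far)   # returned unwarped
})

test_that("warping a trial conserves dwell time and per-triangle occupancy", {
  spec <- small_spec(seed = 31, n_base = 1, n_inj = 0, trials = 2)
  e <- generate_experiment(spec)
  id <- names(e$trials)[1]
  tr <- e$trials[[id]]
  sc <- detect_saccades(tr)
  w <- warp_trial_gaze(tr, sc, e$landmarks, e$mesh, e$mean_shape)
  src <- e$landmarks[[tr$image_id]]
  kept <- gazemorph:::retained_samples(tr, sc)
  expect_identical(nrow(w), nrow(kept))
  expect_identical(w$t_ms, kept$t_ms)   # timestamps preserved: dwell conserved
  # per-triangle dwell equal before and after warping
  before <- warp_points(cbind(kept$x, kept$y), src, e$mesh, e$mean_shape)
  expect_identical(table(w$triangle), table(before$triangle))
  # gaze pinned to a landmark maps to the mean-shape landmark
  i <- match("nose_tip", src$labels)
  pin <- tr
  pin$samples$x[pin$samples$t_ms >= 0] <- src$points[i, 1]
  pin$samples$y[pin$samples$t_ms >= 0] <- src$points[i, 2]
  pin$samples$on_image <- TRUE
  wp <- warp_trial_gaze(pin, sc[0, ], e$landmarks, e$mesh, e$mean_shape)
  expect_lt(max(abs(wp$x - e$mean_shape$points[i, 1])), 1e-9)
  # gaze entirely off-face is entirely out of mesh
  off <- tr
  off$samples$x <- 13; off$samples$y <- -10
  woff <- warp_trial_gaze(off, sc[0, ], e$landmarks, e$mesh, e$mean_shape)
  expect_equal(attr(woff, "frac_out_of_mesh"), 1)
  expect_error(warp_trial_gaze(tr, sc, list(), e$mesh, e$mean_shape),
               "no landmarks")
})
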