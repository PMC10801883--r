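mk_warped <- function(x, y, t0 = 0) {
  n <- length(x)
  data.frame(t_ms = seq.int(t0, t0 + n - 1L), x = x, y = y,
             in_mesh = TRUE, triangle = 1L)
}

roi <- roi_rect("right_eye", 1, 5, 1, 5)

test_that("ROI dwell time counts 1-ms samples inside the closed rectangle", {
  expect_equal(roi_dwell_time(mk_warped(rep(3, 2000), rep(3, 2000)), roi), 2)
  expect_equal(roi_dwell_time(mk_warped(rep(10, 500), rep(10, 500)), roi), 0)
  # constructed trajectory spending exactly 1.25 s inside
  x <- c(rep(3, 1250), rep(8, 600))
  expect_equal(roi_dwell_time(mk_warped(x, rep(2, 1850)), roi), 1.25)
  # boundary is closed
  expect_equal(roi_dwell_time(mk_warped(c(1, 5, 0.999), c(1, 5, 3)), roi), 0.002)
  expect_error(roi_rect("bad", 2, 1, 0, 1), "min")
})

test_that("ipsi-contra differences are signed by hemisphere and reject baseline", {
  rec <- data.frame(t_right_eye = c(2, 1.5), t_left_eye = c(1, 1.5),
                    hemisphere = c("right", "right"))
  expect_equal(ipsi_contra_difference(rec), c(1, 0))
  rec$hemisphere <- "left"
  expect_equal(ipsi_contra_difference(rec), c(-1, 0))
  # flipping the hemisphere label negates the difference exactly
  expect_equal(ipsi_contra_difference(rec, "right"),
               -ipsi_contra_difference(rec, "left"))
  rec$hemisphere <- "none"
  expect_error(ipsi_contra_difference(rec), "baseline")
})

test_that("baseline normalization subtracts the windowed observer-referenced bias", {
  base <- data.frame(session_id = c("b1", "b1", "b2"),
                     session_date = c(10, 10, 200),
                     t_right_eye = c(1.5, 1.7, 9), t_left_eye = c(1.0, 1.2, 0))
  inj <- data.frame(session_id = "i1", session_date = 15, hemisphere = "right",
                    t_right_eye = 2.5, t_left_eye = 1.0)
  # windowed baseline bias = mean(0.5, 0.5) = 0.5; injection bias 1.5
  expect_equal(baseline_normalize(inj, base), 1.0)
  inj$hemisphere <- "left"
  expect_equal(baseline_normalize(inj, base), -1.0)
  # equal biases normalize to zero
  inj0 <- data.frame(session_id = "i2", session_date = 12, hemisphere = "right",
                     t_right_eye = 1.5, t_left_eye = 1.0)
  expect_equal(baseline_normalize(inj0, base), 0)
  # empty window errors naming the session
  far <- data.frame(session_id = "i9", session_date = 120, hemisphere = "right",
                    t_right_eye = 2, t_left_eye = 1)
  expect_error(baseline_normalize(far, base), "i9")
})

test_that("two-sample permutation test matches brute-force enumeration", {
  r <- permutation_test(c(0, 0, 0), c(10, 10, 10), seed = 1)
  expect_true(r$exact)
  expect_equal(r$n_resamples, 20)
  expect_equal(r$p_perm, 2 / 20)
  # independent brute force on a random small case
  set.seed(5)
  a <- rnorm(4); b <- rnorm(3) + 1
  r2 <- permutation_test(a, b, seed = 2)
  pool <- c(a, b)
  splits <- combn(7, 4)
  null <- apply(splits, 2, function(ia) mean(pool[ia]) - mean(pool[-ia]))
  expect_equal(r2$p_perm, mean(abs(null) >= abs(mean(a) - mean(b)) - 1e-12))
  # identical constant groups: p = 1
  expect_equal(permutation_test(c(1, 1), c(1, 1), seed = 3)$p_perm, 1)
  # Monte-Carlo path uses the add-one two-sided rule
  set.seed(6)
  big_a <- rnorm(30); big_b <- rnorm(30)
  r3 <- permutation_test(big_a, big_b, n = 500, seed = 4, exact_cap = 10)
  expect_false(r3$exact)
  expect_gte(r3$p_perm, 1 / 501)
  expect_lte(r3$p_perm, 1)
  expect_error(permutation_test(numeric(), big_b), "non-empty")
  expect_error(permutation_test(big_a, big_b, n = 0), "n must be")
})

test_that("sign-flip test enumerates exactly and is symmetric under the null", {
  r <- paired_difference_test(rep(1, 10), seed = 1)
  expect_true(r$exact)
  expect_equal(r$p_perm, 2 / 1024)
  sym <- paired_difference_test(c(-2, -1, 1, 2), seed = 2)
  expect_equal(sym$observed, 0)
  expect_equal(sym$p_perm, 1)
  expect_error(paired_difference_test(1), "at least 2")
})

test_that("permutation p-values are calibrated under an exchangeable null", {
  set.seed(11)
  rej <- replicate(400, {
    a <- rnorm(12); b <- rnorm(12)
    permutation_test(a, b, n = 300, exact_cap = 100, n_boot = 0)$p_perm <= 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("BH adjustment matches the hand computation and is idempotent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  # idempotent on tied families (re-adjusting changes nothing)
  tied <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_adjust(tied), tied)
  # adjusted values are monotone in the sorted-p order
  once <- bh_adjust(c(0.001, 0.2, 0.04, 0.9))
  expect_true(!is.unsorted(once[order(c(0.001, 0.2, 0.04, 0.9))]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  res <- bh_adjust_results(list(
    new_stat_result(1, 0.01, 100), new_stat_result(1, 0.02, 100)))
  expect_equal(res[[1]]$p_adj, 0.02)
})

test_that("pattern change index matches hand oracles on 2x2 grids", {
  h <- function(v) tiny_heatmap(matrix(v, 2, 2))
  hi <- h(c(1, 0, 0, 0))
  hbar_same <- h(c(1, 0, 0, 0))
  grand <- h(c(0.5, 0.5, 0, 0))
  expect_equal(pattern_change_index(hi, hbar_same, grand), 1)
  hbar_other <- h(c(0, 1, 0, 0))
  expect_equal(pattern_change_index(hi, hbar_other, grand),
               (sqrt(0.5) - sqrt(2)) / sqrt(0.5))
  expect_equal(pattern_change_index(hi, hbar_other, grand), -1, tolerance = 1e-12)
  # equal distances give index 0
  expect_equal(pattern_change_index(hi, grand, grand), 0)
  # undefined when the trial equals the grand mean
  expect_true(is.na(pattern_change_index(hi, hbar_other, hi)))
  # random small grids against the formula oracle
  set.seed(12)
  for (i in 1:25) {
    a <- h(runif(4)); b <- h(runif(4)); g <- h(runif(4))
    dG <- sqrt(sum((a$grid - g$grid)^2)); dh <- sqrt(sum((a$grid - b$grid)^2))
    expect_equal(pattern_change_index(a, b, g), (dG - dh) / dG, tolerance = 1e-12)
    expect_lte(pattern_change_index(a, b, g), 1)
  }
})

test_that("injection shifts raise the pattern change index above the baseline band", {
  set.seed(13)
  h <- function(center) {
    g <- matrix(0, 8, 8)
    g[center[1], center[2]] <- 10
    tiny_heatmap(g + matrix(runif(64), 8, 8))
  }
  base_hms <- replicate(12, h(c(4, 4)), simplify = FALSE)
  inj_hms <- replicate(12, h(c(4, 7)), simplify = FALSE)   # shifted pattern
  imgs <- rep("imgA", 12)
  pc <- pattern_change_indices(inj_hms, base_hms, imgs, imgs)
  pv <- baseline_pattern_variation(base_hms, imgs, seed = 1)
  expect_gt(mean(pc$index), mean(pv$index))
  # identical baseline trials: variation indices are NA (zero grand distance)
  same <- replicate(4, tiny_heatmap(matrix(1, 2, 2)), simplify = FALSE)
  v <- baseline_pattern_variation(same, rep("x", 4), seed = 1)
  expect_true(all(is.na(v$index)))
  expect_warning(baseline_pattern_variation(base_hms[1], "solo", seed = 1),
                 "single")
})

test_that("face detection reports entry, latency and dwell fraction", {
  poly <- rbind(c(-5, -5), c(5, -5), c(5, 5), c(-5, 5))
  inside <- make_pattern_trial(list(c(1000, 1)))   # gaze at origin
  no_sc <- data.frame(trial_id = character(), onset_ms = numeric(),
                      offset_ms = numeric(), A_dva = numeric(),
                      PV_dva_s = numeric(), x1 = numeric(), y1 = numeric(),
                      gap = logical())
  m <- face_detection_metrics(inside, no_sc, poly)
  expect_true(m$found)
  expect_equal(m$latency_ms, 0)
  expect_equal(m$frac_time_on_face, 1)
  # gaze starts outside; first in-polygon saccade ends at 500 ms
  tr <- make_pattern_trial(list(c(2000, 1)))
  tr$samples$x <- c(rep(10, 500), rep(0, 1500))
  sc <- data.frame(trial_id = "t1", onset_ms = 460, offset_ms = 500,
                   A_dva = 10, PV_dva_s = 300, x1 = 0, y1 = 0, gap = FALSE)
  m2 <- face_detection_metrics(tr, sc, poly)
  expect_true(m2$found)
  expect_equal(m2$latency_ms, 500)
  expect_equal(m2$frac_time_on_face, 1500 / 2000)
  # never on the face
  off <- make_pattern_trial(list(c(500, 1)))
  off$samples$x <- 12
  m3 <- face_detection_metrics(off, no_sc, poly)
  expect_false(m3$found)
  expect_true(is.na(m3$latency_ms))
  expect_equal(m3$frac_time_on_face, 0)
})
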