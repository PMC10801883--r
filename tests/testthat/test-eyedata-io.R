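test_that("trial tables round-trip through write/read exactly", {
  spec <- small_spec(seed = 4, n_base = 1, n_inj = 1, trials = 2)
  e <- generate_experiment(spec)
  tp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_trials(e$trials, tp, mp)
  back <- read_trials(tp, mp)
  expect_length(back, length(e$trials))
  expect_identical(names(back), names(e$trials))
  # identity at the declared 4-decimal gaze precision
  again_t <- withr::local_tempfile(fileext = ".tsv")
  again_m <- withr::local_tempfile(fileext = ".tsv")
  write_trials(back, again_t, again_m)
  expect_identical(readLines(tp), readLines(again_t))
  expect_identical(readLines(mp), readLines(again_m))
  tr0 <- e$trials[[1]]; tr1 <- back[[1]]
  expect_identical(tr1$samples$t_ms, as.integer(tr0$samples$t_ms))
  expect_equal(tr1$samples$x, round(tr0$samples$x, 4))
  expect_identical(tr1$samples$on_image, tr0$samples$on_image)
})

test_that("condition metadata survives a round trip for all 8 injection combinations", {
  grid <- expand.grid(site = c("face_patch", "control"),
                      hemisphere = c("left", "right"),
                      volume_ul = c(5, 10), stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(grid)), function(i) {
    gm_trial(trial_id = paste0("t", i), monkey_id = "M1", session_id = "s1",
             session_date = 10, phase = "injection", site = grid$site[i],
             hemisphere = grid$hemisphere[i], volume_ul = grid$volume_ul[i],
             image_id = "img01",
             samples = data.frame(t_ms = 0:9, x = 0, y = 0, on_image = TRUE))
  })
  tp <- withr::local_tempfile(); mp <- withr::local_tempfile()
  write_trials(trials, tp, mp)
  back <- read_trials(tp, mp)
  got <- trials_metadata(back)[, c("site", "hemisphere", "volume_ul")]
  rownames(got) <- NULL
  expect_equal(got, grid, ignore_attr = TRUE)
})

test_that("malformed trials are flagged, not silently dropped", {
  tr <- make_pattern_trial(list(c(100, 1)))
  tp <- withr::local_tempfile(); mp <- withr::local_tempfile()
  write_trials(list(tr, make_pattern_trial(list(c(50, 1)), trial_id = "t2")), tp, mp)
  # duplicate a timestamp inside trial t2
  lines <- readLines(tp)
  dup <- grep("^t2\t10\t", lines)[1]
  writeLines(c(lines, lines[dup]), tp)
  expect_warning(back <- read_trials(tp, mp), "flagged")
  expect_length(back, 1)
  expect_identical(back[[1]]$trial_id, "t1")
  probs <- attr(back, "problems")
  expect_identical(probs$trial_id, "t2")
})

test_that("empty trace file yields empty result with a warning", {
  tp <- withr::local_tempfile(); mp <- withr::local_tempfile()
  write_trials(list(make_pattern_trial(list(c(10, 1)))), tp, mp)
  writeLines(readLines(tp)[1], tp)   # header only
  expect_warning(out <- read_trials(tp, mp), "empty")
  expect_length(out, 0)
})

test_that("zero-sample trials are rejected before write", {
  tr <- make_pattern_trial(list(c(10, 1)))
  tr$samples <- tr$samples[0, ]
  expect_error(write_trials(list(tr), tempfile(), tempfile()), "no samples")
})

test_that("missing required columns produce a schema error naming the column", {
  tp <- withr::local_tempfile(); mp <- withr::local_tempfile()
  write_trials(list(make_pattern_trial(list(c(10, 1)))), tp, mp)
  d <- read.delim(tp); d$on_image <- NULL
  write.table(d, tp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_trials(tp, mp), "on_image")
})

test_that("blink-length interruptions are bridged, long ones are not", {
  tr <- make_pattern_trial(list(c(2000, 1), c(300, 0), c(2000, 1)))
  tr <- bridge_gaps(tr)
  gaps <- attr(tr, "gaps")
  expect_identical(nrow(gaps), 1L)
  expect_true(gaps$bridged)
  tr2 <- make_pattern_trial(list(c(2000, 1), c(600, 0), c(2000, 1)))
  expect_false(attr(bridge_gaps(tr2), "gaps")$bridged)
  # two adjacent 300-ms runs separated by one on-image sample: each bridged
  tr3 <- make_pattern_trial(list(c(1000, 1), c(300, 0), c(1, 1), c(300, NA), c(1000, 1)))
  g3 <- attr(bridge_gaps(tr3), "gaps")
  expect_identical(nrow(g3), 2L)
  expect_true(all(g3$bridged))
  expect_equal(g3$dur_ms, c(300, 300))
})

test_that("the >7 s viewing rule counts bridged gaps and is strict", {
  kept10 <- make_pattern_trial(list(c(10000, 1)))
  expect_equal(viewing_time_s(kept10), 10)
  short <- make_pattern_trial(list(c(6500, 1), c(3500, 0)))
  expect_equal(viewing_time_s(short), 6.5)
  # 7.2 s on image in three stretches, interrupted only by 400-ms gaps:
  # bridged time counts, total 7.2 + 0.8 = 8.0 s
  gappy <- make_pattern_trial(list(c(2000, 1), c(400, 0), c(2600, 1),
                                   c(400, NA), c(2600, 1)))
  expect_equal(viewing_time_s(gappy), 8.0)
  out <- filter_trials(list(kept10, short, gappy))
  expect_length(out, 2)
  log <- attr(out, "exclusion_log")
  expect_identical(nrow(log), 3L)
  expect_equal(sum(log$kept), 2)
  # strictly greater than the threshold
  exactly7 <- make_pattern_trial(list(c(7000, 1), c(3000, 0)))
  expect_length(filter_trials(list(exactly7)), 0)
})

test_that("filter_trials is idempotent and logs every input", {
  spec <- small_spec(seed = 9, trials = 3)
  e <- generate_experiment(spec)
  once <- filter_trials(e$trials)
  twice <- filter_trials(once)
  expect_identical(names(twice), names(once))
  expect_identical(nrow(attr(once, "exclusion_log")), length(e$trials))
})

test_that("landmark files round-trip and enforce the 26-point contract", {
  lms <- list(a = random_landmarks("a", 1), b = random_landmarks("b", 2))
  path <- withr::local_tempfile()
  write_landmarks(lms, path)
  back <- read_landmarks(path)
  expect_equal(back$a$points, lms$a$points, tolerance = 1e-12)
  expect_identical(back$b$labels, lms$b$labels)
  # drop one landmark row of image b -> schema error naming the image
  d <- read.delim(path)
  d <- d[!(d$image_id == "b" & d$role == "landmark" & d$point_index == 25), ]
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_landmarks(path), "b.*25 landmark|expected 26")
})

test_that("mirroring landmarks is an involution that preserves correspondence", {
  lm <- random_landmarks("a", 3)
  m <- mirror_landmarks(lm)
  mm <- mirror_landmarks(m)
  expect_equal(mm$points, lm$points, tolerance = 1e-12)
  expect_identical(mm$labels, lm$labels)
  expect_identical(mm$image_id, lm$image_id)
  # a centered (midline) point is fixed up to x sign flip at x = 0
  i <- match("nose_tip", lm$labels)
  expect_equal(m$points[i, 2], lm$points[i, 2])
  expect_equal(m$points[i, 1], -lm$points[i, 1])
  # the left-eye slot of the mirrored set holds the reflected right eye
  il <- match("left_eye_center", lm$labels)
  ir <- match("right_eye_center", lm$labels)
  expect_equal(m$points[il, ], lm$points[ir, ] * c(-1, 1))
  # mirrored-image landmarks equal the mirror of the originals
  expect_equal(mirror_landmarks(m)$points, lm$points)
})
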