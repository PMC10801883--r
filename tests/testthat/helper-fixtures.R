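# Shared fixtures, all built in code.

# Trial whose on/off-image structure follows a run-length pattern:
# segs = list(c(duration_ms, on)) with on in {1 = on-image, 0 = off-image,
# NA = missing}. Starts at t = 0 unless pre-fixation samples are requested.
make_pattern_trial <- function(segs, trial_id = "t1", pre_ms = 0, ...) {
  t <- integer(); x <- numeric(); on <- logical()
  cur <- 0L
  for (s in segs) {
    n <- s[[1]]
    tt <- seq.int(cur, cur + n - 1L)
    cur <- cur + n
    t <- c(t, tt)
    if (is.na(s[[2]])) { x <- c(x, rep(NA_real_, n)); on <- c(on, rep(FALSE, n)) }
    else if (s[[2]] == 1) { x <- c(x, rep(0, n)); on <- c(on, rep(TRUE, n)) }
    else { x <- c(x, rep(20, n)); on <- c(on, rep(FALSE, n)) }
  }
  if (pre_ms > 0) {
    t <- c(seq.int(-pre_ms, -1L), t)
    x <- c(rep(0, pre_ms), x)
    on <- c(rep(TRUE, pre_ms), on)
  }
  gm_trial(trial_id = trial_id, monkey_id = "M1", session_id = "s1",
           session_date = 1, phase = "baseline", image_id = "img01",
           samples = data.frame(t_ms = t, x = x, y = 0, on_image = on), ...)
}

# Stationary fixation with one embedded raised-cosine saccade of amplitude A
# (dva) and duration dur_ms, starting at t = sacc_at_ms. Includes a 1-s
# pre-stimulus fixation window. noise_sd adds white position noise.
make_saccade_trial <- function(A = 8, dur_ms = 60, sacc_at_ms = 2000,
                               len_ms = 5000, noise_sd = 0, seed = 42,
                               trial_id = "t1") {
  set.seed(seed)
  t <- seq.int(-1000L, len_ms - 1L)
  x <- numeric(length(t))
  idx <- which(t >= sacc_at_ms & t < sacc_at_ms + dur_ms)
  tau <- seq_along(idx) / dur_ms
  x[idx] <- A * (tau - sin(2 * pi * tau) / (2 * pi))
  x[t >= sacc_at_ms + dur_ms] <- A
  x <- x + rnorm(length(t), sd = noise_sd)
  y <- rnorm(length(t), sd = noise_sd)
  gm_trial(trial_id = trial_id, monkey_id = "M1", session_id = "s1",
           session_date = 1, phase = "baseline", image_id = "img01",
           samples = data.frame(t_ms = t, x = x, y = y,
                                on_image = rep(TRUE, length(t))))
}

# Tiny heatmap directly from a grid matrix (extent implied by resolution 1).
tiny_heatmap <- function(grid, signed = FALSE) {
  grid <- as.matrix(grid)
  gm_heatmap(grid, px_per_deg = 1, origin = c(0, 0),
             extent = c(ncol(grid), nrow(grid)), signed = signed)
}

# A small generator spec for fast experiments.
small_spec <- function(seed = 1, n_base = 2, n_inj = 2, trials = 5,
                       effect = 1.4, hemisphere = "right", ...) {
  generator_spec(seed = seed, n_images = 2, conditions = data.frame(
    phase = c("baseline", "injection"), site = c("none", "face_patch"),
    hemisphere = c("none", hemisphere), volume_ul = c(0, 10),
    n_sessions = c(n_base, n_inj), trials_per_session = trials,
    ipsi_effect_s = c(0, effect)), ...)
}

random_landmarks <- function(id = "r1", seed = 1) {
  set.seed(seed)
  tmpl <- face_template()
  gm_landmarks(id, tmpl$points + matrix(rnorm(52, sd = 0.3), ncol = 2),
               tmpl$labels, tmpl$face_polygon)
}
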