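#' Canonical 26-point face landmark template
#'
#' A schematic frontal primate face centered at the origin, about 12 x 14
#' dva: 8 midline points and 9 observer-referenced left/right pairs (left at
#' negative x). The per-image generator jitters this template.
#'
#' @return list with `points` (26 x 2), `labels`, `face_polygon`.
#' @export
face_template <- function() {
  mid <- rbind(
    forehead_top = c(0, 7.5), brow_mid = c(0, 4.5), nasion = c(0, 3.2),
    nose_tip = c(0, 0), philtrum = c(0, -1.4), mouth_center = c(0, -2.6),
    chin_top = c(0, -4.4), chin_bottom = c(0, -6.2))
  pair <- rbind(
    temple = c(5.8, 4.0), brow_outer = c(4.2, 4.8), eye_outer = c(4.6, 3.0),
    eye_center = c(3.2, 3.0), eye_inner = c(1.8, 3.0), cheek = c(4.8, -0.5),
    nostril = c(1.4, -0.6), mouth_corner = c(2.2, -2.6), jaw = c(4.2, -3.8))
  pts <- rbind(mid,
               `colnames<-`(cbind(-pair[, 1], pair[, 2]), NULL),
               pair)
  labels <- c(rownames(mid),
              paste0("left_", rownames(pair)), paste0("right_", rownames(pair)))
  poly <- rbind(c(0, 7.5), c(-5.8, 4.0), c(-4.8, -0.5), c(-4.2, -3.8),
                c(0, -6.2), c(4.2, -3.8), c(4.8, -0.5), c(5.8, 4.0))
  list(points = unname(pts), labels = labels, face_polygon = poly)
}

#' Default injection-session grid (one animal)
#'
#' Mirrors the published per-condition injection-session counts for one
#' animal (face patch / control x 10 / 5 uL x left / right hemisphere:
#' 4, 4, 5, 6, 3, 3, 2, 1 sessions) plus interleaved baseline sessions.
#' Effect sizes default to the seconds-scale magnitudes the conditions are
#' meant to emulate: a strong ipsilateral-eye shift for 10-uL face-patch
#' injections, a weak one for 10-uL control, none for 5 uL.
#'
#' @param n_baseline_sessions number of baseline sessions (default 16).
#' @param trials_per_session trials per session (default 20).
#' @param fp10_effect_s,ctl10_effect_s ipsi effects in seconds.
#' @return data.frame with one row per condition.
#' @export
default_condition_grid <- function(n_baseline_sessions = 16,
                                   trials_per_session = 20,
                                   fp10_effect_s = 1.4, ctl10_effect_s = 0.1) {
  rbind(
    data.frame(phase = "baseline", site = "none", hemisphere = "none",
               volume_ul = 0, n_sessions = n_baseline_sessions,
               trials_per_session = trials_per_session, ipsi_effect_s = 0),
    data.frame(phase = "injection",
               site = rep(c("face_patch", "control", "face_patch", "control"), each = 2),
               hemisphere = rep(c("left", "right"), 4),
               volume_ul = rep(c(10, 10, 5, 5), each = 2),
               n_sessions = c(4, 4, 5, 6, 3, 3, 2, 1),
               trials_per_session = trials_per_session,
               ipsi_effect_s = c(fp10_effect_s, fp10_effect_s,
                                 ctl10_effect_s, ctl10_effect_s, 0, 0, 0, 0)))
}

#' Specification of a synthetic free-viewing experiment
#'
#' Defines the study conditions the generator emulates: 1 kHz sampling, 10-s
#' presentations preceded by 1 s of central fixation on a 28 x 21 dva screen,
#' fixation targets concentrated on the eyes/nose/mouth (the Yarbus-T
#' pattern), a configurable observer-right-eye baseline bias, per-condition
#' ipsilateral-eye effects, main-sequence-compliant saccades, and natural
#' blink gaps shorter than 500 ms.
#'
#' @param seed experiment-level RNG seed.
#' @param n_images number of unique face images (each also gets a mirrored
#'   twin).
#' @param image_extent `c(width, height)` dva.
#' @param shape_jitter_sd per-landmark jitter SD (dva) around the template.
#' @param roi_weights saliency weights `c(eyes, nose, mouth, off_face)`;
#'   `eyes` is the two eyes' combined weight before bias tilting.
#' @param right_eye_baseline_bias_s expected observer-right-minus-left eye
#'   dwell difference in baseline trials (seconds).
#' @param conditions condition grid, see [default_condition_grid()].
#' @param fixation_meanlog,fixation_sdlog log-normal fixation-duration
#'   parameters (seconds scale).
#' @param main_sequence_beta main-sequence slope (dva/s per dva).
#' @param velocity_noise_sd multiplicative (log-normal) SD of saccadic peak
#'   velocity around `beta * A`.
#' @param gaze_noise_sd additive per-sample gaze noise SD (dva).
#' @param blink_rate_hz expected blinks per second of viewing.
#' @param blink_dur_range_ms blink duration range (uniform), under 500 ms.
#' @param sampling_rate_hz nominal sampling rate (1000).
#' @param trial_length_s image presentation length (10).
#' @param fix_pre_s pre-stimulus fixation length (1).
#' @param scatter_frac fixation-target scatter SD as a fraction of the eye
#'   ROI side length.
#' @param roi_scale eye ROI side length as a multiple of eye width (1.6).
#' @param monkey_id animal identifier.
#' @return validated list of class `gm_generator_spec`.
#' @export
generator_spec <- function(seed = 1, n_images = 4, image_extent = c(28, 21),
                           shape_jitter_sd = 0.25,
                           roi_weights = c(eyes = 0.45, nose = 0.25,
                                           mouth = 0.2, off_face = 0.1),
                           right_eye_baseline_bias_s = 1.1,
                           conditions = default_condition_grid(),
                           fixation_meanlog = log(0.3), fixation_sdlog = 0.4,
                           main_sequence_beta = 30, velocity_noise_sd = 0.1,
                           gaze_noise_sd = 0.02, blink_rate_hz = 0.15,
                           blink_dur_range_ms = c(100, 400),
                           sampling_rate_hz = 1000, trial_length_s = 10,
                           fix_pre_s = 1, scatter_frac = 0.25, roi_scale = 1.6,
                           monkey_id = "M1") {
  if (any(roi_weights < 0) || sum(roi_weights) <= 0)
    stop("roi_weights must be non-negative with positive sum")
  if (!all(c("eyes", "nose", "mouth", "off_face") %in% names(roi_weights)))
    stop("roi_weights must name eyes, nose, mouth, off_face")
  if (any(conditions$trials_per_session < 1)) stop("trials_per_session must be >= 1")
  if (!all(is.finite(conditions$ipsi_effect_s))) stop("effects must be finite")
  structure(as.list(environment()), class = "gm_generator_spec")
}

# Analytic expectations used to calibrate the eye-weight tilt so the
# generator's seconds-scale effect parameter equals the expected measured
# ipsi-contra dwell difference.
spec_calibration <- function(spec) {
  tmpl <- face_template()
  eye_w <- sqrt(sum((tmpl$points[match("right_eye_outer", tmpl$labels), ] -
                     tmpl$points[match("right_eye_inner", tmpl$labels), ])^2))
  roi_side <- spec$roi_scale * eye_w
  sigma_eff <- sqrt((spec$scatter_frac * roi_side)^2 + spec$gaze_noise_sd^2)
  z <- (roi_side / 2) / sigma_eff
  q <- (stats::pnorm(z) - stats::pnorm(-z))^2   # P(fixation lands in its ROI rect)
  mu_d <- exp(spec$fixation_meanlog + spec$fixation_sdlog^2 / 2)
  mu_s <- 2 / spec$main_sequence_beta           # raised-cosine: D = 2A / PV
  w <- spec$roi_weights / sum(spec$roi_weights)
  p <- c(w[["eyes"]] / 2, w[["eyes"]] / 2, w[["nose"]], w[["mouth"]], w[["off_face"]])
  p_sacc <- 1 - sum(p^2)                        # repeated-ROI draws merge, no saccade
  blink_frac <- spec$blink_rate_hz * mean(spec$blink_dur_range_ms) / 1000
  t_fix <- spec$trial_length_s * (1 - blink_frac) * mu_d / (mu_d + p_sacc * mu_s)
  list(q = q, t_fix = t_fix, roi_side = roi_side)
}

# Per-ROI draw probabilities for a condition; the eye split is tilted so the
# expected measured right-minus-left dwell equals target_rl_s.
condition_roi_probs <- function(spec, target_rl_s) {
  cal <- spec_calibration(spec)
  w <- spec$roi_weights / sum(spec$roi_weights)
  delta <- target_rl_s / (cal$q * cal$t_fix)
  p <- c(right_eye = w[["eyes"]] / 2 + delta / 2,
         left_eye = w[["eyes"]] / 2 - delta / 2,
         nose = w[["nose"]], mouth = w[["mouth"]], off_face = w[["off_face"]])
  if (any(p < 0))
    stop("requested bias/effect too large for the configured eye weight")
  p
}

#' Generate one face layout (landmarks, ROIs, polygon) plus its mirror
#'
#' The layout is the template plus independent per-landmark Gaussian jitter;
#' jitter producing a self-intersecting face polygon is resampled up to a
#' retry cap. The mirrored twin is produced with [mirror_landmarks()].
#'
#' @param spec a [generator_spec()].
#' @param image_index 1-based image number (enters the derived seed).
#' @return list: `landmarks`, `mirror` ([gm_landmarks()]), `rois` (left/right
#'   eye [roi_rect()]s in this image's coordinates), `targets` (named list of
#'   fixation-target centers).
#' @export
generate_face_layout <- function(spec, image_index) {
  tmpl <- face_template()
  with_seed(derive_seed(spec$seed, image_index), {
    for (try in 1:10) {
      jit <- matrix(stats::rnorm(52, sd = spec$shape_jitter_sd), ncol = 2)
      pts <- tmpl$points + jit
      poly_idx <- apply(tmpl$face_polygon, 1, function(v)
        which.min(colSums((t(tmpl$points) - v)^2)))
      poly <- pts[poly_idx, , drop = FALSE]
      if (polygon_is_simple(poly)) break
      if (try == 10) stop("could not generate a simple face polygon for image ",
                          image_index)
    }
    lm <- gm_landmarks(image_id = sprintf("img%02d", image_index), points = pts,
                       labels = tmpl$labels, face_polygon = poly)
    cal <- spec_calibration(spec)
    g <- function(lab) pts[match(lab, tmpl$labels), ]
    mk_roi <- function(side) {
      ctr <- g(paste0(side, "_eye_center"))
      roi_rect(paste0(side, "_eye"), ctr[1] - cal$roi_side / 2,
               ctr[1] + cal$roi_side / 2, ctr[2] - cal$roi_side / 2,
               ctr[2] + cal$roi_side / 2)
    }
    list(landmarks = lm, mirror = mirror_landmarks(lm),
         rois = list(left = mk_roi("left"), right = mk_roi("right")),
         targets = list(right_eye = g("right_eye_center"),
                        left_eye = g("left_eye_center"),
                        nose = g("nose_tip"), mouth = g("mouth_center")))
  })
}

# Layout pieces for a mirrored image: mirror the ROIs and targets too.
mirror_layout <- function(layout) {
  flip_roi <- function(r, other_name)
    roi_rect(other_name, -r$x_max, -r$x_min, r$y_min, r$y_max)
  list(landmarks = layout$mirror, mirror = layout$landmarks,
       rois = list(left = flip_roi(layout$rois$right, "left_eye"),
                   right = flip_roi(layout$rois$left, "right_eye")),
       targets = list(right_eye = layout$targets$left_eye * c(-1, 1),
                      left_eye = layout$targets$right_eye * c(-1, 1),
                      nose = layout$targets$nose * c(-1, 1),
                      mouth = layout$targets$mouth * c(-1, 1)))
}

# Draw an off-face fixation target uniformly inside the image, outside the
# face polygon.
draw_off_face <- function(extent, poly) {
  for (i in 1:50) {
    p <- c(stats::runif(1, -extent[1] / 2, extent[1] / 2),
           stats::runif(1, -extent[2] / 2, extent[2] / 2))
    if (sp::point.in.polygon(p[1], p[2], poly[, 1], poly[, 2]) == 0) return(p)
  }
  c(-extent[1] / 2 + 1, extent[2] / 2 - 1)
}

#' Generate one synthetic trial with ground truth
#'
#' Simulates an alternating fixation/saccade scanpath: fixation targets are
#' drawn from the ROI saliency weights (eye weights tilted by the baseline
#' bias and, in injection conditions, toward the ipsilateral eye), fixation
#' durations are log-normal, and each saccade follows a raised-cosine speed
#' profile whose peak velocity is `beta * A` with multiplicative noise.
#' Consecutive draws of the same ROI extend the current fixation instead of
#' emitting a zero-length saccade. Blink gaps (missing samples) are inserted
#' inside fixations; white gaze noise is added to every rendered sample.
#'
#' @param spec a [generator_spec()].
#' @param layout a [generate_face_layout()] result (or its [mirror_layout()]).
#' @param condition one row of the condition grid (list or data.frame row
#'   with `phase`, `site`, `hemisphere`, `volume_ul`, `ipsi_effect_s`).
#' @param seed trial RNG seed.
#' @param ids list of identifiers: `trial_id`, `session_id`, `session_date`.
#' @param events_only when TRUE, skip the 1-kHz rendering and return only
#'   the ground truth (fast path for calibration studies).
#' @return list: `trial` ([gm_trial()], NULL when `events_only`), `truth`
#'   (list: `saccades` data.frame, `roi_dwell_ms` named vector,
#'   `target_rl_s` the calibrated expected right-minus-left dwell).
#' @export
generate_scanpath <- function(spec, layout, condition, seed,
                              ids = list(trial_id = "t1", session_id = "s1",
                                         session_date = 1L),
                              events_only = FALSE) {
  hem_sign <- switch(condition$hemisphere, right = 1, left = -1, 0)
  target_rl <- spec$right_eye_baseline_bias_s + hem_sign * condition$ipsi_effect_s
  probs <- condition_roi_probs(spec, target_rl)
  len_ms <- round(spec$trial_length_s * 1000)
  with_seed(seed, {
    # --- event sequence -------------------------------------------------
    fix <- list()   # per fixation: roi, pos, dur_ms
    sacc <- list()  # per saccade: from, to, dur_ms, A, PV
    t <- 0
    cur_pos <- c(0, 0); cur_roi <- "center"
    cal <- spec_calibration(spec)
    sigma_sc <- spec$scatter_frac * cal$roi_side
    min_amp <- 2  # keep every emitted saccade well above the velocity floor
    while (t < len_ms) {
      roi <- sample(names(probs), 1, prob = probs)
      dur <- max(50, round(stats::rlnorm(1, spec$fixation_meanlog,
                                         spec$fixation_sdlog) * 1000))
      if (roi == cur_roi && length(fix)) {
        fix[[length(fix)]]$dur_ms <- fix[[length(fix)]]$dur_ms + dur
        t <- t + dur
        next
      }
      ctr <- if (roi == "off_face")
        draw_off_face(spec$image_extent, layout$landmarks$face_polygon)
      else layout$targets[[roi]]
      pos <- ctr + stats::rnorm(2, sd = sigma_sc)
      for (try in 1:20) {
        if (sqrt(sum((pos - cur_pos)^2)) >= min_amp) break
        pos <- ctr + stats::rnorm(2, sd = sigma_sc)
      }
      A <- sqrt(sum((pos - cur_pos)^2))
      if (A < min_amp) {   # scatter cannot clear the floor; push outward
        dirv <- if (A > 0) (pos - cur_pos) / A else c(1, 0)
        pos <- cur_pos + dirv * min_amp
        A <- min_amp
      }
      pv <- spec$main_sequence_beta * A *
        exp(stats::rnorm(1, 0, spec$velocity_noise_sd) -
              spec$velocity_noise_sd^2 / 2)
      sdur <- max(12, round(2000 * A / pv))
      if (t + sdur + 50 > len_ms) {
        # no room for the saccade plus a minimal fixation: hold gaze instead
        if (length(fix)) fix[[length(fix)]]$dur_ms <-
            fix[[length(fix)]]$dur_ms + (len_ms - t)
        t <- len_ms
        break
      }
      sacc[[length(sacc) + 1]] <- list(from = cur_pos, to = pos, t_ms = t,
                                       dur_ms = sdur, A = A, PV = pv)
      t <- t + sdur
      fix[[length(fix) + 1]] <- list(roi = roi, pos = pos, dur_ms = dur, t_ms = t)
      t <- t + dur
      cur_pos <- pos; cur_roi <- roi
    }
    # --- per-ms attribution --------------------------------------------
    lab <- rep("none", len_ms)          # one slot per ms, index = t + 1
    px <- numeric(len_ms); py <- numeric(len_ms)
    for (f in fix) {
      i0 <- f$t_ms + 1L; i1 <- min(len_ms, f$t_ms + f$dur_ms)
      if (i0 > len_ms) next
      lab[i0:i1] <- f$roi
      px[i0:i1] <- f$pos[1]; py[i0:i1] <- f$pos[2]
    }
    truth_sacc <- list()
    for (s in sacc) {
      i0 <- s$t_ms + 1L; i1 <- min(len_ms, s$t_ms + s$dur_ms)
      if (i0 > len_ms) next
      tau <- seq_len(i1 - i0 + 1L) / s$dur_ms
      prog <- tau - sin(2 * pi * tau) / (2 * pi)
      lab[i0:i1] <- "saccade"
      px[i0:i1] <- s$from[1] + (s$to[1] - s$from[1]) * prog
      py[i0:i1] <- s$from[2] + (s$to[2] - s$from[2]) * prog
      truth_sacc[[length(truth_sacc) + 1]] <- data.frame(
        onset_ms = s$t_ms, offset_ms = min(len_ms - 1L, s$t_ms + s$dur_ms - 1L),
        A_dva = s$A, PV_dva_s = s$PV)
    }
    # --- blinks ----------------------------------------------------------
    blink <- rep(FALSE, len_ms)
    n_blink <- stats::rpois(1, spec$blink_rate_hz * spec$trial_length_s)
    if (n_blink > 0) for (b in seq_len(n_blink)) {
      for (try in 1:20) {
        bd <- round(stats::runif(1, spec$blink_dur_range_ms[1],
                                 spec$blink_dur_range_ms[2]))
        b0 <- sample.int(len_ms - bd, 1)
        idx <- b0:(b0 + bd - 1L)
        # keep blinks inside fixations so saccade kinematics stay clean
        if (all(lab[idx] != "saccade") && lab[max(1L, b0 - 1L)] != "saccade" &&
            lab[min(len_ms, b0 + bd)] != "saccade") { blink[idx] <- TRUE; break }
      }
    }
    dwell <- vapply(names(probs), function(r) sum(lab == r & !blink), numeric(1))
    truth <- list(
      saccades = if (length(truth_sacc)) do.call(rbind, truth_sacc) else
        data.frame(onset_ms = numeric(), offset_ms = numeric(),
                   A_dva = numeric(), PV_dva_s = numeric()),
      roi_dwell_ms = dwell, target_rl_s = target_rl,
      condition = condition)
    if (events_only) return(list(trial = NULL, truth = truth))
    # --- rendering at 1 kHz ---------------------------------------------
    pre <- round(spec$fix_pre_s * 1000)
    t_ms <- seq.int(-pre, len_ms - 1L)
    x <- c(rep(0, pre), px) + stats::rnorm(pre + len_ms, sd = spec$gaze_noise_sd)
    y <- c(rep(0, pre), py) + stats::rnorm(pre + len_ms, sd = spec$gaze_noise_sd)
    blink_full <- c(rep(FALSE, pre), blink)
    x[blink_full] <- NA; y[blink_full] <- NA
    on_image <- !blink_full & !is.na(x) &
      abs(x) <= spec$image_extent[1] / 2 & abs(y) <= spec$image_extent[2] / 2
    trial <- gm_trial(
      trial_id = ids$trial_id, monkey_id = spec$monkey_id,
      session_id = ids$session_id, session_date = ids$session_date,
      phase = condition$phase, site = condition$site,
      hemisphere = condition$hemisphere, volume_ul = condition$volume_ul,
      image_id = layout$landmarks$image_id, image_extent = spec$image_extent,
      fix_window = c(-pre, 0),
      samples = data.frame(t_ms = t_ms, x = x, y = y, on_image = on_image))
    list(trial = trial, truth = truth)
  })
}

#' Generate a complete synthetic experiment
#'
#' Builds the face layouts (plus mirrored twins), lays out sessions so every
#' injection session has baseline sessions within a month, and simulates
#' every trial with ground truth. Fully deterministic under the spec seed.
#'
#' @param spec a [generator_spec()].
#' @param events_only passed to [generate_scanpath()] (fast, no 1-kHz traces).
#' @return list: `trials` (named list of [gm_trial()]), `truth` (named list
#'   aligned with trials), `landmarks` (named list incl. mirrors), `layouts`,
#'   `design` (session table), `rois` (eye ROIs on the mean face),
#'   `mean_shape`, `mesh`.
#' @export
generate_experiment <- function(spec, events_only = FALSE) {
  layouts <- list()
  for (i in seq_len(spec$n_images)) {
    ly <- generate_face_layout(spec, i)
    layouts[[ly$landmarks$image_id]] <- ly
    m <- mirror_layout(ly)
    layouts[[m$landmarks$image_id]] <- m
  }
  landmarks <- lapply(layouts, `[[`, "landmarks")
  # interleave baseline and injection sessions on a 3-day grid so every
  # injection session has baseline neighbours within +/- 31 days
  cond <- spec$conditions
  rows <- rep(seq_len(nrow(cond)), cond$n_sessions)
  is_base <- cond$phase[rows] == "baseline"
  # spread baseline sessions evenly among injection sessions so every
  # injection date has baseline neighbours inside the one-month window
  pos <- numeric(length(rows))
  pos[is_base] <- (seq_len(sum(is_base)) - 0.5) / max(1, sum(is_base))
  pos[!is_base] <- (seq_len(sum(!is_base)) - 0.5) / max(1, sum(!is_base))
  rows <- rows[order(pos)]
  design <- cond[rows, c("phase", "site", "hemisphere", "volume_ul",
                         "trials_per_session", "ipsi_effect_s")]
  design$session_id <- sprintf("s%03d", seq_along(rows))
  design$session_date <- 3L * seq_along(rows)
  rownames(design) <- NULL
  trials <- list(); truth <- list()
  img_ids <- names(layouts)
  trial_counter <- 0L
  for (r in seq_len(nrow(design))) {
    srow <- design[r, ]
    for (tr in seq_len(srow$trials_per_session)) {
      trial_counter <- trial_counter + 1L
      img <- img_ids[[1L + (derive_seed(spec$seed, trial_counter) %% length(img_ids))]]
      tid <- sprintf("%s_t%03d", srow$session_id, tr)
      g <- generate_scanpath(
        spec, layouts[[img]],
        condition = list(phase = srow$phase, site = srow$site,
                         hemisphere = srow$hemisphere,
                         volume_ul = srow$volume_ul,
                         ipsi_effect_s = srow$ipsi_effect_s),
        seed = derive_seed(spec$seed, 100000 + trial_counter),
        ids = list(trial_id = tid, session_id = srow$session_id,
                   session_date = srow$session_date),
        events_only = events_only)
      trials[[tid]] <- g$trial
      truth[[tid]] <- g$truth
    }
  }
  mean_shape <- compute_mean_shape(landmarks)
  list(trials = trials, truth = truth, landmarks = landmarks, layouts = layouts,
       design = design, mean_shape = mean_shape, mesh = triangulate(mean_shape),
       rois = eye_rois_from_shape(mean_shape, spec$roi_scale))
}
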