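#' Permutation-test result container
#'
#' @param observed observed statistic.
#' @param p_perm permutation p-value.
#' @param n_resamples number of resamples (or enumerated assignments).
#' @param ci95 95% bootstrap confidence interval `c(low, high)`.
#' @param seed RNG seed used (or NULL).
#' @param exact TRUE when the null was enumerated exhaustively.
#' @param method short description.
#' @param p_adj BH-adjusted p (filled in by [bh_adjust_results()]).
#' @return object of class `gm_stat_result`.
#' @export
new_stat_result <- function(observed, p_perm, n_resamples, ci95 = c(NA, NA),
                            seed = NULL, exact = FALSE, method = "", p_adj = NA) {
  structure(list(observed = observed, p_perm = p_perm, n_resamples = n_resamples,
                 p_adj = p_adj, ci95 = ci95, seed = seed, exact = exact,
                 method = method),
            class = "gm_stat_result")
}

#' @export
print.gm_stat_result <- function(x, ...) {
  cat(sprintf("%s: observed = %.4g, p = %.4g%s (n = %d%s)",
              if (nzchar(x$method)) x$method else "permutation test",
              x$observed, x$p_perm,
              if (!is.na(x$p_adj)) sprintf(", p_adj = %.4g", x$p_adj) else "",
              x$n_resamples, if (x$exact) ", exact" else ""))
  if (!anyNA(x$ci95)) cat(sprintf(", 95%% CI [%.4g, %.4g]", x$ci95[1], x$ci95[2]))
  cat("\n")
  invisible(x)
}

#' Rectangular region of interest on the mean face
#' @param name ROI name (e.g. `"right_eye"`).
#' @param x_min,x_max,y_min,y_max bounds in mean-face dva; min < max.
#' @return object of class `gm_roi`.
#' @export
roi_rect <- function(name, x_min, x_max, y_min, y_max) {
  if (x_min >= x_max || y_min >= y_max) stop("ROI ", name, ": min must be < max")
  structure(list(name = name, x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max), class = "gm_roi")
}

#' Eye ROIs derived from the mean shape
#'
#' Square ROIs centered on the left/right eye-center landmarks; side length
#' is `scale` times the inner-to-outer eye-corner distance.
#'
#' @param mean_shape a `gm_mean_shape` with `left_eye_center` etc. labels.
#' @param scale side length as a multiple of the eye width (default 1.6).
#' @return list with elements `left` and `right` ([roi_rect()] objects).
#' @export
eye_rois_from_shape <- function(mean_shape, scale = 1.6) {
  get <- function(lab) mean_shape$points[match(lab, mean_shape$labels), ]
  mk <- function(side) {
    ctr <- get(paste0(side, "_eye_center"))
    w <- scale * sqrt(sum((get(paste0(side, "_eye_outer")) -
                           get(paste0(side, "_eye_inner")))^2))
    roi_rect(paste0(side, "_eye"), ctr[1] - w / 2, ctr[1] + w / 2,
             ctr[2] - w / 2, ctr[2] + w / 2)
  }
  list(left = mk("left"), right = mk("right"))
}

#' Dwell time inside a rectangular ROI, in seconds
#'
#' Sums the sampling periods of in-mesh warped samples whose gaze lies inside
#' the closed rectangle; each 1-ms sample contributes one nominal period.
#'
#' @param warped warped-gaze data.frame from [warp_trial_gaze()].
#' @param roi a [roi_rect()].
#' @param period_ms nominal sampling period (default 1).
#' @return dwell time in seconds.
#' @export
roi_dwell_time <- function(warped, roi, period_ms = 1) {
  w <- warped[warped$in_mesh, , drop = FALSE]
  if (!nrow(w)) return(0)
  inside <- w$x >= roi$x_min & w$x <= roi$x_max &
            w$y >= roi$y_min & w$y <= roi$y_max
  sum(inside) * period_ms / 1000
}

#' Per-trial looking-time record
#'
#' Observer-referenced eye dwell times plus face/total dwell for one trial's
#' warped gaze.
#'
#' @param trial a [gm_trial()].
#' @param warped [warp_trial_gaze()] output for the trial.
#' @param rois list with `left` and `right` eye [roi_rect()]s.
#' @param face_polygon optional polygon (k x 2, mean-face dva) for face dwell;
#'   when NULL, in-mesh dwell is used as face dwell.
#' @return one-row data.frame: ids, condition fields, `t_left_eye`,
#'   `t_right_eye`, `t_face`, `t_total` (seconds).
#' @export
looking_time_record <- function(trial, warped, rois, face_polygon = NULL) {
  t_left <- roi_dwell_time(warped, rois$left)
  t_right <- roi_dwell_time(warped, rois$right)
  w <- warped[warped$in_mesh, , drop = FALSE]
  t_face <- if (is.null(face_polygon)) nrow(w) / 1000 else {
    sum(sp::point.in.polygon(w$x, w$y, face_polygon[, 1], face_polygon[, 2]) > 0) / 1000
  }
  t_total <- sum(trial$samples$t_ms >= 0 & trial$samples$on_image &
                 !is.na(trial$samples$x)) / 1000
  data.frame(trial_id = trial$trial_id, monkey_id = trial$monkey_id,
             session_id = trial$session_id, session_date = trial$session_date,
             phase = trial$phase, site = trial$site, hemisphere = trial$hemisphere,
             volume_ul = trial$volume_ul, image_id = trial$image_id,
             t_left_eye = t_left, t_right_eye = t_right, t_face = t_face,
             t_total = t_total, stringsAsFactors = FALSE)
}

#' Per-trial ipsilateral-minus-contralateral eye dwell difference
#'
#' "Ipsilateral eye" is observer-referenced: a right-hemisphere injection
#' makes the observer-right eye ipsilateral.
#'
#' @param records looking-time table ([looking_time_record()] rows).
#' @param hemisphere `"left"` or `"right"`; default taken per-row from the
#'   records.
#' @return numeric vector of per-trial differences (seconds).
#' @export
ipsi_contra_difference <- function(records, hemisphere = NULL) {
  hemi <- hemisphere %||% records$hemisphere
  if (length(hemi) == 1) hemi <- rep(hemi, nrow(records))
  if (any(!hemi %in% c("left", "right")))
    stop("ipsi_contra_difference requires an injection hemisphere; ",
         "baseline trials have none (use observer-referenced bias instead)")
  sign <- ifelse(hemi == "right", 1, -1)
  sign * (records$t_right_eye - records$t_left_eye)
}

#' Baseline-normalize injection-session eye biases
#'
#' Subtracts from each injection trial's observer-referenced eye bias
#' (right minus left dwell) the mean baseline bias measured in baseline
#' sessions dated within `window_days` of the injection session, then
#' re-expresses the result as ipsilateral minus contralateral.
#'
#' @param inj_records looking-time rows for injection trials.
#' @param base_records looking-time rows for baseline trials.
#' @param window_days half-width of the baseline window in days (default 31).
#' @return numeric vector of normalized per-trial ipsi-contra differences
#'   (seconds), in `inj_records` order.
#' @export
baseline_normalize <- function(inj_records, base_records, window_days = 31) {
  if (!nrow(inj_records)) return(numeric())
  base_bias <- base_records$t_right_eye - base_records$t_left_eye
  out <- numeric(nrow(inj_records))
  for (sid in unique(inj_records$session_id)) {
    rows <- inj_records$session_id == sid
    date <- inj_records$session_date[rows][1]
    in_win <- abs(base_records$session_date - date) <= window_days
    if (!any(in_win))
      stop("no baseline session within ", window_days, " days of injection session ", sid)
    b <- mean(base_bias[in_win])
    sgn <- ifelse(inj_records$hemisphere[rows] == "right", 1, -1)
    out[rows] <- sgn * ((inj_records$t_right_eye[rows] -
                         inj_records$t_left_eye[rows]) - b)
  }
  out
}

#' Two-sample permutation test
#'
#' Builds the null by pooling the two groups and re-splitting at the original
#' group sizes. When the number of distinct splits is at most `exact_cap`
#' they are enumerated exhaustively (p = fraction of splits with
#' `|null| >= |observed|`); otherwise `n` Monte-Carlo resamples are drawn and
#' the two-sided add-one p-value `(1 + hits) / (1 + n)` is reported.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @param statistic function of two vectors (default difference of means).
#' @param n Monte-Carlo resamples (default 10000).
#' @param seed RNG seed.
#' @param exact_cap enumerate exhaustively up to this many splits.
#' @param n_boot bootstrap resamples for the 95% CI (0 disables).
#' @return a [new_stat_result()].
#' @export
permutation_test <- function(values_a, values_b,
                             statistic = function(a, b) mean(a) - mean(b),
                             n = 10000, seed = NULL, exact_cap = 20000,
                             n_boot = 2000) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  if (n < 1) stop("n must be >= 1")
  obs <- statistic(values_a, values_b)
  pool <- c(values_a, values_b)
  na <- length(values_a); ntot <- length(pool)
  with_seed(seed, {
    n_splits <- choose(ntot, na)
    if (n_splits <= exact_cap) {
      splits <- utils::combn(ntot, na)
      null <- apply(splits, 2, function(ia) statistic(pool[ia], pool[-ia]))
      p <- sum(abs(null) >= abs(obs) - 1e-12) / n_splits
      n_used <- n_splits; exact <- TRUE
    } else {
      null <- vapply(seq_len(n), function(i) {
        ia <- sample.int(ntot, na)
        statistic(pool[ia], pool[-ia])
      }, numeric(1))
      p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n)
      n_used <- n; exact <- FALSE
    }
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      boot <- vapply(seq_len(n_boot), function(i) {
        statistic(sample(values_a, na, replace = TRUE),
                  sample(values_b, ntot - na, replace = TRUE))
      }, numeric(1))
      ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
    }
    new_stat_result(observed = obs, p_perm = p, n_resamples = n_used, ci95 = ci,
                    seed = seed, exact = exact, method = "two-sample permutation test")
  })
}

#' One-sample sign-flip permutation test of mean difference = 0
#'
#' The null randomly flips the sign of each paired difference. All `2^m` sign
#' patterns are enumerated when feasible; otherwise Monte-Carlo with the
#' add-one two-sided p-value.
#'
#' @param deltas numeric vector of paired differences (length >= 2).
#' @param n Monte-Carlo resamples (default 10000).
#' @param seed RNG seed.
#' @param exact_cap enumerate when `2^length(deltas) <= exact_cap`.
#' @param n_boot bootstrap resamples for the 95% CI of the mean.
#' @return a [new_stat_result()].
#' @export
paired_difference_test <- function(deltas, n = 10000, seed = NULL,
                                   exact_cap = 4096, n_boot = 2000) {
  m <- length(deltas)
  if (m < 2) stop("paired_difference_test needs at least 2 differences")
  obs <- mean(deltas)
  with_seed(seed, {
    if (2^m <= exact_cap) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
      null <- as.numeric(signs %*% deltas) / m
      p <- sum(abs(null) >= abs(obs) - 1e-12) / nrow(signs)
      n_used <- nrow(signs); exact <- TRUE
    } else {
      null <- vapply(seq_len(n), function(i)
        mean(deltas * sample(c(-1, 1), m, replace = TRUE)), numeric(1))
      p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n)
      n_used <- n; exact <- FALSE
    }
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      boot <- vapply(seq_len(n_boot), function(i)
        mean(sample(deltas, m, replace = TRUE)), numeric(1))
      ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
    }
    new_stat_result(observed = obs, p_perm = p, n_resamples = n_used, ci95 = ci,
                    seed = seed, exact = exact, method = "sign-flip permutation test")
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving and
#' idempotent.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Apply BH correction across a family of permutation results
#' @param results list of [new_stat_result()] objects forming one family.
#' @return the list with `p_adj` filled in.
#' @export
bh_adjust_results <- function(results) {
  adj <- bh_adjust(vapply(results, `[[`, numeric(1), "p_perm"))
  Map(function(r, a) { r$p_adj <- a; r }, results, adj)
}

#' Pattern change index for one trial heatmap
#'
#' `(d(h_i, G) - d(h_i, hbar)) / d(h_i, G)` where `hbar` is the stimulus'
#' mean heatmap within the trial's injection condition and `G` the grand
#' average over that condition's trials plus all baseline trials of the same
#' stimulus. The index is 1 when the trial sits exactly on the condition mean
#' but away from the grand mean, 0 when both distances are equal, and
#' negative when the trial lies farther from its condition mean.
#'
#' @param trial_hm,condition_mean_hm,grand_mean_hm [gm_heatmap()] objects on
#'   the same (analysis-resolution) grid.
#' @return scalar index, or `NA` when `d(h_i, G) = 0` (undefined).
#' @export
pattern_change_index <- function(trial_hm, condition_mean_hm, grand_mean_hm) {
  dG <- heatmap_distance(trial_hm, grand_mean_hm)
  if (dG == 0) return(NA_real_)
  dh <- heatmap_distance(trial_hm, condition_mean_hm)
  (dG - dh) / dG
}

#' Per-trial pattern change indices for an injection condition
#'
#' For each stimulus, the condition mean is the average heatmap over the
#' injection trials showing it, and the grand mean additionally pools the
#' baseline trials of the same stimulus.
#'
#' @param inj_hms,base_hms lists of analysis-resolution [gm_heatmap()]s.
#' @param inj_images,base_images stimulus ids aligned with the heatmap lists.
#' @return data.frame `image_id`, `index` with one row per injection trial
#'   (NA rows flagged where the grand distance is zero).
#' @export
pattern_change_indices <- function(inj_hms, base_hms, inj_images, base_images) {
  out <- data.frame(image_id = character(), index = numeric())
  for (img in unique(inj_images)) {
    ii <- which(inj_images == img)
    bi <- which(base_images == img)
    hbar <- average_heatmaps(inj_hms[ii])
    grand <- average_heatmaps(c(inj_hms[ii], base_hms[bi]))
    idx <- vapply(ii, function(i)
      pattern_change_index(inj_hms[[i]], hbar, grand), numeric(1))
    out <- rbind(out, data.frame(image_id = img, index = idx))
  }
  out
}

#' Expected natural pattern variation estimated from baseline trials
#'
#' For each stimulus, baseline trials are split at random into a pseudo
#' "condition" half and a remainder; the pattern change index is computed for
#' the pseudo-condition trials against the all-baseline grand mean. This
#' yields the index distribution expected without any injection.
#'
#' @param base_hms list of analysis-resolution baseline [gm_heatmap()]s.
#' @param base_images stimulus ids aligned with `base_hms`.
#' @param seed RNG seed for the random split.
#' @return data.frame `image_id`, `index`; single-trial stimuli are skipped
#'   with a warning.
#' @export
baseline_pattern_variation <- function(base_hms, base_images, seed = NULL) {
  out <- data.frame(image_id = character(), index = numeric())
  skipped <- 0L
  with_seed(seed, for (img in unique(base_images)) {
    bi <- which(base_images == img)
    if (length(bi) < 2) { skipped <- skipped + 1L; next }
    half <- sample(bi, max(1L, floor(length(bi) / 2)))
    hbar <- average_heatmaps(base_hms[half])
    grand <- average_heatmaps(base_hms[bi])
    idx <- vapply(half, function(i)
      pattern_change_index(base_hms[[i]], hbar, grand), numeric(1))
    out <- rbind(out, data.frame(image_id = img, index = idx))
  })
  if (skipped) warning(skipped, " stimulus/stimuli with a single baseline trial skipped")
  out
}

#' Face-detection metrics for one trial
#'
#' @param trial a [gm_trial()].
#' @param saccades [detect_saccades()] output for the trial.
#' @param face_polygon k x 2 polygon in source-image dva.
#' @return list: `found` (gaze ever inside the polygon), `latency_ms` (image
#'   onset to end of the first saccade landing inside; 0 when gaze starts
#'   inside; time of first inside sample when gaze drifts in without a
#'   saccade; NA when never found), `frac_time_on_face`.
#' @export
face_detection_metrics <- function(trial, saccades, face_polygon) {
  s <- trial$samples
  post <- s$t_ms >= 0 & !is.na(s$x)
  sp_ <- s[post, , drop = FALSE]
  if (!nrow(sp_)) return(list(found = FALSE, latency_ms = NA_real_,
                              frac_time_on_face = 0))
  inside <- sp::point.in.polygon(sp_$x, sp_$y, face_polygon[, 1], face_polygon[, 2]) > 0
  found <- any(inside)
  frac <- sum(inside & sp_$on_image) / max(1L, sum(sp_$on_image))
  latency <- NA_real_
  if (found) {
    if (inside[1]) latency <- 0 else {
      sc <- saccades[saccades$onset_ms >= 0, , drop = FALSE]
      if (nrow(sc)) {
        lands <- sp::point.in.polygon(sc$x1, sc$y1, face_polygon[, 1],
                                      face_polygon[, 2]) > 0
        if (any(lands)) latency <- min(sc$offset_ms[lands])
      }
      if (is.na(latency)) latency <- sp_$t_ms[which(inside)[1]]
    }
  }
  list(found = found, latency_ms = latency, frac_time_on_face = frac)
}
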