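#' Per-sample gaze speed (dva/s)
#'
#' Positions are smoothed with a short centered moving average, then
#' differentiated by central differences (one-sided at the trace ends); speed
#' is the Euclidean norm of the velocity vector. Samples adjacent to missing
#' data yield `NA` speed and are excluded from threshold estimation.
#'
#' @param samples data.frame with `t_ms`, `x`, `y` (a trial's `samples`).
#' @param smooth_ms moving-average window in ms (default 5).
#' @return numeric vector of speeds (dva/s), aligned with `samples` rows.
#' @export
velocity_profile <- function(samples, smooth_ms = 5) {
  n <- nrow(samples)
  if (n < 3) stop("velocity_profile needs at least 3 samples")
  if (all(is.na(samples$x))) stop("velocity_profile: all samples missing")
  half <- max(0L, (as.integer(smooth_ms) - 1L) %/% 2L)
  sm <- function(v) {
    if (half == 0L) return(v)
    k <- rep(1 / (2 * half + 1), 2 * half + 1)
    out <- as.numeric(stats::filter(v, k, sides = 2))
    # truncated windows at the trace ends
    for (i in c(seq_len(half), seq(n - half + 1L, n))) {
      w <- v[max(1L, i - half):min(n, i + half)]
      out[i] <- if (anyNA(w)) NA_real_ else mean(w)
    }
    out
  }
  xs <- sm(samples$x); ys <- sm(samples$y)
  t <- samples$t_ms
  vx <- vy <- rep(NA_real_, n)
  dt <- (t[3:n] - t[1:(n - 2)]) / 1000
  vx[2:(n - 1)] <- (xs[3:n] - xs[1:(n - 2)]) / dt
  vy[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / dt
  vx[1] <- (xs[2] - xs[1]) / ((t[2] - t[1]) / 1000)
  vy[1] <- (ys[2] - ys[1]) / ((t[2] - t[1]) / 1000)
  vx[n] <- (xs[n] - xs[n - 1]) / ((t[n] - t[n - 1]) / 1000)
  vy[n] <- (ys[n] - ys[n - 1]) / ((t[n] - t[n - 1]) / 1000)
  sqrt(vx^2 + vy^2)
}

#' Detect saccades by a median + k SD velocity threshold
#'
#' The speed median `m` and SD `s` are estimated within the trial's
#' pre-stimulus fixation window. Candidate saccades are maximal runs with
#' speed above `m + k_on * s`; each run is extended backward and forward to
#' the nearest samples where speed falls below `m + k_off * s`. Overlapping
#' or near-adjacent extensions merge; very short events are discarded.
#'
#' @param trial a [gm_trial()].
#' @param k_on onset threshold multiplier (default 6 SD above the median).
#' @param k_off on/offset extension multiplier (default 2 SD).
#' @param min_duration_ms discard events shorter than this (default 8).
#' @param merge_gap_ms merge events separated by less than this (default 10).
#' @param fixation_window `c(start_ms, end_ms)`; default the trial's own.
#' @param smooth_ms smoothing window for [velocity_profile()].
#' @param abs_floor `c(on, off)` absolute thresholds (dva/s) used, with a
#'   warning, when the fixation-window speed SD is degenerate (zero).
#' @return data.frame of class `gm_saccades`: `trial_id`, `onset_ms`,
#'   `offset_ms`, `A_dva`, `PV_dva_s`, `x0`, `y0`, `x1`, `y1`,
#'   `direction_rad`, `gap` (TRUE when missing samples fall inside the
#'   event). Attributes `thr_on`, `thr_off` record the thresholds used.
#' @export
detect_saccades <- function(trial, k_on = 6, k_off = 2, min_duration_ms = 8,
                            merge_gap_ms = 10, fixation_window = NULL,
                            smooth_ms = 5, abs_floor = c(on = 100, off = 20)) {
  s <- trial$samples
  fw <- fixation_window %||% trial$fix_window
  speed <- velocity_profile(s, smooth_ms = smooth_ms)
  in_fix <- s$t_ms >= fw[1] & s$t_ms < fw[2] & !is.na(speed)
  if (sum(in_fix) < 100)
    stop("trial ", trial$trial_id, ": fixation window has fewer than 100 valid samples")
  m <- stats::median(speed[in_fix])
  sd_fix <- stats::sd(speed[in_fix])
  if (!is.finite(sd_fix) || sd_fix == 0) {
    warning("trial ", trial$trial_id,
            ": degenerate fixation-window speed SD; using absolute floor thresholds")
    thr_on <- abs_floor[["on"]]; thr_off <- abs_floor[["off"]]
  } else {
    thr_on <- m + k_on * sd_fix
    thr_off <- m + k_off * sd_fix
  }
  above_off <- !is.na(speed) & speed >= thr_off
  cand <- true_runs(!is.na(speed) & speed > thr_on)
  empty <- data.frame(trial_id = character(), onset_ms = numeric(),
                      offset_ms = numeric(), A_dva = numeric(),
                      PV_dva_s = numeric(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(), direction_rad = numeric(),
                      gap = logical())
  as_sacc <- function(d) {
    structure(d, class = c("gm_saccades", "data.frame"),
              thr_on = thr_on, thr_off = thr_off)
  }
  if (nrow(cand) == 0) return(as_sacc(empty))
  # extend each candidate run to where speed drops below the offset threshold
  for (k in seq_len(nrow(cand))) {
    i <- cand$start[k]
    while (i > 1L && above_off[i - 1L]) i <- i - 1L
    cand$start[k] <- i
    j <- cand$end[k]
    while (j < nrow(s) && above_off[j + 1L]) j <- j + 1L
    cand$end[k] <- j
  }
  # merge overlapping or near-adjacent extensions
  cand <- cand[order(cand$start), , drop = FALSE]
  merged <- cand[1, , drop = FALSE]
  if (nrow(cand) > 1) for (k in 2:nrow(cand)) {
    last <- nrow(merged)
    if (s$t_ms[cand$start[k]] - s$t_ms[merged$end[last]] <= merge_gap_ms) {
      merged$end[last] <- max(merged$end[last], cand$end[k])
    } else merged <- rbind(merged, cand[k, ])
  }
  ev <- lapply(seq_len(nrow(merged)), function(k) {
    i0 <- merged$start[k]; i1 <- merged$end[k]
    if (s$t_ms[i1] - s$t_ms[i0] < min_duration_ms) return(NULL)
    seg <- s[i0:i1, ]
    has_gap <- anyNA(seg$x) || any(diff(seg$t_ms) > 1)
    x0 <- seg$x[1]; y0 <- seg$y[1]
    x1 <- seg$x[nrow(seg)]; y1 <- seg$y[nrow(seg)]
    data.frame(trial_id = trial$trial_id, onset_ms = s$t_ms[i0],
               offset_ms = s$t_ms[i1],
               A_dva = sqrt((x1 - x0)^2 + (y1 - y0)^2),
               PV_dva_s = max(speed[i0:i1], na.rm = TRUE),
               x0 = x0, y0 = y0, x1 = x1, y1 = y1,
               direction_rad = atan2(y1 - y0, x1 - x0), gap = has_gap)
  })
  ev <- ev[!vapply(ev, is.null, logical(1))]
  if (!length(ev)) return(as_sacc(empty))
  as_sacc(do.call(rbind, ev))
}

#' Segment the non-saccadic, on-image portions of a trial into fixations
#'
#' Fixation segments are the complement of the detected saccade intervals
#' within on-image viewing time (`t >= 0`). Segments interrupted only by a
#' bridged blink-length gap are kept whole; longer gaps split them.
#'
#' @param trial a [gm_trial()].
#' @param saccades output of [detect_saccades()] for the trial.
#' @param max_gap_ms blink-bridging threshold (default 500).
#' @return data.frame: `start_ms`, `end_ms`, `duration_ms`, `cx`, `cy`
#'   (centroid, dva), `n_samples`.
#' @export
segment_fixations <- function(trial, saccades, max_gap_ms = 500) {
  s <- trial$samples
  valid <- s$t_ms >= 0 & s$on_image & !is.na(s$x)
  in_sacc <- rep(FALSE, nrow(s))
  if (nrow(saccades)) for (k in seq_len(nrow(saccades)))
    in_sacc <- in_sacc | (s$t_ms >= saccades$onset_ms[k] & s$t_ms <= saccades$offset_ms[k])
  runs <- true_runs(valid & !in_sacc)
  if (nrow(runs) == 0)
    return(data.frame(start_ms = numeric(), end_ms = numeric(),
                      duration_ms = numeric(), cx = numeric(), cy = numeric(),
                      n_samples = integer()))
  # merge runs separated only by a short (bridged) non-saccadic gap
  keep <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
    last <- nrow(keep)
    gap_idx <- (keep$end[last] + 1L):(runs$start[k] - 1L)
    gap_ms <- s$t_ms[runs$start[k]] - s$t_ms[keep$end[last]] - 1L
    if (gap_ms < max_gap_ms && !any(in_sacc[gap_idx])) {
      keep$end[last] <- runs$end[k]
    } else keep <- rbind(keep, runs[k, ])
  }
  do.call(rbind, lapply(seq_len(nrow(keep)), function(k) {
    idx <- keep$start[k]:keep$end[k]
    idx <- idx[valid[idx] & !in_sacc[idx]]
    data.frame(start_ms = s$t_ms[min(idx)], end_ms = s$t_ms[max(idx)],
               duration_ms = s$t_ms[max(idx)] - s$t_ms[min(idx)] + 1,
               cx = mean(s$x[idx]), cy = mean(s$y[idx]),
               n_samples = length(idx))
  }))
}

#' Fit the saccadic main sequence PV = beta * A
#'
#' Least-squares through-origin fit of peak velocity on amplitude. The slope
#' has the closed form `beta = sum(A * PV) / sum(A^2)`. R-squared is computed
#' about the mean of PV (not about zero), the conservative convention for
#' through-origin models.
#'
#' @param saccades a `gm_saccades` table; events flagged `gap` are excluded.
#' @return object of class `gm_main_sequence`: `beta` (dva/s per dva),
#'   `r_squared`, `n_saccades`.
#' @export
fit_main_sequence <- function(saccades) {
  d <- saccades[!saccades$gap & saccades$A_dva > 0, , drop = FALSE]
  if (nrow(d) < 2) stop("fit_main_sequence needs at least 2 saccades with positive amplitude")
  A <- d$A_dva; PV <- d$PV_dva_s
  beta <- sum(A * PV) / sum(A^2)
  ss_res <- sum((PV - beta * A)^2)
  ss_tot <- sum((PV - mean(PV))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(beta = beta, r_squared = r2, n_saccades = nrow(d)),
            class = "gm_main_sequence")
}

#' @export
print.gm_main_sequence <- function(x, ...) {
  cat(sprintf("Main sequence PV = beta * A: beta = %.2f dva/s per dva, R^2 = %.3f (n = %d)\n",
              x$beta, x$r_squared, x$n_saccades))
  invisible(x)
}

#' Permutation comparison of main-sequence slopes between two saccade groups
#'
#' Tests the observed slope difference `beta_a - beta_b` against a null built
#' by permuting saccades between the groups.
#'
#' @param saccades_a,saccades_b `gm_saccades` tables for the two groups.
#' @param n number of resamples (default 10000).
#' @param seed RNG seed (optional).
#' @return a [gm_stat_result] with `observed = beta_a - beta_b`.
#' @export
compare_main_sequences <- function(saccades_a, saccades_b, n = 10000, seed = NULL) {
  da <- saccades_a[!saccades_a$gap & saccades_a$A_dva > 0, c("A_dva", "PV_dva_s")]
  db <- saccades_b[!saccades_b$gap & saccades_b$A_dva > 0, c("A_dva", "PV_dva_s")]
  if (nrow(da) == 0 || nrow(db) == 0) stop("both saccade groups must be non-empty")
  slope <- function(d) sum(d$A_dva * d$PV_dva_s) / sum(d$A_dva^2)
  obs <- slope(da) - slope(db)
  pool <- rbind(da, db)
  na <- nrow(da); ntot <- nrow(pool)
  null <- with_seed(seed, vapply(seq_len(n), function(i) {
    ia <- sample.int(ntot, na)
    slope(pool[ia, ]) - slope(pool[-ia, ])
  }, numeric(1)))
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n)
  new_stat_result(observed = obs, p_perm = p, n_resamples = n, ci95 = c(NA, NA),
                  seed = seed, exact = FALSE, method = "main-sequence slope difference")
}
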