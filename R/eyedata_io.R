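#' Construct a free-viewing trial
#'
#' A trial bundles a 1 kHz gaze trace with its experimental metadata. Time is
#' integer milliseconds with 0 at image onset; the 1-s pre-stimulus fixation
#' occupies negative times. Gaze coordinates are screen-centered degrees of
#' visual angle (dva), x rightward, y upward, image center at the origin.
#'
#' @param trial_id,monkey_id,session_id identifiers (coerced to character).
#' @param session_date session date as `Date` or integer day number.
#' @param phase `"baseline"` or `"injection"`.
#' @param site injection site: `"face_patch"`, `"control"`, or `"none"`.
#' @param hemisphere `"left"`, `"right"`, or `"none"`.
#' @param volume_ul injected muscimol volume in microliters (0, 5 or 10).
#' @param image_id stimulus identifier.
#' @param image_extent `c(width, height)` of the image in dva (default 28 x 21).
#' @param fix_window `c(start_ms, end_ms)` of the pre-stimulus fixation used
#'   for velocity-threshold estimation (default `c(-1000, 0)`).
#' @param samples data.frame with columns `t_ms` (integer, strictly
#'   increasing), `x`, `y` (dva, `NA` during tracker dropout/blinks) and
#'   `on_image` (logical).
#' @return An object of class `gm_trial`.
#' @export
gm_trial <- function(trial_id, monkey_id, session_id, session_date,
                     phase = c("baseline", "injection"),
                     site = c("none", "face_patch", "control"),
                     hemisphere = c("none", "left", "right"),
                     volume_ul = 0, image_id, image_extent = c(28, 21),
                     fix_window = c(-1000, 0), samples) {
  phase <- match.arg(phase)
  site <- match.arg(site)
  hemisphere <- match.arg(hemisphere)
  tr <- structure(list(
    trial_id = as.character(trial_id), monkey_id = as.character(monkey_id),
    session_id = as.character(session_id), session_date = as.integer(session_date),
    phase = phase, site = site, hemisphere = hemisphere,
    volume_ul = as.numeric(volume_ul), image_id = as.character(image_id),
    image_extent = as.numeric(image_extent), fix_window = as.numeric(fix_window),
    samples = samples
  ), class = "gm_trial")
  validate_trial(tr)
  tr
}

validate_trial <- function(tr) {
  s <- tr$samples
  req <- c("t_ms", "x", "y", "on_image")
  miss <- setdiff(req, names(s))
  if (length(miss)) stop("trial ", tr$trial_id, ": samples missing column(s) ",
                         paste(miss, collapse = ", "))
  if (nrow(s) == 0) stop("trial ", tr$trial_id, ": no samples")
  if (any(diff(s$t_ms) <= 0)) stop("trial ", tr$trial_id, ": timestamps not strictly increasing")
  if (any(tr$image_extent <= 0)) stop("trial ", tr$trial_id, ": non-positive image extent")
  if (tr$phase == "baseline" && (tr$site != "none" || tr$volume_ul != 0))
    stop("trial ", tr$trial_id, ": baseline trial must have site 'none' and volume 0")
  invisible(tr)
}

#' @export
print.gm_trial <- function(x, ...) {
  cat(sprintf("<gm_trial %s> %s/%s %s %s %s %g uL, image %s, %d samples\n",
              x$trial_id, x$monkey_id, x$session_id, x$phase, x$site,
              x$hemisphere, x$volume_ul, x$image_id, nrow(x$samples)))
  invisible(x)
}

trial_metadata_row <- function(tr) {
  data.frame(trial_id = tr$trial_id, monkey_id = tr$monkey_id,
             session_id = tr$session_id, session_date = tr$session_date,
             phase = tr$phase, site = tr$site, hemisphere = tr$hemisphere,
             volume_ul = tr$volume_ul, image_id = tr$image_id,
             img_w_dva = tr$image_extent[1], img_h_dva = tr$image_extent[2],
             fix_start_ms = tr$fix_window[1], fix_end_ms = tr$fix_window[2],
             stringsAsFactors = FALSE)
}

#' Metadata table for a list of trials
#' @param trials list of [gm_trial()] objects.
#' @return data.frame, one row per trial.
#' @export
trials_metadata <- function(trials) {
  do.call(rbind, lapply(trials, trial_metadata_row))
}

#' Write trials to plain tab-separated files
#'
#' Writes a sample table (`trial_id, t_ms, x_dva, y_dva, on_image`) and a
#' sidecar metadata table. Gaze is rounded to `digits` decimals; a subsequent
#' [read_trials()] reproduces the trials exactly at that precision.
#'
#' @param trials list of [gm_trial()] objects (all validated, non-empty).
#' @param trace_path,meta_path output file paths.
#' @param digits decimal precision for gaze coordinates.
#' @return Invisibly, `trace_path`.
#' @export
write_trials <- function(trials, trace_path, meta_path, digits = 4) {
  for (tr in trials) validate_trial(tr)
  traces <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, t_ms = as.integer(tr$samples$t_ms),
               x_dva = round(tr$samples$x, digits), y_dva = round(tr$samples$y, digits),
               on_image = tr$samples$on_image, stringsAsFactors = FALSE)
  }))
  utils::write.table(traces, trace_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(trials_metadata(trials), meta_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(trace_path)
}

#' Read trials from tab-separated trace + metadata files
#'
#' Rows are grouped by `trial_id` and time-sorted. Trials whose timestamps are
#' not strictly increasing (e.g., duplicated samples) are excluded and reported
#' in the `problems` attribute rather than silently dropped.
#'
#' @param trace_path,meta_path files produced by [write_trials()] (or any
#'   tables with the same columns).
#' @return list of [gm_trial()] objects with attribute `problems`
#'   (data.frame `trial_id`, `issue`).
#' @export
read_trials <- function(trace_path, meta_path) {
  if (!file.exists(trace_path)) stop("trace file not found: ", trace_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  traces <- utils::read.delim(trace_path, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  req_t <- c("trial_id", "t_ms", "x_dva", "y_dva", "on_image")
  req_m <- c("trial_id", "monkey_id", "session_id", "session_date", "phase",
             "site", "hemisphere", "volume_ul", "image_id", "img_w_dva",
             "img_h_dva", "fix_start_ms", "fix_end_ms")
  for (col in req_t) if (!col %in% names(traces))
    stop("trace file missing required column: ", col)
  for (col in req_m) if (!col %in% names(meta))
    stop("metadata file missing required column: ", col)
  problems <- data.frame(trial_id = character(), issue = character(),
                         stringsAsFactors = FALSE)
  if (nrow(traces) == 0) {
    warning("empty trace file: ", trace_path)
    out <- list()
    attr(out, "problems") <- problems
    return(out)
  }
  traces$trial_id <- as.character(traces$trial_id)
  meta$trial_id <- as.character(meta$trial_id)
  out <- list()
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    s <- traces[traces$trial_id == m$trial_id, , drop = FALSE]
    if (nrow(s) == 0) {
      problems <- rbind(problems, data.frame(trial_id = m$trial_id,
                                             issue = "no samples"))
      next
    }
    s <- s[order(s$t_ms), , drop = FALSE]
    if (any(diff(s$t_ms) <= 0)) {
      problems <- rbind(problems, data.frame(
        trial_id = m$trial_id, issue = "non-monotone or duplicated timestamps"))
      next
    }
    out[[m$trial_id]] <- gm_trial(
      trial_id = m$trial_id, monkey_id = m$monkey_id, session_id = m$session_id,
      session_date = m$session_date, phase = m$phase, site = m$site,
      hemisphere = m$hemisphere, volume_ul = m$volume_ul, image_id = m$image_id,
      image_extent = c(m$img_w_dva, m$img_h_dva),
      fix_window = c(m$fix_start_ms, m$fix_end_ms),
      samples = data.frame(t_ms = as.integer(s$t_ms), x = s$x_dva, y = s$y_dva,
                           on_image = as.logical(s$on_image)))
  }
  if (nrow(problems)) warning(nrow(problems), " trial(s) flagged during read; ",
                              "see attr(,'problems')")
  attr(out, "problems") <- problems
  out
}

#' Annotate off-image/missing gaps and mark blink-length gaps as bridged
#'
#' Interruptions of image viewing (gaze off the image or tracker dropout)
#' shorter than `max_gap_ms` are marked "bridged": they count as continuous
#' viewing for trial inclusion, emulating tolerance of natural blinks. The
#' missing samples themselves are never fabricated; bridging only annotates.
#' Only interior gaps (flanked by on-image viewing on both sides) are bridged.
#'
#' @param trial a [gm_trial()].
#' @param max_gap_ms gaps strictly shorter than this are bridged (default 500).
#' @return The trial with a logical `bridged` column added to `samples` and a
#'   `gaps` attribute (data.frame `start_ms`, `end_ms`, `dur_ms`, `bridged`)
#'   describing interruptions at `t >= 0`.
#' @export
bridge_gaps <- function(trial, max_gap_ms = 500) {
  s <- trial$samples
  post <- s$t_ms >= 0
  viewing <- post & s$on_image & !is.na(s$x)
  bridged <- rep(FALSE, nrow(s))
  gaps <- data.frame(start_ms = integer(), end_ms = integer(),
                     dur_ms = integer(), bridged = logical())
  runs <- true_runs(post & !viewing)
  if (nrow(runs)) {
    for (k in seq_len(nrow(runs))) {
      i0 <- runs$start[k]; i1 <- runs$end[k]
      # duration includes time skipped by absent rows
      t0 <- s$t_ms[i0]
      t1 <- if (i1 < nrow(s)) s$t_ms[i1 + 1L] else s$t_ms[i1] + 1L
      dur <- t1 - t0
      interior <- i0 > 1L && i1 < nrow(s) && viewing[i0 - 1L] && viewing[i1 + 1L]
      br <- interior && dur < max_gap_ms
      if (br) bridged[i0:i1] <- TRUE
      gaps <- rbind(gaps, data.frame(start_ms = t0, end_ms = t1, dur_ms = dur,
                                     bridged = br))
    }
  }
  trial$samples$bridged <- bridged
  attr(trial, "gaps") <- gaps
  trial
}

#' Cumulative on-image viewing time of a trial, in seconds
#'
#' Each 1-ms sample at `t >= 0` that is on the image (or inside a bridged
#' blink-length gap, see [bridge_gaps()]) contributes one sampling period.
#'
#' @inheritParams bridge_gaps
#' @return viewing time in seconds.
#' @export
viewing_time_s <- function(trial, max_gap_ms = 500) {
  trial <- bridge_gaps(trial, max_gap_ms)
  s <- trial$samples
  post <- s$t_ms >= 0
  viewing <- post & (((s$on_image %in% TRUE) & !is.na(s$x)) | s$bridged)
  gaps <- attr(trial, "gaps")
  extra <- 0
  if (nrow(gaps)) {
    # bridged gap durations may exceed the number of stored rows when rows
    # are absent; count the full bridged duration, not just stored samples
    stored <- vapply(seq_len(nrow(gaps)), function(k) {
      sum(s$t_ms >= gaps$start_ms[k] & s$t_ms < gaps$end_ms[k])
    }, numeric(1))
    extra <- sum((gaps$dur_ms - stored)[gaps$bridged])
  }
  (sum(viewing) + extra) / 1000
}

#' Apply the trial-inclusion rule on cumulative viewing time
#'
#' Keeps trials whose cumulative on-image time (with blink-length gaps
#' bridged) strictly exceeds `min_on_image_s` seconds.
#'
#' @param trials list of [gm_trial()] objects.
#' @param min_on_image_s inclusion threshold in seconds (default 7).
#' @param max_gap_ms blink-bridging threshold passed to [bridge_gaps()].
#' @return The kept trials, with attribute `exclusion_log` (data.frame
#'   `trial_id`, `viewing_s`, `kept`) covering every input trial.
#' @export
filter_trials <- function(trials, min_on_image_s = 7, max_gap_ms = 500) {
  vt <- vapply(trials, viewing_time_s, numeric(1), max_gap_ms = max_gap_ms)
  kept <- vt > min_on_image_s
  log <- data.frame(trial_id = vapply(trials, `[[`, "", "trial_id"),
                    viewing_s = vt, kept = kept, stringsAsFactors = FALSE)
  out <- trials[kept]
  attr(out, "exclusion_log") <- log
  out
}
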