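#' Default pipeline configuration
#'
#' All tunable parameters of the analysis in one list: trial inclusion
#' (cumulative viewing > 7 s, blink gaps < 500 ms bridged), saccade detection
#' (median + 6/2 SD velocity thresholds), heatmap recipes (0.25 dva display
#' smoothing; 5 px/deg analysis grid with 2.5 px smoothing), ROI geometry,
#' permutation count and seed.
#'
#' @param seed experiment seed.
#' @param out_dir output directory.
#' @return named list of class `gm_config`.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("gazemorph_run_")) {
  structure(list(
    seed = seed, out_dir = out_dir,
    min_on_image_s = 7, max_gap_ms = 500,
    k_on = 6, k_off = 2, min_duration_ms = 8, merge_gap_ms = 10, smooth_ms = 5,
    sigma_dva = 0.25, exclude_amp_dva = 1, display_px_per_deg = 20,
    analysis_px_per_deg = 5, analysis_sigma_px = 2.5,
    roi_scale = 1.6, baseline_window_days = 31,
    n_perm = 10000, n_boot = 2000,
    normalize_by_baseline = TRUE, report = FALSE,
    generator = list(n_images = 4, trials_per_session = 20,
                     n_baseline_sessions = 16,
                     fp10_effect_s = 1.4, ctl10_effect_s = 0.1,
                     right_eye_baseline_bias_s = 1.1)
  ), class = "gm_config")
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and out-of-range values before any stage runs.
#'
#' @param config list (e.g. from [default_config()] or [read_config()]).
#' @return the validated config, invisibly classed `gm_config`.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(unclass(ref), config)
  if (merged$n_perm < 1) stop("n_perm must be >= 1")
  if (merged$min_on_image_s < 0) stop("min_on_image_s must be >= 0")
  if (merged$max_gap_ms < 0) stop("max_gap_ms must be >= 0")
  if (merged$analysis_px_per_deg > merged$display_px_per_deg)
    stop("analysis resolution must not exceed display resolution")
  invisible(structure(merged, class = "gm_config"))
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with a subset of the [default_config()] keys.
#' @return validated `gm_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the end-to-end analysis pipeline on a synthetic experiment
#'
#' Stages, in dependency order: simulate, filter, detect, morph, heatmap,
#' analyze (and optionally report). Each stage writes its outputs before the
#' next begins and drops a `.done_<stage>` marker, so a failed run names the
#' stage and leaves completed outputs intact. All randomness flows from
#' `config$seed`; a manifest with per-file digests supports verifying that
#' identical configurations reproduce identical results.
#'
#' @param config a validated configuration ([default_config()] /
#'   [validate_config()]).
#' @return list with the main result tables, the run directory and the
#'   manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    file.create(file.path(cfg$out_dir, paste0(".done_", name)))
    res
  }
  # --- simulate ---------------------------------------------------------
  exp <- stage("simulate", {
    spec <- generator_spec(
      seed = cfg$seed, n_images = cfg$generator$n_images,
      right_eye_baseline_bias_s = cfg$generator$right_eye_baseline_bias_s,
      conditions = default_condition_grid(
        n_baseline_sessions = cfg$generator$n_baseline_sessions,
        trials_per_session = cfg$generator$trials_per_session,
        fp10_effect_s = cfg$generator$fp10_effect_s,
        ctl10_effect_s = cfg$generator$ctl10_effect_s),
      roi_scale = cfg$roi_scale)
    e <- generate_experiment(spec)
    write_trials(e$trials, file.path(cfg$out_dir, "traces.tsv"),
                 file.path(cfg$out_dir, "metadata.tsv"))
    write_landmarks(e$landmarks, file.path(cfg$out_dir, "landmarks.tsv"))
    write_tsv(e$design, file.path(cfg$out_dir, "design.tsv"))
    e
  })
  # --- filter -----------------------------------------------------------
  kept <- stage("filter", {
    k <- filter_trials(exp$trials, cfg$min_on_image_s, cfg$max_gap_ms)
    write_tsv(attr(k, "exclusion_log"), file.path(cfg$out_dir, "exclusions.tsv"))
    k
  })
  # --- detect -----------------------------------------------------------
  saccades <- stage("detect", {
    sc <- lapply(kept, detect_saccades, k_on = cfg$k_on, k_off = cfg$k_off,
                 min_duration_ms = cfg$min_duration_ms,
                 merge_gap_ms = cfg$merge_gap_ms, smooth_ms = cfg$smooth_ms)
    write_tsv(do.call(rbind, sc), file.path(cfg$out_dir, "saccades.tsv"))
    sc
  })
  # --- morph ------------------------------------------------------------
  warped <- stage("morph", {
    w <- Map(function(tr, sc) warp_trial_gaze(tr, sc, exp$landmarks, exp$mesh,
                                              exp$mean_shape, cfg$exclude_amp_dva),
             kept, saccades)
    frac <- vapply(w, function(x) attr(x, "frac_out_of_mesh") %||% NA_real_,
                   numeric(1))
    write_tsv(data.frame(trial_id = names(w), frac_out_of_mesh = frac),
              file.path(cfg$out_dir, "morph_summary.tsv"))
    w
  })
  # --- heatmap ----------------------------------------------------------
  hms <- stage("heatmap", {
    lapply(names(kept), function(id) {
      hm <- build_fixation_heatmap(kept[[id]], saccades[[id]], cfg$sigma_dva,
                                   cfg$exclude_amp_dva, cfg$display_px_per_deg)
      resample_for_analysis(hm, cfg$analysis_px_per_deg, cfg$analysis_sigma_px)
    })
  })
  names(hms) <- names(kept)
  # --- analyze ----------------------------------------------------------
  results <- stage("analyze", {
    analyze_experiment(exp, kept, saccades, warped, hms, cfg)
  })
  manifest <- build_manifest(cfg)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(cfg$report)) stage("report", render_report(cfg$out_dir))
  c(results, list(out_dir = cfg$out_dir, manifest = manifest))
}

# Looking-time, ipsi/contra, pattern-change, main-sequence and
# face-detection analyses over a filtered experiment.
analyze_experiment <- function(exp, kept, saccades, warped, hms, cfg) {
  lt <- do.call(rbind, lapply(names(kept), function(id)
    looking_time_record(kept[[id]], warped[[id]], exp$rois)))
  write_tsv(lt, file.path(cfg$out_dir, "looking_times.tsv"))
  base <- lt[lt$phase == "baseline", ]
  # observer-referenced baseline bias
  bias <- permutation_test(base$t_right_eye, base$t_left_eye,
                           n = cfg$n_perm, seed = derive_seed(cfg$seed, 11),
                           n_boot = cfg$n_boot)
  bias$method <- "baseline right-left eye bias"
  # per injection condition: normalized ipsi-contra effect
  inj <- lt[lt$phase == "injection", ]
  conds <- unique(inj[, c("site", "volume_ul")])
  cond_tests <- list(); cond_names <- character()
  for (r in seq_len(nrow(conds))) {
    sel <- inj$site == conds$site[r] & inj$volume_ul == conds$volume_ul[r]
    deltas <- if (cfg$normalize_by_baseline)
      baseline_normalize(inj[sel, ], base, cfg$baseline_window_days)
    else ipsi_contra_difference(inj[sel, ])
    st <- paired_difference_test(deltas, n = cfg$n_perm,
                                 seed = derive_seed(cfg$seed, 20 + r),
                                 n_boot = cfg$n_boot)
    nm <- sprintf("%s_%guL", conds$site[r], conds$volume_ul[r])
    st$method <- paste0("ipsi-contra eye dwell, ", nm)
    cond_tests[[nm]] <- st
    cond_names <- c(cond_names, nm)
  }
  cond_tests <- bh_adjust_results(cond_tests)
  eff <- do.call(rbind, lapply(cond_names, function(nm) {
    s <- cond_tests[[nm]]
    data.frame(condition = nm, effect_s = s$observed, p_perm = s$p_perm,
               p_adj = s$p_adj, ci_low = s$ci95[1], ci_high = s$ci95[2],
               n_resamples = s$n_resamples)
  }))
  write_tsv(eff, file.path(cfg$out_dir, "effects.tsv"))
  # pattern change: face-patch 10 uL vs baseline heatmaps
  ids_inj <- lt$trial_id[lt$site == "face_patch" & lt$volume_ul == 10]
  ids_base <- base$trial_id
  hms <- lapply(hms, normalize_heatmap)   # compare patterns, not dwell mass
  pc <- pattern_change_indices(hms[ids_inj], hms[ids_base],
                               lt$image_id[match(ids_inj, lt$trial_id)],
                               lt$image_id[match(ids_base, lt$trial_id)])
  pc_base <- baseline_pattern_variation(hms[ids_base],
                                        lt$image_id[match(ids_base, lt$trial_id)],
                                        seed = derive_seed(cfg$seed, 31))
  write_tsv(pc, file.path(cfg$out_dir, "pattern_change.tsv"))
  write_tsv(pc_base, file.path(cfg$out_dir, "pattern_change_baseline.tsv"))
  # main sequence: baseline vs face-patch 10 uL
  sc_all <- do.call(rbind, saccades)
  sc_base <- sc_all[sc_all$trial_id %in% ids_base, ]
  sc_inj <- sc_all[sc_all$trial_id %in% ids_inj, ]
  ms <- data.frame(
    group = c("baseline", "face_patch_10uL"),
    beta = c(fit_main_sequence(sc_base)$beta, fit_main_sequence(sc_inj)$beta),
    r_squared = c(fit_main_sequence(sc_base)$r_squared,
                  fit_main_sequence(sc_inj)$r_squared),
    n_saccades = c(fit_main_sequence(sc_base)$n_saccades,
                   fit_main_sequence(sc_inj)$n_saccades))
  write_tsv(ms, file.path(cfg$out_dir, "main_sequence.tsv"))
  # face detection
  fd <- do.call(rbind, lapply(names(kept), function(id) {
    m <- face_detection_metrics(kept[[id]], saccades[[id]],
                                exp$landmarks[[kept[[id]]$image_id]]$face_polygon)
    data.frame(trial_id = id, phase = kept[[id]]$phase, found = m$found,
               latency_ms = m$latency_ms, frac_time_on_face = m$frac_time_on_face)
  }))
  write_tsv(fd, file.path(cfg$out_dir, "face_detection.tsv"))
  list(looking_times = lt, baseline_bias = bias, effects = eff,
       effect_tests = cond_tests, pattern_change = pc,
       pattern_change_baseline = pc_base, main_sequence = ms,
       face_detection = fd)
}

build_manifest <- function(cfg) {
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  persisted <- unclass(cfg)
  persisted$out_dir <- NULL   # path is run-local; keep the hash portable
  yaml::write_yaml(persisted, cfg_path)
  files <- sort(list.files(cfg$out_dir, pattern = "\\.tsv$|\\.yaml$",
                           full.names = TRUE))
  dig <- tools::md5sum(files)
  list(package_version = as.character(utils::packageVersion("gazemorph")),
       seed = cfg$seed,
       config_md5 = unname(tools::md5sum(cfg_path)),
       digests = as.list(stats::setNames(unname(dig), basename(files))),
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Render summary figures from a pipeline results directory
#'
#' Produces analogue plots of the study's figure panels: per-condition effect
#' bars with CIs, pattern-change bars with the baseline-variation band, the
#' main-sequence fit, face-detection latencies, and the exclusion summary.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @return invisibly, the figure file paths.
#' @export
render_report <- function(results_dir) {
  need <- c("effects.tsv", "pattern_change.tsv", "pattern_change_baseline.tsv",
            "main_sequence.tsv", "face_detection.tsv", "saccades.tsv")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing)) stop("missing result table(s): ", paste(missing, collapse = ", "))
  rd <- function(f) utils::read.delim(file.path(results_dir, f))
  figs <- character()
  sv <- function(p, name, w = 6, h = 4) {
    f <- file.path(results_dir, name)
    ggplot2::ggsave(f, p, width = w, height = h, dpi = 120)
    figs <<- c(figs, f)
  }
  eff <- rd("effects.tsv")
  sv(ggplot2::ggplot(eff, ggplot2::aes(x = condition, y = effect_s)) +
       ggplot2::geom_col(fill = "steelblue") +
       ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                              width = 0.2) +
       ggplot2::labs(y = "ipsi - contra eye dwell (s)", x = NULL) +
       ggplot2::theme_minimal(), "fig_effects.png")
  pc <- rd("pattern_change.tsv"); pcb <- rd("pattern_change_baseline.tsv")
  pc$group <- "injection"; pcb$group <- "baseline variation"
  sv(ggplot2::ggplot(rbind(pc, pcb), ggplot2::aes(x = group, y = index)) +
       ggplot2::geom_boxplot() +
       ggplot2::labs(y = "pattern change index", x = NULL) +
       ggplot2::theme_minimal(), "fig_pattern_change.png")
  sc <- rd("saccades.tsv")
  ms <- rd("main_sequence.tsv")
  sv(ggplot2::ggplot(sc, ggplot2::aes(x = A_dva, y = PV_dva_s)) +
       ggplot2::geom_point(alpha = 0.2, size = 0.5) +
       ggplot2::geom_abline(slope = ms$beta[1], intercept = 0, color = "red") +
       ggplot2::labs(x = "amplitude (dva)", y = "peak velocity (dva/s)") +
       ggplot2::theme_minimal(), "fig_main_sequence.png")
  fd <- rd("face_detection.tsv")
  sv(ggplot2::ggplot(fd, ggplot2::aes(x = phase, y = latency_ms)) +
       ggplot2::geom_boxplot() +
       ggplot2::labs(y = "first face saccade latency (ms)", x = NULL) +
       ggplot2::theme_minimal(), "fig_face_latency.png")
  ex <- rd("exclusions.tsv")
  sv(ggplot2::ggplot(ex, ggplot2::aes(x = viewing_s, fill = kept)) +
       ggplot2::geom_histogram(bins = 30) +
       ggplot2::labs(x = "cumulative viewing time (s)") +
       ggplot2::theme_minimal(), "fig_viewing_times.png")
  invisible(figs)
}
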