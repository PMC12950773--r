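#' Write a session to a directory
#'
#' One multi-frame 32-bit float TIFF per trial plus `manifest.json` listing
#' per-trial metadata, acquisition defaults and provenance, and (for
#' synthetic sessions) `ground_truth.json` with the injected parameters and
#' the true vessel masks as single-frame TIFFs. Intensities are stored as
#' `counts * intensity_scale` with the scale recorded in the manifest.
#'
#' @param session List with `trials` (and optionally `truth`), as returned
#'   by [synthesize_session()].
#' @param dir Output directory (created if absent).
#' @param intensity_scale Multiplier applied before writing (default
#'   1/65536, keeping counts well inside the float \[0, 1\] TIFF range).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, intensity_scale = 1 / 65536) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(session$trials, function(tm) {
    fn <- paste0(tm$trial_id, ".tif")
    frames <- lapply(seq_len(dim(tm$frames)[1]),
                     function(i) tm$frames[i, , ] * intensity_scale)
    tiff::writeTIFF(frames, file.path(dir, fn), bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    list(file = fn, trial_id = tm$trial_id, channel = tm$channel,
         odorant = tm$odorant,
         concentration_pct_svp = tm$concentration_pct_svp,
         odor_onset_s = tm$odor_onset_s,
         odor_duration_s = tm$odor_duration_s,
         frame_rate_hz = tm$frame_rate_hz,
         n_frames = dim(tm$frames)[1],
         trial_duration_s = dim(tm$frames)[1] / tm$frame_rate_hz,
         subject_id = tm$subject$id,
         age_months = tm$subject$age_months,
         genotype = tm$subject$genotype)
  })
  d <- dim(session$trials[[1]]$frames)
  truth <- session$truth
  manifest <- list(
    trials = recs,
    acquisition = list(image_size = d[2:3]),
    intensity_scale = intensity_scale,
    provenance = if (!is.null(truth))
      list(generator = "nvcouple synthetic_session", seed = truth$seed)
    else list(generator = "real"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(truth)) {
    for (hemi in c("LEFT", "RIGHT", "FULL")) {
      m <- truth$vessel_mask[[hemi]]
      if (hemi != "FULL") {  # pad hemisphere masks to full geometry
        full <- matrix(FALSE, d[2], d[3])
        half <- floor(d[3] / 2)
        cols <- if (hemi == "LEFT") seq_len(half) else (half + 1):d[3]
        full[, cols] <- m
        m <- full
      }
      tiff::writeTIFF(m * 1.0,
                      file.path(dir, sprintf("vessel_mask_%s.tif", hemi)),
                      bits.per.sample = 8L, compression = "none")
    }
    gt <- list(true_hrf = unclass(truth$true_hrf),
               ca_tau_s = truth$ca_tau_s,
               conc_gain = as.list(truth$conc_gain),
               bleach_tau_s = truth$bleach_tau_s,
               bleach_amp_frac = truth$bleach_amp_frac,
               noise_sd_frac = truth$noise_sd_frac,
               age_gain_per_month = truth$age_gain_per_month,
               genotype_gain = truth$genotype_gain,
               seed = truth$seed)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a session directory
#'
#' Loads every trial referenced by `manifest.json`, validating that each
#' file exists, geometry matches the manifest, and the frame count is
#' consistent with the declared frame rate. Validation failures are
#' collected and the load fails atomically with all messages.
#'
#' @param dir Session directory written by [write_session()] (or laid out
#'   the same way for real data).
#' @return List with `trials` (list of [trial_movie()]) and `manifest`.
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::fromJSON(mpath, simplifyDataFrame = FALSE)
  scale <- manifest$intensity_scale %||% 1
  geom <- unlist(manifest$acquisition$image_size)
  errs <- character()
  trials <- list()
  for (rec in manifest$trials) {
    path <- file.path(dir, rec$file)
    if (!file.exists(path)) {
      errs <- c(errs, sprintf("missing file: %s", rec$file))
      next
    }
    imgs <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e) NULL)
    if (is.null(imgs)) {
      errs <- c(errs, sprintf("corrupt TIFF: %s", rec$file))
      next
    }
    if (length(imgs) != rec$n_frames) {
      errs <- c(errs, sprintf("%s: %d frames on disk, %d in manifest",
                              rec$file, length(imgs), rec$n_frames))
      next
    }
    if (!all(dim(imgs[[1]]) == geom)) {
      errs <- c(errs, sprintf("%s: geometry %s does not match manifest %s",
                              rec$file, paste(dim(imgs[[1]]), collapse = "x"),
                              paste(geom, collapse = "x")))
      next
    }
    # frame count must be the declared trial duration at the declared rate
    dur <- rec$trial_duration_s %||% (rec$n_frames / rec$frame_rate_hz)
    if (rec$n_frames != round(dur * rec$frame_rate_hz)) {
      errs <- c(errs, sprintf(
        "%s: %d frames does not match declared frame rate %g Hz x %.1f s",
        rec$file, rec$n_frames, rec$frame_rate_hz, dur))
      next
    }
    if (rec$odor_onset_s + rec$odor_duration_s >= dur) {
      errs <- c(errs, sprintf(
        "%s: %d frames at %g Hz (%.1f s) inconsistent with odor timing",
        rec$file, rec$n_frames, rec$frame_rate_hz, dur))
      next
    }
    frames <- array(0, dim = c(length(imgs), geom[1], geom[2]))
    for (i in seq_along(imgs)) frames[i, , ] <- imgs[[i]] / scale
    trials[[length(trials) + 1L]] <- trial_movie(
      frames, rec$frame_rate_hz, rec$channel,
      odorant = rec$odorant,
      concentration_pct_svp = rec$concentration_pct_svp,
      odor_onset_s = rec$odor_onset_s,
      odor_duration_s = rec$odor_duration_s,
      subject = list(id = rec$subject_id, age_months = rec$age_months,
                     genotype = rec$genotype),
      trial_id = rec$trial_id)
  }
  if (length(errs) > 0)
    stop("session validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  list(trials = trials, manifest = manifest)
}

#' Pipeline configuration
#'
#' All numeric defaults mirror the imaging protocol: 1 SD / 4-of-6 and
#' 3 SD / 3-of-6 consistency ROIs, 10 s AUC window, 13 s detrend
#' exclusion, alignment to 25 Hz with 4 s pre / 15 s post + 100 zeros,
#' 250 ms GCaMP6f decay, transfer-function start (0.8, 4, 3, 0.2) with
#' tolerance 1e-10 and 700 max iterations.
#'
#' @param yaml Optional path to a YAML file overriding any field.
#' @param ... Field overrides (take precedence over the YAML).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(yaml = NULL, ...) {
  cfg <- list(
    roi_kinds = c("SD1", "SD3", "RECT"),
    sd1_k = 1, sd1_min_trials = 4L,
    sd3_k = 3, sd3_min_trials = 3L,
    response_metric = "mean",
    auc_window_s = 10,
    detrend_exclude_post_s = 13,
    target_rate_hz = 25, pre_s = 4, post_s = 15, pad_zeros = 100L,
    ca_tau_s = 0.25,
    hrf_init = c(0.8, 4, 3, 0.2),
    fit_tol = 1e-10, fit_max_iter = 700L, max_lag_frames = 12L,
    fit_roi_kind = "SD1",
    fit_average_trials = FALSE)
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

# masks for one concentration group of BV dF/F trials
build_masks <- function(dff_group, config) {
  stats <- pixel_response_stats(dff_group, metric = config$response_metric)
  geom <- dim(dff_group[[1]]$values)[2:3]
  out <- list()
  if ("SD1" %in% config$roi_kinds)
    out$SD1 <- consistency_mask(stats, config$sd1_k, config$sd1_min_trials)
  if ("SD3" %in% config$roi_kinds)
    out$SD3 <- consistency_mask(stats, config$sd3_k, config$sd3_min_trials)
  if ("RECT" %in% config$roi_kinds)
    out$RECT <- rect_mask(geom)
  out
}

#' Run the full analysis pipeline on a session directory
#'
#' Stages: load and validate the session; convert blood-volume trials to
#' dF/F; build the consistency and rectangular ROI masks per nonzero
#' concentration (odorants pooled, 6 trials each at protocol defaults);
#' extract and detrend ROI-mean traces; compute the 10 s AUC per trial on
#' the as-acquired 7 Hz trace; when calcium trials are present, upsample
#' and align both channels, deconvolve the calcium trace, and fit the
#' gamma-variate transfer function per odor trial. Writes masks (TIFF +
#' JSON descriptor), traces (CSV), the per-trial fit table (CSV), metrics
#' (CSV + JSON summary) and a run log; a pure function of (input dir,
#' config), so reruns are byte-identical.
#'
#' @param dir Session directory (see [read_session()]).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (default `file.path(dir, "out")`).
#' @return Invisibly, a list with `masks`, `traces`, `metrics`,
#'   `fit_table` (NULL without calcium data), `warnings`, `out_dir`.
#' @export
run_pipeline <- function(dir, config = pipeline_config(),
                         out_dir = file.path(dir, "out")) {
  session <- read_session(dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  trials <- session$trials
  chan <- vapply(trials, function(t) t$channel, "")
  conc <- vapply(trials, function(t) t$concentration_pct_svp, 0)
  bv_idx <- which(chan == "BV590")
  ca_idx <- which(chan == "CA488")
  if (length(bv_idx) == 0) stop("no BV590 trials in session", call. = FALSE)

  # stage 1: dF/F on all BV trials
  dff_bv <- lapply(trials[bv_idx], compute_dff)
  names(dff_bv) <- vapply(trials[bv_idx], function(t) t$trial_id, "")

  # stage 2: masks per nonzero concentration, odorants pooled
  concs <- sort(unique(conc[bv_idx][conc[bv_idx] > 0]))
  masks <- list()
  for (cc in concs) {
    grp <- dff_bv[vapply(dff_bv, function(d)
      d$concentration_pct_svp == cc, TRUE)]
    masks[[as.character(cc)]] <- build_masks(grp, config)
  }

  # stage 3: ROI traces, detrend, AUC per odor trial
  metric_rows <- list()
  trace_rows <- list()
  aligned_bv <- list()  # keyed trial_id|kind|hemi, for the fit stage
  for (d in dff_bv) {
    if (d$concentration_pct_svp == 0) next
    mk <- masks[[as.character(d$concentration_pct_svp)]]
    rate <- d$frame_rate_hz
    onset_idx <- floor(d$odor_onset_s * rate) + 1L
    tt <- (seq_len(dim(d$values)[1]) - 1) / rate
    for (kind in names(mk)) for (hemi in c("LEFT", "RIGHT")) {
      m <- mk[[kind]][[hemi]]
      if (m$empty_warning) {
        note("empty %s/%s mask at %g%%: trial %s skipped",
             kind, hemi, d$concentration_pct_svp, d$trial_id)
        next
      }
      tr <- extract_roi_trace(d, m)
      det <- fit_remove_exponential(tr, tt, onset_s = d$odor_onset_s,
                                    exclude_post_s =
                                      config$detrend_exclude_post_s)
      if (det$fallback_linear)
        note("linear detrend fallback: %s %s/%s", d$trial_id, kind, hemi)
      a <- auc(det$values, onset_idx, rate, config$auc_window_s)
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        trial_id = d$trial_id, odorant = d$odorant,
        concentration = d$concentration_pct_svp, channel = "BV590",
        roi_kind = kind, hemisphere = hemi, n_pixels = sum(m$mask),
        auc = a, auc_oriented = -a,
        peak_dff = det$values[onset_idx:length(det$values)][
          which.max(abs(det$values[onset_idx:length(det$values)]))],
        subject_id = d$subject$id, age_months = d$subject$age_months,
        genotype = d$subject$genotype, stringsAsFactors = FALSE)
      trace_rows[[length(trace_rows) + 1L]] <- data.frame(
        time_s = tt, dff_pct = det$values, channel = "BV590",
        trial_id = d$trial_id, roi_kind = kind, hemisphere = hemi,
        stringsAsFactors = FALSE)
      if (kind == config$fit_roi_kind) {
        al <- resample_align(det$values, tt - d$odor_onset_s,
                             config$target_rate_hz, config$pre_s,
                             config$post_s, config$pad_zeros, "BV590")
        aligned_bv[[paste(d$trial_id, hemi, sep = "|")]] <- al
      }
    }
  }
  metrics_df <- do.call(rbind, c(metric_rows, list(make.row.names = FALSE)))
  traces_df <- do.call(rbind, c(trace_rows, list(make.row.names = FALSE)))

  # stage 4: calcium -> firing rate -> transfer-function fit
  fit_df <- NULL
  if (length(ca_idx) > 0) {
    fit_rows <- list()
    for (tm in trials[ca_idx]) {
      if (tm$concentration_pct_svp == 0) next
      d <- compute_dff(tm)
      mk <- masks[[as.character(tm$concentration_pct_svp)]]
      rate <- d$frame_rate_hz
      tt <- (seq_len(dim(d$values)[1]) - 1) / rate
      base_id <- sub("_CA488$", "", tm$trial_id)
      for (hemi in c("LEFT", "RIGHT")) {
        m <- mk[[config$fit_roi_kind]][[hemi]]
        if (m$empty_warning) next
        bv_key <- paste0(sub("CA488", "BV590", tm$trial_id), "|", hemi)
        if (is.null(aligned_bv[[bv_key]])) next
        tr <- extract_roi_trace(d, m)
        det <- fit_remove_exponential(tr, tt, onset_s = tm$odor_onset_s,
                                      exclude_post_s =
                                        config$detrend_exclude_post_s)
        al_ca <- resample_align(det$values, tt - tm$odor_onset_s,
                                config$target_rate_hz, config$pre_s,
                                config$post_s, config$pad_zeros, "CA488")
        fr <- deconvolve_gcamp(al_ca, config$ca_tau_s)
        res <- fit_transfer_function(
          fr, aligned_bv[[bv_key]], init = config$hrf_init,
          tol = config$fit_tol, max_iter = config$fit_max_iter,
          max_lag_frames = config$max_lag_frames)
        if (!res$converged) note("non-converged fit: %s %s", base_id, hemi)
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          trial_id = base_id, hemisphere = hemi, odorant = tm$odorant,
          concentration = tm$concentration_pct_svp,
          y_m = res$hrf$y_m, t_m = res$hrf$t_m, alpha = res$hrf$alpha,
          y_0 = res$hrf$y_0, fwhm_empirical = fwhm_empirical(res$hrf),
          gof = res$gof_max_xcorr, lag = res$gof_lag_frames,
          converged = res$converged, stringsAsFactors = FALSE)
      }
    }
    fit_df <- do.call(rbind, c(fit_rows, list(make.row.names = FALSE)))
  }

  # stage 5: write artifacts
  for (cc in names(masks)) for (kind in names(masks[[cc]]))
    for (hemi in c("LEFT", "RIGHT")) {
      m <- masks[[cc]][[kind]][[hemi]]
      stem <- sprintf("mask_%s_%s_c%s", kind, hemi, cc)
      tiff::writeTIFF(m$mask * 1.0, file.path(out_dir, paste0(stem, ".tif")),
                      bits.per.sample = 8L, compression = "none")
      jsonlite::write_json(
        list(roi_kind = m$roi_kind, hemisphere = m$hemisphere,
             k_sd = m$k_sd, min_trials = m$min_trials,
             n_trials = m$n_trials, n_pixels = sum(m$mask),
             concentration = as.numeric(cc)),
        file.path(out_dir, paste0(stem, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  utils::write.csv(traces_df, file.path(out_dir, "traces.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics_df, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(fit_df))
    utils::write.csv(fit_df, file.path(out_dir, "fit_table.csv"),
                     row.names = FALSE)
  summary <- list(
    n_trials = length(trials), n_bv = length(bv_idx), n_ca = length(ca_idx),
    concentrations = concs,
    mean_auc_by_kind = lapply(split(metrics_df$auc, metrics_df$roi_kind),
                              mean),
    mean_gof_by_conc = if (!is.null(fit_df))
      lapply(split(fit_df$gof, fit_df$concentration), mean) else NULL,
    warnings = warnings_log,
    config = unclass(config))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c("# pipeline run",
               sprintf("- trials: %d (BV %d, Ca %d)", length(trials),
                       length(bv_idx), length(ca_idx)),
               sprintf("- concentrations: %s", paste(concs, collapse = ", ")),
               sprintf("- ROI kinds: %s",
                       paste(config$roi_kinds, collapse = ", ")),
               if (length(warnings_log))
                 c("## warnings", paste("-", warnings_log)) else
                   "no warnings"),
             file.path(out_dir, "report.md"))
  invisible(list(masks = masks, traces = traces_df, metrics = metrics_df,
                 fit_table = fit_df, warnings = warnings_log,
                 out_dir = out_dir))
}
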