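#' Goodness-of-fit by concentration on a default synthetic session
#'
#' Synthesizes a dual-channel session at generator defaults, runs the full
#' pipeline (dF/F, consistency ROIs, detrend, alignment, deconvolution,
#' transfer-function fits) and returns the mean maximum cross-correlation
#' between measured and predicted blood-volume traces per concentration.
#' Trace SNR rises with concentration through the gain table, so the mean
#' fit quality is expected to rise with concentration.
#'
#' @param seed Integer seed for the session noise.
#' @param image_size Session geometry (default the generator's 64 x 64).
#' @return List: `gof_by_conc` (named numeric, ascending concentration),
#'   `fit_table` (per-trial data.frame).
#' @export
gof_by_concentration_study <- function(seed, image_size = c(64L, 64L)) {
  cfg <- synth_config(image_size = image_size,
                      channels = c("BV590", "CA488"))
  dir <- tempfile("gofsession")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_session(synthesize_session(cfg, seed = seed), dir)
  out <- run_pipeline(dir)
  ft <- out$fit_table
  gof <- vapply(split(ft$gof, ft$concentration), mean, numeric(1))
  gof <- gof[order(as.numeric(names(gof)))]
  list(gof_by_conc = gof, fit_table = ft)
}

#' Trace-level synthetic cohort for coupling analyses
#'
#' Simulates `n_subjects` subjects x 3 concentrations on the aligned
#' 25 Hz grid: a firing rate (subject-jittered gain following the default
#' concentration-gain table), the paired calcium trace (GCaMP6f forward
#' kernel) and blood-volume trace (gamma-variate HRF), both with additive
#' Gaussian noise at amplitude `snr`. The HRF amplitude is multiplied by
#' `amp_per_decade^log10(conc/0.3)`: 1 keeps neurovascular coupling fixed
#' across concentrations, 2 doubles it per concentration decade. Each
#' trial is deconvolved and fitted.
#'
#' @param seed Integer seed.
#' @param amp_per_decade HRF amplitude fold change per concentration
#'   decade (default 1, fixed coupling).
#' @param n_subjects Number of synthetic subjects (default 8).
#' @param snr Peak-amplitude signal-to-noise ratio of both traces
#'   (default 20).
#' @return data.frame: `subject`, `concentration`, `ratio` (BV/Ca AUC,
#'   oriented), `y_m` (fitted amplitude), `gof`.
#' @export
coupling_cohort_study <- function(seed, amp_per_decade = 1,
                                  n_subjects = 8L, snr = 20) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  concs <- c(0.3, 1, 3)
  gains <- c(1, 1.8, 3.2)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subj_gain <- stats::runif(1, 0.8, 1.2)
    for (i in seq_along(concs)) {
      r <- make_firing_rate(4, 4, concs[i], gains[i] * subj_gain, 25, 19)
      r <- c(r, rep(0, 100))
      amp <- 0.8 * amp_per_decade^log10(concs[i] / 0.3)
      hrf <- gamma_hrf(amp, 4, 3, 0.2)
      bv <- predict_bv(r, hrf, frame_rate_hz = 25)
      ca <- convolve_gcamp(r)
      bv <- bv + stats::rnorm(length(bv), 0, max(bv) / snr)
      ca <- ca + stats::rnorm(length(ca), 0, max(ca) / snr)
      fr <- deconvolve_gcamp(ca, frame_rate_hz = 25)
      fit <- fit_transfer_function(fr, bv, orient = "oriented",
                                   frame_rate_hz = 25)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("s%02d", s), concentration = concs[i],
        ratio = coupling_ratio(auc(bv, 101, 25),
                               auc(ca, 101, 25))$ratio,
        y_m = fit$hrf$y_m, gof = fit$gof_max_xcorr,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Transfer-function fit quality at the generator's high-concentration SNR
#'
#' Simulates paired calcium/blood-volume trials at the highest odor
#' concentration with the ROI-trace SNR implied by the generator defaults
#' (per-pixel noise `noise_sd_frac`, averaged over the default vessel-mask
#' pixel count), deconvolves the calcium traces, fits the transfer
#' function per trial from the default starting values, and returns each
#' trial's maximum normalized cross-correlation between the measured and
#' predicted blood-volume traces.
#'
#' @param seed Integer seed.
#' @param n_trials Number of simulated trials (default 20).
#' @return List: `gof` (per-trial), `mean_gof`, `snr` (the derived
#'   ROI-trace amplitude SNR).
#' @export
high_snr_gof_study <- function(seed, n_trials = 20L) {
  cfg <- synth_config()
  truth <- session_ground_truth(cfg, seed)
  n_px <- sum(truth$vessel_mask$FULL)
  # ROI-mean trace noise: per-pixel fraction averaged over the mask
  sigma_pct <- 100 * cfg$noise_sd_frac / sqrt(n_px)
  snr_bv <- abs(cfg$bv_peak_dff) / sigma_pct
  snr_ca <- cfg$ca_peak_dff / sigma_pct
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  gof <- vapply(seq_len(n_trials), function(i) {
    r <- make_firing_rate(4, 4, 3, max(cfg$conc_gain) *
                            stats::runif(1, 0.9, 1.1), 25, 19)
    r <- c(r, rep(0, 100))
    bv <- predict_bv(r, cfg$true_hrf, frame_rate_hz = 25)
    ca <- convolve_gcamp(r, cfg$ca_tau_s)
    bv <- bv + stats::rnorm(length(bv), 0, max(bv) / snr_bv)
    ca <- ca + stats::rnorm(length(ca), 0, max(ca) / snr_ca)
    fr <- deconvolve_gcamp(ca, cfg$ca_tau_s, frame_rate_hz = 25)
    fit_transfer_function(fr, bv, orient = "oriented",
                          frame_rate_hz = 25)$gof_max_xcorr
  }, numeric(1))
  list(gof = gof, mean_gof = mean(gof), snr = snr_bv)
}
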