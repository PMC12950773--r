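#' One trial's widefield movie
#'
#' A frame stack (time x height x width) of nonnegative camera intensities
#' plus the trial's acquisition and stimulus metadata. The blood-volume
#' channel (`"BV590"`, 590 nm isosbestic reflectance) is acquired at 7 Hz;
#' the calcium channel (`"CA488"`, GCaMP6f fluorescence) at 25 Hz.
#'
#' @param frames Numeric 3D array, time first (`[frame, row, col]`), all
#'   values finite and >= 0.
#' @param frame_rate_hz Sampling rate in frames/s (7 for BV590, 25 for CA488).
#' @param channel `"BV590"` or `"CA488"`.
#' @param odorant Odorant id, e.g. `"EB"`, `"MV"`, or `"control"`.
#' @param concentration_pct_svp Concentration in % saturated vapor pressure;
#'   0 iff `odorant == "control"`.
#' @param odor_onset_s Odor onset in seconds from trial start (default 8).
#' @param odor_duration_s Odor duration in seconds (default 4).
#' @param subject List with `id`, `age_months`, `genotype` (`"WT"` or
#'   `"A4T2"`).
#' @param trial_id Unique trial identifier string.
#' @return An object of class `trial_movie`.
#' @export
trial_movie <- function(frames, frame_rate_hz, channel,
                        odorant = "control", concentration_pct_svp = 0,
                        odor_onset_s = 8, odor_duration_s = 4,
                        subject = list(id = "s1", age_months = 12,
                                       genotype = "WT"),
                        trial_id = "t1") {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("frames must be finite and nonnegative", call. = FALSE)
  channel <- match.arg(channel, c("BV590", "CA488"))
  n <- dim(frames)[1]
  dur <- n / frame_rate_hz
  if (odor_onset_s + odor_duration_s >= dur)
    stop("odor_onset_s + odor_duration_s must be < trial duration", call. = FALSE)
  if ((concentration_pct_svp == 0) != identical(odorant, "control"))
    stop("concentration_pct_svp must be 0 iff odorant is 'control'", call. = FALSE)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 channel = channel, odorant = odorant,
                 concentration_pct_svp = concentration_pct_svp,
                 odor_onset_s = odor_onset_s,
                 odor_duration_s = odor_duration_s,
                 subject = subject, trial_id = trial_id),
            class = "trial_movie")
}

#' @export
print.trial_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("trial_movie %s: %s %s %.3g%% SVP, %d frames %dx%d @ %g Hz\n",
              x$trial_id, x$channel, x$odorant, x$concentration_pct_svp,
              d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}

#' A dF/F time series aligned to odor onset
#'
#' Holds `round((pre_s + post_s) * frame_rate_hz)` data samples followed by
#' `pad_zeros` appended zeros, with onset at sample `round(pre_s *
#' frame_rate_hz) + 1` (1-based; serialized 0-based).
#'
#' @param values Signed dF/F values in %.
#' @param frame_rate_hz Sampling rate (25 after upsampling).
#' @param pre_s Seconds retained before odor onset (default 4).
#' @param post_s Seconds retained after onset (default 15).
#' @param pad_zeros Count of appended zeros (default 100).
#' @param channel `"BV590"`, `"CA488"`, or `"RATE"` for deconvolved firing
#'   rate.
#' @return Object of class `aligned_trace` with a `t0_index` field
#'   (1-based index of the onset sample).
#' @export
aligned_trace <- function(values, frame_rate_hz, pre_s = 4, post_s = 15,
                          pad_zeros = 100, channel = "BV590") {
  n_data <- round((pre_s + post_s) * frame_rate_hz)
  if (length(values) != n_data + pad_zeros)
    stop(sprintf("length(values) must be %d (= round((pre+post)*rate) + pad)",
                 n_data + pad_zeros), call. = FALSE)
  structure(list(values = as.numeric(values), frame_rate_hz = frame_rate_hz,
                 t0_index = as.integer(round(pre_s * frame_rate_hz)) + 1L,
                 pre_s = pre_s, post_s = post_s, pad_zeros = pad_zeros,
                 channel = channel),
            class = "aligned_trace")
}

#' Time axis of an aligned trace
#'
#' Seconds relative to odor onset, continuing uniformly through the zero
#' padding.
#'
#' @param trace An [aligned_trace()].
#' @return Numeric vector of times in seconds.
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "aligned_trace"))
  (seq_along(trace$values) - trace$t0_index) / trace$frame_rate_hz
}

#' @export
print.aligned_trace <- function(x, ...) {
  cat(sprintf("aligned_trace %s: %d samples @ %g Hz (%g s pre, %g s post, %d pad)\n",
              x$channel, length(x$values), x$frame_rate_hz, x$pre_s,
              x$post_s, x$pad_zeros))
  invisible(x)
}

#' ROI pixel mask for one hemisphere
#'
#' @param mask Logical matrix (height x width) marking included pixels.
#' @param roi_kind `"SD1"` (1 SD exceedance in >= 4/6 trials), `"SD3"`
#'   (3 SD in >= 3/6), or `"RECT"` (unthresholded rectangle).
#' @param hemisphere `"LEFT"` or `"RIGHT"` (split at the vertical midline).
#' @param k_sd Threshold multiplier (1 or 3); `NA` for RECT.
#' @param min_trials Minimum exceedance count m; `NA` for RECT.
#' @param n_trials Number of trials entering the consistency rule
#'   (6 at defaults).
#' @param empty_warning TRUE if the mask came back empty.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(mask, roi_kind, hemisphere, k_sd = NA_real_,
                     min_trials = NA_integer_, n_trials = NA_integer_,
                     empty_warning = FALSE) {
  stopifnot(is.logical(mask), is.matrix(mask))
  roi_kind <- match.arg(roi_kind, c("SD1", "SD3", "RECT"))
  hemisphere <- match.arg(hemisphere, c("LEFT", "RIGHT"))
  structure(list(mask = mask, roi_kind = roi_kind, hemisphere = hemisphere,
                 k_sd = k_sd, min_trials = min_trials, n_trials = n_trials,
                 empty_warning = isTRUE(empty_warning)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask %s/%s: %d px of %dx%d%s\n", x$roi_kind, x$hemisphere,
              sum(x$mask), nrow(x$mask), ncol(x$mask),
              if (x$empty_warning) " [EMPTY]" else ""))
  invisible(x)
}
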