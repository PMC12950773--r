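#' Pixelwise dF/F conversion
#'
#' Converts a raw trial movie to percent dF/F against a pre-odor baseline:
#' per pixel, `100 * (F(t) - F0) / F0` with `F0` the mean over
#' `baseline_window`. Pixels with `F0 == 0` are flagged invalid (their
#' dF/F is set to `NA`) and are excluded from all ROI construction.
#'
#' @param movie A [trial_movie()].
#' @param baseline_window Integer frame indices (1-based) used as F0;
#'   must lie entirely before odor onset. Default: all pre-onset frames.
#' @return Object of class `dff_movie`: list with `values` (time x height
#'   x width array of dF/F %), `baseline_window`, `invalid_px` (logical
#'   matrix), and the source metadata.
#' @export
compute_dff <- function(movie, baseline_window = NULL) {
  stopifnot(inherits(movie, "trial_movie"))
  n <- dim(movie$frames)[1]
  onset_frame <- floor(movie$odor_onset_s * movie$frame_rate_hz)
  if (is.null(baseline_window)) baseline_window <- seq_len(onset_frame)
  stopifnot(length(baseline_window) > 0,
            max(baseline_window) <= onset_frame,
            min(baseline_window) >= 1)
  h <- dim(movie$frames)[2]; w <- dim(movie$frames)[3]
  f0 <- apply(movie$frames[baseline_window, , , drop = FALSE], c(2, 3), mean)
  if (all(f0 == 0))
    stop("all-zero baseline across the frame", call. = FALSE)
  invalid <- f0 == 0
  f0safe <- ifelse(invalid, NA_real_, f0)
  vals <- 100 * sweep(sweep(movie$frames, c(2, 3), f0safe, "-"),
                      c(2, 3), f0safe, "/")
  structure(list(values = vals, baseline_window = baseline_window,
                 invalid_px = invalid,
                 frame_rate_hz = movie$frame_rate_hz,
                 channel = movie$channel, odorant = movie$odorant,
                 concentration_pct_svp = movie$concentration_pct_svp,
                 odor_onset_s = movie$odor_onset_s,
                 odor_duration_s = movie$odor_duration_s,
                 subject = movie$subject, trial_id = movie$trial_id),
            class = "dff_movie")
}

#' @export
print.dff_movie <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("dff_movie %s: %s, %d frames %dx%d @ %g Hz (F0 from %d frames)\n",
              x$trial_id, x$channel, d[1], d[2], d[3], x$frame_rate_hz,
              length(x$baseline_window)))
  invisible(x)
}

#' Remove LED dimming / photobleach drift by exponential subtraction
#'
#' Fits `a * exp(-t / tau) + c` by least squares to samples *outside* the
#' response exclusion window (odor onset to onset + 13 s at defaults),
#' subtracts the fitted curve over the whole trace and adds back the
#' curve's pre-odor mean so the pre-odor level of the trace is preserved
#' (for a drift that has decayed by trial end this added constant is the
#' asymptote `c`). If the exponential fit fails to converge the function
#' falls back to a linear detrend (fitted on the same samples) and flags
#' the trace.
#'
#' @param values Numeric trace (ROI-mean dF/F %, or any uniform series).
#' @param time_s Time axis in seconds (same length as `values`).
#' @param exclude_window Numeric c(start, end) in the units of `time_s`;
#'   samples inside are excluded from the fit. Default `c(onset, onset +
#'   13)` must be supplied by the caller via `onset_s`.
#' @param onset_s Odor onset time used to build the default exclusion
#'   window.
#' @param exclude_post_s Length of the exclusion window after onset
#'   (default 13 s).
#' @return List with `values` (detrended trace), `fit` (named a/tau/c),
#'   `fallback_linear` (logical flag).
#' @export
fit_remove_exponential <- function(values, time_s, onset_s = NULL,
                                   exclude_post_s = 13,
                                   exclude_window = NULL) {
  stopifnot(length(values) == length(time_s))
  if (is.null(exclude_window)) {
    stopifnot(!is.null(onset_s))
    exclude_window <- c(onset_s, onset_s + exclude_post_s)
  }
  keep <- time_s < exclude_window[1] | time_s > exclude_window[2]
  if (sum(keep) < 10)
    stop("need at least 10 samples outside the exclusion window", call. = FALSE)
  tk <- time_s[keep]; vk <- values[keep]

  fallback <- FALSE
  fit <- tryCatch({
    # linearized start values, then Levenberg-Marquardt refinement
    rng <- diff(range(vk))
    start <- list(a = if (rng > 0) vk[1] - vk[length(vk)] else 0,
                  tau = max(diff(range(tk)) / 2, 1e-3),
                  c = vk[length(vk)])
    m <- minpack.lm::nlsLM(vk ~ a * exp(-tk / tau) + c,
                           start = start,
                           lower = c(-Inf, 1e-3, -Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    as.list(stats::coef(m))
  }, error = function(e) NULL)

  # level added back after subtraction: the fitted curve's mean over the
  # pre-exclusion samples, so the pre-odor mean of the trace is preserved
  # exactly (it reduces to the asymptote c when the drift has fully
  # decayed before trial end).
  pre <- time_s < exclude_window[1]
  if (!any(pre)) pre <- keep
  if (is.null(fit) || !all(is.finite(unlist(fit)))) {
    fallback <- TRUE
    lmfit <- stats::lm(vk ~ tk)
    trend <- stats::coef(lmfit)[1] + stats::coef(lmfit)[2] * time_s
    out <- values - trend + mean(trend[pre])
    fit <- list(a = NA_real_, tau = NA_real_, c = mean(trend[pre]))
  } else {
    curve <- fit$a * exp(-time_s / fit$tau) + fit$c
    out <- values - curve + mean(curve[pre])
  }
  list(values = out, fit = fit, fallback_linear = fallback)
}

#' Pixelwise exponential detrend of a dF/F movie
#'
#' Removes LED-dimming/photobleach drift from every pixel before
#' thresholding statistics are computed. The drift model is
#' `a * exp(-t / tau) + c` per pixel with a single global `tau` (LED and
#' bleach drift are spatially shared): for each candidate `tau` on a log
#' grid the per-pixel `(a, c)` are solved in closed form on the samples
#' outside the response exclusion window (identical regressors for all
#' pixels, one 2x2 Gram matrix), the `tau` minimizing the total residual
#' is kept, and the fitted curve minus its baseline-window mean is
#' subtracted so each pixel's pre-odor mean is preserved.
#'
#' @param dff A [compute_dff()] movie.
#' @param exclude_post_s Seconds after odor onset excluded from the drift
#'   fit (default 13).
#' @param tau_grid_s Candidate time constants in seconds.
#' @return The `dff_movie` with detrended `values` and a `drift_tau_s`
#'   field.
#' @export
detrend_dff_movie <- function(dff, exclude_post_s = 13,
                              tau_grid_s = exp(seq(log(2), log(100),
                                                   length.out = 24))) {
  stopifnot(inherits(dff, "dff_movie"))
  n <- dim(dff$values)[1]
  tt <- (seq_len(n) - 1) / dff$frame_rate_hz
  keep <- tt < dff$odor_onset_s | tt > dff$odor_onset_s + exclude_post_s
  Y <- matrix(dff$values, nrow = n)        # frames x pixels
  Yk <- Y[keep, , drop = FALSE]
  Yk[is.na(Yk)] <- 0
  best <- NULL
  for (tau in tau_grid_s) {
    X <- cbind(1, exp(-tt[keep] / tau))
    G <- crossprod(X)
    XtY <- crossprod(X, Yk)
    B <- solve(G, XtY)                     # 2 x pixels
    sse <- sum(Yk^2) - sum(B * XtY)
    if (is.null(best) || sse < best$sse)
      best <- list(tau = tau, B = B, sse = sse)
  }
  Xf <- cbind(1, exp(-tt / best$tau))
  curve <- Xf %*% best$B                   # frames x pixels
  bw <- dff$baseline_window
  curve <- sweep(curve, 2, colMeans(curve[bw, , drop = FALSE]), "-")
  out <- dff
  out$values <- array(Y - curve, dim = dim(dff$values))
  out$drift_tau_s <- best$tau
  out
}

#' Resample and align a trace to odor onset
#'
#' Linear-interpolation resampling to `target_rate_hz` (25 Hz at defaults,
#' matching the calcium channel), retaining `pre_s` seconds before and
#' `post_s` seconds after odor onset and appending `pad_zeros` zeros: at
#' defaults the output has `round(19 * 25) + 100 = 575` samples with onset
#' at sample 101 (100 samples strictly before onset).
#'
#' @param values Source trace (any uniform rate).
#' @param time_s Source time axis in seconds *relative to odor onset*
#'   (onset at 0).
#' @param target_rate_hz Output rate (default 25).
#' @param pre_s,post_s Window retained around onset (defaults 4 and 15 s).
#' @param pad_zeros Zeros appended after the data window (default 100).
#' @param channel Channel label carried on the output.
#' @return An [aligned_trace()].
#' @export
resample_align <- function(values, time_s, target_rate_hz = 25,
                           pre_s = 4, post_s = 15, pad_zeros = 100,
                           channel = "BV590") {
  stopifnot(length(values) == length(time_s))
  n_data <- round((pre_s + post_s) * target_rate_hz)
  tq <- (seq_len(n_data) - 1) / target_rate_hz - pre_s
  eps <- 1e-9
  if (min(time_s) > -pre_s + eps || max(time_s) < tq[n_data] - eps)
    stop(sprintf(
      "source trace covers [%.3f, %.3f] s but [%.3f, %.3f] s is required",
      min(time_s), max(time_s), -pre_s, tq[n_data]), call. = FALSE)
  vq <- stats::approx(time_s, values, xout = tq, rule = 2)$y
  aligned_trace(c(vq, rep(0, pad_zeros)), target_rate_hz,
                pre_s = pre_s, post_s = post_s, pad_zeros = pad_zeros,
                channel = channel)
}
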