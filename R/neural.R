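#' Estimate firing rate by inverting the GCaMP6f decay kernel
#'
#' The calcium trace is modeled as the firing rate convolved (causally,
#' sum x dt) with the single-exponential indicator kernel
#' `k(t) = exp(-t / tau)`, tau = 250 ms for GCaMP6f. The exact discrete
#' inverse is the causal two-tap filter
#' `r[i] = (c[i] - exp(-dt/tau) * c[i-1]) / dt` (with `c[0] = 0`), so
#' forward-convolving the unclipped output reproduces the input to machine
#' precision. Negative values (noise, indicator undershoot) are clipped in
#' the reported rate by default; the unclipped series is retained for
#' linear downstream use such as transfer-function fitting.
#'
#' @param ca_trace An [aligned_trace()] of the calcium channel at 25 Hz
#'   (or a plain numeric vector with `frame_rate_hz` supplied).
#' @param tau_decay_s Indicator decay constant in seconds (default 0.25).
#' @param clip_negative Clip the reported rate at zero (default TRUE).
#' @param frame_rate_hz Required when `ca_trace` is a bare vector.
#' @return Object of class `firing_rate_estimate`: `values`
#'   (clipped if requested), `values_unclipped`, `frame_rate_hz`,
#'   `tau_decay_s`, `clip_applied`.
#' @export
deconvolve_gcamp <- function(ca_trace, tau_decay_s = 0.25,
                             clip_negative = TRUE, frame_rate_hz = NULL) {
  if (inherits(ca_trace, "aligned_trace")) {
    vals <- ca_trace$values
    rate <- ca_trace$frame_rate_hz
  } else {
    stopifnot(is.numeric(ca_trace), !is.null(frame_rate_hz))
    vals <- as.numeric(ca_trace)
    rate <- frame_rate_hz
  }
  stopifnot(tau_decay_s > 0)
  dt <- 1 / rate
  if (dt > tau_decay_s)
    warning(paste("frame interval exceeds the decay constant;",
                  "inversion is ill-conditioned at this rate",
                  "(blood-volume traces must not be deconvolved)"),
            call. = FALSE)
  a <- exp(-dt / tau_decay_s)
  r <- (vals - a * c(0, vals[-length(vals)])) / dt
  structure(list(values = if (clip_negative) pmax(r, 0) else r,
                 values_unclipped = r,
                 frame_rate_hz = rate, tau_decay_s = tau_decay_s,
                 clip_applied = clip_negative),
            class = "firing_rate_estimate")
}

#' Forward GCaMP convolution (oracle counterpart of the deconvolution)
#'
#' Convolves a rate with the discrete exponential kernel
#' `k[i] = exp(-i dt / tau) * dt`, the exact forward model inverted by
#' [deconvolve_gcamp()].
#'
#' @param rate Numeric firing-rate vector.
#' @param tau_decay_s Decay constant in seconds.
#' @param frame_rate_hz Sampling rate.
#' @return Numeric calcium trace of the same length.
#' @export
convolve_gcamp <- function(rate, tau_decay_s = 0.25, frame_rate_hz = 25) {
  dt <- 1 / frame_rate_hz
  k <- exp(-(seq_along(rate) - 1) * dt / tau_decay_s)
  conv_causal(rate, k, dt)
}

#' @export
print.firing_rate_estimate <- function(x, ...) {
  cat(sprintf("firing_rate_estimate: %d samples @ %g Hz, tau = %g s%s\n",
              length(x$values), x$frame_rate_hz, x$tau_decay_s,
              if (x$clip_applied) " (negatives clipped)" else ""))
  invisible(x)
}
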