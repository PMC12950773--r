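# Internal numerical helpers shared across modules.

# Causal discrete convolution, sum x dt, truncated to length(x).
# Keeps the units of convolved traces independent of frame rate.
conv_causal <- function(x, kernel, dt) {
  n <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(n)] * dt
}

# Sample a gamma_hrf on the grid of a trace at `rate` Hz, starting at t = 0.
sample_hrf <- function(hrf, rate, duration_s) {
  t <- seq(0, duration_s, by = 1 / rate)
  gamma_variate(t, hrf)
}
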