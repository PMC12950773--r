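# Shared fixtures, built once per test run.

.fixtures <- new.env()

get_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small geometry keeps per-test cost low; all code is size-agnostic
tiny_config <- function(...) {
  synth_config(image_size = c(24L, 24L), ...)
}

# noiseless, drift-free dual-channel truth: exact round-trip fixtures
clean_truth <- function() {
  get_fixture("clean_truth", function() {
    session_ground_truth(
      tiny_config(channels = c("BV590", "CA488"),
                  noise_sd_frac = 0, bleach_amp_frac = 0), seed = 1L)
  })
}

# default-noise 32x32 dual-channel session (drift + noise on)
default_session <- function() {
  get_fixture("default_session", function() {
    synthesize_session(
      synth_config(image_size = c(32L, 32L),
                   channels = c("BV590", "CA488")), seed = 11L)
  })
}

# a padded rate + matched BV pair on the aligned 25 Hz grid
make_rate_bv <- function(hrf = gamma_hrf(0.8, 4, 3, 0.2), gain = 2.5,
                         pre_s = 4, post_s = 15, pad = 100) {
  r <- make_firing_rate(pre_s, 4, 3, gain, 25, pre_s + post_s)
  r <- c(r, rep(0, pad))
  list(rate = r, bv = predict_bv(r, hrf, frame_rate_hz = 25), hrf = hrf)
}
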