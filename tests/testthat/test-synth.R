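test_that("firing rate template obeys onset, offset, scaling and control contracts", {
  r <- make_firing_rate(8, 4, 3, 2, frame_rate_hz = 25, trial_duration_s = 30)
  tt <- (seq_along(r) - 1) / 25
  expect_true(all(r[tt < 8] == 0))
  expect_true(all(r >= 0))
  expect_equal(max(r), 2)                        # peak equals gain
  expect_gt(max(r[tt >= 8 & tt <= 8.5]), 0.9 * max(r))  # rises within ~0.5 s
  expect_true(all(r[tt >= 15] == 0))             # back to 0 within 3 s of offset
  # control trials are blank
  expect_identical(make_firing_rate(8, 4, 0, 2, 25, 30), rep(0, 750))
  # linear scaling: doubled gain doubles the course pointwise
  expect_equal(make_firing_rate(8, 4, 3, 4, 25, 30), 2 * r)
  # peaks follow the concentration gain table exactly
  gains <- c(1, 1.8, 3.2)
  peaks <- vapply(seq_along(gains), function(i)
    max(make_firing_rate(8, 4, c(0.3, 1, 3)[i], gains[i], 25, 30)),
    numeric(1))
  expect_equal(peaks / peaks[1], gains / gains[1], tolerance = 1e-12)
  expect_error(make_firing_rate(8, 4, 3, -1, 25, 30), "gain")
})

test_that("synthesized trials follow the forward model and sign conventions", {
  truth <- clean_truth()
  cfg <- truth$config
  # control, no noise, no bleach -> every pixel constant at baseline
  ctrl <- synthesize_trial(truth, list(odorant = "control",
                                       concentration_pct_svp = 0,
                                       trial_id = "c"), "BV590")
  expect_true(all(ctrl$frames == cfg$baseline))
  # BV odor trial: reflectance dips after onset (negative dF/F extremum)
  bv <- synthesize_trial(truth, list(odorant = "EB",
                                     concentration_pct_svp = 3,
                                     trial_id = "b"), "BV590")
  d <- compute_dff(bv)
  tr <- extract_roi_trace(d, truth$vessel_mask$FULL)
  expect_lt(min(tr), 0)
  expect_gt(which.min(tr), floor(cfg$odor_onset_s * cfg$bv_rate_hz))
  # in-mask extremum equals the injected peak dF/F at the top concentration
  expect_equal(min(tr), cfg$bv_peak_dff, tolerance = 1e-6)
  # out-of-mask pixels carry baseline only
  flat <- matrix(d$values, nrow = dim(d$values)[1])
  expect_lt(max(abs(flat[, !as.vector(truth$vessel_mask$FULL)])), 1e-9)
  expect_error(synthesize_trial(truth, list(odorant = "EB",
                                            concentration_pct_svp = 3,
                                            trial_id = "x"), "XY"))
})

test_that("calcium trials deconvolve back to the injected firing rate", {
  truth <- clean_truth()
  ca <- synthesize_trial(truth, list(odorant = "EB",
                                     concentration_pct_svp = 3,
                                     trial_id = "c3"), "CA488")
  s <- extract_roi_trace(compute_dff(ca), truth$vessel_mask$FULL) / 100
  fr <- deconvolve_gcamp(s, frame_rate_hz = 25)
  r_true <- truth$firing_rate_fn(3, 25) * truth$ca_scale
  rel <- sqrt(sum((fr$values_unclipped - r_true)^2) / sum(r_true^2))
  expect_lt(rel, 1e-3)
})

test_that("session layout yields 24 BV trials, 6 per concentration pooled", {
  ses <- default_session()
  chan <- vapply(ses$trials, function(t) t$channel, "")
  bv <- ses$trials[chan == "BV590"]
  expect_length(bv, 24L)
  conc <- vapply(bv, function(t) t$concentration_pct_svp, 0)
  expect_equal(sum(conc == 0), 6L)
  for (cc in c(0.3, 1, 3)) expect_equal(sum(conc == cc), 6L)
  odorants <- vapply(bv, function(t) t$odorant, "")
  expect_setequal(unique(odorants), c("control", "EB", "MV"))
  expect_false(any(duplicated(vapply(ses$trials, function(t) t$trial_id, ""))))
})

test_that("sessions are reproducible from seed; new seeds change only noise", {
  cfg <- tiny_config()
  a <- synthesize_session(cfg, seed = 4)
  b <- synthesize_session(cfg, seed = 4)
  expect_identical(a$trials[[5]]$frames, b$trials[[5]]$frames)
  c2 <- synthesize_session(cfg, seed = 5)
  expect_false(identical(a$trials[[5]]$frames, c2$trials[[5]]$frames))
  # ground-truth structure shared across seeds
  expect_identical(a$truth$vessel_mask$FULL, c2$truth$vessel_mask$FULL)
  expect_identical(unclass(a$truth$true_hrf), unclass(c2$truth$true_hrf))
})

test_that("noiseless responses are linear in the firing-rate amplitude", {
  truth <- clean_truth()
  meta <- function(cc) list(odorant = "EB", concentration_pct_svp = cc,
                            trial_id = "t")
  ext <- function(tm) {
    d <- compute_dff(tm)
    tr <- extract_roi_trace(d, truth$vessel_mask$FULL)
    tr[which.max(abs(tr))]
  }
  for (ch in c("BV590", "CA488")) {
    e1 <- ext(synthesize_trial(truth, meta(0.3), ch))
    e3 <- ext(synthesize_trial(truth, meta(3), ch))
    gains <- truth$conc_gain
    expect_equal(e3 / e1, unname(gains[["3"]] / gains[["0.3"]]),
                 tolerance = 1e-6)
  }
})

test_that("generated BV response has ~1 s onset and >10 s offset at default truth", {
  truth <- clean_truth()
  bv <- synthesize_trial(truth, list(odorant = "EB",
                                     concentration_pct_svp = 3,
                                     trial_id = "b"), "BV590")
  tr <- extract_roi_trace(compute_dff(bv), truth$vessel_mask$FULL)
  tt <- (seq_along(tr) - 1) / truth$config$bv_rate_hz - truth$config$odor_onset_s
  onset <- min(tt[tr < 0.01 * min(tr)])    # first departure from baseline
  expect_lt(onset, 1.5)
  last <- max(tt[tr < 0.1 * min(tr)])      # >10% of extremum this late
  expect_gt(last, 10)
})
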