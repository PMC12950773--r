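# hand-built dF/F fixtures: direct control over per-pixel responses
dff_fixture <- function(resp_matrix, n = 126, rate = 7, onset = 8,
                        noise_sd = 0, seed = 1) {
  h <- nrow(resp_matrix); w <- ncol(resp_matrix)
  set.seed(seed)
  fr <- array(1000, c(n, h, w))
  resp_frames <- (floor(onset * rate) + 1):n
  for (i in seq_len(h)) for (j in seq_len(w))
    fr[resp_frames, i, j] <- 1000 * (1 + resp_matrix[i, j] / 100)
  if (noise_sd > 0) fr <- fr + stats::rnorm(length(fr), 0, noise_sd)
  compute_dff(trial_movie(fr, rate, "BV590", odorant = "EB",
                          concentration_pct_svp = 3, odor_onset_s = onset,
                          odor_duration_s = 4, trial_id = "f"))
}

test_that("exceedance flags use strict inequality on the BV-increase axis", {
  # per-pixel baseline noise so baseline_sd > 0; detrend off to keep the
  # constructed boundary exact
  h <- 6; w <- 6
  resp <- matrix(0, h, w)
  resp[2, 2] <- -5            # strong BV increase (negative reflectance)
  resp[3, 3] <- +5            # reflectance increase: must never flag
  trials <- lapply(1:6, function(s) dff_fixture(resp, noise_sd = 1, seed = s))
  st <- pixel_response_stats(trials, detrend = FALSE)
  expect_true(all(st$exceed_k3[2, 2, ]))
  expect_false(any(st$exceed_k1[3, 3, ]))
  # k=3 flags imply k=1 flags everywhere
  expect_true(all(st$exceed_k1[st$exceed_k3]))
  # noiseless zero-response trials: no flags anywhere
  quiet <- lapply(1:6, function(s) dff_fixture(matrix(0, h, w)))
  stq <- pixel_response_stats(quiet, detrend = FALSE)
  expect_false(any(stq$exceed_k1))
  # response exactly at -k*SD is NOT flagged (strict inequality)
  d <- dff_fixture(matrix(0, h, w))
  bsd <- 0.5
  d$values[, 1, 1] <- rep(c(-bsd, bsd), length.out = dim(d$values)[1])
  onset_f <- floor(8 * 7)
  d$values[(onset_f + 1):dim(d$values)[1], 1, 1] <-
    -1 * stats::sd(d$values[1:onset_f, 1, 1])
  st1 <- pixel_response_stats(list(d), detrend = FALSE)
  expect_false(st1$exceed_k1[1, 1, 1])
  expect_error(pixel_response_stats(list(d, dff_fixture(matrix(0, 4, 4)))),
               "geometries")
})

test_that("consistency rules include/exclude pixels by trial counts", {
  h <- 6; w <- 6
  # pixel (2,2): responds in 4/6 trials; pixel (2,5): responds in 3/6
  trials <- lapply(1:6, function(s) {
    resp <- matrix(0, h, w)
    if (s <= 4) resp[2, 2] <- -5
    if (s <= 3) resp[2, 5] <- -5
    dff_fixture(resp, noise_sd = 1, seed = s)
  })
  st <- pixel_response_stats(trials, detrend = FALSE)
  # one hemisphere is legitimately empty in this fixture
  sd1 <- suppressWarnings(consistency_mask(st, 1, 4))
  sd3 <- suppressWarnings(consistency_mask(st, 3, 3))
  expect_true(sd1$LEFT$mask[2, 2])    # 4/6 at 1 SD -> in
  expect_false(sd1$RIGHT$mask[2, 5])  # 3/6 at 1 SD, min 4 -> out
  expect_true(sd3$RIGHT$mask[2, 5])   # 3/6 at 3 SD, min 3 -> in
  expect_identical(sd1$LEFT$roi_kind, "SD1")
  expect_identical(sd3$RIGHT$k_sd, 3)
  # hemisphere split at the midline: left mask has no right-half pixels
  expect_false(any(sd1$LEFT$mask[, (w / 2 + 1):w]))
  # empty mask: warning flag, not an error
  expect_warning(em <- consistency_mask(st, 3, 6), "empty")
  expect_true(em$LEFT$empty_warning)
})

test_that("raising k or min_trials never adds pixels; SD3 nests in SD1", {
  ses <- default_session()
  dff <- lapply(Filter(function(t)
    t$channel == "BV590" && t$concentration_pct_svp == 3, ses$trials),
    compute_dff)
  st <- pixel_response_stats(dff)
  suppressWarnings({
    for (m in 2:6) {
      lo <- consistency_mask(st, 1, m - 1)
      hi <- consistency_mask(st, 1, m)
      for (hemi in c("LEFT", "RIGHT"))
        expect_true(all(!hi[[hemi]]$mask | lo[[hemi]]$mask))
    }
    k1 <- consistency_mask(st, 1, 3)
    k3 <- consistency_mask(st, 3, 3)
    for (hemi in c("LEFT", "RIGHT"))
      expect_true(all(!k3[[hemi]]$mask | k1[[hemi]]$mask))
  })
})

test_that("SD3 mask recovers the true vessel mask at high SNR", {
  ses <- get_fixture("snr20_session", function() {
    synthesize_session(synth_config(image_size = c(32L, 32L),
                                    noise_sd_frac = 0.001), seed = 3L)
  })
  dff <- lapply(Filter(function(t) t$concentration_pct_svp == 3, ses$trials),
                compute_dff)
  st <- pixel_response_stats(dff)
  sd3 <- consistency_mask(st, 3, 3)
  full <- sd3$LEFT$mask | sd3$RIGHT$mask
  expect_gte(mask_jaccard(full, ses$truth$vessel_mask$FULL), 0.8)
  # flagged pixels cover at least 95% of the true vessel pixels
  cover <- sum(full & ses$truth$vessel_mask$FULL) /
    sum(ses$truth$vessel_mask$FULL)
  expect_gte(cover, 0.95)
})

test_that("rectangular masks and trace extraction behave as contracts state", {
  geom <- c(20L, 20L)
  rm <- rect_mask(geom, list(LEFT = c(1, 20, 1, 10), RIGHT = c(1, 20, 11, 20)))
  expect_equal(sum(rm$LEFT$mask), 200)
  expect_equal(sum(rm$RIGHT$mask), 200)
  expect_error(rect_mask(geom, list(LEFT = c(1, 25, 1, 10),
                                    RIGHT = c(1, 20, 11, 20))), "bounds")
  expect_error(rect_mask(geom, list(LEFT = c(5, 5, 1, 10),
                                    RIGHT = c(1, 20, 11, 20))), "degenerate")
  # default rectangles stay within their hemispheres
  rd <- rect_mask(geom)
  expect_false(any(rd$LEFT$mask[, 11:20]))
  expect_false(any(rd$RIGHT$mask[, 1:10]))

  d <- dff_fixture(matrix(seq(-3, 2, length.out = 36), 6, 6))
  one <- matrix(FALSE, 6, 6); one[4, 5] <- TRUE
  expect_equal(extract_roi_trace(d, one), d$values[, 4, 5])
  # uniform movie: trace equals any pixel
  du <- dff_fixture(matrix(-1, 6, 6))
  expect_equal(extract_roi_trace(du, matrix(TRUE, 6, 6)), du$values[, 1, 1])
  expect_error(extract_roi_trace(d, matrix(FALSE, 6, 6)), "empty")
})
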