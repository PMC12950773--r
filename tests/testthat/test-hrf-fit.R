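test_that("predict_bv obeys convolution identities", {
  h <- gamma_hrf(0.8, 4, 3, 0.2)
  n <- 575; dt <- 1 / 25
  # unit impulse (area 1) at onset reproduces the sampled gamma variate
  imp <- rep(0, n); imp[101] <- 1 / dt
  pred <- predict_bv(imp, h, frame_rate_hz = 25)
  tg <- (0:(n - 101)) * dt
  expect_equal(pred[101:n], gamma_variate(tg, h), tolerance = 1e-10)
  expect_equal(pred[1:100], rep(0, 100))
  # zero-amplitude HRF predicts zero; tiny y_m scales linearly
  h0 <- gamma_hrf(1e-12, 4, 3, 0.2)
  expect_lt(max(abs(predict_bv(imp, h0, frame_rate_hz = 25))), 1e-10)
  # boxcar drive peaks later than the impulse response
  box <- rep(0, n); box[101:200] <- 1
  pb <- predict_bv(box, h, frame_rate_hz = 25)
  expect_gt(which.max(pb), which.max(pred))
})

test_that("goodness of fit finds the correct lag and handles degeneracy", {
  x <- make_rate_bv()$bv
  g <- goodness_of_fit(x, x)
  expect_equal(g$max_xcorr, 1)
  expect_identical(g$lag_frames, 0L)
  # one-frame shift detected at lag 1 with near-unit correlation
  shifted <- c(0, x[-length(x)])
  g1 <- goodness_of_fit(x, shifted)
  expect_identical(g1$lag_frames, 1L)
  expect_gt(g1$max_xcorr, 0.999)
  # anticorrelated at lag 0
  g2 <- goodness_of_fit(x, -x, max_lag_frames = 0L)
  expect_equal(g2$max_xcorr, -1)
  # zero-variance input flagged
  g3 <- goodness_of_fit(rep(2, 100), seq_len(100))
  expect_true(g3$degenerate)
  expect_equal(g3$max_xcorr, 0)
})

test_that("noiseless transfer-function inversion is exact from default start", {
  pair <- make_rate_bv()      # truth equals the default starting values
  res <- fit_transfer_function(pair$rate, pair$bv, orient = "oriented",
                               frame_rate_hz = 25)
  expect_true(res$converged)
  expect_lte(res$n_iterations, 700L)
  expect_equal(unlist(res$hrf), unlist(pair$hrf), tolerance = 1e-3)
  expect_gt(res$gof_max_xcorr, 1 - 1e-8)
  # truth away from the default start is still recovered exactly
  h2 <- gamma_hrf(1.3, 5.5, 2.1, 0.6)
  pair2 <- make_rate_bv(h2)
  res2 <- fit_transfer_function(pair2$rate, pair2$bv, orient = "oriented",
                                frame_rate_hz = 25)
  expect_equal(unlist(res2$hrf), unlist(h2), tolerance = 1e-3)
  # initializations within +-50% of truth converge to truth
  for (f in c(0.5, 1.5)) {
    r3 <- fit_transfer_function(pair2$rate, pair2$bv, init = unlist(h2) * f,
                                orient = "oriented", frame_rate_hz = 25,
                                multistart = FALSE)
    expect_equal(unlist(r3$hrf), unlist(h2), tolerance = 1e-3)
  }
})

test_that("fit is equivariant to rate scaling and rejects bad input", {
  pair <- make_rate_bv(gamma_hrf(1.1, 4.5, 2.5, 0.3))
  res <- fit_transfer_function(pair$rate, pair$bv, orient = "oriented",
                               frame_rate_hz = 25)
  resc <- fit_transfer_function(pair$rate * 4, pair$bv, orient = "oriented",
                                frame_rate_hz = 25)
  expect_equal(resc$hrf$y_m, res$hrf$y_m / 4, tolerance = 1e-3)
  expect_equal(resc$hrf$t_m, res$hrf$t_m, tolerance = 1e-3)
  expect_equal(resc$hrf$alpha, res$hrf$alpha, tolerance = 5e-3)
  expect_error(fit_transfer_function(rep(0, 575), pair$bv,
                                     orient = "oriented",
                                     frame_rate_hz = 25), "no neural drive")
  bad <- pair$bv; bad[3] <- NA
  expect_error(fit_transfer_function(pair$rate, bad, orient = "oriented",
                                     frame_rate_hz = 25), "NaNs")
})

test_that("the fitted objective never exceeds the starting objective", {
  set.seed(21)
  pair <- make_rate_bv(gamma_hrf(0.9, 3.5, 4, 0.4))
  bvn <- pair$bv + stats::rnorm(length(pair$bv), 0, max(pair$bv) / 15)
  init <- c(0.8, 4, 3, 0.2)
  sse0 <- sum((predict_bv(pair$rate, do.call(gamma_hrf, as.list(init)),
                          frame_rate_hz = 25) - bvn)^2)
  res <- fit_transfer_function(pair$rate, bvn, init = init,
                               orient = "oriented", frame_rate_hz = 25)
  expect_lte(res$residual_norm, sse0)
})

test_that("reflectance orientation recovers the same kernel as oriented input", {
  pair <- make_rate_bv(gamma_hrf(1.0, 4.2, 2.8, 0.25))
  res_refl <- fit_transfer_function(pair$rate, -pair$bv,
                                    frame_rate_hz = 25)  # default orient
  expect_equal(unlist(res_refl$hrf), unlist(pair$hrf), tolerance = 1e-3)
})

test_that("fit quality degrades gracefully with trace noise", {
  set.seed(33)
  pair <- make_rate_bv()
  gof_at <- function(snr) {
    bvn <- pair$bv + stats::rnorm(length(pair$bv), 0, max(pair$bv) / snr)
    fit_transfer_function(pair$rate, bvn, orient = "oriented",
                          frame_rate_hz = 25)$gof_max_xcorr
  }
  g <- vapply(c(5, 20, 100), gof_at, numeric(1))
  expect_true(all(diff(g) > 0))
  expect_gt(g[3], 0.995)
})

test_that("fit_table assembles one row per trial with derived columns", {
  pair <- make_rate_bv()
  fits <- list(list(rate = pair$rate, bv = -pair$bv, trial_id = "a",
                    odorant = "EB", concentration = 3),
               list(rate = pair$rate * 2, bv = -pair$bv, trial_id = "b",
                    odorant = "MV", concentration = 1))
  tab <- fit_table(fits, frame_rate_hz = 25)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("y_m", "t_m", "alpha", "y_0", "fwhm_empirical",
                    "gof", "lag", "converged") %in% names(tab)))
  expect_equal(tab$fwhm_empirical[1],
               fwhm_empirical(gamma_hrf(tab$y_m[1], tab$t_m[1],
                                        tab$alpha[1], tab$y_0[1])))
  expect_equal(tab$y_m[2], tab$y_m[1] / 2, tolerance = 1e-3)
})
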