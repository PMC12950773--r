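test_that("sessions round-trip through TIFF + manifest to high precision", {
  ses <- get_fixture("io_session", function()
    synthesize_session(tiny_config(n_reps = 1L, n_controls = 1L,
                                   odorants = "EB"), seed = 2L))
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_session(dir)
  expect_length(back$trials, length(ses$trials))
  orig <- ses$trials[[2]]
  got <- back$trials[[which(vapply(back$trials, function(t) t$trial_id, "")
                            == orig$trial_id)]]
  # float32 storage: relative error bounded by single precision
  expect_lt(max(abs(got$frames - orig$frames)) / max(orig$frames), 1e-6)
  expect_identical(got$channel, orig$channel)
  expect_equal(got$concentration_pct_svp, orig$concentration_pct_svp)
  expect_identical(got$subject$genotype, orig$subject$genotype)
  # injected truth is readable back
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(gt$true_hrf$t_m, ses$truth$true_hrf$t_m)
})

test_that("session validation fails atomically with named problems", {
  ses <- get_fixture("io_session", function()
    synthesize_session(tiny_config(n_reps = 1L, n_controls = 1L,
                                   odorants = "EB"), seed = 2L))
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  # missing referenced file
  mpath <- file.path(dir, "manifest.json")
  man <- jsonlite::fromJSON(mpath, simplifyDataFrame = FALSE)
  victim <- man$trials[[1]]$file
  file.remove(file.path(dir, victim))
  expect_error(read_session(dir), victim, fixed = TRUE)
  # frame-rate / frame-count mismatch
  write_session(ses, dir)
  man <- jsonlite::fromJSON(mpath, simplifyDataFrame = FALSE)
  man$trials[[2]]$frame_rate_hz <- 2   # stack length no longer matches
  jsonlite::write_json(man, mpath, auto_unbox = TRUE, digits = NA)
  expect_error(read_session(dir), "does not match declared frame rate")
  expect_error(read_session(withr::local_tempdir()), "manifest")
})

test_that("pipeline produces per-trial artifacts on a synthetic session", {
  ses <- get_fixture("pipe_session", function()
    synthesize_session(synth_config(image_size = c(32L, 32L),
                                    channels = c("BV590", "CA488"),
                                    n_reps = 2L),
                       seed = 6L))
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  out <- suppressWarnings(run_pipeline(dir))  # sparse low-conc masks
  expect_true(file.exists(file.path(out$out_dir, "traces.csv")))
  expect_true(file.exists(file.path(out$out_dir, "metrics.csv")))
  expect_true(file.exists(file.path(out$out_dir, "fit_table.csv")))
  expect_true(file.exists(file.path(out$out_dir, "summary.json")))
  # one fit row per odor trial and hemisphere that had a usable mask
  ft <- out$fit_table
  expect_true(all(ft$concentration %in% c(0.3, 1, 3)))
  expect_true(all(ft$gof >= -1 & ft$gof <= 1))
  # AUC magnitude grows with concentration within each ROI kind
  ag <- stats::aggregate(auc ~ concentration + roi_kind, out$metrics, mean)
  for (kind in unique(ag$roi_kind)) {
    sub <- ag[ag$roi_kind == kind, ]
    sub <- sub[order(sub$concentration), ]
    if (nrow(sub) == 3) expect_true(all(diff(sub$auc) < 0))
  }
  # config with only the SD3 rule produces only SD3 masks
  out3 <- suppressWarnings(
    run_pipeline(dir, pipeline_config(roi_kinds = "SD3",
                                      fit_roi_kind = "SD3"),
                 out_dir = file.path(dir, "out3")))
  expect_setequal(unique(out3$metrics$roi_kind), "SD3")
})

test_that("pipeline defaults mirror the protocol constants", {
  cfg <- pipeline_config()
  expect_equal(cfg$sd1_min_trials, 4L)
  expect_equal(cfg$sd3_min_trials, 3L)
  expect_equal(cfg$auc_window_s, 10)
  expect_equal(cfg$detrend_exclude_post_s, 13)
  expect_equal(cfg$target_rate_hz, 25)
  expect_equal(cfg$pre_s, 4)
  expect_equal(cfg$post_s, 15)
  expect_equal(cfg$pad_zeros, 100L)
  expect_equal(cfg$ca_tau_s, 0.25)
  expect_equal(cfg$hrf_init, c(0.8, 4, 3, 0.2))
  expect_equal(cfg$fit_tol, 1e-10)
  expect_equal(cfg$fit_max_iter, 700L)
  # YAML and dots override
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines("auc_window_s: 5", yml)
  expect_equal(pipeline_config(yaml = yml)$auc_window_s, 5)
  expect_equal(pipeline_config(yaml = yml, auc_window_s = 7)$auc_window_s, 7)
  # generator protocol defaults
  sc <- synth_config()
  expect_equal(sc$odor_onset_s, 8)
  expect_equal(sc$odor_duration_s, 4)
  expect_equal(sc$bv_rate_hz, 7)
  expect_equal(sc$ca_rate_hz, 25)
  expect_equal(sc$concentrations, c(0.3, 1, 3))
  expect_equal(sc$n_reps + 0L, 3L)
  expect_equal(sc$ca_tau_s, 0.25)
})
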