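#' Configuration for the synthetic session generator
#'
#' Bundles acquisition geometry, trial protocol and forward-model parameters
#' for [synthesize_session()]. Protocol defaults follow the imaging
#' protocol the pipeline targets: odor for 4 s starting 8 s into the trial,
#' three control trials then nine odor trials per odorant (3 concentrations
#' x 3 repetitions, odorants EB and MV), blood-volume channel at 7 Hz and
#' calcium channel at 25 Hz. The default image size (64 x 64) is a
#' desk-scale reduction of the 256 x 256 acquisition geometry; all
#' downstream code is size-agnostic.
#'
#' @param image_size Integer c(height, width).
#' @param trial_duration_s Total recorded seconds per trial; must cover
#'   4 s pre-odor and 15 s post-onset analysis windows.
#' @param odor_onset_s,odor_duration_s Stimulus timing (seconds).
#' @param bv_rate_hz,ca_rate_hz Channel frame rates.
#' @param channels Channels to synthesize: `"BV590"` and/or `"CA488"`.
#' @param odorants Odorant ids (one 3-control + 9-odor block each).
#' @param concentrations Nonzero concentrations in % SVP, increasing.
#' @param n_reps Repetitions per concentration per odorant.
#' @param n_controls Control trials preceding each odorant block.
#' @param subject List with `id`, `age_months`, `genotype`.
#' @param baseline Baseline camera level in counts.
#' @param bv_peak_dff Peak BV reflectance dF/F in % at the highest
#'   concentration for a 12-month WT subject (negative: blood-volume
#'   increase absorbs more 590 nm light, so reflectance drops).
#' @param ca_peak_dff Peak calcium dF/F in % at the highest concentration.
#' @param conc_gain Named numeric vector of multiplicative response gains
#'   per concentration; strictly increasing.
#' @param true_hrf True [gamma_hrf()] used by the blood-volume forward
#'   model.
#' @param ca_tau_s GCaMP6f indicator decay constant in seconds.
#' @param bleach_tau_s,bleach_amp_frac Multiplicative exponential
#'   photobleach/LED drift: time constant and fraction of intensity lost
#'   over a long trial.
#' @param noise_sd_frac Additive Gaussian noise SD as fraction of baseline.
#' @param age_gain_per_month,genotype_gain Amplitude modifiers: A4T2
#'   subjects respond `genotype_gain * (1 + age_gain_per_month *
#'   (age_months - 12))` times the WT amplitude (WT flat in age).
#' @param adaptation_frac Fractional sag of the firing rate during
#'   sustained odor.
#' @param structure_seed RNG seed for the ground-truth *structure* (vessel
#'   geometry); kept separate from the session noise seed so different
#'   noise seeds share identical ground truth.
#' @param n_vessels Branch count per hemisphere vessel tree.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_size = c(64L, 64L),
                         trial_duration_s = 30,
                         odor_onset_s = 8, odor_duration_s = 4,
                         bv_rate_hz = 7, ca_rate_hz = 25,
                         channels = "BV590",
                         odorants = c("EB", "MV"),
                         concentrations = c(0.3, 1, 3),
                         n_reps = 3L, n_controls = 3L,
                         subject = list(id = "sim1", age_months = 12,
                                        genotype = "WT"),
                         baseline = 1000,
                         bv_peak_dff = -2, ca_peak_dff = 8,
                         conc_gain = c("0.3" = 1, "1" = 1.8, "3" = 3.2),
                         true_hrf = gamma_hrf(0.8, 4, 3, 0.2),
                         ca_tau_s = 0.25,
                         bleach_tau_s = 20, bleach_amp_frac = 0.05,
                         noise_sd_frac = 0.002,
                         age_gain_per_month = 0.05, genotype_gain = 1.3,
                         adaptation_frac = 0.2,
                         structure_seed = 20L, n_vessels = 4L) {
  channels <- match.arg(channels, c("BV590", "CA488"), several.ok = TRUE)
  stopifnot(length(image_size) == 2L, all(image_size >= 8),
            trial_duration_s > odor_onset_s + 15,
            odor_onset_s >= 4,
            all(diff(concentrations) > 0),
            length(conc_gain) == length(concentrations),
            all(diff(conc_gain) > 0), all(conc_gain > 0),
            bv_peak_dff < 0, ca_peak_dff > 0, baseline > 0,
            noise_sd_frac >= 0, bleach_amp_frac >= 0, bleach_amp_frac < 1)
  names(conc_gain) <- as.character(concentrations)
  structure(as.list(environment()), class = "synth_config")
}

#' Synthetic firing-rate time course
#'
#' Deterministic template of the odor-evoked mitral/tufted firing rate:
#' zero before onset, a fast (~0.5 s) rise, a sustained plateau with
#' fractional adaptation, and a return to zero within 3 s of odor offset.
#' The course is normalized so its peak equals `gain`; control trials
#' (concentration 0) are identically zero. Across the default
#' concentration gains the peak therefore scales exactly as the gain table.
#'
#' @param onset_s,duration_s Stimulus timing in seconds; `duration_s > 0`.
#' @param concentration_pct_svp Concentration in % SVP; 0 returns zeros.
#' @param gain Peak firing rate (arbitrary units); must be >= 0.
#' @param frame_rate_hz Sampling rate of the returned course.
#' @param trial_duration_s Length of the returned course in seconds.
#' @param adaptation_frac Fractional sag of the plateau (0 = none).
#' @param rise_tau_s,fall_tau_s Rise/fall time constants in seconds.
#' @param seed Optional seed for trial-to-trial amplitude jitter.
#' @param jitter_frac SD of multiplicative amplitude jitter (default 0,
#'   i.e. deterministic).
#' @return Numeric vector of length `round(trial_duration_s *
#'   frame_rate_hz)`, nonnegative.
#' @export
make_firing_rate <- function(onset_s, duration_s, concentration_pct_svp,
                             gain, frame_rate_hz = 25,
                             trial_duration_s = 30,
                             adaptation_frac = 0.2,
                             rise_tau_s = 0.15, fall_tau_s = 0.6,
                             seed = NULL, jitter_frac = 0) {
  stopifnot(duration_s > 0)
  if (gain < 0)
    stop("invalid parameter: gain must be >= 0", call. = FALSE)
  n <- round(trial_duration_s * frame_rate_hz)
  t <- (seq_len(n) - 1) / frame_rate_hz
  r <- numeric(n)
  if (concentration_pct_svp == 0 || gain == 0) return(r)

  offset_s <- onset_s + duration_s
  during <- t >= onset_s & t < offset_s
  td <- t[during] - onset_s
  plateau <- (1 - adaptation_frac) + adaptation_frac * exp(-td / 2)
  r[during] <- (1 - exp(-td / rise_tau_s)) * plateau

  after <- t >= offset_s & t < offset_s + 3
  r_off <- (1 - exp(-duration_s / rise_tau_s)) *
    ((1 - adaptation_frac) + adaptation_frac * exp(-duration_s / 2))
  r[after] <- r_off * exp(-(t[after] - offset_s) / fall_tau_s)

  r <- r / max(r)
  amp <- gain
  if (jitter_frac > 0) {
    if (!is.null(seed)) set.seed(seed)
    amp <- gain * max(0, 1 + stats::rnorm(1, 0, jitter_frac))
  }
  amp * r
}

# Branching random-walk vessel tree for one hemisphere, dilated to 2-5 px
# width: sparse arterial-like geometry for the SD-threshold ROIs to find.
make_vessel_mask <- function(height, width, n_vessels = 4L) {
  mask <- matrix(FALSE, height, width)
  stamp <- function(r, c, rad) {
    for (dr in -rad:rad) for (dc in -rad:rad) {
      if (dr * dr + dc * dc <= rad * rad) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= height && cc >= 1 && cc <= width)
          mask[rr, cc] <<- TRUE
      }
    }
  }
  walk <- function(r, c, dir, len, rad) {
    for (i in seq_len(len)) {
      stamp(round(r), round(c), rad)
      dir <- dir + stats::rnorm(1, 0, 0.25)
      r <- r + sin(dir); c <- c + cos(dir)
      if (r < 2 || r > height - 1 || c < 2 || c > width - 1) break
      if (stats::runif(1) < 0.02 && rad > 1)  # occasional side branch
        walk(r, c, dir + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1),
             round(len / 2), rad - 1L)
    }
  }
  for (v in seq_len(n_vessels)) {
    walk(stats::runif(1, height * 0.15, height * 0.85),
         stats::runif(1, width * 0.15, width * 0.85),
         stats::runif(1, 0, 2 * pi),
         round(stats::runif(1, 0.4, 0.7) * height),
         sample(1:2, 1))
  }
  mask
}

#' Ground truth for a synthetic session
#'
#' Derives the fixed ground-truth structure (vessel masks per hemisphere,
#' true HRF, gains, drift/noise parameters, firing-rate generator) from a
#' [synth_config()]. Vessel geometry is drawn with `config$structure_seed`,
#' so the structure is identical across session noise seeds.
#'
#' @param config A [synth_config()].
#' @param seed Session noise seed recorded for provenance.
#' @return Object of class `session_ground_truth` with fields
#'   `vessel_mask` (list LEFT/RIGHT plus combined), `true_hrf`, `ca_tau_s`,
#'   `conc_gain`, `bleach_tau_s`, `bleach_amp_frac`, `noise_sd_frac`,
#'   `age_gain_per_month`, `genotype_gain`, `firing_rate_fn` (function of
#'   concentration and frame rate) and the scale factors of the forward
#'   model.
#' @export
session_ground_truth <- function(config = synth_config(), seed = 1L) {
  h <- config$image_size[1]; w <- config$image_size[2]
  half <- floor(w / 2)
  old <- .Random.seed_save()
  set.seed(config$structure_seed)
  left <- make_vessel_mask(h, half, config$n_vessels)
  right <- make_vessel_mask(h, w - half, config$n_vessels)
  .Random.seed_restore(old)
  vm <- matrix(FALSE, h, w)
  vm[, seq_len(half)] <- left
  vm[, (half + 1):w] <- right
  stopifnot(any(left), any(right))

  fr_fn <- function(concentration, frame_rate_hz, gain = NULL) {
    g <- if (!is.null(gain)) gain else if (concentration == 0) 0 else
      config$conc_gain[[as.character(concentration)]]
    make_firing_rate(config$odor_onset_s, config$odor_duration_s,
                     concentration, g, frame_rate_hz,
                     config$trial_duration_s, config$adaptation_frac)
  }

  # Forward-model scale factors, fixed at the highest-concentration
  # reference so responses stay linear in the firing rate.
  ref_conc <- max(config$concentrations)
  ref_gain <- max(config$conc_gain)
  scale_for <- function(rate_hz, kernel_fn) {
    r_ref <- fr_fn(ref_conc, rate_hz, gain = ref_gain)
    tk <- (seq_len(round(config$trial_duration_s * rate_hz)) - 1) / rate_hz
    peak <- max(abs(conv_causal(r_ref, kernel_fn(tk), 1 / rate_hz)))
    peak
  }
  ca_kernel <- function(t) exp(-t / config$ca_tau_s)
  bv_kernel <- function(t) gamma_variate(t, config$true_hrf)
  structure(list(
    vessel_mask = list(LEFT = left, RIGHT = right, FULL = vm),
    true_hrf = config$true_hrf, ca_tau_s = config$ca_tau_s,
    conc_gain = config$conc_gain,
    bleach_tau_s = config$bleach_tau_s,
    bleach_amp_frac = config$bleach_amp_frac,
    noise_sd_frac = config$noise_sd_frac,
    age_gain_per_month = config$age_gain_per_month,
    genotype_gain = config$genotype_gain,
    firing_rate_fn = fr_fn,
    ca_scale = (config$ca_peak_dff / 100) /
      scale_for(config$ca_rate_hz, ca_kernel),
    bv_scale = (abs(config$bv_peak_dff) / 100) /
      scale_for(config$bv_rate_hz, bv_kernel),
    config = config, seed = as.integer(seed)),
    class = "session_ground_truth")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Noiseless fractional modulation s(t) for one trial/channel: the signed
# dF/F (as a fraction, not %) every in-mask pixel follows.
trial_modulation <- function(truth, concentration, channel,
                             subject = truth$config$subject) {
  cfg <- truth$config
  rate_hz <- if (channel == "BV590") cfg$bv_rate_hz else cfg$ca_rate_hz
  amp_mult <- if (identical(subject$genotype, "A4T2")) {
    max(0.1, truth$genotype_gain *
          (1 + truth$age_gain_per_month * (subject$age_months - 12)))
  } else 1
  r <- truth$firing_rate_fn(concentration, rate_hz) * amp_mult
  n <- round(cfg$trial_duration_s * rate_hz)
  tk <- (seq_len(n) - 1) / rate_hz
  if (channel == "BV590") {
    -truth$bv_scale * conv_causal(r, gamma_variate(tk, truth$true_hrf),
                                  1 / rate_hz)
  } else {
    truth$ca_scale * conv_causal(r, exp(-tk / truth$ca_tau_s), 1 / rate_hz)
  }
}

#' Synthesize one trial movie
#'
#' Forward model: pixels inside the hemisphere vessel masks follow
#' `baseline * (1 + s(t)) * bleach(t) + noise`, where for the calcium
#' channel `s(t)` is the firing rate convolved with the GCaMP6f
#' single-exponential decay kernel (positive dF/F) and for the blood-volume
#' channel it is the firing rate convolved with the true gamma-variate HRF,
#' sign-flipped (reflectance at 590 nm decreases when blood volume
#' increases). Pixels outside the masks carry baseline, drift and noise
#' only.
#'
#' @param truth A [session_ground_truth()].
#' @param meta List with `odorant`, `concentration_pct_svp`, `trial_id`,
#'   and optionally `subject` (defaults to the config's subject).
#' @param channel `"BV590"` or `"CA488"`.
#' @return A [trial_movie()].
#' @export
synthesize_trial <- function(truth, meta, channel) {
  stopifnot(inherits(truth, "session_ground_truth"))
  channel <- match.arg(channel, c("BV590", "CA488"))
  cfg <- truth$config
  subject <- meta$subject %||% cfg$subject
  rate_hz <- if (channel == "BV590") cfg$bv_rate_hz else cfg$ca_rate_hz
  n <- round(cfg$trial_duration_s * rate_hz)
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  s <- trial_modulation(truth, meta$concentration_pct_svp, channel, subject)
  tk <- (seq_len(n) - 1) / rate_hz
  bleach <- 1 - truth$bleach_amp_frac * (1 - exp(-tk / truth$bleach_tau_s))

  vm <- truth$vessel_mask$FULL
  # per-pixel time course: baseline*(1 + s*mask)*bleach (+ noise below)
  base_tc <- cfg$baseline * (1 + outer(s, as.numeric(vm))) * bleach
  frames <- array(base_tc, dim = c(n, h, w))
  if (truth$noise_sd_frac > 0) {
    frames <- frames + stats::rnorm(length(frames), 0,
                                    truth$noise_sd_frac * cfg$baseline)
    frames[frames < 0] <- 0
  }
  trial_movie(frames, rate_hz, channel,
              odorant = meta$odorant,
              concentration_pct_svp = meta$concentration_pct_svp,
              odor_onset_s = cfg$odor_onset_s,
              odor_duration_s = cfg$odor_duration_s,
              subject = subject, trial_id = meta$trial_id)
}

#' Synthesize a complete imaging session
#'
#' Emits, per odorant, `n_controls` control trials followed by
#' `n_reps x length(concentrations)` odor trials at increasing
#' concentration (defaults: 3 control + 9 EB + 3 control + 9 MV = 24
#' blood-volume trials, so pooling odorants gives 6 trials per nonzero
#' concentration), plus matching calcium trials when `"CA488"` is in
#' `config$channels`. Bit-identical output for identical `(config, seed)`;
#' different seeds share identical ground-truth structure and differ only
#' in noise.
#'
#' @param config A [synth_config()].
#' @param seed Integer noise seed.
#' @return List with `trials` (list of [trial_movie()]) and `truth`
#'   (the [session_ground_truth()] used).
#' @export
synthesize_session <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  truth <- session_ground_truth(config, seed)
  metas <- list()
  k <- 0L
  for (od in config$odorants) {
    for (i in seq_len(config$n_controls)) {
      k <- k + 1L
      metas[[k]] <- list(odorant = "control", concentration_pct_svp = 0,
                         trial_id = sprintf("%s_ctrl%02d", od, i))
    }
    for (conc in config$concentrations) {
      for (i in seq_len(config$n_reps)) {
        k <- k + 1L
        metas[[k]] <- list(odorant = od, concentration_pct_svp = conc,
                           trial_id = sprintf("%s_c%s_r%d", od, conc, i))
      }
    }
  }
  old <- .Random.seed_save()
  set.seed(seed)
  trials <- list()
  for (m in metas) {
    for (ch in config$channels) {
      tm <- synthesize_trial(truth, m, ch)
      tm$trial_id <- paste0(m$trial_id, "_", ch)
      trials[[length(trials) + 1L]] <- tm
    }
  }
  .Random.seed_restore(old)
  list(trials = trials, truth = truth)
}
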