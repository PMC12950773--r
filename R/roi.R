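#' Per-pixel, per-trial response consistency statistics
#'
#' For each pixel and trial computes the baseline SD of dF/F (over the
#' pre-odor `baseline_window`), the response metric (mean dF/F over
#' `response_window`, or the signed extremum when `metric = "peak"`), and
#' the threshold exceedance flags used by the consistency ROI rule. A
#' blood-volume *increase* is a reflectance *decrease* at 590 nm, so
#' exceedance is `(-response_metric) > k * baseline_sd` (strict), for
#' k in \{1, 3\}.
#'
#' @param dff_trials List of [compute_dff()] movies sharing geometry and
#'   concentration (6 at protocol defaults: 3 repetitions x 2 odorants).
#' @param baseline_window Frame indices for the baseline SD (default: all
#'   pre-onset frames).
#' @param response_window Frame indices for the response metric (default:
#'   odor onset to onset + 10 s, matching the AUC window).
#' @param metric `"mean"` (default) or `"peak"` (most-negative dF/F in the
#'   window).
#' @param detrend Remove per-pixel exponential drift
#'   ([detrend_dff_movie()]) before computing the statistics (default
#'   TRUE; LED/bleach drift otherwise confounds the response-window mean
#'   against the baseline SD).
#' @return Object of class `pixel_response_stats`: arrays `baseline_sd`,
#'   `response_metric` (height x width x trial), logical exceedance arrays
#'   `exceed_k1`, `exceed_k3`, the invalid-pixel mask, and `n_trials`.
#' @export
pixel_response_stats <- function(dff_trials, baseline_window = NULL,
                                 response_window = NULL,
                                 metric = c("mean", "peak"),
                                 detrend = TRUE) {
  metric <- match.arg(metric)
  if (detrend) dff_trials <- lapply(dff_trials, detrend_dff_movie)
  stopifnot(length(dff_trials) >= 1,
            all(vapply(dff_trials, inherits, TRUE, "dff_movie")))
  dims <- lapply(dff_trials, function(d) dim(d$values)[2:3])
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("trial geometries do not match", call. = FALSE)
  d1 <- dff_trials[[1]]
  h <- dim(d1$values)[2]; w <- dim(d1$values)[3]
  nt <- length(dff_trials)
  rate <- d1$frame_rate_hz
  onset_frame <- floor(d1$odor_onset_s * rate)
  if (is.null(baseline_window)) baseline_window <- seq_len(onset_frame)
  if (is.null(response_window))
    response_window <- (onset_frame + 1):min(onset_frame + round(10 * rate),
                                             dim(d1$values)[1])

  bsd <- array(NA_real_, c(h, w, nt))
  resp <- array(NA_real_, c(h, w, nt))
  invalid <- matrix(FALSE, h, w)
  for (i in seq_len(nt)) {
    v <- dff_trials[[i]]$values
    bsd[, , i] <- apply(v[baseline_window, , , drop = FALSE], c(2, 3),
                        stats::sd)
    resp[, , i] <- if (metric == "mean") {
      apply(v[response_window, , , drop = FALSE], c(2, 3), mean)
    } else {
      apply(v[response_window, , , drop = FALSE], c(2, 3), min)
    }
    invalid <- invalid | dff_trials[[i]]$invalid_px
  }
  ex1 <- (-resp) > 1 * bsd
  ex3 <- (-resp) > 3 * bsd
  ex1[is.na(ex1)] <- FALSE
  ex3[is.na(ex3)] <- FALSE
  structure(list(baseline_sd = bsd, response_metric = resp,
                 exceed_k1 = ex1, exceed_k3 = ex3,
                 invalid_px = invalid, n_trials = nt,
                 baseline_window = baseline_window,
                 response_window = response_window, metric = metric),
            class = "pixel_response_stats")
}

#' Consistency-thresholded ROI masks
#'
#' Includes a pixel when its blood-volume increase exceeded `k_sd` baseline
#' SDs in at least `min_trials` of the trials (the two standard rules are
#' 1 SD in 4/6 trials and 3 SD in 3/6 trials). Returns one mask per
#' hemisphere, split at the vertical midline; an empty mask is returned
#' with a warning flag rather than an error.
#'
#' @param stats A [pixel_response_stats()].
#' @param k_sd 1 or 3.
#' @param min_trials Minimum exceedance count (<= `stats$n_trials`).
#' @return Named list of two [roi_mask()]s (`LEFT`, `RIGHT`).
#' @export
consistency_mask <- function(stats, k_sd, min_trials) {
  stopifnot(inherits(stats, "pixel_response_stats"),
            k_sd %in% c(1, 3), min_trials <= stats$n_trials)
  ex <- if (k_sd == 1) stats$exceed_k1 else stats$exceed_k3
  counts <- apply(ex, c(1, 2), sum)
  full <- counts >= min_trials & !stats$invalid_px
  kind <- if (k_sd == 1) "SD1" else "SD3"
  h <- nrow(full); w <- ncol(full)
  half <- floor(w / 2)
  split_mask <- function(hemi) {
    m <- matrix(FALSE, h, w)
    cols <- if (hemi == "LEFT") seq_len(half) else (half + 1):w
    m[, cols] <- full[, cols]
    if (!any(m))
      warning(sprintf("%s %s mask is empty", kind, hemi), call. = FALSE)
    roi_mask(m, kind, hemi, k_sd = k_sd,
             min_trials = as.integer(min_trials),
             n_trials = as.integer(stats$n_trials),
             empty_warning = !any(m))
  }
  list(LEFT = split_mask("LEFT"), RIGHT = split_mask("RIGHT"))
}

#' Rectangular (unthresholded) ROI masks
#'
#' One axis-aligned rectangle per hemisphere covering a large section of
#' each dorsal bulb, with no statistical assumptions. Default bounds inset
#' each hemisphere by 10% of its span.
#'
#' @param geometry Integer c(height, width) of the image.
#' @param bounds_per_hemisphere Named list `LEFT`/`RIGHT`, each
#'   c(row1, row2, col1, col2) (1-based, inclusive); `NULL` for the
#'   default inset rectangles.
#' @return Named list of two [roi_mask()]s.
#' @export
rect_mask <- function(geometry, bounds_per_hemisphere = NULL) {
  h <- geometry[1]; w <- geometry[2]
  half <- floor(w / 2)
  if (is.null(bounds_per_hemisphere)) {
    inset <- function(c1, c2) {
      dr <- max(1, round(0.1 * h)); dc <- max(1, round(0.1 * (c2 - c1 + 1)))
      c(1 + dr, h - dr, c1 + dc, c2 - dc)
    }
    bounds_per_hemisphere <- list(LEFT = inset(1, half),
                                  RIGHT = inset(half + 1, w))
  }
  mk <- function(hemi) {
    b <- bounds_per_hemisphere[[hemi]]
    if (any(b < 1) || b[2] > h || b[4] > w)
      stop("rectangle bounds outside image", call. = FALSE)
    if (b[1] >= b[2] || b[3] >= b[4])
      stop("degenerate rectangle", call. = FALSE)
    m <- matrix(FALSE, h, w)
    m[b[1]:b[2], b[3]:b[4]] <- TRUE
    roi_mask(m, "RECT", hemi)
  }
  list(LEFT = mk("LEFT"), RIGHT = mk("RIGHT"))
}

#' Extract the ROI-mean trace from a dF/F movie
#'
#' Unweighted mean over the included pixels per frame.
#'
#' @param dff_movie A [compute_dff()] movie.
#' @param mask A [roi_mask()] (or plain logical matrix) with at least one
#'   included pixel.
#' @return Numeric vector, one value per frame (dF/F %).
#' @export
extract_roi_trace <- function(dff_movie, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stopifnot(is.logical(m),
            all(dim(m) == dim(dff_movie$values)[2:3]))
  if (!any(m)) stop("empty mask", call. = FALSE)
  n <- dim(dff_movie$values)[1]
  flat <- matrix(dff_movie$values, nrow = n)
  rowMeans(flat[, as.vector(m), drop = FALSE])
}

#' Jaccard index between two masks
#'
#' Intersection over union of two logical matrices (used to score ROI
#' recovery against the synthetic ground-truth vessel mask).
#'
#' @param a,b Logical matrices or [roi_mask()]s of equal size.
#' @return A number in \[0, 1\] (1 when both masks are empty).
#' @export
mask_jaccard <- function(a, b) {
  ma <- if (inherits(a, "roi_mask")) a$mask else a
  mb <- if (inherits(b, "roi_mask")) b$mask else b
  stopifnot(all(dim(ma) == dim(mb)))
  un <- sum(ma | mb)
  if (un == 0) return(1)
  sum(ma & mb) / un
}
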