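#' Area under the curve of an odor response
#'
#' Plain frame-sum of dF/F% over `round(window_s * frame_rate_hz)` frames
#' starting at odor onset (70 frames at the 10 s / 7 Hz defaults). No
#' dt multiplication: the unit is %·frames, and the sign is preserved, so
#' blood-volume reflectance responses yield *negative* AUC (more negative
#' = larger blood-volume response).
#'
#' @param values Numeric dF/F trace in % (as acquired; the blood-volume
#'   AUC is conventionally computed on the 7 Hz trace).
#' @param onset_index 1-based index of the odor-onset frame.
#' @param frame_rate_hz Sampling rate of `values`.
#' @param window_s Integration window in seconds (default 10).
#' @return AUC in %·frames.
#' @export
auc <- function(values, onset_index, frame_rate_hz, window_s = 10) {
  nwin <- round(window_s * frame_rate_hz)
  if (onset_index + nwin - 1 > length(values))
    stop("integration window exceeds the trace", call. = FALSE)
  sum(values[onset_index:(onset_index + nwin - 1)])
}

#' Neurovascular coupling ratio
#'
#' Ratio of the blood-volume to calcium response magnitudes, computed on
#' *oriented* values (blood volume positive-going) so a normal response
#' gives a positive ratio. Scale-invariant: rescaling both AUCs by a
#' common factor leaves the ratio unchanged.
#'
#' @param bv_auc Oriented blood-volume AUC (or amplitude).
#' @param ca_auc Calcium AUC (or amplitude); magnitude must exceed
#'   `floor`.
#' @param floor Denominator floor below which the ratio is undefined
#'   (default 1e-9).
#' @return List `ratio` (NA when undefined) and `defined` flag.
#' @export
coupling_ratio <- function(bv_auc, ca_auc, floor = 1e-9) {
  if (abs(ca_auc) < floor)
    return(list(ratio = NA_real_, defined = FALSE))
  list(ratio = bv_auc / ca_auc, defined = TRUE)
}

#' Concentration-response slope and fold change
#'
#' Per subject, ordinary least-squares slope of a response metric versus
#' odor concentration on the linear % SVP scale (optionally log10), plus
#' the fold change between the highest and lowest concentration. Across
#' subjects, a one-sided one-sample t-test of slopes > 0 (skipped, with a
#' message in the result, when fewer than 3 subjects are available).
#'
#' @param data data.frame with columns `subject`, `concentration`,
#'   `value` (>= 2 concentrations per subject).
#' @param log_scale Regress on log10(concentration) instead of the linear
#'   scale (default FALSE).
#' @return List: `slopes` (per-subject data.frame with slope and
#'   fold_change), `mean_slope`, `t_statistic`, `p_one_sided` (NA when
#'   skipped), `mean_fold_change`, `sd_fold_change`.
#' @export
concentration_slope <- function(data, log_scale = FALSE) {
  stopifnot(all(c("subject", "concentration", "value") %in% names(data)))
  subjects <- unique(data$subject)
  rows <- lapply(subjects, function(s) {
    d <- data[data$subject == s, ]
    if (length(unique(d$concentration)) < 2)
      stop("need >= 2 concentrations per subject", call. = FALSE)
    x <- if (log_scale) log10(d$concentration) else d$concentration
    sl <- unname(stats::coef(stats::lm(d$value ~ x))[2])
    cmin <- min(d$concentration); cmax <- max(d$concentration)
    fc <- mean(d$value[d$concentration == cmax]) /
      mean(d$value[d$concentration == cmin])
    data.frame(subject = s, slope = sl, fold_change = fc,
               stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, rows)
  tt <- if (nrow(slopes) >= 3) {
    if (stats::sd(slopes$slope) == 0) {
      # degenerate one-sample test; p is the sign-determined limit
      m <- mean(slopes$slope)
      if (abs(m) < 1e-12) m <- 0
      list(statistic = c(t = sign(m) * Inf),
           p.value = if (m > 0) 0 else if (m < 0) 1 else 0.5)
    } else {
      stats::t.test(slopes$slope, mu = 0, alternative = "greater")
    }
  } else NULL
  list(slopes = slopes,
       mean_slope = mean(slopes$slope),
       sd_slope = stats::sd(slopes$slope),
       t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       p_one_sided = if (is.null(tt)) NA_real_ else tt$p.value,
       mean_fold_change = mean(slopes$fold_change),
       sd_fold_change = stats::sd(slopes$fold_change))
}

#' Age regression of response magnitude per genotype
#'
#' Ordinary least squares of per-mouse AUC versus age in months, fitted
#' separately per genotype group. The slope is reported both raw (AUC
#' units/month) and normalized as % of the group-mean |AUC| per month
#' (`slope_pct_per_month = 100 * slope / mean(|AUC|)`), the normalization
#' convention also recorded in the output.
#'
#' @param data data.frame with columns `auc`, `age_months`, `group`
#'   (>= 3 mice per group, non-degenerate ages).
#' @return data.frame, one row per group: `slope`, `slope_pct_per_month`,
#'   `r_squared`, `n`, `normalization`.
#' @export
age_regression <- function(data) {
  stopifnot(all(c("auc", "age_months", "group") %in% names(data)))
  rows <- lapply(split(data, data$group), function(d) {
    if (nrow(d) < 3) stop("need >= 3 mice per group", call. = FALSE)
    if (stats::sd(d$age_months) == 0)
      stop("degenerate ages in group ", d$group[1], call. = FALSE)
    m <- stats::lm(auc ~ age_months, data = d)
    sl <- unname(stats::coef(m)[2])
    data.frame(group = d$group[1], slope = sl,
               slope_pct_per_month = 100 * sl / mean(abs(d$auc)),
               r_squared = summary(m)$r.squared, n = nrow(d),
               normalization = "percent of group mean |AUC| per month",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
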