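#' Names of the 13 time-domain activation features
#' @export
TIME_FEATURES <- c("mean", "sd", "var", "cv", "range", "peak", "ttp",
                   "centroid", "auc", "onset_slope", "recovery_slope",
                   "skewness", "kurtosis")

#' Time-domain activation features
#'
#' Computes 13 scalar activation statistics from the task period of the
#' subject's prefrontal dHbO trace. Channels are averaged first (in-use
#' channels that survived QC), giving a single PFC trace, so the feature
#' count stays at 13 per subject. Features of the task-period trace x(t),
#' t in seconds from task onset:
#' mean, standard deviation, variance, coefficient of variation (sd/mean, 0
#' for a zero-mean trace), min-max range, peak amplitude (maximum), time to
#' peak (s), power-weighted centroid time sum(t x^2)/sum(x^2) (s), area under
#' the curve (trapezoidal), onset slope (least squares over the first
#' `slope_window_s` of the task), recovery slope (least squares over the
#' first `slope_window_s` after task offset), skewness, and excess kurtosis
#' (both 0 for a zero-variance trace). Amplitude-bearing features are
#' reported in micromolar (the field's customary unit for activation
#' statistics): mean/sd/range/peak/slopes in uM (or uM/s), variance in uM^2,
#' AUC in uM s; times in seconds.
#'
#' @param hb Baseline-corrected `nirs_hemo`.
#' @param paradigm The task paradigm (defaults to the recording's own).
#' @param channels Channels to average; typically the in-use channels kept by
#'   QC. Must be nonempty.
#' @param slope_window_s Window for the onset/recovery slopes (default 10 s).
#' @return Named numeric vector of length 13.
#' @export
extract_time_features <- function(hb, paradigm = hb$paradigm,
                                  channels = rownames(hb$hbo),
                                  slope_window_s = 10) {
  stopifnot(inherits(hb, "nirs_hemo"))
  channels <- intersect(channels, rownames(hb$hbo))
  if (!length(channels))
    stop_nirs("no usable channels remain for feature extraction (subject ",
              hb$subject_id, ")")
  fs <- paradigm$sampling_rate
  trace <- 1e6 * colMeans(hb$hbo[channels, , drop = FALSE])   # molar -> uM
  on_s <- task_onset_s(paradigm); off_s <- task_offset_s(paradigm)
  ti <- window_idx(paradigm, on_s, off_s)
  x <- trace[ti]
  t_rel <- (ti - ti[1]) / fs                       # seconds from task onset
  m <- mean(x); s <- stats::sd(x)
  p2 <- sum(x^2)
  centroid <- if (p2 > 0) sum(t_rel * x^2) / p2 else mean(t_rel)
  slope_i <- window_idx(paradigm, on_s, on_s + slope_window_s)
  rec_i <- window_idx(paradigm, off_s, off_s + slope_window_s)
  slope_of <- function(idx) {
    tt <- (idx - idx[1]) / fs
    stats::cov(tt, trace[idx]) / stats::var(tt)
  }
  out <- c(mean = m, sd = s, var = stats::var(x),
           cv = if (abs(m) > 0) s / m else 0,
           range = diff(range(x)), peak = max(x),
           ttp = t_rel[which.max(x)], centroid = centroid,
           auc = trapz_int(t_rel, x),
           onset_slope = slope_of(slope_i), recovery_slope = slope_of(rec_i),
           skewness = moment_skewness(x), kurtosis = moment_kurtosis(x))
  stopifnot(identical(names(out), TIME_FEATURES))
  out
}
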