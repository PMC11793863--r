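#' Linear detrending
#'
#' Removes the least-squares line from every channel/wavelength trace,
#' eliminating slow drift; the output has zero fitted slope.
#'
#' @param od A `nirs_od` with at least two samples.
#' @return Detrended `nirs_od`.
#' @export
detrend_linear <- function(od) {
  stopifnot(inherits(od, "nirs_od"))
  n <- dim(od$od)[3]
  if (n < 2L) stop_nirs("at least 2 samples are required to detrend")
  t <- seq_len(n)
  tc <- t - mean(t)
  stt <- sum(tc^2)
  out <- od$od
  for (ch in seq_len(dim(out)[1])) for (wl in seq_len(dim(out)[2])) {
    x <- out[ch, wl, ]
    slope <- sum(tc * x) / stt
    out[ch, wl, ] <- x - mean(x) - slope * tc
  }
  od_update(od, out, detrended = TRUE)
}

#' Butterworth band-pass filtering
#'
#' Cascade of a 5th-order Butterworth high-pass at `low` Hz and a 3rd-order
#' low-pass at `high` Hz, each applied forward-backward (zero phase) so task
#' timing is not shifted. The default 0.01-0.1 Hz band isolates the
#' task-evoked hemodynamic response from drift, Mayer waves at the upper band
#' edge, and respiratory/cardiac oscillations.
#'
#' @param od A `nirs_od`.
#' @param low,high Band edges in Hz (0 < low < high < Nyquist).
#' @param lp_order,hp_order Filter orders (defaults 3 and 5).
#' @return Filtered `nirs_od`.
#' @export
bandpass <- function(od, low = 0.01, high = 0.1, lp_order = 3, hp_order = 5) {
  stopifnot(inherits(od, "nirs_od"))
  fs <- od$paradigm$sampling_rate
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop_nirs("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  hp <- signal::butter(hp_order, low / nyq, type = "high")
  lp <- signal::butter(lp_order, high / nyq, type = "low")
  out <- od$od
  for (ch in seq_len(dim(out)[1])) for (wl in seq_len(dim(out)[2])) {
    x <- out[ch, wl, ] - mean(out[ch, wl, ])   # DC removed exactly
    x <- signal::filtfilt(hp, x)
    out[ch, wl, ] <- signal::filtfilt(lp, x)
  }
  od_update(od, out, filtered = TRUE)
}

# Two-point linear baseline through (center(w1), mean over w1) and
# (center(w2), mean over w2); returns the baseline evaluated at 1..n.
two_point_baseline <- function(x, w1, w2) {
  c1 <- mean(w1); c2 <- mean(w2)
  if (isTRUE(all.equal(c1, c2)))
    stop_nirs("degenerate baseline windows (identical centers)")
  m1 <- mean(x[w1]); m2 <- mean(x[w2])
  slope <- (m2 - m1) / (c2 - c1)
  m1 + slope * (seq_along(x) - c1)
}

#' Two-point baseline correction
#'
#' Anchors every channel's hemoglobin trace to the two task-relative baseline
#' windows of the paradigm: the line through (center of the pre-task `b1`
#' window, its mean) and (center of the post-task `b2` window, its mean) is
#' subtracted, leaving both window means at zero. Applied to dHbO and dHbR.
#'
#' @param hb A `nirs_hemo`.
#' @param paradigm The paradigm defining the `b1`/`b2` windows (defaults to
#'   the recording's own).
#' @return Baseline-corrected `nirs_hemo`.
#' @export
baseline_correct <- function(hb, paradigm = hb$paradigm) {
  stopifnot(inherits(hb, "nirs_hemo"))
  w1 <- b1_idx(paradigm); w2 <- b2_idx(paradigm)
  for (ch in seq_len(nrow(hb$hbo))) {
    hb$hbo[ch, ] <- hb$hbo[ch, ] - two_point_baseline(hb$hbo[ch, ], w1, w2)
    hb$hbr[ch, ] <- hb$hbr[ch, ] - two_point_baseline(hb$hbr[ch, ], w1, w2)
  }
  hb$flags$baseline_corrected <- TRUE
  hb
}
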