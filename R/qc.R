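# Welch power spectral density: Hann-windowed segments, 50% overlap.
welch_psd <- function(x, fs, nperseg = 256L) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  if (nperseg < 8L) stop_nirs("recording too short for one Welch window")
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)))
  U <- sum(win^2) * fs
  acc <- numeric(nperseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2 / U
    acc <- acc + sp[seq_len(length(acc))]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  psd[-1L] <- psd[-1L] * 2
  if (nperseg %% 2L == 0L) psd[length(psd)] <- psd[length(psd)] / 2
  freq <- (seq_along(psd) - 1L) * fs / nperseg
  list(freq = freq, psd = psd)
}

band_power <- function(welch, lo, hi) {
  sel <- welch$freq > lo & welch$freq < hi
  df <- welch$freq[2] - welch$freq[1]
  sum(welch$psd[sel]) * df
}

#' Channel quality control
#'
#' Computes, per channel, (1) a spectral SNR on the motion-corrected,
#' pre-band-pass optical density -- the Welch band power below 0.1 Hz (the
#' hemodynamic band of interest, DC excluded) divided by the band power above
#' 4.5 Hz (instrument/power-line noise floor) -- and (2) the min-max amplitude
#' of the channel's dHbO trace. In the default mode a channel is discarded
#' when its SNR falls below `snr_thresh` or its amplitude range exceeds
#' `amp_thresh`; `literal = TRUE` instead discards channels whose SNR exceeds
#' the threshold. With two wavelengths the more pessimistic (smaller) SNR of
#' the two is used. Channels whose spectrum carries no power in either band
#' have undefined SNR and are discarded as degenerate.
#'
#' @param od_prefilter Motion-corrected `nirs_od` *before* band-pass filtering
#'   (the band-pass removes the >4.5 Hz reference band).
#' @param hb The subject's `nirs_hemo` (amplitude criterion uses dHbO).
#' @param snr_thresh SNR threshold (default 10).
#' @param amp_thresh Molar amplitude-range threshold (default 1.5e-3).
#' @param literal Use the literal discard direction for the SNR rule.
#' @return A `qc_report` data.frame: `channel`, `snr`, `amp_range`, `keep`,
#'   `reason`.
#' @export
channel_qc <- function(od_prefilter, hb, snr_thresh = 10, amp_thresh = 1.5e-3,
                       literal = FALSE) {
  stopifnot(inherits(od_prefilter, "nirs_od"), inherits(hb, "nirs_hemo"))
  fs <- od_prefilter$paradigm$sampling_rate
  chans <- dimnames(od_prefilter$od)[[1]]
  n <- length(chans)
  snr <- amp <- numeric(n)
  keep <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    snr_wl <- vapply(seq_len(dim(od_prefilter$od)[2]), function(wl) {
      w <- welch_psd(od_prefilter$od[i, wl, ], fs)
      sig <- band_power(w, 0, 0.1)
      noi <- band_power(w, 4.5, Inf)
      if (sig == 0 && noi == 0) NaN else sig / noi
    }, 0)
    snr[i] <- suppressWarnings(min(snr_wl))
    amp[i] <- diff(range(hb$hbo[i, ]))
    if (!is.finite(snr[i]) && !is.nan(snr[i])) snr[i] <- Inf  # zero noise floor
    if (is.nan(snr[i])) {
      keep[i] <- FALSE; reason[i] <- "degenerate"
    } else if (amp[i] > amp_thresh) {
      keep[i] <- FALSE; reason[i] <- "amplitude"
    } else if (!literal && snr[i] < snr_thresh) {
      keep[i] <- FALSE; reason[i] <- "snr"
    } else if (literal && snr[i] > snr_thresh) {
      keep[i] <- FALSE; reason[i] <- "snr"
    } else {
      keep[i] <- TRUE; reason[i] <- ""
    }
  }
  structure(data.frame(channel = chans, snr = snr, amp_range = amp,
                       keep = keep, reason = reason, stringsAsFactors = FALSE),
            class = c("qc_report", "data.frame"))
}

#' Full preprocessing chain for one recording
#'
#' Runs the fixed order: optical density, motion detection, spline then
#' wavelet motion correction, linear detrend, Butterworth band-pass,
#' MBLL conversion, two-point baseline correction, channel QC.
#'
#' @param rec A `nirs_recording`.
#' @param montage A `nirs_montage`.
#' @param motion,qc Optional lists overriding [detect_motion()] and
#'   [channel_qc()] defaults.
#' @param extinction,coeffs Passed to [od_to_hemoglobin()].
#' @return List with `hb` (baseline-corrected `nirs_hemo`), `qc`
#'   (`qc_report`), and `od_prefilter` (motion-corrected OD).
#' @export
preprocess_recording <- function(rec, montage, motion = list(), qc = list(),
                                 extinction = extinction_table(),
                                 coeffs = dpf_coefficients()) {
  od <- intensity_to_od(rec)
  mask <- do.call(detect_motion, c(list(od), motion))
  od <- correct_motion_spline(od, mask)
  od <- correct_motion_wavelet(od)
  od_mc <- od                              # pre-band-pass OD for the QC SNR
  od <- detrend_linear(od)
  od <- bandpass(od)
  hb <- od_to_hemoglobin(od, montage, extinction = extinction, coeffs = coeffs)
  hb <- baseline_correct(hb)
  qcr <- do.call(channel_qc, c(list(od_mc, hb), qc))
  list(hb = hb, qc = qcr, od_prefilter = od_mc)
}
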