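#' Motion artifact detection
#'
#' Flags samples where the optical-density signal changes too quickly: within
#' any sliding window of length `t_motion` seconds, a peak-to-peak excursion
#' exceeding `std_thresh` times the channel's robust standard deviation
#' (1.4826 MAD, so that the artifacts themselves do not inflate the
#' reference scale) or exceeding `amp_thresh` (OD units) marks the window as
#' artifact. Flags are dilated by
#' `t_mask` seconds on both sides. A channel is flagged when either wavelength
#' trips the detector.
#'
#' @param od A `nirs_od`.
#' @param t_motion Detection window length in seconds (default 0.5).
#' @param t_mask Dilation of detected segments in seconds (default 1).
#' @param std_thresh Threshold in channel standard deviations (default 20).
#' @param amp_thresh Absolute OD excursion threshold (default 5).
#' @return Logical matrix `channel x time`; `TRUE` marks artifact samples.
#' @export
detect_motion <- function(od, t_motion = 0.5, t_mask = 1.0,
                          std_thresh = 20, amp_thresh = 5) {
  stopifnot(inherits(od, "nirs_od"))
  if (t_motion <= 0 || t_mask < 0 || std_thresh <= 0 || amp_thresh <= 0)
    stop_nirs("motion detection thresholds must be positive")
  fs <- od$paradigm$sampling_rate
  n <- dim(od$od)[3]
  w <- max(2L, as.integer(round(t_motion * fs)))
  if (w >= n) stop_nirs("t_motion (", t_motion, " s) is not shorter than the recording")
  pad <- as.integer(round(t_mask * fs))
  nch <- dim(od$od)[1]
  mask <- matrix(FALSE, nch, n, dimnames = list(dimnames(od$od)[[1]], NULL))
  for (ch in seq_len(nch)) for (wl in seq_len(dim(od$od)[2])) {
    x <- od$od[ch, wl, ]
    sdx <- stats::mad(x)
    if (sdx == 0) sdx <- stats::sd(x)
    shifted <- lapply(0:(w - 1L), function(m) x[(1L + m):(n - w + 1L + m)])
    rng <- do.call(pmax, shifted) - do.call(pmin, shifted)
    hit <- which(rng > std_thresh * sdx | rng > amp_thresh)
    if (!length(hit)) next
    for (t0 in hit) {
      lo <- max(1L, t0 - pad)
      hi <- min(n, t0 + w - 1L + pad)
      mask[ch, lo:hi] <- TRUE
    }
  }
  mask
}

mask_segments <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Segment-wise spline motion correction
#'
#' Within each flagged artifact segment a smoothing-spline fit is subtracted
#' and the segment is re-levelled to the mean of the preceding clean segment
#' (the following one for an artifact at the recording start). Samples outside
#' flagged segments are unchanged. The smoothing parameter `p` in (0, 1]
#' controls fidelity of the spline to the artifact shape; values near 1
#' approach interpolation, so the artifact is removed almost entirely and the
#' segment collapses onto the surrounding level.
#'
#' @param od A `nirs_od`.
#' @param mask Artifact mask from [detect_motion()].
#' @param p Smoothing parameter in (0, 1] (default 0.99).
#' @return Corrected `nirs_od` with `motion_corrected` provenance set.
#' @export
correct_motion_spline <- function(od, mask, p = 0.99) {
  stopifnot(inherits(od, "nirs_od"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop_nirs("spline smoothing parameter p must be in (0, 1]")
  out <- od$od
  fs <- od$paradigm$sampling_rate
  level_w <- max(1L, as.integer(round(2 * fs)))   # level window: up to 2 s
  spar <- 1.5 * (1 - p)                           # p -> 1 approaches interpolation
  for (ch in seq_len(dim(out)[1])) {
    segs <- mask_segments(mask[ch, ])
    if (!nrow(segs)) next
    for (wl in seq_len(dim(out)[2])) {
      x <- out[ch, wl, ]
      n <- length(x)
      for (s in seq_len(nrow(segs))) {
        i0 <- segs$start[s]; i1 <- segs$end[s]
        seg <- x[i0:i1]
        fit <- if (length(seg) >= 4L)
          stats::smooth.spline(seq_along(seg), seg, spar = spar,
                               all.knots = TRUE)$y
        else seg
        resid <- seg - fit
        ref <- if (i0 > 1L) {
          prev0 <- max(1L, i0 - level_w)
          clean <- !mask[ch, prev0:(i0 - 1L)]
          if (any(clean)) mean(x[prev0:(i0 - 1L)][clean]) else NA_real_
        } else NA_real_
        if (is.na(ref) && i1 < n) {
          nxt1 <- min(n, i1 + level_w)
          clean <- !mask[ch, (i1 + 1L):nxt1]
          ref <- if (any(clean)) mean(x[(i1 + 1L):nxt1][clean]) else NA_real_
        }
        if (is.na(ref)) ref <- mean(seg)
        x[i0:i1] <- resid + ref
      }
      out[ch, wl, ] <- x
    }
  }
  od_update(od, out, motion_corrected = TRUE)
}

# ---- Daubechies-4 discrete wavelet transform (periodized) -----------------

DB4_H <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
DB4_G <- rev(DB4_H) * c(1, -1, 1, -1)

dwt_step <- function(x) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  base <- 2L * seq_len(half) - 2L
  for (m in 0:3) {
    idx <- (base + m) %% n + 1L
    a <- a + DB4_H[m + 1L] * x[idx]
    d <- d + DB4_G[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * seq_len(half) - 2L
  for (m in 0:3) {
    idx <- (base + m) %% n + 1L
    contrib <- DB4_H[m + 1L] * a + DB4_G[m + 1L] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

# C1-continuous cubic Hermite bridge from x[n] back to x[1], so the
# periodized transform sees no boundary discontinuity.
pad_periodic <- function(x, n2) {
  n <- length(x)
  k <- n2 - n
  if (k <= 0) return(x)
  if (n < 2L) return(c(x, rep(x[1], k)))
  s0 <- x[n]; s1 <- x[1]
  m0 <- (x[n] - x[n - 1]) * (k + 1)
  m1 <- (x[2] - x[1]) * (k + 1)
  u <- seq_len(k) / (k + 1)
  bridge <- (2 * u^3 - 3 * u^2 + 1) * s0 + (u^3 - 2 * u^2 + u) * m0 +
    (-2 * u^3 + 3 * u^2) * s1 + (u^3 - u^2) * m1
  c(x, bridge)
}

dwt_db4 <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

idwt_db4 <- function(w) {
  a <- w$approx
  for (j in rev(seq_along(w$details))) a <- idwt_step(a, w$details[[j]])
  a
}

#' Wavelet motion correction
#'
#' Decomposes each channel trace with a periodized Daubechies-4 discrete
#' wavelet transform and zeroes detail coefficients falling outside the
#' interquartile fence of their level (below Q1 - `iqr_factor` * IQR or above
#' Q3 + `iqr_factor` * IQR); transient motion spikes concentrate in such
#' outlier coefficients while the slow hemodynamic signal does not. Only
#' detail levels at artifact timescales (up to `max_scale_s` seconds) are
#' fenced, so the slow hemodynamic band passes through untouched. The cleaned
#' coefficients are reconstructed into the corrected signal. An infinite
#' `iqr_factor` recovers the input exactly.
#'
#' @param od A `nirs_od`.
#' @param iqr_factor Positive fence width in IQR units (default 1.5).
#' @param max_scale_s Longest wavelet scale (seconds) treated as an artifact
#'   timescale (default 4 s; motion spikes last fractions of a second to a
#'   couple of seconds).
#' @return Corrected `nirs_od`.
#' @export
correct_motion_wavelet <- function(od, iqr_factor = 1.5, max_scale_s = 4) {
  stopifnot(inherits(od, "nirs_od"))
  if (!is.numeric(iqr_factor) || iqr_factor <= 0)
    stop_nirs("iqr_factor must be positive")
  n <- dim(od$od)[3]
  if (n < 16L) stop_nirs("recording too short for wavelet decomposition")
  fs <- od$paradigm$sampling_rate
  n2 <- 2L^ceiling(log2(n))
  levels <- as.integer(log2(n2)) - 3L        # keep >= 8 approximation coeffs
  fence_levels <- which(2^seq_len(levels) / fs <= max_scale_s)
  out <- od$od
  for (ch in seq_len(dim(out)[1])) for (wl in seq_len(dim(out)[2])) {
    x <- out[ch, wl, ]
    xp <- pad_periodic(x, n2)
    w <- dwt_db4(xp, levels)
    if (is.finite(iqr_factor)) {
      for (j in fence_levels) {
        d <- w$details[[j]]
        q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        d[d < q[1] - iqr_factor * iqr | d > q[2] + iqr_factor * iqr] <- 0
        w$details[[j]] <- d
      }
    }
    out[ch, wl, ] <- idwt_db4(w)[seq_len(n)]
  }
  od_update(od, out, motion_corrected = TRUE)
}
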