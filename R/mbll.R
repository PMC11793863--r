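#' Differential pathlength factor coefficients
#'
#' Coefficients of the age- and wavelength-dependent differential pathlength
#' factor model DPF = alpha + beta * age^gamma + delta * lambda^3 +
#' epsilon * lambda^2 + zeta * lambda (lambda in nm, age in years). The
#' default cubic-term coefficient is `delta = -5.723e-7`; the variant
#' `-5.723e-3` sometimes quoted for this model produces DPF values around
#' minus three million at near-infrared wavelengths and is physically
#' impossible, so it is only available as an explicit override (the function
#' refuses coefficient sets that produce nonpositive DPF).
#'
#' @param alpha,beta,gamma,delta,epsilon,zeta Model coefficients.
#' @return A `dpf_coefficients` list.
#' @export
dpf_coefficients <- function(alpha = 223.3, beta = 0.05624, gamma = 0.8493,
                             delta = -5.723e-7, epsilon = 0.001245,
                             zeta = -0.9025) {
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 epsilon = epsilon, zeta = zeta),
            class = "dpf_coefficients")
}

#' Differential pathlength factor
#'
#' Dimensionless correction for photon path elongation through scalp and
#' cortex; increases with age and varies with wavelength. Typical adult values
#' at 695/830 nm are around 5-7.
#'
#' @param age Age in years (>= 0).
#' @param wavelength Wavelength in nm, within (600, 1000).
#' @param coeffs A [dpf_coefficients()] set.
#' @return Positive scalar DPF.
#' @examples
#' compute_dpf(30, 830)  # ~5.69
#' compute_dpf(30, 695)  # ~6.32
#' @export
compute_dpf <- function(age, wavelength, coeffs = dpf_coefficients()) {
  if (age < 0) stop_nirs("age must be nonnegative")
  if (wavelength <= 600 || wavelength >= 1000)
    stop_nirs("wavelength ", wavelength, " nm outside supported range (600, 1000)")
  dpf <- with(coeffs,
              alpha + beta * age^gamma + delta * wavelength^3 +
                epsilon * wavelength^2 + zeta * wavelength)
  if (!is.finite(dpf) || dpf <= 0)
    stop_nirs("nonpositive DPF (", signif(dpf, 4),
              "); check the delta coefficient scale")
  dpf
}

#' Molar extinction coefficients of hemoglobin
#'
#' 2 x 2 table of molar extinction coefficients (cm^-1 M^-1, natural
#' compilation values) of oxy- and deoxy-hemoglobin at the two measurement
#' wavelengths. Shipped as editable configuration: the absolute concentration
#' scale of the pipeline depends on these values.
#'
#' @param wavelengths Numeric pair in nm.
#' @param hbo,hbr Extinction coefficients for HbO and HbR at `wavelengths`.
#' @return An `extinction_table` with an invertible 2 x 2 matrix.
#' @export
extinction_table <- function(wavelengths = c(695, 830),
                             hbo = c(319.6, 974.0),
                             hbr = c(1894.0, 693.0)) {
  E <- cbind(HbR = hbr, HbO = hbo)          # rows: wavelengths
  rownames(E) <- as.character(wavelengths)
  if (abs(det(E)) < 1e-9)
    stop_nirs("extinction matrix is singular; HbO/HbR cannot be separated")
  structure(list(wavelengths = wavelengths, matrix = E),
            class = "extinction_table")
}

#' Optical density conversion
#'
#' Converts raw intensity to optical-density change
#' dOD(t, lambda) = -log10(I(t, lambda) / I0(lambda)), with I0 the mean
#' intensity over the whole recording, per channel and wavelength. dOD is
#' dimensionless and invariant to a common rescaling of the intensities.
#'
#' @param rec A [nirs_recording()].
#' @return A `nirs_od` object (array `[channel, wavelength, time]` plus
#'   provenance flags).
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "nirs_recording"))
  arr <- rec$intensity
  od <- arr
  for (ch in seq_len(dim(arr)[1])) for (w in seq_len(dim(arr)[2])) {
    x <- arr[ch, w, ]
    od[ch, w, ] <- -log10(x / mean(x))
  }
  new_od(od, rec)
}

new_od <- function(od, rec, flags = list()) {
  structure(list(od = od, subject_id = rec$subject_id, age = rec$age,
                 wavelengths = rec$wavelengths, paradigm = rec$paradigm,
                 flags = utils::modifyList(
                   list(motion_corrected = FALSE, detrended = FALSE,
                        filtered = FALSE), flags)),
            class = "nirs_od")
}

od_update <- function(od_obj, od, ...) {
  od_obj$od <- od
  od_obj$flags <- utils::modifyList(od_obj$flags, list(...))
  od_obj
}

#' @export
print.nirs_od <- function(x, ...) {
  cat(sprintf("Optical density '%s': %d channels x %d wavelengths x %d samples [%s]\n",
              x$subject_id, dim(x$od)[1], dim(x$od)[2], dim(x$od)[3],
              paste(names(Filter(isTRUE, x$flags)), collapse = ", ")))
  invisible(x)
}

#' Modified Beer-Lambert law conversion
#'
#' Maps dual-wavelength optical density to hemoglobin concentration changes:
#' per channel and time point, each wavelength's dOD is scaled by
#' 1 / DPF(lambda, age), the 2 x 2 extinction system is solved, and the result
#' is divided by the source-detector distance, yielding dHbO and dHbR in molar
#' units.
#'
#' @param od A `nirs_od` with both wavelengths.
#' @param montage A `nirs_montage` (provides the source-detector distance).
#' @param extinction An [extinction_table()].
#' @param coeffs [dpf_coefficients()] for the DPF model.
#' @return A `nirs_hemo` object with matrices `hbo` and `hbr`
#'   (`channel x time`, molar).
#' @export
od_to_hemoglobin <- function(od, montage, extinction = extinction_table(),
                             coeffs = dpf_coefficients()) {
  stopifnot(inherits(od, "nirs_od"))
  if (length(od$wavelengths) != 2L)
    stop_nirs("both wavelengths are required for the MBLL inversion")
  dpf <- vapply(od$wavelengths, compute_dpf, 0, age = od$age, coeffs = coeffs)
  Einv <- solve(extinction$matrix)          # [HbR, HbO] x [wl1, wl2]
  d <- montage$distance_cm
  nch <- dim(od$od)[1]; n <- dim(od$od)[3]
  scaled1 <- od$od[, 1, , drop = TRUE] / dpf[1]
  scaled2 <- od$od[, 2, , drop = TRUE] / dpf[2]
  if (nch == 1L) { scaled1 <- matrix(scaled1, 1L); scaled2 <- matrix(scaled2, 1L) }
  hbr <- (Einv[1, 1] * scaled1 + Einv[1, 2] * scaled2) / d
  hbo <- (Einv[2, 1] * scaled1 + Einv[2, 2] * scaled2) / d
  dimnames(hbo) <- dimnames(hbr) <- list(dimnames(od$od)[[1]], NULL)
  new_hemo(hbo, hbr, od)
}

# Forward model used by the simulator: hemoglobin -> optical density.
hemoglobin_to_od <- function(hbo, hbr, age, montage,
                             wavelengths = c(695, 830),
                             extinction = extinction_table(),
                             coeffs = dpf_coefficients()) {
  dpf <- vapply(wavelengths, compute_dpf, 0, age = age, coeffs = coeffs)
  E <- extinction$matrix
  d <- montage$distance_cm
  od <- array(NA_real_, dim = c(nrow(hbo), length(wavelengths), ncol(hbo)),
              dimnames = list(rownames(hbo), as.character(wavelengths), NULL))
  for (w in seq_along(wavelengths))
    od[, w, ] <- dpf[w] * d * (E[w, "HbR"] * hbr + E[w, "HbO"] * hbo)
  od
}

new_hemo <- function(hbo, hbr, od_obj, flags = list()) {
  stopifnot(all(dim(hbo) == dim(hbr)))
  structure(list(hbo = hbo, hbr = hbr, subject_id = od_obj$subject_id,
                 age = od_obj$age, paradigm = od_obj$paradigm,
                 flags = utils::modifyList(list(baseline_corrected = FALSE), flags)),
            class = "nirs_hemo")
}

#' @export
print.nirs_hemo <- function(x, ...) {
  cat(sprintf("Hemoglobin series '%s': %d channels x %d samples%s\n",
              x$subject_id, nrow(x$hbo), ncol(x$hbo),
              if (isTRUE(x$flags$baseline_corrected)) " (baseline corrected)" else ""))
  invisible(x)
}
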