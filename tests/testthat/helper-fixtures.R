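# Fixture builders: construct small domain objects in code.

fast_paradigm <- function() vft_paradigm()

# nirs_od with given channel x time matrix (single wavelength by default)
make_od <- function(x, wavelengths = 695, fs = 10, age = 30) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  arr <- array(NA_real_, dim = c(nrow(x), length(wavelengths), ncol(x)),
               dimnames = list(rownames(x) %||% paste0("C", seq_len(nrow(x))),
                               as.character(wavelengths), NULL))
  for (w in seq_along(wavelengths)) arr[, w, ] <- x
  nirstreat:::new_od(arr, list(subject_id = "fix", age = age,
                               wavelengths = wavelengths,
                               paradigm = vft_paradigm(sampling_rate = fs)))
}

# nirs_hemo with given hbo matrix (hbr defaults to -hbo/3)
make_hemo <- function(hbo, hbr = -hbo / 3, fs = 10) {
  if (is.null(dim(hbo))) hbo <- matrix(hbo, nrow = 1)
  if (is.null(dim(hbr))) hbr <- matrix(hbr, nrow = 1)
  rownames(hbo) <- rownames(hbo) %||% paste0("C", seq_len(nrow(hbo)))
  rownames(hbr) <- rownames(hbo)
  nirstreat:::new_hemo(hbo, hbr,
                       list(subject_id = "fix", age = 30,
                            paradigm = vft_paradigm(sampling_rate = fs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# constant-intensity recording over the default paradigm
make_recording <- function(nch = 2, value = 1, age = 30) {
  p <- vft_paradigm()
  n <- 170 * 10
  arr <- array(value, dim = c(nch, 2, n),
               dimnames = list(paste0("C", seq_len(nch)), c("695", "830"), NULL))
  nirs_recording("fix", age, arr, p)
}

# a qc_report marking `discard` channels as discarded
make_qc <- function(channels, discard = character()) {
  structure(data.frame(channel = channels, snr = 100,
                       amp_range = 1e-6,
                       keep = !channels %in% discard,
                       reason = ifelse(channels %in% discard, "snr", ""),
                       stringsAsFactors = FALSE),
            class = c("qc_report", "data.frame"))
}

# small reduced cohort for pipeline-level tests
small_cohort <- function(seed = 11) {
  simulate_cohort(sim_config(group_sizes = c(NR = 8, PR = 6, R = 6),
                             seed = seed))
}
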