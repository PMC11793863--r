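#' miRNA feature panel names
#'
#' The three circulating miRNAs carried as molecular features alongside the
#' fNIRS-derived features.
#' @export
MIRNA_FEATURES <- c("hsa-miR-550b-2-5p", "hsa-miR-125a-5p", "hsa-miR-374b-3p")

#' Raw dual-wavelength intensity recording
#'
#' Container for one subject's raw light-intensity recording: a
#' channel x wavelength x time array of strictly positive intensities
#' (arbitrary units) at 695 and 830 nm, plus the subject's age (which drives
#' the differential pathlength factor) and the task paradigm.
#'
#' @param subject_id Subject identifier.
#' @param age Age in years.
#' @param intensity Numeric array `[channel, wavelength, time]`; dimnames for
#'   the first two margins give channel ids and wavelengths.
#' @param paradigm A [vft_paradigm()].
#' @param wavelengths Numeric pair of wavelengths in nm (default 695, 830).
#' @return A `nirs_recording`.
#' @export
nirs_recording <- function(subject_id, age, intensity, paradigm,
                           wavelengths = c(695, 830)) {
  stopifnot(length(dim(intensity)) == 3L)
  if (dim(intensity)[2] != length(wavelengths))
    stop_nirs("intensity array must have one slice per wavelength")
  n_expect <- paradigm_n_samples(paradigm)
  if (dim(intensity)[3] != n_expect)
    stop_nirs("recording length ", dim(intensity)[3], " does not match paradigm (",
              n_expect, " samples)")
  bad <- which(!is.finite(intensity) | intensity <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_nirs("nonpositive intensity at channel ",
              dimnames(intensity)[[1]][bad[1, 1]] %||% bad[1, 1],
              ", sample ", bad[1, 3])
  if (!is.numeric(age) || age < 0) stop_nirs("age must be nonnegative")
  dimnames(intensity)[[2]] <- as.character(wavelengths)
  structure(list(subject_id = as.character(subject_id), age = age,
                 intensity = intensity, wavelengths = wavelengths,
                 paradigm = paradigm),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("fNIRS recording '%s' (age %g): %d channels x %d wavelengths x %d samples @ %g Hz\n",
              x$subject_id, x$age, dim(x$intensity)[1], dim(x$intensity)[2],
              dim(x$intensity)[3], x$paradigm$sampling_rate))
  invisible(x)
}

#' Read and write raw intensity recordings as CSV
#'
#' The on-disk dialect is a plain comma-separated file with a header row and
#' one row per channel-wavelength trace: columns `channel`, `wavelength`, then
#' one column per sample. Subject metadata (id, age, paradigm timing, sampling
#' rate) lives in a JSON sidecar next to the CSV (same path with `.json`
#' extension). The format is deliberately hand-inspectable.
#'
#' @param rec A `nirs_recording`.
#' @param path CSV file path; the sidecar is derived from it.
#' @return `read_recording` returns a `nirs_recording`; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  nch <- dim(rec$intensity)[1]
  nwl <- dim(rec$intensity)[2]
  rows <- vector("list", nch * nwl)
  k <- 1L
  for (w in seq_len(nwl)) for (ch in seq_len(nch)) {
    rows[[k]] <- data.frame(channel = dimnames(rec$intensity)[[1]][ch],
                            wavelength = rec$wavelengths[w],
                            t(rec$intensity[ch, w, ]))
    k <- k + 1L
  }
  df <- do.call(rbind, rows)
  names(df) <- c("channel", "wavelength",
                 sprintf("s%04d", seq_len(dim(rec$intensity)[3])))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, age = rec$age,
               wavelengths = rec$wavelengths,
               paradigm = unclass(rec$paradigm))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_nirs("recording file not found: ", path)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path)) stop_nirs("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  paradigm <- do.call(vft_paradigm, as.list(meta$paradigm))
  df <- utils::read.csv(path, check.names = FALSE)
  wls <- sort(unique(df$wavelength))
  if (!setequal(wls, meta$wavelengths))
    stop_nirs("unknown wavelength in ", path, ": ",
              paste(setdiff(wls, meta$wavelengths), collapse = ", "))
  chans <- unique(df$channel)
  n <- ncol(df) - 2L
  arr <- array(NA_real_, dim = c(length(chans), length(meta$wavelengths), n),
               dimnames = list(chans, as.character(meta$wavelengths), NULL))
  for (i in seq_len(nrow(df))) {
    arr[as.character(df$channel[i]), as.character(df$wavelength[i]), ] <-
      as.numeric(df[i, -(1:2)])
  }
  if (anyNA(arr)) stop_nirs("missing channel/wavelength traces in ", path)
  nirs_recording(meta$subject_id, meta$age, arr, paradigm,
                 wavelengths = meta$wavelengths)
}

#' Read and write the miRNA expression table
#'
#' One row per subject with the three panel miRNAs as columns; all three
#' values must be present for a subject to be usable.
#'
#' @param path CSV path with header `subject_id` plus the miRNA names.
#' @param tab Data frame as returned by `read_mirna`.
#' @return Data frame with columns `subject_id` and the three miRNAs.
#' @export
read_mirna <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("subject_id", MIRNA_FEATURES), names(df))
  if (length(missing_cols))
    stop_nirs("miRNA table missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, c("subject_id", MIRNA_FEATURES)]
  if (anyNA(df))
    stop_nirs("missing miRNA value for subject ",
              df$subject_id[which(rowSums(is.na(df)) > 0)[1]])
  if (anyDuplicated(df$subject_id))
    stop_nirs("duplicated subject in miRNA table: ",
              df$subject_id[duplicated(df$subject_id)][1])
  df
}

#' @rdname read_mirna
#' @export
write_mirna <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read and write response labels
#'
#' CSV with columns `subject_id`, `label` and optionally `hamd_baseline`,
#' `hamd_post`. When both HAM-D scores are present the label is checked for
#' consistency with [annotate_response()].
#'
#' @param path CSV path.
#' @param tab Data frame as returned by `read_labels`.
#' @return Data frame of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(df)))
    stop_nirs("label table must have subject_id and label columns")
  bad <- setdiff(unique(df$label), RESPONSE_LEVELS)
  if (length(bad)) stop_nirs("unknown response label: ", bad[1])
  if (all(c("hamd_baseline", "hamd_post") %in% names(df))) {
    for (i in seq_len(nrow(df))) {
      if (is.na(df$hamd_baseline[i]) || is.na(df$hamd_post[i])) next
      expect <- suppressWarnings(
        annotate_response(df$hamd_baseline[i], df$hamd_post[i]))
      if (as.character(expect) != df$label[i])
        stop_nirs("label ", df$label[i], " for subject ", df$subject_id[i],
                  " inconsistent with HAM-D pair (", df$hamd_baseline[i], ", ",
                  df$hamd_post[i], ")")
    }
  }
  df
}

#' @rdname read_labels
#' @export
write_labels <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Join the three modalities into a cohort
#'
#' Subjects missing any modality (recording, miRNA row, or label) are dropped
#' from the joined cohort and reported via a message, mirroring the exclusion
#' of incomplete clinical measurements.
#'
#' @param recordings List of `nirs_recording` objects.
#' @param mirna miRNA table (see [read_mirna()]).
#' @param labels Label table (see [read_labels()]).
#' @return List with `recordings`, `mirna`, `labels` restricted to complete
#'   subjects, and `dropped` (character vector of excluded subject ids).
#' @export
join_cohort <- function(recordings, mirna, labels) {
  rec_ids <- vapply(recordings, function(r) r$subject_id, "")
  keep <- Reduce(intersect, list(rec_ids, mirna$subject_id, labels$subject_id))
  all_ids <- unique(c(rec_ids, mirna$subject_id, labels$subject_id))
  dropped <- setdiff(all_ids, keep)
  if (length(dropped))
    message("excluding ", length(dropped), " subject(s) with missing modality: ",
            paste(dropped, collapse = ", "))
  list(recordings = recordings[match(keep, rec_ids)],
       mirna = mirna[match(keep, mirna$subject_id), , drop = FALSE],
       labels = labels[match(keep, labels$subject_id), , drop = FALSE],
       dropped = dropped)
}
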