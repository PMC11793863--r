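#' Verbal fluency task paradigm
#'
#' Timing model of the block-design verbal fluency task (VFT) used for all
#' recordings: a pre-scan rest, a pre-task rest, a single 60 s word-generation
#' block, and a post-task rest, sampled at `sampling_rate` Hz. Two baseline
#' windows are defined relative to the task block: `b1` covers the
#' `b1_window_s` seconds immediately before task onset and `b2` the first
#' `b2_window_s` seconds after task offset; both anchor the two-point linear
#' baseline correction.
#'
#' @param sampling_rate Sampling rate in Hz (default 10).
#' @param pre_scan_s,pre_task_s,task_s,post_task_s Segment durations in
#'   seconds (defaults 10, 30, 60, 70; total 170 s).
#' @param b1_window_s Length of the pre-task baseline window in seconds
#'   (default 10, ending at task onset).
#' @param b2_window_s Length of the post-task baseline window in seconds
#'   (default 55, starting at task offset).
#' @return An object of class `vft_paradigm`.
#' @examples
#' p <- vft_paradigm()
#' paradigm_duration(p)   # 170 s
#' @export
vft_paradigm <- function(sampling_rate = 10, pre_scan_s = 10, pre_task_s = 30,
                         task_s = 60, post_task_s = 70,
                         b1_window_s = 10, b2_window_s = 55) {
  stopifnot(sampling_rate > 0, pre_scan_s >= 0, pre_task_s > 0, task_s > 0,
            post_task_s > 0)
  if (b1_window_s <= 0 || b1_window_s > pre_task_s)
    stop_nirs("b1 window (", b1_window_s, " s) must lie inside the pre-task period")
  if (b2_window_s <= 0 || b2_window_s > post_task_s)
    stop_nirs("b2 window (", b2_window_s, " s) must lie inside the post-task period")
  structure(list(sampling_rate = sampling_rate, pre_scan_s = pre_scan_s,
                 pre_task_s = pre_task_s, task_s = task_s,
                 post_task_s = post_task_s, b1_window_s = b1_window_s,
                 b2_window_s = b2_window_s),
            class = "vft_paradigm")
}

#' @rdname vft_paradigm
#' @param paradigm A `vft_paradigm` object.
#' @export
paradigm_duration <- function(paradigm) {
  with(paradigm, pre_scan_s + pre_task_s + task_s + post_task_s)
}

paradigm_n_samples <- function(paradigm) {
  as.integer(round(paradigm_duration(paradigm) * paradigm$sampling_rate))
}

# Sample indices (1-based) for a [from, to) window in seconds.
window_idx <- function(paradigm, from_s, to_s) {
  fs <- paradigm$sampling_rate
  i0 <- as.integer(floor(from_s * fs)) + 1L
  i1 <- as.integer(floor(to_s * fs))
  if (i0 < 1L || i1 > paradigm_n_samples(paradigm) || i1 < i0)
    stop_nirs("window [", from_s, ", ", to_s, ") s outside recording")
  i0:i1
}

task_onset_s <- function(paradigm) paradigm$pre_scan_s + paradigm$pre_task_s
task_offset_s <- function(paradigm) task_onset_s(paradigm) + paradigm$task_s

# b1 / b2 baseline windows as sample indices.
b1_idx <- function(paradigm)
  window_idx(paradigm, task_onset_s(paradigm) - paradigm$b1_window_s,
             task_onset_s(paradigm))
b2_idx <- function(paradigm)
  window_idx(paradigm, task_offset_s(paradigm),
             task_offset_s(paradigm) + paradigm$b2_window_s)

#' @export
print.vft_paradigm <- function(x, ...) {
  cat(sprintf("VFT paradigm: %gs pre-scan | %gs pre-task | %gs task | %gs post-task @ %g Hz\n",
              x$pre_scan_s, x$pre_task_s, x$task_s, x$post_task_s, x$sampling_rate))
  invisible(x)
}
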