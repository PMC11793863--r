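#' Response-group annotation from HAM-D scores
#'
#' Treatment response is graded by the percentage reduction of the Hamilton
#' Depression Rating Scale (HAM-D) score from baseline to post-treatment,
#' r = 100 (baseline - post) / baseline: below 25% is a non-responder (NR),
#' from 25% up to and including 50% a partial responder (PR), and above 50% a
#' responder (R). Both boundary percentages map to PR. A post score above
#' baseline (negative reduction) is annotated NR with a warning; a zero
#' baseline leaves the reduction undefined and is an error.
#'
#' @param hamd_baseline Baseline HAM-D score (> 0).
#' @param hamd_post Post-treatment HAM-D score (>= 0).
#' @return Character scalar: `"NR"`, `"PR"` or `"R"`, with attribute
#'   `reduction` holding r in percent.
#' @examples
#' annotate_response(20, 16)  # 20% -> NR
#' annotate_response(20, 10)  # 50% -> PR
#' annotate_response(20, 4)   # 80% -> R
#' @export
annotate_response <- function(hamd_baseline, hamd_post) {
  if (!is.numeric(hamd_baseline) || !is.numeric(hamd_post) ||
      hamd_baseline < 0 || hamd_post < 0)
    stop_nirs("HAM-D scores must be nonnegative numbers")
  if (hamd_baseline == 0)
    stop_nirs("HAM-D baseline of 0 leaves the percentage reduction undefined")
  r <- 100 * (hamd_baseline - hamd_post) / hamd_baseline
  if (r < 0)
    warning("post-treatment HAM-D above baseline (reduction ", round(r, 1),
            "%); annotated NR", call. = FALSE)
  label <- if (r < 25) "NR" else if (r <= 50) "PR" else "R"
  structure(label, reduction = r)
}

RESPONSE_LEVELS <- c("NR", "PR", "R")

#' Merge partial responders into the responder class
#'
#' For binary classification the PR subjects are merged into R and classified
#' against NR; only PR entries change.
#'
#' @param labels Character vector (or factor) of `NR`/`PR`/`R` labels.
#' @return Factor with levels `NR`, `R`.
#' @export
merge_binary <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), RESPONSE_LEVELS)
  if (length(bad)) stop_nirs("unknown response label: ", bad[1])
  factor(ifelse(labels == "PR", "R", labels), levels = c("NR", "R"))
}
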