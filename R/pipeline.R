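#' Extract the full 20-feature fNIRS matrix for a cohort
#'
#' Runs the complete preprocessing chain and both feature extractors for
#' every subject: 13 time-domain activation features from the QC-kept in-use
#' channels plus 7 functional-connectivity network metrics from the
#' reconstructed in-use channel set.
#'
#' @param cohort A `nirs_cohort` (or list with `recordings`).
#' @param montage A `nirs_montage`.
#' @param qc Optional list of [channel_qc()] overrides.
#' @param seed Seed for the (seeded) small-worldness reference graphs.
#' @return List: `features` (subjects x 20 matrix; attribute `modality`
#'   marks columns `"time"`/`"fc"`), `qc` (list of `qc_report`s), `failed`
#'   (character vector of subjects whose extraction failed, with reasons).
#' @export
featurize_cohort <- function(cohort, montage = default_montage(), qc = list(),
                             seed = 1) {
  recs <- cohort$recordings
  rows <- list(); qcs <- list(); failed <- character()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    res <- tryCatch({
      pp <- preprocess_recording(rec, montage, qc = qc)
      kept_in_use <- intersect(montage$in_use, pp$qc$channel[pp$qc$keep])
      tf <- extract_time_features(pp$hb, channels = kept_in_use)
      ff <- extract_fc_features(pp$hb, pp$qc, montage,
                                seed = child_seed(seed, i))
      list(row = c(tf, ff), qc = pp$qc)
    }, nirstreat_error = function(e) e)
    if (inherits(res, "error")) {
      failed[rec$subject_id] <- conditionMessage(res)
      next
    }
    rows[[rec$subject_id]] <- res$row
    qcs[[rec$subject_id]] <- res$qc
  }
  if (!length(rows)) stop_nirs("feature extraction failed for every subject")
  features <- do.call(rbind, rows)
  attr(features, "modality") <- c(rep("time", length(TIME_FEATURES)),
                                  rep("fc", length(FC_METRICS)))
  list(features = features, qc = qcs, failed = failed)
}

#' Run the full classification pipeline on a cohort
#'
#' Orchestrates feature assembly, the optional reference-group PCA routine,
#' modality fusion, seeded RBF-SVM training and macro-averaged evaluation.
#' In the default leakage mode (`"cohort"`) the projection basis is fitted
#' once on all non-responders before cross-validation, replicating the
#' original modelling workflow (a leakage warning is emitted);
#' `leakage = "fold_safe"` refits the basis on the training portion of every
#' fold instead.
#'
#' @param cohort A `nirs_cohort`; ignored when `features` is supplied.
#' @param features Precomputed [featurize_cohort()] feature matrix (optional,
#'   avoids re-preprocessing).
#' @param montage Montage used for featurization.
#' @param modalities Subset of `c("time", "fc", "mirna")`.
#' @param pca Apply the reference-group PCA routine to the fNIRS block.
#' @param theta,pca_mode Passed to [fit_projection()].
#' @param leakage `"cohort"` (fit basis once, as in the original workflow) or
#'   `"fold_safe"` (refit per training fold).
#' @param binary Merge PR into R and classify NR vs R.
#' @param downsample Balanced down-sampling to the smallest class.
#' @param folds,iters,seed Passed to [train_svm()].
#' @return A `classification_report` with additional elements `config`,
#'   `hyperparameters`, `fold`, `subjects`.
#' @export
run_pipeline <- function(cohort = NULL, features = NULL,
                         montage = default_montage(),
                         modalities = c("time", "fc", "mirna"),
                         pca = TRUE, theta = 0.99,
                         pca_mode = c("exclude", "include"),
                         leakage = c("cohort", "fold_safe"),
                         binary = FALSE, downsample = FALSE,
                         folds = 5, iters = 1000, seed = 0) {
  pca_mode <- match.arg(pca_mode)
  leakage <- match.arg(leakage)
  modalities <- match.arg(modalities, c("time", "fc", "mirna"),
                          several.ok = TRUE)
  if (is.null(features)) {
    if (is.null(cohort)) stop_nirs("either a cohort or a feature matrix is required")
    features <- featurize_cohort(cohort, montage, seed = seed)$features
  }
  labels <- cohort$labels[cohort$labels$subject_id %in% rownames(features), ]
  if (binary) labels$label <- as.character(merge_binary(labels$label))

  modality_cols <- attr(features, "modality") %||%
    c(rep("time", length(TIME_FEATURES)), rep("fc", length(FC_METRICS)))
  fnirs_mod <- intersect(modalities, c("time", "fc"))
  fnirs <- NULL
  basis <- NULL
  preproc <- NULL
  if (length(fnirs_mod)) {
    fnirs <- features[, modality_cols %in% fnirs_mod, drop = FALSE]
    if (pca) {
      nr_ids <- labels$subject_id[labels$label == "NR"]
      if (leakage == "cohort") {
        warning("projection basis fitted on all reference subjects before ",
                "cross-validation (replication mode); use leakage = ",
                "'fold_safe' to refit per fold", call. = FALSE)
        basis <- fit_projection(fnirs[intersect(rownames(fnirs), nr_ids), ,
                                      drop = FALSE],
                                theta = theta, mode = pca_mode)
        fnirs <- project(fnirs, basis)
      } else {
        nfn <- ncol(fnirs)
        preproc <- function(x_tr, y_tr, x_te) {
          ref <- x_tr[y_tr == "NR", seq_len(nfn), drop = FALSE]
          b <- fit_projection(ref, theta = theta, mode = pca_mode)
          list(train = cbind(project(x_tr[, seq_len(nfn), drop = FALSE], b),
                             x_tr[, -seq_len(nfn), drop = FALSE]),
               test = cbind(project(x_te[, seq_len(nfn), drop = FALSE], b),
                            x_te[, -seq_len(nfn), drop = FALSE]))
        }
      }
    }
  }
  mirna <- if ("mirna" %in% modalities) cohort$mirna else NULL
  fused <- fuse_features(fnirs, mirna, labels)
  if (downsample) fused <- downsample_balanced(fused, seed = seed)
  fit <- train_svm(fused, folds = folds, iters = iters, seed = seed,
                   preproc = preproc)
  report <- evaluate(fit$cv_predictions, fused$y)
  report$config <- list(modalities = modalities, pca = pca, theta = theta,
                        pca_mode = pca_mode, leakage = leakage,
                        binary = binary, downsample = downsample,
                        folds = folds, iters = iters, seed = seed)
  report$hyperparameters <- fit$best
  report$fold <- fit$fold
  report$subjects <- fused$subjects
  report$basis <- basis
  report
}

#' Modality x PCA experiment grid
#'
#' Runs the seven modality combinations (time, fc, mirna, time+fc,
#' time+mirna, fc+mirna, all three) with the PCA routine off and on (14 runs;
#' PCA applies to the fNIRS block, so for the miRNA-only rows the two runs
#' coincide by construction).
#'
#' @inheritParams run_pipeline
#' @return Data frame with one row per run (modalities, pca, accuracy and
#'   macro metrics); the full reports are attached as attribute `reports`.
#' @export
run_grid <- function(cohort, features = NULL, montage = default_montage(),
                     folds = 5, iters = 1000, seed = 0, ...) {
  if (is.null(features))
    features <- featurize_cohort(cohort, montage, seed = seed)$features
  sets <- list("time", "fc", "mirna", c("time", "fc"), c("time", "mirna"),
               c("fc", "mirna"), c("time", "fc", "mirna"))
  rows <- list(); reports <- list()
  for (s in sets) for (p in c(FALSE, TRUE)) {
    rep_i <- suppressWarnings(
      run_pipeline(cohort, features = features, montage = montage,
                   modalities = s, pca = p, folds = folds, iters = iters,
                   seed = seed, ...))
    key <- paste0(paste(s, collapse = "+"), if (p) "+pca" else "")
    reports[[key]] <- rep_i
    rows[[key]] <- data.frame(modalities = paste(s, collapse = "+"), pca = p,
                              accuracy = rep_i$accuracy,
                              sensitivity = rep_i$sensitivity,
                              precision = rep_i$precision,
                              specificity = rep_i$specificity)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Explained-variance ablation grid
#'
#' Multimodal runs with the projection built from either the leading
#' components holding up to `theta` of the explained variance (`include`) or
#' their complement (`exclude`), for theta in 0.95 and 0.99 (4 runs).
#'
#' @inheritParams run_pipeline
#' @return Data frame (theta, mode, accuracy, macro metrics) with attribute
#'   `reports`.
#' @export
run_ablation <- function(cohort, features = NULL, montage = default_montage(),
                         thetas = c(0.95, 0.99), folds = 5, iters = 1000,
                         seed = 0, ...) {
  if (is.null(features))
    features <- featurize_cohort(cohort, montage, seed = seed)$features
  rows <- list(); reports <- list()
  for (th in thetas) for (mode in c("include", "exclude")) {
    rep_i <- suppressWarnings(
      run_pipeline(cohort, features = features, montage = montage,
                   pca = TRUE, theta = th, pca_mode = mode,
                   folds = folds, iters = iters, seed = seed, ...))
    key <- sprintf("%s-%g", mode, th)
    reports[[key]] <- rep_i
    rows[[key]] <- data.frame(theta = th, mode = mode,
                              accuracy = rep_i$accuracy,
                              sensitivity = rep_i$sensitivity,
                              precision = rep_i$precision,
                              specificity = rep_i$specificity)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
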