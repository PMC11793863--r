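#' Fuse feature modalities into one classification table
#'
#' Inner-joins any combination of feature blocks (projected or raw fNIRS
#' features, miRNA panel) with the response labels on subject id. The miRNA
#' values pass through unmanipulated; no rescaling is applied to any block.
#' Subjects missing from any supplied block are excluded and reported.
#'
#' @param fnirs Optional subjects x features matrix with subject ids as row
#'   names (projected or raw fNIRS features).
#' @param mirna Optional miRNA table (`subject_id` + the three panel columns).
#' @param labels Label table with `subject_id` and `label`.
#' @return A `fused_features` list: `x` (numeric matrix), `y` (factor),
#'   `subjects`.
#' @export
fuse_features <- function(fnirs = NULL, mirna = NULL, labels) {
  if (is.null(fnirs) && is.null(mirna))
    stop_nirs("at least one feature block is required")
  ids <- labels$subject_id
  if (!is.null(fnirs)) ids <- intersect(ids, rownames(fnirs))
  if (!is.null(mirna)) ids <- intersect(ids, mirna$subject_id)
  if (!length(ids)) stop_nirs("no subjects shared across modalities")
  dropped <- setdiff(labels$subject_id, ids)
  if (length(dropped))
    message("fuse_features: excluding ", length(dropped),
            " subject(s) missing a modality: ", paste(dropped, collapse = ", "))
  blocks <- list()
  if (!is.null(fnirs)) blocks$fnirs <- as.matrix(fnirs)[ids, , drop = FALSE]
  if (!is.null(mirna)) {
    mm <- as.matrix(mirna[match(ids, mirna$subject_id), MIRNA_FEATURES,
                          drop = FALSE])
    rownames(mm) <- ids
    blocks$mirna <- mm
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- ids
  y <- factor(labels$label[match(ids, labels$subject_id)],
              levels = intersect(RESPONSE_LEVELS,
                                 unique(labels$label)))
  structure(list(x = x, y = y, subjects = ids), class = "fused_features")
}

stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' RBF-SVM training with seeded hyperparameter search and cross-validation
#'
#' Trains a radial-basis-function support vector machine under stratified
#' k-fold cross-validation with a seeded random search over `iters`
#' hyperparameter candidates, box constraint C and kernel scale gamma both
#' drawn log-uniformly over `[1e-3, 1e3]`. The winning candidate minimizes
#' the upper confidence bound of the cross-validated classification error
#' (mean fold error + 1 standard error); ties go to the earliest candidate.
#' Features are passed to the kernel unscaled. Multi-class problems use the
#' one-vs-one decomposition. The final model is refit on all data with the
#' chosen hyperparameters; out-of-fold predictions are returned for
#' evaluation. Identical seeds reproduce folds, candidates, and predictions
#' exactly.
#'
#' @param fused A [fuse_features()] table, or a numeric matrix (then `y` is
#'   required).
#' @param y Response factor when `fused` is a plain matrix.
#' @param folds Number of cross-validation folds (default 5).
#' @param iters Number of search candidates (default 1000).
#' @param seed RNG seed governing fold shuffling and the candidate draw
#'   (default 0).
#' @param cost_range,gamma_range Log-uniform search ranges.
#' @param preproc Optional fold-level preprocessing hook
#'   `function(x_train, y_train, x_test)` returning `list(train, test)`;
#'   refit inside every fold (e.g. a leakage-safe projection refit). The
#'   final full-data model applies `preproc` to all data.
#' @return An `svm_fit` list: `model`, `cv_predictions`, `fold`, `best`
#'   (cost, gamma, cv error, upper bound), `seed`.
#' @export
train_svm <- function(fused, y = NULL, folds = 5, iters = 1000, seed = 0,
                      cost_range = c(1e-3, 1e3), gamma_range = c(1e-3, 1e3),
                      preproc = NULL) {
  if (inherits(fused, "fused_features")) {
    x <- fused$x; y <- fused$y
  } else {
    x <- as.matrix(fused)
    if (is.null(y)) stop_nirs("y is required when x is a plain matrix")
    y <- droplevels(as.factor(y))
  }
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop_nirs("need at least 2 classes to train")
  small <- table(y) < folds
  if (any(small))
    stop_nirs("class ", names(which(small))[1], " has fewer samples than folds; ",
              "reduce folds or rebalance")
  fold <- stratified_folds(y, folds, seed)
  cand <- with_seed(child_seed(seed, 1L), data.frame(
    cost = 10^stats::runif(iters, log10(cost_range[1]), log10(cost_range[2])),
    gamma = 10^stats::runif(iters, log10(gamma_range[1]), log10(gamma_range[2]))))
  cv_run <- function(cost, gamma) {
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    errs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      xtr <- x[tr, , drop = FALSE]; xte <- x[!tr, , drop = FALSE]
      if (!is.null(preproc)) {
        pp <- preproc(xtr, y[tr], xte)
        xtr <- pp$train; xte <- pp$test
      }
      fit <- e1071::svm(xtr, y[tr],
                        type = "C-classification", kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      p <- stats::predict(fit, xte)
      pred[!tr] <- p
      errs[f] <- mean(p != y[!tr])
    }
    list(pred = pred, mean = mean(errs), se = stats::sd(errs) / sqrt(folds))
  }
  ucb <- rep(NA_real_, iters)
  for (i in seq_len(iters)) {
    r <- cv_run(cand$cost[i], cand$gamma[i])
    ucb[i] <- r$mean + r$se
  }
  best_i <- which.min(ucb)
  best <- cv_run(cand$cost[best_i], cand$gamma[best_i])
  x_full <- if (is.null(preproc)) x else preproc(x, y, x)$train
  model <- e1071::svm(x_full, y, type = "C-classification", kernel = "radial",
                      cost = cand$cost[best_i], gamma = cand$gamma[best_i],
                      scale = FALSE)
  structure(list(model = model, cv_predictions = best$pred, fold = fold,
                 best = list(cost = cand$cost[best_i],
                             gamma = cand$gamma[best_i],
                             cv_error = best$mean, ucb = ucb[best_i]),
                 seed = seed, iters = iters, folds = folds),
            class = "svm_fit")
}

#' Macro-averaged classification report
#'
#' Builds the confusion matrix (rows: truth, columns: prediction) and the
#' one-vs-rest counts per class i -- TP_i (correctly predicted i), FN_i (true
#' i predicted otherwise), FP_i (other classes predicted i), TN_i (the rest)
#' -- from which accuracy = sum_i TP_i / n and the macro-averaged
#' sensitivity_i = TP_i/(TP_i+FN_i), precision_i = TP_i/(TP_i+FP_i) and
#' specificity_i = TN_i/(TN_i+FP_i) are computed; all metrics except accuracy
#' are unweighted means over classes. A class never predicted and never
#' present gets precision 0 with a warning so macro averages stay defined.
#'
#' @param predictions Factor/character vector of predicted labels.
#' @param truth Factor/character vector of true labels (same length).
#' @return A `classification_report`: `confusion`, `per_class` (data.frame of
#'   counts and metrics), `accuracy`, `sensitivity`, `precision`,
#'   `specificity` (macro), `n`.
#' @export
evaluate <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop_nirs("predictions and truth differ in length")
  lev <- union(levels(as.factor(truth)), levels(as.factor(predictions)))
  pred <- factor(predictions, levels = lev)
  tru <- factor(truth, levels = lev)
  cm <- table(truth = tru, prediction = pred)
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  prec <- numeric(length(lev))
  for (i in seq_along(lev)) {
    if (tp[i] + fp[i] > 0) prec[i] <- tp[i] / (tp[i] + fp[i])
    else {
      warning("class ", lev[i], " has no predictions; precision set to 0",
              call. = FALSE)
      prec[i] <- 0
    }
  }
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  structure(list(confusion = cm,
                 per_class = data.frame(class = lev, tp = as.integer(tp),
                                        fn = as.integer(fn), fp = as.integer(fp),
                                        tn = as.integer(tn),
                                        sensitivity = sens, precision = prec,
                                        specificity = spec,
                                        row.names = NULL),
                 accuracy = 100 * sum(tp) / n,
                 sensitivity = 100 * mean(sens),
                 precision = 100 * mean(prec),
                 specificity = 100 * mean(spec),
                 n = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (n = %d)\n", x$n))
  print(x$confusion)
  cat(sprintf("accuracy %.2f%% | sensitivity %.2f%% | precision %.2f%% | specificity %.2f%% (macro)\n",
              x$accuracy, x$sensitivity, x$precision, x$specificity))
  invisible(x)
}

#' Balanced down-sampling
#'
#' Seeded uniform sampling without replacement of `per_class` subjects from
#' every response class (default: the size of the smallest class), so class
#' counts come out equal.
#'
#' @param fused A [fuse_features()] table.
#' @param per_class Samples kept per class; defaults to the minimum class
#'   count.
#' @param seed RNG seed.
#' @return A reduced `fused_features` table.
#' @export
downsample_balanced <- function(fused, per_class = NULL, seed = 0) {
  stopifnot(inherits(fused, "fused_features"))
  counts <- table(fused$y)
  per_class <- per_class %||% min(counts)
  if (any(counts < per_class))
    stop_nirs("per_class = ", per_class, " exceeds the smallest class (",
              min(counts), ")")
  keep <- with_seed(seed, unlist(lapply(levels(fused$y), function(cl)
    sort(sample(which(fused$y == cl), per_class)))))
  keep <- sort(keep)
  structure(list(x = fused$x[keep, , drop = FALSE],
                 y = droplevels(fused$y[keep]),
                 subjects = fused$subjects[keep]),
            class = "fused_features")
}
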