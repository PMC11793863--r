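make_labels <- function(ids, labels)
  data.frame(subject_id = ids, label = labels, stringsAsFactors = FALSE)

make_mirna_tab <- function(ids, mat = NULL) {
  if (is.null(mat)) mat <- matrix(rnorm(length(ids) * 3), ncol = 3)
  colnames(mat) <- MIRNA_FEATURES
  data.frame(subject_id = ids, mat, check.names = FALSE)
}

test_that("feature fusion concatenates modalities on the subject join", {
  ids <- paste0("s", 1:6)
  proj <- matrix(rnorm(30), 6, 5, dimnames = list(ids, paste0("PC", 1:5)))
  fused <- fuse_features(proj, make_mirna_tab(ids),
                         make_labels(ids, rep(c("NR", "PR", "R"), 2)))
  expect_equal(ncol(fused$x), 8L)            # l = 5 projected + 3 miRNA
  expect_equal(levels(fused$y), c("NR", "PR", "R"))

  # subject present in only one modality is excluded and reported
  expect_message(
    part <- fuse_features(proj[1:4, ], make_mirna_tab(ids),
                          make_labels(ids, rep("NR", 6))),
    "excluding 2")
  expect_equal(part$subjects, ids[1:4])
  expect_error(fuse_features(proj[0, , drop = FALSE], make_mirna_tab(ids),
                             make_labels(ids, rep("NR", 6))),
               "no subjects")
})

test_that("SVM training separates well-separated classes and is seeded", {
  set.seed(0)
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 10, 0.1), 20, 2))
  y <- factor(rep(c("NR", "R"), each = 20))
  fit <- train_svm(x, y, iters = 30, seed = 0)
  expect_equal(mean(fit$cv_predictions == y), 1)

  fit2 <- train_svm(x, y, iters = 30, seed = 0)
  expect_identical(fit$fold, fit2$fold)
  expect_identical(fit$best, fit2$best)
  expect_identical(fit$cv_predictions, fit2$cv_predictions)

  expect_error(train_svm(x, factor(rep("NR", 40))), "at least 2 classes")
  expect_error(train_svm(x[1:22, ], factor(rep(c("NR", "R"), c(20, 2)))),
               "fewer samples than folds")
})

test_that("evaluation reproduces hand-computed multi-class counts", {
  # confusion (rows truth, cols prediction): [[3,1,0],[1,2,1],[0,1,3]]
  truth <- rep(c("NR", "PR", "R"), each = 4)
  pred <- c("NR", "NR", "NR", "PR",
            "NR", "PR", "PR", "R",
            "PR", "R", "R", "R")
  rep_ <- evaluate(pred, truth)
  expect_equal(rep_$accuracy, 100 * 8 / 12, tolerance = 1e-12)
  expect_equal(rep_$sensitivity, 100 * mean(c(3 / 4, 2 / 4, 3 / 4)),
               tolerance = 1e-12)
  expect_equal(rep_$precision, 100 * mean(c(3 / 4, 2 / 4, 3 / 4)),
               tolerance = 1e-12)
  expect_equal(rep_$specificity, 100 * mean(c(7 / 8, 6 / 8, 7 / 8)),
               tolerance = 1e-12)
  expect_equal(unname(rep_$per_class$tp), c(3, 2, 3))
  expect_equal(unname(rep_$per_class$fn), c(1, 2, 1))
  expect_equal(unname(rep_$per_class$fp), c(1, 2, 1))

  perfect <- evaluate(rep(c("NR", "PR", "R"), 4), rep(c("NR", "PR", "R"), 4))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
})

test_that("degenerate predictions keep macro metrics defined", {
  truth <- rep(c("NR", "R"), each = 6)
  pred <- rep("NR", 12)
  expect_warning(rep_ <- evaluate(pred, truth), "precision set to 0")
  expect_equal(rep_$accuracy, 50)
  expect_equal(rep_$per_class$specificity[rep_$per_class$class == "NR"], 0)
  expect_equal(rep_$per_class$precision[rep_$per_class$class == "R"], 0)
})

test_that("report internal consistency holds for random confusions", {
  set.seed(30)
  for (trial in 1:10) {
    n <- 40
    truth <- sample(c("NR", "PR", "R"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    pred <- sample(c("NR", "PR", "R"), n, replace = TRUE)
    rep_ <- suppressWarnings(evaluate(pred, truth))
    with(rep_$per_class, expect_true(all(tp + fn + fp + tn == n)))
    expect_equal(rep_$sensitivity, 100 * mean(rep_$per_class$sensitivity),
                 tolerance = 1e-12)
    expect_equal(rep_$specificity, 100 * mean(rep_$per_class$specificity),
                 tolerance = 1e-12)
    expect_equal(rep_$accuracy, 100 * sum(diag(rep_$confusion)) / n,
                 tolerance = 1e-12)
  }
})

test_that("balanced down-sampling equalizes class counts reproducibly", {
  ids <- paste0("s", 1:52)
  labs <- make_labels(ids, rep(c("NR", "PR", "R"), c(24, 15, 13)))
  fused <- fuse_features(matrix(rnorm(52 * 4), 52, 4,
                                dimnames = list(ids, paste0("f", 1:4))),
                         NULL, labs)
  down <- downsample_balanced(fused, seed = 0)
  expect_equal(as.vector(table(down$y)), c(13, 13, 13))
  down2 <- downsample_balanced(fused, seed = 0)
  expect_identical(down$subjects, down2$subjects)
  expect_false(identical(down$subjects,
                         downsample_balanced(fused, seed = 1)$subjects))
  expect_error(downsample_balanced(fused, per_class = 14), "smallest class")
  # already balanced at the minimum: a permutation of the input
  bal <- downsample_balanced(down, seed = 5)
  expect_setequal(bal$subjects, down$subjects)
})
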