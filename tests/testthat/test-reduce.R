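test_that("projection basis matches an independent eigen-decomposition", {
  set.seed(0)
  m <- 24
  u <- rnorm(m); v <- rnorm(m)
  X <- cbind(f1 = u + 0.005 * rnorm(m),
             f2 = v + 0.005 * rnorm(m),
             f3 = (u + v) / sqrt(2) + 0.01 * rnorm(m))
  b <- fit_projection(X)
  # oracle: eigen-decomposition of the z-scored covariance
  z <- scale(X)
  C <- t(z) %*% z / (m - 1)
  eig <- eigen(C, symmetric = TRUE)
  expect_equal(b$explained, eig$values / sum(eig$values), tolerance = 1e-10)
  expect_equal(b$k, 2L)                      # two factors hold >= 99%
  expect_equal(ncol(b$V), 1L)
  cosine <- abs(sum(b$V[, 1] * eig$vectors[, 3]))
  expect_gt(cosine, 0.99)                    # retained PC = near-null relation
})

test_that("basis invariants: orthonormal V, EV partition, minimal discard", {
  set.seed(21)
  X <- matrix(rnorm(24 * 20), 24, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  X <- X + outer(rnorm(24, sd = 4), runif(20))   # dominant rank-1 nuisance
  b <- fit_projection(X)
  gram <- t(b$V) %*% b$V
  expect_lt(max(abs(gram - diag(ncol(b$V)))), 1e-10)
  expect_equal(sum(b$explained), 1, tolerance = 1e-10)
  expect_gte(sum(b$explained[seq_len(b$k)]), 0.99)
  expect_lt(sum(b$explained[seq_len(b$k - 1)]), 0.99)  # k minimal
  # include mode retains the complementary leading subspace
  bi <- fit_projection(X, mode = "include")
  expect_equal(ncol(bi$V), bi$k)
  expect_equal(bi$k, b$k)
})

test_that("degenerate references and thresholds are handled", {
  same <- matrix(1, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fit_projection(same), "zero-variance feature")
  set.seed(3)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  b0 <- fit_projection(X, theta = 0)
  expect_equal(b0$k, 0L)
  expect_equal(ncol(b0$V), 3L)               # all PCs retained
  expect_error(fit_projection(X[1, , drop = FALSE]), "at least 2")
})

test_that("projection equals naive z-score-and-multiply", {
  set.seed(22)
  ref <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("f", 1:4)))
  b <- fit_projection(ref, theta = 0.8)
  X <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(paste0("s", 1:5),
                                                  paste0("f", 1:4)))
  P <- project(X, b)
  z <- sweep(sweep(X, 2, b$center), 2, b$scale, "/")
  expect_equal(unname(P), naive_matmul(z, b$V), tolerance = 1e-12)
  # z-scored zero matrix projects to zero
  zero <- matrix(rep(b$center, each = 2), 2, 4, byrow = FALSE,
                 dimnames = list(NULL, paste0("f", 1:4)))
  expect_equal(max(abs(project(zero, b))), 0, tolerance = 1e-12)
  # column mismatch is a schema error
  bad <- X; colnames(bad) <- c("f1", "f2", "f3", "g4")
  expect_error(project(bad, b), "do not match")
})

test_that("reference-group variance is suppressed to the trailing share", {
  set.seed(23)
  for (theta in c(0.95, 0.99)) {
    X <- matrix(rnorm(24 * 10), 24, 10, dimnames = list(NULL, paste0("f", 1:10)))
    X <- X + outer(rnorm(24, sd = 3), runif(10, 0.5, 1))
    b <- fit_projection(X, theta = theta)
    P <- project(X, b)
    z <- sweep(sweep(X, 2, b$center), 2, b$scale, "/")
    ratio <- sum(apply(P, 2, var)) / sum(apply(z, 2, var))
    expect_lte(ratio, 1 - theta + 1e-8)
  }
})

test_that("basis serializes to JSON and back", {
  set.seed(24)
  X <- matrix(rnorm(15 * 5), 15, 5, dimnames = list(NULL, paste0("f", 1:5)))
  b <- fit_projection(X, theta = 0.9)
  path <- withr::local_tempfile(fileext = ".json")
  write_projection(b, path)
  b2 <- read_projection(path)
  expect_equal(b2$center, b$center, tolerance = 1e-12)
  expect_equal(b2$scale, b$scale, tolerance = 1e-12)
  expect_equal(unname(b2$V), unname(b$V), tolerance = 1e-12)
  expect_equal(b2$k, b$k)
  Y <- matrix(rnorm(10), 2, 5, dimnames = list(NULL, paste0("f", 1:5)))
  expect_equal(project(Y, b2), project(Y, b), tolerance = 1e-12)
})
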