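test_that("task-segment extraction removes the two-point baseline", {
  p <- vft_paradigm()
  t <- (1:1700) / 10
  expect_true(all(extract_task_segment(make_hemo(matrix(5, 1, 1700))) == 0))
  ramp <- extract_task_segment(make_hemo(matrix(0.7 * t + 1, 1)))
  expect_lt(max(abs(ramp)), 1e-10)
  seg <- extract_task_segment(make_hemo(matrix(rnorm(1700), 1)))
  expect_equal(ncol(seg), 600L)              # 60 s at 10 Hz
  short <- vft_paradigm(pre_scan_s = 0, pre_task_s = 40)
  expect_error(extract_task_segment(make_hemo(matrix(1, 1, 1700)),
                                    paradigm = vft_paradigm(), margin_s = 50),
               "margins")
})

test_that("discarded channels are rebuilt from kept perpendicular donors", {
  m <- default_montage()
  set.seed(8)
  task <- matrix(rnorm(32 * 50), 32, 50, dimnames = list(m$in_use, NULL))
  qc <- make_qc(m$in_use, discard = "C14")
  out <- reconstruct_channels(task, qc, m)
  expect_equal(out["C14", ],
               colMeans(task[c("C7", "C8", "C20", "C21"), ]),
               tolerance = 1e-12)
  expect_equal(attr(out, "reconstructed"), "C14")
  # untouched without discards
  none <- reconstruct_channels(task, make_qc(m$in_use), m)
  expect_equal(none[, ], task, ignore_attr = TRUE)
})

test_that("reconstructed channels never donate to each other", {
  m <- default_montage()
  set.seed(9)
  task <- matrix(rnorm(32 * 40), 32, 40, dimnames = list(m$in_use, NULL))
  discard <- c("C14", "C8")                  # mutual neighbors
  out <- reconstruct_channels(task, make_qc(m$in_use, discard), m)
  # brute-force donor sets: shared-optode perpendicular channels, kept only
  ch <- m$channels
  donors_of <- function(id) {
    i <- match(id, ch$id)
    opt <- c(ch$source[i], ch$detector[i])
    share <- ch$id[(ch$source %in% opt | ch$detector %in% opt) & ch$id != id]
    perp <- share[vapply(share, function(s)
      nirstreat:::channel_orientation(m, s) !=
        nirstreat:::channel_orientation(m, id), logical(1))]
    setdiff(intersect(perp, m$in_use), discard)
  }
  for (d in discard)
    expect_equal(out[d, ], colMeans(task[donors_of(d), , drop = FALSE]),
                 tolerance = 1e-12, label = paste("donors of", d))
  # a channel whose donors are all discarded fails (or drops) the subject
  lonely <- c("C3", neighbors(m, "C3"))
  expect_error(reconstruct_channels(task, make_qc(m$in_use, lonely), m),
               "no kept neighbor")
  dropped <- reconstruct_channels(task, make_qc(m$in_use, lonely), m,
                                  on_no_donor = "drop")
  expect_false("C3" %in% rownames(dropped))
})

test_that("connectivity matrix is clipped Pearson correlation", {
  set.seed(10)
  x <- rnorm(50)
  same <- connectivity_matrix(rbind(a = x, b = x, c = rnorm(50)))
  expect_equal(same$weights["a", "b"], 1)
  opp <- connectivity_matrix(rbind(a = x, b = -x))
  expect_equal(opp$weights["a", "b"], 0)     # r = -1 clipped to 0
  expect_true(all(diag(same$weights) == 0))

  task <- matrix(rnorm(5 * 60), 5, 60, dimnames = list(paste0("C", 1:5), NULL))
  cm <- connectivity_matrix(task)
  oracle <- oracle_pearson(task)
  oracle[oracle < 0] <- 0; diag(oracle) <- 0
  expect_equal(cm$weights, oracle, tolerance = 1e-12)
  expect_equal(cm$weights, t(cm$weights))
  expect_true(all(cm$weights >= 0 & cm$weights <= 1))

  flat <- rbind(a = rep(1, 10), b = rnorm(10))
  expect_error(connectivity_matrix(flat), "zero-variance channel: a")
})

test_that("connectivity is invariant to positive affine channel rescaling", {
  set.seed(11)
  task <- matrix(rnorm(4 * 80), 4, 80, dimnames = list(paste0("C", 1:4), NULL))
  scaled <- task * c(2, 0.5, 7, 1.3) + c(10, -4, 0, 2)
  expect_equal(connectivity_matrix(task)$weights,
               connectivity_matrix(scaled)$weights, tolerance = 1e-12)
})

make_cm <- function(W) structure(list(weights = W, channels = rownames(W)),
                                 class = "connectivity_matrix")

test_that("OMST keeps a lone spanning tree and follows the GCE rule", {
  # already a tree: returned unchanged at k = 1
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["b", "a"] <- 0.9
  W["b", "c"] <- W["c", "b"] <- 0.8
  W["c", "d"] <- W["d", "c"] <- 0.7
  bg <- omst_binarize(make_cm(W))
  expect_equal(bg$n_trees, 1L)
  expect_equal(bg$adjacency, sign(W), ignore_attr = TRUE)

  # triangle: first MST {ab, bc}; leftover {ac} cannot span
  W3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W3["a", "b"] <- W3["b", "a"] <- 0.9
  W3["b", "c"] <- W3["c", "b"] <- 0.8
  W3["a", "c"] <- W3["c", "a"] <- 0.1
  bg3 <- omst_binarize(make_cm(W3))
  expect_equal(bg3$adjacency["a", "b"], 1L)
  expect_equal(bg3$adjacency["b", "c"], 1L)
  expect_equal(bg3$adjacency["a", "c"], 0L)

  disc <- matrix(0, 3, 3, dimnames = dimnames(W3))
  disc["a", "b"] <- disc["b", "a"] <- 0.5
  expect_error(omst_binarize(make_cm(disc)), "disconnected")
})

test_that("OMST matches exhaustive spanning-tree enumeration", {
  set.seed(12)
  for (trial in 1:25) {
    n <- sample(4:5, 1)
    W <- random_weighted_graph(n)
    bg <- omst_binarize(make_cm(W))
    oracle <- oracle_omst(W)
    expect_equal(bg$adjacency, oracle$adjacency, ignore_attr = TRUE,
                 label = paste("trial", trial))
    expect_equal(bg$n_trees, oracle$n_trees)
    expect_equal(bg$gce_trace, oracle$gce_trace, tolerance = 1e-12)
    # structural invariants
    g <- igraph::graph_from_adjacency_matrix(bg$adjacency, mode = "undirected")
    expect_true(igraph::is_connected(g))
    expect_lte(igraph::ecount(g), bg$n_trees * (n - 1))
  }
})

test_that("graph metrics reproduce closed forms on canonical graphs", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  ms <- graph_metrics(star, n_random = 2)
  expect_length(ms, 7L)
  expect_named(ms, FC_METRICS)
  expect_equal(unname(ms["assortativity"]), -1)
  expect_equal(unname(ms["clustering"]), 0)
  expect_equal(unname(ms["small_worldness"]), 0)   # triangle-free

  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  mk <- graph_metrics(k5, n_random = 2)
  expect_equal(unname(mk[c("clustering", "path_length", "global_efficiency")]),
               c(1, 1, 1))

  p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
  expect_equal(unname(graph_metrics(p4, n_random = 2)["path_length"]), 5 / 3)
  expect_equal(unname(graph_metrics(p4, n_random = 2)["path_length"]),
               unname(oracle_metrics(p4)["path_length"]))

  expect_error(graph_metrics(diag(0, 4)), "connected")
})

test_that("deterministic metrics agree with brute force on small graphs", {
  # exhaustive over all labeled connected graphs on 4 nodes
  det5 <- c("assortativity", "clustering", "path_length",
            "global_efficiency", "local_efficiency")
  edges4 <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  for (code in 0:(2^6 - 1)) {
    adj <- matrix(0, 4, 4)
    on <- which(bitwAnd(code, 2^(0:5)) > 0)
    for (e in on) adj[edges4[e, 1], edges4[e, 2]] <-
        adj[edges4[e, 2], edges4[e, 1]] <- 1
    reach <- diag(4) + adj
    for (k in 1:4) reach <- sign(reach %*% (diag(4) + adj))
    if (!all(reach > 0)) next
    expect_equal(graph_metrics(adj, n_random = 2)[det5], oracle_metrics(adj),
                 tolerance = 1e-12, label = paste("graph code", code))
  }
  # random 5- and 6-node graphs
  set.seed(13)
  for (trial in 1:30) {
    adj <- random_connected_graph(sample(5:6, 1))
    expect_equal(graph_metrics(adj, n_random = 2)[det5], oracle_metrics(adj),
                 tolerance = 1e-12)
  }
})

test_that("greedy modularity finds the planted two-community split", {
  barbell <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4)))
    barbell[e[1], e[2]] <- barbell[e[2], e[1]] <- 1
  ms <- graph_metrics(barbell, n_random = 2)
  expect_equal(unname(ms["modularity"]), 3 / 7 - 0.25 + 3 / 7 - 0.25,
               tolerance = 1e-12)
  # seeded small-worldness is reproducible
  expect_equal(graph_metrics(barbell, seed = 4), graph_metrics(barbell, seed = 4))
})
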