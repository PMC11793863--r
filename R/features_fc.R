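#' Names of the 7 functional-connectivity network metrics
#' @export
FC_METRICS <- c("assortativity", "clustering", "path_length",
                "global_efficiency", "local_efficiency", "modularity",
                "small_worldness")

#' Task-segment extraction for connectivity analysis
#'
#' Returns the task-period dHbO samples per channel after subtracting a
#' two-point linear baseline anchored on the 1 s windows immediately before
#' and after the task block.
#'
#' @param hb A `nirs_hemo`.
#' @param paradigm Task paradigm (defaults to the recording's own).
#' @param channels Channels to extract (default: all rows).
#' @param margin_s Width of the flanking baseline windows in seconds.
#' @return Numeric matrix `channel x task-sample`.
#' @export
extract_task_segment <- function(hb, paradigm = hb$paradigm,
                                 channels = rownames(hb$hbo), margin_s = 1) {
  stopifnot(inherits(hb, "nirs_hemo"))
  on_s <- task_onset_s(paradigm); off_s <- task_offset_s(paradigm)
  n <- ncol(hb$hbo); fs <- paradigm$sampling_rate
  if (on_s - margin_s < 0 || (off_s + margin_s) * fs > n)
    stop_nirs("task window plus ", margin_s, " s margins falls outside the recording")
  w1 <- window_idx(paradigm, on_s - margin_s, on_s)
  w2 <- window_idx(paradigm, off_s, off_s + margin_s)
  ti <- window_idx(paradigm, on_s, off_s)
  x <- hb$hbo[channels, , drop = FALSE]
  out <- matrix(NA_real_, nrow(x), length(ti),
                dimnames = list(rownames(x), NULL))
  for (i in seq_len(nrow(x)))
    out[i, ] <- (x[i, ] - two_point_baseline(x[i, ], w1, w2))[ti]
  out
}

#' Reconstruction of discarded channels from neighbors
#'
#' Each QC-discarded channel's task trace is replaced by the arithmetic mean
#' of its kept neighbors' traces ([neighbors()] donor rule); channels that
#' were themselves discarded never act as donors, so reconstructed channels
#' are never built from one another.
#'
#' @param task Matrix `channel x time` over the in-use channels.
#' @param qc A `qc_report` from [channel_qc()].
#' @param montage The montage defining the neighbor relation.
#' @param on_no_donor `"error"` (default) fails the subject when a discarded
#'   channel has no kept neighbor; `"drop"` removes that channel instead.
#' @return Matrix of the same shape (or fewer rows under `"drop"`), with
#'   attribute `reconstructed` listing imputed channels.
#' @export
reconstruct_channels <- function(task, qc, montage,
                                 on_no_donor = c("error", "drop")) {
  on_no_donor <- match.arg(on_no_donor)
  chans <- rownames(task)
  kept <- qc$channel[qc$keep]
  discarded <- setdiff(chans, kept)
  if (length(discarded) == length(chans))
    stop_nirs("no kept channels available for reconstruction")
  dropped <- character()
  for (ch in discarded) {
    donors <- intersect(neighbors(montage, ch, exclude = discarded), chans)
    if (!length(donors)) {
      if (on_no_donor == "error")
        stop_nirs("channel ", ch, " has no kept neighbor to reconstruct from")
      dropped <- c(dropped, ch)
      next
    }
    task[ch, ] <- colMeans(task[donors, , drop = FALSE])
  }
  if (length(dropped)) task <- task[setdiff(chans, dropped), , drop = FALSE]
  attr(task, "reconstructed") <- setdiff(discarded, dropped)
  task
}

#' Pearson functional-connectivity matrix
#'
#' Pairwise Pearson correlation of the channel task traces; the diagonal and
#' all negative correlations are set to zero so that edges carry only
#' positive coupling weights in [0, 1].
#'
#' @param task Matrix `channel x time` (>= 2 channels, >= 3 samples).
#' @return A `connectivity_matrix` object wrapping the symmetric weight
#'   matrix.
#' @export
connectivity_matrix <- function(task) {
  if (nrow(task) < 2L || ncol(task) < 3L)
    stop_nirs("need at least 2 channels and 3 time points")
  v <- apply(task, 1, stats::var)
  if (any(v == 0))
    stop_nirs("zero-variance channel: ", rownames(task)[which(v == 0)[1]])
  r <- stats::cor(t(task))
  r[r < 0] <- 0
  diag(r) <- 0
  structure(list(weights = r, channels = rownames(task)),
            class = "connectivity_matrix")
}

#' Orthogonal minimal spanning tree binarization
#'
#' Thresholds a weighted connectivity matrix into a sparse binary graph by
#' aggregating successive edge-disjoint minimum spanning trees (distances
#' 1/weight): after adding each tree, the global cost efficiency
#' GCE = E_glob(union, weighted) - cost is evaluated, where cost is the sum of
#' selected weights over the sum of all positive weights; the union attaining
#' the maximal GCE is returned. The result is connected, its edges decompose
#' into k spanning trees, and |edges| <= k (n - 1).
#'
#' @param cm A [connectivity_matrix()] whose positive graph is connected.
#' @return A `binary_graph`: 0/1 adjacency `matrix`, `n_trees`, and the
#'   `gce_trace` across aggregation steps.
#' @export
omst_binarize <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  W <- cm$weights
  n <- nrow(W)
  g_full <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                                weighted = TRUE)
  if (!igraph::is_connected(g_full))
    stop_nirs("positive-weight connectivity graph is disconnected; ",
              "exclude this subject")
  total_w <- sum(W) / 2
  residual <- W
  rounds <- list()
  gce <- numeric()
  sel_w <- 0
  union <- matrix(0, n, n, dimnames = dimnames(W))
  repeat {
    gr <- igraph::graph_from_adjacency_matrix(residual, mode = "undirected",
                                              weighted = TRUE)
    if (!igraph::is_connected(gr) || igraph::ecount(gr) < n - 1) break
    igraph::E(gr)$dist <- 1 / igraph::E(gr)$weight
    tree <- igraph::mst(gr, weights = igraph::E(gr)$dist)
    el <- igraph::as_edgelist(tree, names = TRUE)
    rounds[[length(rounds) + 1L]] <- el
    for (e in seq_len(nrow(el))) {
      i <- el[e, 1]; j <- el[e, 2]
      sel_w <- sel_w + W[i, j]
      union[i, j] <- union[j, i] <- W[i, j]
      residual[i, j] <- residual[j, i] <- 0
    }
    gu <- igraph::graph_from_adjacency_matrix(union, mode = "undirected",
                                              weighted = TRUE)
    ge <- igraph::global_efficiency(gu, weights = 1 / igraph::E(gu)$weight)
    gce[length(rounds)] <- ge - sel_w / total_w
  }
  if (!length(rounds))
    stop_nirs("positive-weight connectivity graph is disconnected; ",
              "exclude this subject")
  k_best <- which.max(gce)
  adj <- matrix(0L, n, n, dimnames = dimnames(W))
  for (k in seq_len(k_best)) {
    el <- rounds[[k]]
    for (e in seq_len(nrow(el))) {
      adj[el[e, 1], el[e, 2]] <- 1L
      adj[el[e, 2], el[e, 1]] <- 1L
    }
  }
  structure(list(adjacency = adj, channels = cm$channels, n_trees = k_best,
                 gce_trace = gce),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binary brain graph: %d nodes, %d edges (%d orthogonal MSTs)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$n_trees))
  invisible(x)
}

#' Seven functional-connectivity network metrics
#'
#' Graph-theoretical summary of the binarized brain network: degree
#' assortativity (0 when undefined, e.g. regular graphs), mean local
#' clustering coefficient, characteristic path length, global efficiency,
#' mean local efficiency, modularity of the greedy community partition, and
#' small-worldness sigma = (C / C_rand) / (L / L_rand) against degree-matched
#' rewired reference graphs (seeded; sigma is 0 for triangle-free graphs).
#'
#' @param g A `binary_graph` (or 0/1 adjacency matrix) of a connected graph.
#' @param n_random Number of rewired reference graphs for sigma (default 10).
#' @param rewire_per_edge Degree-preserving rewiring attempts per edge
#'   (default 20).
#' @param seed Seed for the reference-graph rewiring (default 1).
#' @return Named numeric vector of length 7.
#' @export
graph_metrics <- function(g, n_random = 10, rewire_per_edge = 20, seed = 1) {
  adj <- if (inherits(g, "binary_graph")) g$adjacency else g
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (!igraph::is_connected(gr)) stop_nirs("graph metrics require a connected graph")
  C <- igraph::transitivity(gr, type = "localaverage", isolates = "zero")
  L <- igraph::mean_distance(gr)
  assort <- igraph::assortativity_degree(gr)
  if (!is.finite(assort)) assort <- 0
  eff_g <- igraph::global_efficiency(gr)
  # local efficiency of v: global efficiency of the subgraph induced by its
  # neighbors (paths within the neighborhood only)
  eff_l <- mean(vapply(igraph::V(gr), function(v) {
    nb <- igraph::neighbors(gr, v)
    if (length(nb) < 2) return(0)
    igraph::global_efficiency(igraph::induced_subgraph(gr, nb))
  }, 0))
  mod <- igraph::modularity(igraph::cluster_fast_greedy(gr))
  sigma <- if (C <= 0) 0 else {
    refs <- with_seed(seed, lapply(seq_len(n_random), function(i)
      igraph::rewire(gr, igraph::keeping_degseq(
        niter = rewire_per_edge * igraph::ecount(gr)))))
    C_r <- mean(vapply(refs, igraph::transitivity, 0,
                       type = "localaverage", isolates = "zero"))
    L_r <- mean(vapply(refs, igraph::mean_distance, 0, unconnected = TRUE))
    if (C_r <= 0 || !is.finite(L_r) || L_r <= 0) 0 else (C / C_r) / (L / L_r)
  }
  out <- c(assortativity = assort, clustering = C, path_length = L,
           global_efficiency = eff_g, local_efficiency = eff_l,
           modularity = mod, small_worldness = sigma)
  stopifnot(identical(names(out), FC_METRICS))
  out
}

#' Functional-connectivity features for one subject
#'
#' Convenience wrapper: task-segment extraction, neighbor reconstruction of
#' discarded channels, Pearson connectivity, OMST binarization, and the seven
#' network metrics.
#'
#' @inheritParams extract_task_segment
#' @inheritParams reconstruct_channels
#' @inheritParams graph_metrics
#' @return Named numeric vector of length 7.
#' @export
extract_fc_features <- function(hb, qc, montage, paradigm = hb$paradigm,
                                seed = 1) {
  task <- extract_task_segment(hb, paradigm,
                               channels = intersect(rownames(hb$hbo),
                                                    montage$in_use))
  task <- reconstruct_channels(task, qc, montage)
  cm <- connectivity_matrix(task)
  bg <- omst_binarize(cm)
  graph_metrics(bg, seed = seed)
}
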