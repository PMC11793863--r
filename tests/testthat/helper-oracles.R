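# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive textbook formulations (explicit loops,
# exhaustive enumeration) and share no code with the package internals.

oracle_pearson <- function(mat) {
  n <- nrow(mat)
  r <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- mat[i, ]; y <- mat[j, ]
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    r[i, j] <- num / den
  }
  r
}

# All-pairs shortest paths by Floyd-Warshall on a distance matrix
# (Inf off-graph).
oracle_shortest_paths <- function(dist) {
  n <- nrow(dist)
  d <- dist
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  # local clustering
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    links <- 0
    for (a in nb) for (b in nb) if (a < b && adj[a, b] == 1) links <- links + 1
    cc[i] <- 2 * links / (k * (k - 1))
  }
  dist <- ifelse(adj == 1, 1, Inf)
  sp <- oracle_shortest_paths(dist)
  off <- sp[upper.tri(sp)]
  # degree assortativity: Pearson r of degrees over directed edge list
  xs <- ys <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) if (adj[i, j] == 1) {
    xs <- c(xs, deg[i]); ys <- c(ys, deg[j])
  }
  assort <- suppressWarnings(stats::cor(xs, ys))
  if (!is.finite(assort)) assort <- 0
  # local efficiency: global efficiency of each neighborhood subgraph
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) { le[i] <- 0; next }
    sub <- adj[nb, nb, drop = FALSE]
    spd <- oracle_shortest_paths(ifelse(sub == 1, 1, Inf))
    pairs <- spd[upper.tri(spd)]
    le[i] <- mean(1 / pairs)
  }
  c(assortativity = assort,
    clustering = mean(cc),
    path_length = mean(off),
    global_efficiency = mean(1 / off),
    local_efficiency = mean(le))
}

# Exhaustive spanning-tree enumeration on a weight matrix (n <= 6).
oracle_spanning_trees <- function(W) {
  n <- nrow(W)
  edges <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(edges)
  if (m < n - 1) return(list())
  out <- list()
  for (combo in utils::combn(m, n - 1, simplify = FALSE)) {
    adj <- matrix(0, n, n)
    for (e in combo) adj[edges[e, 1], edges[e, 2]] <-
        adj[edges[e, 2], edges[e, 1]] <- 1
    reach <- (diag(n) + adj)
    for (k in seq_len(n)) reach <- sign(reach %*% (diag(n) + adj))
    if (all(reach > 0))
      out[[length(out) + 1L]] <- edges[combo, , drop = FALSE]
  }
  out
}

# Brute-force orthogonal-MST thresholding: repeat minimum spanning trees on
# distance 1/w by exhaustive enumeration, track global cost efficiency, and
# return the union at its maximum.
oracle_omst <- function(W) {
  n <- nrow(W)
  total_w <- sum(W) / 2
  residual <- W
  union <- matrix(0, n, n)
  sel_w <- 0
  gce <- numeric(0)
  unions <- list()
  repeat {
    trees <- oracle_spanning_trees(residual)
    if (!length(trees)) break
    costs <- vapply(trees, function(el)
      sum(1 / residual[cbind(el[, 1], el[, 2])]), 0)
    el <- trees[[which.min(costs)]]
    for (e in seq_len(nrow(el))) {
      i <- el[e, 1]; j <- el[e, 2]
      sel_w <- sel_w + W[i, j]
      union[i, j] <- union[j, i] <- W[i, j]
      residual[i, j] <- residual[j, i] <- 0
    }
    d <- ifelse(union > 0, 1 / union, Inf)
    sp <- oracle_shortest_paths(d)
    ge <- mean(1 / sp[upper.tri(sp)])
    gce <- c(gce, ge - sel_w / total_w)
    unions[[length(unions) + 1L]] <- sign(union)
  }
  if (!length(unions)) return(NULL)
  k <- which.max(gce)
  list(adjacency = unions[[k]], n_trees = k, gce_trace = gce)
}

naive_matmul <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(b)))
    for (k in seq_len(ncol(a))) out[i, j] <- out[i, j] + a[i, k] * b[k, j]
  out
}

# random connected 0/1 adjacency matrix
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
    adj <- adj + t(adj)
    reach <- diag(n) + adj
    for (k in seq_len(n)) reach <- sign(reach %*% (diag(n) + adj))
    if (all(reach > 0)) return(adj)
  }
}

# random connected positive weight matrix (continuous weights, a.s. no ties)
random_weighted_graph <- function(n, p = 0.7) {
  adj <- random_connected_graph(n, p)
  W <- matrix(0, n, n)
  w <- stats::runif(sum(upper.tri(adj) & adj == 1), 0.05, 1)
  W[upper.tri(W)][adj[upper.tri(adj)] == 1] <- w
  W <- W + t(W)
  dimnames(W) <- list(paste0("n", 1:n), paste0("n", 1:n))
  W
}
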