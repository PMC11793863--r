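#' Reference-group PCA inter-subject-variability reduction
#'
#' Fits, on the feature matrix of the reference (non-responder) group, the
#' projection that discards the leading principal-component subspace. The
#' reference matrix is z-scored with its own per-feature mean and standard
#' deviation, principal components are ordered by descending explained
#' variance, and the smallest k with cumulative explained variance >= `theta`
#' is discarded; the retained matrix V holds components k+1..n (the trailing
#' subspace that sums the remaining 1 - `theta` of variance, where the
#' reference subjects form their densest cluster). `mode = "include"` instead
#' retains the *leading* components 1..k, the ablation counterpart.
#'
#' Component signs follow the convention that each component's
#' largest-magnitude loading is positive, so bases are reproducible across
#' linear-algebra backends.
#'
#' @param x_ref Numeric matrix or data.frame, reference-group subjects x
#'   features (>= 2 rows, no zero-variance feature).
#' @param theta Cumulative explained-variance threshold in (0, 1] defining
#'   the discarded leading subspace (default 0.99).
#' @param mode `"exclude"` (default) retains the trailing components;
#'   `"include"` retains the leading ones.
#' @return A `projection_basis`: z-score statistics (`center`, `scale`),
#'   `rotation` (all PCs), `explained` (variance fractions), `k`
#'   (discard count), `V` (retained matrix), `theta`, `mode`.
#' @export
fit_projection <- function(x_ref, theta = 0.99, mode = c("exclude", "include")) {
  mode <- match.arg(mode)
  x_ref <- as.matrix(x_ref)
  if (nrow(x_ref) < 2L) stop_nirs("need at least 2 reference subjects")
  if (!is.numeric(theta) || theta < 0 || theta > 1)
    stop_nirs("theta must lie in [0, 1]")
  ctr <- colMeans(x_ref)
  scl <- apply(x_ref, 2, stats::sd)
  zero <- which(scl == 0)
  if (length(zero))
    stop_nirs("zero-variance feature in reference group: ",
              colnames(x_ref)[zero[1]] %||% zero[1])
  z <- scale(x_ref, center = ctr, scale = scl)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {                 # sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  k <- if (theta == 0) 0L else min(which(cumsum(ev) >= theta - 1e-12))
  retained <- if (mode == "exclude") setdiff(seq_along(ev), seq_len(k))
              else seq_len(k)
  if (!length(retained))
    stop_nirs("no components retained (k = n); lower theta or use mode = 'include'")
  structure(list(center = ctr, scale = scl, rotation = rot, explained = ev,
                 k = k, V = rot[, retained, drop = FALSE],
                 features = colnames(x_ref), theta = theta, mode = mode),
            class = "projection_basis")
}

#' @export
print.projection_basis <- function(x, ...) {
  cat(sprintf(
    "PCA projection basis (%s-leading, theta = %g): %d features, %d PCs discarded, %d retained\n",
    x$mode, x$theta, length(x$features), x$k, ncol(x$V)))
  cat(sprintf("  discarded leading components hold %.2f%% of reference variance\n",
              100 * sum(x$explained[seq_len(x$k)])))
  invisible(x)
}

#' Project a feature matrix through a fitted basis
#'
#' Z-scores `x` with the basis's reference statistics and right-multiplies by
#' the retained component matrix V; the identical basis fitted on the
#' reference group is applied to every response group.
#'
#' @param x Subjects x features matrix or data.frame; columns must match the
#'   basis's feature names in order.
#' @param basis A [fit_projection()] result.
#' @return Projected matrix (subjects x retained components).
#' @export
project <- function(x, basis) {
  stopifnot(inherits(basis, "projection_basis"))
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !identical(colnames(x), basis$features)) {
    extra <- setdiff(colnames(x), basis$features)
    miss <- setdiff(basis$features, colnames(x))
    ooo <- if (!length(extra) && !length(miss)) "columns out of order" else ""
    stop_nirs("feature columns do not match basis: ",
              paste(c(if (length(miss)) paste("missing:", paste(miss, collapse = ",")),
                      if (length(extra)) paste("unexpected:", paste(extra, collapse = ",")),
                      ooo), collapse = "; "))
  }
  if (ncol(x) != length(basis$features))
    stop_nirs("feature count mismatch: ", ncol(x), " vs ", length(basis$features))
  z <- scale(x, center = basis$center, scale = basis$scale)
  p <- z %*% basis$V
  colnames(p) <- colnames(basis$V)
  rownames(p) <- rownames(x)
  p
}

#' Serialize / restore a projection basis as JSON
#'
#' @param basis A `projection_basis`.
#' @param path JSON path.
#' @return `read_projection` returns the restored basis.
#' @export
write_projection <- function(basis, path) {
  jsonlite::write_json(
    list(center = as.list(stats::setNames(basis$center, basis$features)),
         scale = as.list(stats::setNames(basis$scale, basis$features)),
         explained = basis$explained, k = basis$k, theta = basis$theta,
         mode = basis$mode, features = basis$features,
         rotation = basis$rotation, V = basis$V),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- j$features
  rot <- matrix(unlist(j$rotation), nrow = length(feats))
  V <- matrix(unlist(j$V), nrow = length(feats))
  rownames(rot) <- rownames(V) <- feats
  colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  colnames(V) <- if (j$mode == "exclude")
    paste0("PC", seq.int(j$k + 1L, length.out = ncol(V)))
  else paste0("PC", seq_len(ncol(V)))
  structure(list(center = unlist(j$center), scale = unlist(j$scale),
                 rotation = rot, explained = j$explained, k = j$k, V = V,
                 features = feats, theta = j$theta, mode = j$mode),
            class = "projection_basis")
}
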