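#' Feature diagnostics: group ANOVA, cluster structure, collinearity
#'
#' Screens a feature matrix against the response labels with (1) a one-way
#' ANOVA p-value per feature (constant features are skipped with a note),
#' (2) silhouette scores (squared Euclidean distance) of seeded k-means
#' clusterings of the z-scored features for k in `ks`, and (3) the number of
#' feature pairs whose Pearson correlation exceeds `r_thresh` in magnitude.
#'
#' @param features Subjects x features numeric matrix or data.frame.
#' @param labels Group labels (>= 2 groups, >= 3 subjects per group).
#' @param ks Candidate cluster counts for k-means (default 2:4).
#' @param r_thresh Collinearity threshold on |r| (default 0.7).
#' @param seed Seed for k-means initialization.
#' @return A `feature_diagnostics` list: `anova` (data.frame feature,
#'   p_value, note), `silhouette` (data.frame k, avg_width), `best_k`,
#'   `collinear_pairs` (count), `n_pairs`.
#' @export
feature_diagnostics <- function(features, labels, ks = 2:4, r_thresh = 0.7,
                                seed = 0) {
  x <- as.matrix(features)
  g <- droplevels(as.factor(labels))
  if (nlevels(g) < 2L) stop_nirs("need at least 2 groups")
  if (any(table(g) < 3L)) stop_nirs("need at least 3 subjects per group")
  if (nrow(x) != length(g)) stop_nirs("features and labels differ in length")

  pvals <- rep(NA_real_, ncol(x))
  note <- character(ncol(x))
  for (j in seq_len(ncol(x))) {
    if (stats::var(x[, j]) == 0) { note[j] <- "constant feature; ANOVA skipped"; next }
    pvals[j] <- summary(stats::aov(x[, j] ~ g))[[1]][["Pr(>F)"]][1]
  }
  anova_df <- data.frame(feature = colnames(x) %||% paste0("f", seq_len(ncol(x))),
                         p_value = pvals, note = note, stringsAsFactors = FALSE)

  z <- scale(x[, apply(x, 2, stats::var) > 0, drop = FALSE])
  d2 <- stats::dist(z)^2
  sil <- vapply(ks, function(k) {
    km <- with_seed(child_seed(seed, k), stats::kmeans(z, centers = k,
                                                       nstart = 10))
    mean(cluster::silhouette(km$cluster, d2)[, "sil_width"])
  }, 0)
  sil_df <- data.frame(k = ks, avg_width = sil)

  r <- suppressWarnings(stats::cor(x))
  ut <- upper.tri(r)
  structure(list(anova = anova_df, silhouette = sil_df,
                 best_k = ks[which.max(sil)],
                 collinear_pairs = sum(abs(r[ut]) > r_thresh, na.rm = TRUE),
                 n_pairs = sum(ut)),
            class = "feature_diagnostics")
}

#' @export
print.feature_diagnostics <- function(x, ...) {
  cat(sprintf("Feature diagnostics: %d/%d features with ANOVA p < 0.05; best k = %d; %d/%d collinear pairs\n",
              sum(x$anova$p_value < 0.05, na.rm = TRUE), nrow(x$anova),
              x$best_k, x$collinear_pairs, x$n_pairs))
  invisible(x)
}
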