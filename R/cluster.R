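# Internal cluster-quality indices on feature embeddings (Euclidean), and
# the 2-D embedding helper used for visualising learned representations.

#' Cluster-quality metrics
#'
#' Computes, directly from their definitions with Euclidean distances:
#' the mean silhouette score `(b - a) / max(a, b)`, the Calinski-Harabasz
#' index `(B / (K-1)) / (W / (n-K))` (between/within dispersion), and the
#' Davies-Bouldin index `mean_i max_{j != i} (s_i + s_j) / d_ij` with `s_i`
#' the mean distance of cluster members to their centroid.
#'
#' @param embeddings n x d numeric matrix.
#' @param labels Cluster labels (>= 2 clusters, each non-empty).
#' @return Tibble with columns `silhouette`, `calinski_harabasz`,
#'   `davies_bouldin`.
#' @export
cluster_metrics <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  y <- as.integer(as.factor(labels))
  k <- max(y)
  n <- nrow(embeddings)
  if (k < 2) stop_input("at least two clusters are required")
  if (n < 3) stop_input("at least three points are required")

  d <- as.matrix(stats::dist(embeddings))
  # silhouette: a = mean distance to own cluster (excluding self),
  # b = min over other clusters of the mean distance
  sil <- vapply(seq_len(n), function(i) {
    own <- y == y[i]
    n_own <- sum(own) - 1
    if (n_own == 0) return(0) # singleton convention
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(setdiff(seq_len(k), y[i]),
                    function(j) mean(d[i, y == j]), 1))
    (b - a) / max(a, b)
  }, 1)

  centroids <- t(vapply(seq_len(k), function(j) {
    colMeans(embeddings[y == j, , drop = FALSE])
  }, numeric(ncol(embeddings))))
  overall <- colMeans(embeddings)
  nj <- tabulate(y, k)
  between <- sum(nj * rowSums(sweep(centroids, 2, overall)^2))
  within <- sum(vapply(seq_len(k), function(j) {
    sum(sweep(embeddings[y == j, , drop = FALSE], 2, centroids[j, ])^2)
  }, 1))
  ch <- if (within == 0) Inf else (between / (k - 1)) / (within / (n - k))

  s_i <- vapply(seq_len(k), function(j) {
    mean(sqrt(rowSums(sweep(embeddings[y == j, , drop = FALSE], 2,
                            centroids[j, ])^2)))
  }, 1)
  dcent <- as.matrix(stats::dist(centroids))
  db_terms <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      if (dcent[i, j] == 0) stop_input(
        "Davies-Bouldin undefined: coincident cluster centroids")
      (s_i[i] + s_i[j]) / dcent[i, j]
    }, 1))
  }, 1)

  tibble::tibble(silhouette = mean(sil),
                 calinski_harabasz = ch,
                 davies_bouldin = mean(db_terms))
}

#' 2-D embedding of feature vectors
#'
#' Projects features to two dimensions for visualisation and cluster
#' scoring. The default method is principal component analysis (the
#' package's deterministic embedding); `"mds"` uses classical
#' multidimensional scaling on Euclidean distances.
#'
#' @param features n x d numeric matrix (n >= 5).
#' @param seed Seed (kept for interface stability; the default methods are
#'   deterministic).
#' @param method `"pca"` or `"mds"`.
#' @return n x 2 coordinate matrix.
#' @export
embed_2d <- function(features, seed = 1, method = c("pca", "mds")) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (nrow(features) < 5) stop_input("need at least 5 points to embed")
  coords <- with_seed(seed, {
    if (method == "pca") {
      p <- prcomp(features, center = TRUE, scale. = FALSE, rank. = 2)
      p$x[, 1:2, drop = FALSE]
    } else {
      stats::cmdscale(stats::dist(features), k = 2)
    }
  })
  if (ncol(coords) < 2) coords <- cbind(coords, 0)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Extract penultimate-layer features
#'
#' Global-average-pooled final-stage activations (the classifier head's
#' input) for a batch of images; the feature space that the 2-D embedding
#' and cluster metrics are computed on.
#'
#' @param model A `kct_model`.
#' @param images H x W x n array in `[0, 1]`.
#' @param batch_size Forward-pass batch size.
#' @return n x C feature matrix.
#' @export
extract_features <- function(model, images, batch_size = 32) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  n <- dim(images)[3]
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1, n)
    fwd <- forward_pipeline(model, images[, , ids, drop = FALSE],
                            keep_intermediates = TRUE)
    s4 <- fwd$intermediates$stages[[4]]
    g <- t(gap_fwd(s4))
    out <- rbind(out, g)
  }
  out
}
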