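#' Embed a patristic distance matrix in low dimension
#'
#' Reduces the n x n patristic distance matrix to an n x d point cloud for
#' mixture clustering. The matrix is consumed as a precomputed metric (no
#' re-derivation of Euclidean distances from matrix rows): UMAP builds its
#' fuzzy neighborhood graph directly on the supplied distances. For very
#' small trees (n < \code{mdsBelow}) neighborhood-graph embedding is
#' unreliable and classical metric scaling of the distance matrix is used
#' instead; the route taken is recorded in the \code{"method"} attribute.
#'
#' Deterministic for a fixed seed: the same matrix, parameters and seed
#' yield byte-identical coordinates.
#'
#' @param pdm symmetric non-negative distance matrix with zero diagonal and
#'   row/column names (leaf labels).
#' @param d target dimensionality, 2..10 (default 2).
#' @param seed integer seed for the embedder.
#' @param nNeighbors UMAP neighborhood size; clamped to n - 1
#'   (default \code{min(15, n - 1)}).
#' @param minDist UMAP minimum embedding distance (default 0.1).
#' @param mdsBelow trees with fewer leaves than this use classical metric
#'   scaling instead of UMAP (default 8).
#' @return n x d numeric matrix, rownames = leaf labels in matrix order,
#'   with attributes \code{seed}, \code{method} ("umap" or "mds") and
#'   \code{params}.
#' @examples
#' sim <- simulatePlantedTree(2, c(10, 10), seed = 1)
#' pdm <- patristicMatrix(sim$tree)
#' emb <- embedDistances(pdm, seed = 1)
#' dim(emb)
#' @export
embedDistances <- function(pdm, d = 2L, seed = 42L, nNeighbors = NULL,
                           minDist = 0.1, mdsBelow = 8L) {
  if (!is.matrix(pdm) || nrow(pdm) != ncol(pdm)) stop("pdm must be a square matrix")
  n <- nrow(pdm)
  if (any(!is.finite(pdm))) stop("pdm has non-finite entries")
  if (max(abs(pdm - t(pdm))) > 1e-8 * max(1, max(pdm))) stop("pdm is not symmetric")
  if (n < 4L) stop("need at least 4 leaves to embed (n = ", n, ")")
  d <- as.integer(d)
  if (d < 2L || d > 10L) stop("embedding dimension d must be in 2..10")
  if (d >= n) stop("embedding dimension d = ", d, " must be smaller than n = ", n)
  labels <- rownames(pdm)
  if (is.null(labels)) stop("pdm must carry leaf labels as dimnames")

  if (n < mdsBelow) {
    coords <- classicalMds(pdm, d)
    method <- "mds"
    params <- list(d = d)
  } else {
    nn <- if (is.null(nNeighbors)) min(15L, n - 1L) else min(as.integer(nNeighbors), n - 1L)
    if (nn < 2L) stop("too few points for the neighborhood size after clamping")
    set.seed(seed)
    coords <- uwot::umap(stats::as.dist(pdm), n_neighbors = nn, min_dist = minDist,
                         n_components = d, n_threads = 1, n_sgd_threads = 1)
    method <- "umap"
    params <- list(d = d, n_neighbors = nn, min_dist = minDist)
  }
  dimnames(coords) <- list(labels, NULL)
  storage.mode(coords) <- "double"
  attr(coords, "seed") <- as.integer(seed)
  attr(coords, "method") <- method
  attr(coords, "params") <- params
  coords
}

# Classical (Torgerson) metric scaling with a fixed sign convention so the
# result is stable: each axis is flipped so its largest-magnitude loading
# is positive. Axes beyond the matrix rank are padded with zeros.
classicalMds <- function(pdm, d) {
  sc <- stats::cmdscale(stats::as.dist(pdm), k = min(d, nrow(pdm) - 1L))
  if (ncol(sc) < d) {
    sc <- cbind(sc, matrix(0, nrow(sc), d - ncol(sc)))
  }
  for (j in seq_len(ncol(sc))) {
    i <- which.max(abs(sc[, j]))
    if (sc[i, j] < 0) sc[, j] <- -sc[, j]
  }
  sc
}

#' Export an embedding as TSV
#'
#' Writes leaf label plus one column per embedding axis.
#' @param embedding matrix from [embedDistances()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEmbedding <- function(embedding, path) {
  df <- data.frame(leaf_label = rownames(embedding), embedding,
                   check.names = FALSE)
  names(df)[-1] <- paste0("dim", seq_len(ncol(embedding)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
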