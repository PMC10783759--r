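#' Simulate a planted-partition tree
#'
#' Generates a rooted tree with \code{nClades} known clades for pipeline
#' testing. Each clade is a tight radiation: a random-split topology whose
#' internal branches are short (exponential, mean
#' \code{internalFraction * withinHeight}) while terminal branches are
#' extended so every tip sits at depth about \code{withinHeight} below the
#' clade root (uniform jitter of +/-10%). Clades hang off a backbone whose
#' branches have length \code{stemLength}, so the within-clade patristic
#' scale is about \code{2 * withinHeight} and the between-clade scale is at
#' least \code{2 * stemLength}: the defaults give the 50x separation ratio
#' of a tree with discrete subfamilies on long stems. Tip labels encode
#' the truth ("c01_t003").
#'
#' @param nClades number of planted clades (>= 1).
#' @param cladeSizes integer vector of leaves per clade, length 1 (recycled)
#'   or \code{nClades}.
#' @param withinHeight within-clade height scale, tree units (default 0.02).
#' @param stemLength backbone/stem branch length (default 1).
#' @param backbone "caterpillar" (clades chained along a spine) or
#'   "balanced" (clades joined pairwise).
#' @param internalFraction mean internal branch length inside a clade, as a
#'   fraction of \code{withinHeight} (default 0.01).
#' @param seed integer seed; the same spec and seed give an identical tree.
#' @return list with \code{tree} (a \code{phylo}) and \code{partition}
#'   (named character vector leaf -> planted cluster id "0", "1", ...).
#' @examples
#' sim <- simulatePlantedTree(4, 8, seed = 1)
#' table(sim$partition)
#' @export
simulatePlantedTree <- function(nClades, cladeSizes, withinHeight = 0.02,
                                stemLength = 1, backbone = c("caterpillar", "balanced"),
                                internalFraction = 0.01, seed = 42L) {
  backbone <- match.arg(backbone)
  nClades <- as.integer(nClades)
  if (nClades < 1L) stop("nClades must be >= 1")
  if (length(cladeSizes) == 1L) cladeSizes <- rep(as.integer(cladeSizes), nClades)
  if (length(cladeSizes) != nClades) {
    stop("cladeSizes must have length 1 or nClades")
  }
  if (any(cladeSizes < 1L)) stop("every clade needs at least 1 leaf")
  if (withinHeight <= 0 || stemLength <= 0) stop("withinHeight and stemLength must be > 0")

  set.seed(seed)
  subs <- lapply(seq_len(nClades), function(i) {
    cl <- radiationClade(cladeSizes[i], withinHeight, internalFraction)
    cl$tip.label <- sprintf("c%02d_t%03d", i, seq_len(cladeSizes[i]))
    cl
  })
  tree <- if (nClades == 1L) {
    subs[[1L]]
  } else {
    back <- ape::read.tree(text = paste0(backboneNewick(nClades, backbone), ";"))
    back$edge.length <- rep(stemLength, nrow(back$edge))
    for (i in seq_len(nClades)) {
      # grafting at a placeholder tip: the clade root inherits the tip's
      # edge, which becomes the clade's stem branch
      back <- ape::bind.tree(back, subs[[i]],
                             where = which(back$tip.label == paste0("P", i)))
    }
    back
  }
  truth <- stats::setNames(
    as.character(as.integer(sub("^c([0-9]+)_.*$", "\\1", tree$tip.label)) - 1L),
    tree$tip.label)
  list(tree = tree, partition = truth)
}

# single tight clade: random-split topology, short internal edges, tips
# extended to depth ~ h * (0.9..1.1)
radiationClade <- function(n, h, internalFraction) {
  if (n == 1L) {
    tr <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "t1",
               Nnode = 1L, edge.length = h)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::rtree(n)
  tipEdge <- tr$edge[, 2] <= n
  tr$edge.length <- ifelse(tipEdge, 0,
                           stats::rexp(nrow(tr$edge), rate = 1 / (internalFraction * h)))
  depth <- ape::node.depth.edgelength(tr)
  target <- h * stats::runif(sum(tipEdge), 0.9, 1.1)
  tr$edge.length[tipEdge] <- pmax(target - depth[tr$edge[tipEdge, 1]], 0.05 * h)
  tr
}

# rooted binary backbone skeleton over placeholder tips P1..Pc
backboneNewick <- function(c, shape) {
  build <- function(idx) {
    if (length(idx) == 1L) return(paste0("P", idx))
    split <- if (shape == "caterpillar") 1L else ceiling(length(idx) / 2)
    paste0("(", build(idx[seq_len(split)]), ",",
           build(idx[-seq_len(split)]), ")")
  }
  build(seq_len(c))
}

#' Simulate labeled Gaussian mixture points
#'
#' Isotropic Gaussian components with means placed at least
#' \code{separation} apart (on a circle for k >= 2), for testing the
#' mixture sweep in isolation.
#'
#' @param k number of components (>= 1).
#' @param n points per component (default 100).
#' @param d dimensionality (default 2; means vary in the first two axes).
#' @param separation minimum distance between component means.
#' @param sigma isotropic component standard deviation.
#' @param seed integer seed.
#' @return list with \code{points} (matrix, rownames "p0001", ...) and
#'   \code{labels} (integer vector of generating components, 0-based).
#' @export
simulateMixturePoints <- function(k, n = 100L, d = 2L, separation = 10,
                                  sigma = 1, seed = 42L) {
  k <- as.integer(k); n <- as.integer(n); d <- as.integer(d)
  if (k < 1L) stop("k must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  set.seed(seed)
  means <- matrix(0, k, d)
  if (k == 2L) {
    means[2, 1] <- separation
  } else if (k > 2L) {
    r <- separation / (2 * sin(pi / k))  # chord of the regular k-gon
    ang <- 2 * pi * (seq_len(k) - 1L) / k
    means[, 1] <- r * cos(ang)
    means[, 2] <- r * sin(ang)
  }
  pts <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(stats::rnorm(n * d, sd = sigma), n, d), 2, means[j, ], `+`)
  }))
  rownames(pts) <- sprintf("p%04d", seq_len(k * n))
  list(points = pts, labels = rep(seq_len(k) - 1L, each = n))
}
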