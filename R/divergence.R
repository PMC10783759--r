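#' Mean pairwise patristic distance of a leaf set
#'
#' Average of \eqn{\delta(i, j)} over all unordered leaf pairs in the set,
#' i.e. the sum over pairs divided by \eqn{n (n - 1) / 2}. A singleton has
#' no pairs and returns 0 (flagged as undefined downstream).
#'
#' @param pdm patristic distance matrix (from [patristicMatrix()]).
#' @param leafset character vector of leaf labels present in \code{pdm}.
#' @return non-negative numeric scalar.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
#' meanPairwiseDistance(patristicMatrix(tr), c("A", "B"))  # 3
#' @export
meanPairwiseDistance <- function(pdm, leafset) {
  leafset <- as.character(leafset)
  if (length(leafset) == 0) stop("empty leaf set")
  unknown <- setdiff(leafset, rownames(pdm))
  if (length(unknown)) stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  leafset <- unique(leafset)
  if (length(leafset) == 1L) return(0)
  sub <- pdm[leafset, leafset, drop = FALSE]
  sum(sub[upper.tri(sub)]) / (length(leafset) * (length(leafset) - 1) / 2)
}

#' Subtending branch length of a clade
#'
#' Length of the edge from the clade's most recent common ancestor to its
#' parent -- the branch leading to the previous split in the tree. Only
#' monophyletic leaf sets may be scored (hard error otherwise). For the
#' full leaf set the MRCA is the root, which has no parent branch:
#' \code{NA} is returned with a \code{"reason"} attribute
#' \code{"root-cluster"}. For a singleton the value is the leaf's own
#' pendant branch.
#'
#' @param tree a rooted \code{phylo} tree.
#' @param leafset character vector of leaf labels forming a clade.
#' @return numeric scalar, or \code{NA} with a reason attribute.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
#' subtendingBranchLength(tr, c("A", "B"))  # 3
#' subtendingBranchLength(tr, "C")          # 4
#' @export
subtendingBranchLength <- function(tree, leafset) {
  leafset <- checkLeafset(tree, leafset)
  if (!isMonophyletic(tree, leafset)) {
    stop("leaf set is not monophyletic; only final (clade) clusters have a subtending branch")
  }
  node <- if (length(leafset) == 1L) {
    match(leafset, tree$tip.label)
  } else {
    ape::getMRCA(tree, leafset)
  }
  edge <- which(tree$edge[, 2] == node)
  if (length(edge) == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "root-cluster"
    return(out)
  }
  tree$edge.length[edge]
}

#' Log-ratio divergence score
#'
#' \eqn{\log(\mathrm{MPD} / \mathrm{subtending})}: the within-cluster mean
#' pairwise distance relative to the branch subtending the cluster. A
#' strongly negative score marks a tight cluster hanging on a long stem.
#' Defined only when both quantities are strictly positive; otherwise
#' \code{NA} is returned with a \code{"reason"} attribute
#' (\code{"singleton"} for zero MPD, \code{"zero-subtending"}, or
#' \code{"root-cluster"} propagated from an undefined subtending branch).
#'
#' @param mpd non-negative mean pairwise distance.
#' @param subtending non-negative subtending branch length (may be
#'   \code{NA} with a reason attribute).
#' @param base logarithm base; natural log by default, 10 supported.
#' @return numeric scalar or \code{NA} with a reason attribute.
#' @export
logRatio <- function(mpd, subtending, base = exp(1)) {
  if (!is.na(mpd) && mpd < 0) stop("mpd must be non-negative")
  if (!is.na(subtending) && subtending < 0) stop("subtending length must be non-negative")
  if (is.na(subtending)) {
    out <- NA_real_
    attr(out, "reason") <- attr(subtending, "reason") %||% "root-cluster"
    return(out)
  }
  if (mpd <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "singleton"
    return(out)
  }
  if (subtending <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero-subtending"
    return(out)
  }
  log(mpd / subtending, base = base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cluster divergence report
#'
#' One row per cluster of a post-maximization partition (all clusters
#' monophyletic), ordered by cluster label: tip count, mean pairwise
#' distance, subtending branch length and log-ratio score. Undefined
#' scores are carried with their reason codes (singleton | root-cluster |
#' zero-subtending), never dropped.
#'
#' @param tree a rooted \code{phylo} tree.
#' @param pdm patristic distance matrix of \code{tree}.
#' @param partition a [CladePartition-class] (or named character vector).
#' @param base log base for the score (default natural log).
#' @return data.frame: cluster, n_tips, mpd, subtending_length, log_ratio,
#'   defined, reason.
#' @export
divergenceReport <- function(tree, pdm, partition, base = exp(1)) {
  labels <- if (is(partition, "CladePartition")) partition@labels else partition
  cl <- unique(labels)
  cl <- cl[orderClusterLabels(cl)]
  rows <- lapply(cl, function(lab) {
    members <- names(labels)[labels == lab]
    mpd <- meanPairwiseDistance(pdm, members)
    stl <- subtendingBranchLength(tree, members)
    lr <- logRatio(mpd, stl, base = base)
    data.frame(
      cluster = lab,
      n_tips = length(members),
      mpd = mpd,
      subtending_length = as.numeric(stl),
      log_ratio = as.numeric(lr),
      defined = !is.na(lr),
      reason = if (is.na(lr)) attr(lr, "reason") else "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Export a divergence report as TSV
#' @param report data.frame from [divergenceReport()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDivergence <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
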