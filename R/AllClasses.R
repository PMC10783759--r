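#' @import methods
NULL

#' Gaussian mixture sweep result
#'
#' Holds one record per swept component count k: the fitted log-likelihood,
#' the BIC on the scale \eqn{p \ln n - 2 \ln \hat L} (lower is better), and a
#' convergence flag; plus the selected k (argmin BIC over converged fits,
#' ties resolved toward smaller k) and the hard maximum-posterior labels
#' under the selected model. Labels are consecutive integers starting at 0.
#'
#' @slot table data.frame with columns \code{k}, \code{loglik}, \code{bic},
#'   \code{converged}, one row per swept k in increasing order.
#' @slot selectedK integer, the selected component count.
#' @slot labels named integer vector (0-based, consecutive), one entry per
#'   embedded point, names = leaf labels.
#' @slot d integer, embedding dimensionality the sweep was run in.
#' @slot seed integer seed recorded for the sweep.
#' @export
setClass("GmmSweep", representation(
  table = "data.frame",
  selectedK = "integer",
  labels = "integer",
  d = "integer",
  seed = "integer"
))

setValidity("GmmSweep", function(object) {
  tab <- object@table
  msgs <- character()
  need <- c("k", "loglik", "bic", "converged")
  if (!all(need %in% names(tab))) {
    return(paste("sweep table must have columns", paste(need, collapse = ", ")))
  }
  if (any(tab$k < 1)) msgs <- c(msgs, "swept k values must be >= 1")
  conv <- tab[tab$converged & is.finite(tab$bic), , drop = FALSE]
  if (nrow(conv) == 0) msgs <- c(msgs, "no converged sweep entry")
  else {
    best <- min(conv$bic)
    selBic <- conv$bic[match(object@selectedK, conv$k)]
    if (is.na(selBic) || selBic > best + 1e-8) {
      msgs <- c(msgs, "selectedK does not attain the minimum BIC among converged fits")
    }
  }
  lab <- object@labels
  if (length(lab) > 0) {
    if (is.null(names(lab)) || any(!nzchar(names(lab)))) {
      msgs <- c(msgs, "labels must be named by leaf label")
    }
    u <- sort(unique(lab))
    if (!identical(u, seq.int(0L, length(u) - 1L))) {
      msgs <- c(msgs, "labels must be consecutive integers starting at 0")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Leaf partition into (monophyletic) clusters
#'
#' Total mapping from every leaf of a tree to a cluster label. Labels follow
#' the integer / integer.decimal scheme: clusters taken directly from the
#' mixture keep their bare integer label ("3"); parts obtained by splitting
#' a non-monophyletic mixture cluster carry a decimal suffix in extraction
#' order ("3.0", "3.1", ...). The per-cluster provenance flag records which
#' route produced each cluster.
#'
#' @slot labels named character vector, leaf label -> cluster label,
#'   each matching \code{^[0-9]+(\\.[0-9]+)?$}.
#' @slot provenance named character vector, cluster label -> "direct" or
#'   "split".
#' @export
setClass("CladePartition", representation(
  labels = "character",
  provenance = "character"
))

setValidity("CladePartition", function(object) {
  msgs <- character()
  lab <- object@labels
  if (length(lab) == 0) msgs <- c(msgs, "partition is empty")
  if (is.null(names(lab)) || anyDuplicated(names(lab)) || any(!nzchar(names(lab)))) {
    msgs <- c(msgs, "leaf names must be unique and non-empty")
  }
  if (any(!grepl("^[0-9]+(\\.[0-9]+)?$", lab))) {
    msgs <- c(msgs, "cluster labels must match ^[0-9]+(\\.[0-9]+)?$")
  }
  prov <- object@provenance
  cl <- unique(lab)
  if (!setequal(names(prov), cl)) {
    msgs <- c(msgs, "provenance must cover exactly the cluster labels")
  }
  if (any(!prov %in% c("direct", "split"))) {
    msgs <- c(msgs, "provenance values must be 'direct' or 'split'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Full pipeline run result
#'
#' Container for one end-to-end subfamily clustering run: the (validated,
#' possibly midpoint-rooted) tree, the patristic distance matrix, the
#' low-dimensional embedding, the mixture sweep, the final monophyletic
#' partition, the per-cluster divergence table and the run metadata.
#'
#' @slot tree the \code{ape::phylo} tree the run operated on.
#' @slot pdm patristic distance matrix (rows/cols in tree tip order).
#' @slot embedding n x d coordinate matrix, rows in the same order.
#' @slot sweep \code{GmmSweep} with the BIC curve and selected model.
#' @slot partition final \code{CladePartition} (every cluster monophyletic).
#' @slot divergence data.frame, one row per final cluster: n_tips, mpd,
#'   subtending_length, log_ratio, defined, reason.
#' @slot annotation optional list with the parsimony randomization result
#'   (empty when no annotations were supplied).
#' @slot metadata list: config echo, version, per-stage timings, counts.
#' @export
setClass("SubfamilyRun", representation(
  tree = "ANY",
  pdm = "matrix",
  embedding = "matrix",
  sweep = "GmmSweep",
  partition = "CladePartition",
  divergence = "data.frame",
  annotation = "list",
  metadata = "list"
))

setValidity("SubfamilyRun", function(object) {
  msgs <- character()
  tips <- object@tree$tip.label
  if (!setequal(names(object@partition@labels), tips)) {
    msgs <- c(msgs, "partition does not cover exactly the tree's leaf set")
  }
  counts <- object@metadata$counts
  if (!is.null(counts$final_clusters) &&
      counts$final_clusters != length(unique(object@partition@labels))) {
    msgs <- c(msgs, "metadata final cluster count disagrees with the partition")
  }
  if (length(msgs)) msgs else TRUE
})
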