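#' Cluster labels of a partition or run
#'
#' @param x a \code{CladePartition}, \code{GmmSweep} or \code{SubfamilyRun}.
#' @return for a \code{CladePartition} / \code{SubfamilyRun}, a named
#'   character vector leaf -> cluster label; for a \code{GmmSweep}, the
#'   0-based integer mixture labels.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Selected number of mixture components
#' @param x a \code{GmmSweep} or \code{SubfamilyRun}.
#' @return integer, the component count with the lowest BIC.
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' BIC curve of a mixture sweep
#' @param x a \code{GmmSweep} or \code{SubfamilyRun}.
#' @return data.frame with columns \code{k} and \code{bic}, one row per
#'   swept component count in increasing k order.
#' @export
setGeneric("bicCurve", function(x) standardGeneric("bicCurve"))

#' Per-cluster divergence table
#' @param x a \code{SubfamilyRun}.
#' @return data.frame with one row per final cluster (label order):
#'   cluster, n_tips, mpd, subtending_length, log_ratio, defined, reason.
#' @export
setGeneric("divergenceTable", function(x) standardGeneric("divergenceTable"))

#' Run metadata
#' @param x a \code{SubfamilyRun}.
#' @return list with config echo, version, stage timings and counts.
#' @export
setGeneric("runMetadata", function(x) standardGeneric("runMetadata"))

#' Number of clusters in a partition
#' @param x a \code{CladePartition} or \code{SubfamilyRun}.
#' @return integer count of distinct cluster labels.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

setMethod("clusterLabels", "CladePartition", function(x) x@labels)
setMethod("clusterLabels", "GmmSweep", function(x) x@labels)
setMethod("clusterLabels", "SubfamilyRun", function(x) x@partition@labels)

setMethod("selectedK", "GmmSweep", function(x) x@selectedK)
setMethod("selectedK", "SubfamilyRun", function(x) x@sweep@selectedK)

setMethod("bicCurve", "GmmSweep", function(x) x@table[, c("k", "bic")])
setMethod("bicCurve", "SubfamilyRun", function(x) bicCurve(x@sweep))

setMethod("divergenceTable", "SubfamilyRun", function(x) x@divergence)
setMethod("runMetadata", "SubfamilyRun", function(x) x@metadata)

setMethod("nClusters", "CladePartition", function(x) length(unique(x@labels)))
setMethod("nClusters", "SubfamilyRun", function(x) nClusters(x@partition))

setMethod("show", "GmmSweep", function(object) {
  cat("GmmSweep: k = 1..", max(object@table$k), " (d = ", object@d, ")\n", sep = "")
  cat("  selected k =", object@selectedK,
      "(BIC =", format(min(object@table$bic[object@table$converged], na.rm = TRUE)), ")\n")
  cat(" ", sum(object@table$converged), "of", nrow(object@table), "fits converged\n")
})

setMethod("show", "CladePartition", function(object) {
  sz <- table(object@labels)
  cat("CladePartition:", length(object@labels), "leaves in", length(sz), "clusters\n")
  cat("  split-derived clusters:", sum(object@provenance == "split"), "\n")
  cat("  cluster sizes:", paste(sprintf("%s:%d", names(sz), sz), collapse = " "), "\n")
})

setMethod("show", "SubfamilyRun", function(object) {
  md <- object@metadata
  cat("SubfamilyRun:", length(object@tree$tip.label), "leaves\n")
  cat("  mixture: selected k =", object@sweep@selectedK,
      "| non-monophyletic mixture clusters:", md$counts$nonmonophyletic_clusters, "\n")
  cat("  final clusters:", md$counts$final_clusters, "(all monophyletic)\n")
  nd <- object@divergence
  cat("  divergence scores defined for", sum(nd$defined), "of", nrow(nd), "clusters\n")
})
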