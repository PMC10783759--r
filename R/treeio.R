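#' Validate a rooted tree for subfamily analysis
#'
#' Checks the invariants every downstream stage relies on: unique non-empty
#' leaf labels, branch lengths present, finite and non-negative on every
#' non-root edge, a single (binary) root, and a minimum leaf count.
#' Zero-length branches are allowed (they occur in MCC summary trees);
#' negative lengths are a hard error.
#'
#' @param tree an \code{ape::phylo} object.
#' @param minTips minimum number of leaves required (2 suffices for distance
#'   computation; the clustering pipeline needs more).
#' @return the tree, invisibly, if valid; otherwise an error is thrown.
#' @export
assertRootedTree <- function(tree, minTips = 2L) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree object")
  tips <- tree$tip.label
  if (length(tips) < minTips) {
    stop("tree has ", length(tips), " leaves; at least ", minTips, " required")
  }
  if (any(!nzchar(tips))) stop("tree has empty leaf labels")
  if (anyDuplicated(tips)) {
    dup <- unique(tips[duplicated(tips)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    stop("tree is missing branch lengths on one or more edges")
  }
  if (any(!is.finite(tree$edge.length))) {
    stop("tree has missing or non-finite branch lengths; no silent default is applied")
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (length(tips) >= 3L && !ape::is.rooted(tree)) {
    stop("tree is not rooted (basal multifurcation); ",
         "re-root it or use midpointRoot = TRUE when reading")
  }
  # single connected component / no cycles: every non-root node has exactly
  # one parent edge and all nodes are reachable from the root
  nNode <- length(tips) + tree$Nnode
  parents <- tabulate(tree$edge[, 2], nbins = nNode)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(root) != 1L || any(parents[-root] != 1L) || parents[root] != 0L) {
    stop("tree is not a rooted tree: node with zero or multiple parents found")
  }
  invisible(tree)
}

#' Read a rooted phylogenetic tree from newick or nexus
#'
#' Reads one tree with branch lengths and validates it (see
#' [assertRootedTree()]). Quoted labels are unquoted and bracketed comments
#' stripped by the underlying parsers; nexus TRANSLATE tables are resolved
#' to full labels. Unrooted input is rejected unless \code{midpointRoot}
#' is set, in which case midpoint rooting is applied and recorded in the
#' \code{"midpointRooted"} attribute of the result.
#'
#' @param path file path.
#' @param format "newick", "nexus", or "auto" (sniffs a leading #NEXUS and
#'   falls back to the file extension).
#' @param midpointRoot logical; root unrooted input at its midpoint instead
#'   of failing.
#' @param minTips minimum leaf count passed to the validator.
#' @return a validated \code{phylo} tree.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:2):3,(C:4,D:5):6);", tf)
#' tr <- readPhyloTree(tf)
#' tr$tip.label
#' @export
readPhyloTree <- function(path, format = c("auto", "newick", "nexus"),
                          midpointRoot = FALSE, minTips = 2L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head1 <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(head1, "#NEXUS") ||
                  grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE)) {
      "nexus"
    } else {
      "newick"
    }
  }
  tree <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("file contains ", length(tree), " trees; expected one")
    tree <- tree[[1L]]
  }
  if (is.null(tree)) stop("could not parse a tree from ", path)
  rooted <- FALSE
  if (length(tree$tip.label) >= 3L && !ape::is.rooted(tree)) {
    if (!midpointRoot) {
      stop("input tree is unrooted; pass midpointRoot = TRUE to apply midpoint rooting")
    }
    if (is.null(tree$edge.length)) stop("cannot midpoint-root a tree without branch lengths")
    tree <- phangorn::midpoint(tree)
    rooted <- TRUE
  }
  assertRootedTree(tree, minTips = minTips)
  attr(tree, "midpointRooted") <- rooted
  tree
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j. Rows and columns are ordered exactly as
#' \code{tree$tip.label} (the tree's stable tip order); the matrix is
#' symmetric with a zero diagonal and, being a tree metric, satisfies the
#' four-point condition.
#'
#' @param tree a validated rooted tree with >= 2 leaves.
#' @return n x n numeric matrix with dimnames = leaf labels.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
#' patristicMatrix(tr)["A", "C"]  # 1 + 3 + 6 + 4 = 14
#' @export
patristicMatrix <- function(tree) {
  assertRootedTree(tree, minTips = 2L)
  pdm <- ape::cophenetic.phylo(tree)
  pdm[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Deterministic cluster colors
#'
#' One distinct HCL hue per cluster label, assigned in label order.
#' @param labels character vector of cluster labels (duplicates allowed).
#' @return named character vector label -> "#RRGGBB".
#' @keywords internal
clusterColors <- function(labels) {
  cl <- unique(labels)
  cl <- cl[orderClusterLabels(cl)]
  hues <- seq(15, 375, length.out = length(cl) + 1L)[seq_along(cl)]
  cols <- grDevices::hcl(h = hues, c = 90, l = 55)
  stats::setNames(substr(cols, 1, 7), cl)
}

#' Write a tree annotated with cluster labels
#'
#' Newick output appends \code{|<label>} to every leaf name. Nexus output
#' additionally carries one FigTree-style color comment
#' (\code{[&!color=#RRGGBB]}) per taxon, one distinct color per cluster,
#' with a deterministic label -> color assignment.
#'
#' @param tree the tree that was clustered.
#' @param partition a \code{CladePartition} (or named character vector
#'   leaf -> cluster label) covering exactly the tree's leaf set.
#' @param path output file path.
#' @param format "newick" or "nexus".
#' @return \code{path}, invisibly.
#' @export
writeClusteredTree <- function(tree, partition, path,
                               format = c("newick", "nexus")) {
  format <- match.arg(format)
  assertRootedTree(tree, minTips = 2L)
  labels <- if (is(partition, "CladePartition")) partition@labels else partition
  if (length(labels) == 0) stop("empty partition")
  extra <- setdiff(names(labels), tree$tip.label)
  miss <- setdiff(tree$tip.label, names(labels))
  if (length(extra) || length(miss)) {
    stop("partition/leaf-set mismatch; missing from partition: {",
         paste(miss, collapse = ", "), "}; not in tree: {",
         paste(extra, collapse = ", "), "}")
  }
  out <- tree
  out$tip.label <- paste0(tree$tip.label, "|", labels[tree$tip.label])
  if (format == "newick") {
    ape::write.tree(out, file = path, digits = 15)
  } else {
    cols <- clusterColors(labels)
    tipcol <- cols[labels[tree$tip.label]]
    lines <- c(
      "#NEXUS",
      "begin taxa;",
      paste0("\tdimensions ntax=", length(out$tip.label), ";"),
      "\ttaxlabels",
      paste0("\t'", out$tip.label, "'[&!color=", tipcol, "]"),
      ";",
      "end;",
      "begin trees;",
      paste0("\ttree annotated = [&R] ",
             ape::write.tree(out, digits = 15)),
      "end;"
    )
    writeLines(lines, path)
  }
  invisible(path)
}
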