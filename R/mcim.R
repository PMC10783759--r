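#' Is a leaf set monophyletic?
#'
#' A leaf set is monophyletic (a clade) iff the descendant leaf set of its
#' most recent common ancestor equals it exactly. Evaluated on the rooted
#' tree; singletons and the full leaf set are clades by definition.
#'
#' @param tree a rooted \code{phylo} tree.
#' @param leafset character vector of leaf labels (non-empty, subset of the
#'   tree's leaves).
#' @return logical.
#' @examples
#' tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
#' isMonophyletic(tr, c("A", "B"))     # TRUE
#' isMonophyletic(tr, c("A", "B", "D")) # FALSE: MRCA is the root
#' @export
isMonophyletic <- function(tree, leafset) {
  leafset <- checkLeafset(tree, leafset)
  if (length(leafset) <= 1L || length(leafset) == length(tree$tip.label)) return(TRUE)
  mrca <- ape::getMRCA(tree, leafset)
  setequal(cladeTips(tree, mrca), leafset)
}

# tip labels descending from a node (the node itself if it is a tip)
cladeTips <- function(tree, node) {
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1L]]]
}

checkLeafset <- function(tree, leafset) {
  leafset <- as.character(leafset)
  if (length(leafset) == 0) stop("empty leaf set")
  unknown <- setdiff(leafset, tree$tip.label)
  if (length(unknown)) stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  unique(leafset)
}

#' Decompose a leaf set into maximal contained clades
#'
#' Returns the clades of the tree whose leaf sets are contained in
#' \code{leafset} and are maximal under inclusion. Because the clades of a
#' rooted tree form a laminar family, these maximal clades are unique,
#' pairwise disjoint, and their union is \code{leafset}; a monophyletic
#' input comes back as a single set. The result is ordered by extraction:
#' size descending, equal sizes broken toward the set containing the
#' lexicographically smallest leaf label.
#'
#' @param tree a rooted \code{phylo} tree.
#' @param leafset character vector of leaf labels.
#' @return list of character vectors (disjoint, union = \code{leafset}).
#' @examples
#' tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
#' decomposeCluster(tr, c("A", "B", "D"))  # list({A,B}, {D})
#' @export
decomposeCluster <- function(tree, leafset) {
  leafset <- checkLeafset(tree, leafset)
  nTip <- length(tree$tip.label)
  # candidate clades: every tree node whose tip set is contained in leafset
  tipSets <- c(as.list(tree$tip.label),
               lapply(phangorn::Descendants(tree, (nTip + 1L):(nTip + tree$Nnode),
                                            type = "tips"),
                      function(i) tree$tip.label[i]))
  contained <- tipSets[vapply(tipSets, function(s) all(s %in% leafset), logical(1))]
  # maximal = not a strict subset of another contained clade; since clades
  # are laminar, keeping the largest-first non-overlapping ones is exact
  ord <- order(-lengths(contained),
               vapply(contained, function(s) min(s), character(1)))
  contained <- contained[ord]
  out <- list()
  used <- character(0)
  for (s in contained) {
    if (!any(s %in% used)) {
      out[[length(out) + 1L]] <- sort(s)
      used <- c(used, s)
    }
    if (length(used) == length(leafset)) break
  }
  out
}

#' Monophyletic cluster maximization
#'
#' Maps mixture labels onto the tree and enforces monophyly: clusters whose
#' leaves already form a clade keep their bare integer label; every
#' non-monophyletic cluster with base label B is decomposed into its
#' maximal contained clades via [decomposeCluster()], and the parts are
#' labeled B.0, B.1, ... in extraction order. The result is a total
#' partition of the leaf set in which every cluster is monophyletic.
#'
#' @param tree a rooted \code{phylo} tree.
#' @param mixtureLabels named integer (or character) vector, leaf label ->
#'   mixture cluster id, covering every leaf exactly once.
#' @return a [CladePartition-class] object.
#' @examples
#' tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
#' lab <- c(A = 0, B = 0, D = 0, C = 1, E = 2)
#' clusterLabels(maximizeMonophyly(tr, lab))
#' @export
maximizeMonophyly <- function(tree, mixtureLabels) {
  if (is.null(names(mixtureLabels))) stop("mixtureLabels must be named by leaf label")
  miss <- setdiff(tree$tip.label, names(mixtureLabels))
  extra <- setdiff(names(mixtureLabels), tree$tip.label)
  if (length(miss) || length(extra)) {
    stop("mixture labels must cover exactly the tree's leaves; missing: {",
         paste(miss, collapse = ", "), "}; unknown: {",
         paste(extra, collapse = ", "), "}")
  }
  bases <- sort(unique(as.integer(mixtureLabels)))
  labels <- character(0)
  provenance <- character(0)
  for (b in bases) {
    members <- names(mixtureLabels)[as.integer(mixtureLabels) == b]
    if (isMonophyletic(tree, members)) {
      labels[members] <- as.character(b)
      provenance[as.character(b)] <- "direct"
    } else {
      parts <- decomposeCluster(tree, members)
      for (i in seq_along(parts)) {
        lab <- paste0(b, ".", i - 1L)
        labels[parts[[i]]] <- lab
        provenance[lab] <- "split"
      }
    }
  }
  new("CladePartition", labels = labels[tree$tip.label], provenance = provenance)
}

# order cluster labels numerically: by integer base, then by decimal suffix
# ("10" after "9", "3.1" after "3.0", bare "3" before "3.0")
orderClusterLabels <- function(labels) {
  base <- as.integer(sub("\\..*$", "", labels))
  suff <- ifelse(grepl("\\.", labels),
                 as.integer(sub("^[0-9]+\\.", "", labels)), -1L)
  order(base, suff)
}

#' Export a partition as TSV
#'
#' Columns: leaf_label, cluster_label, provenance (direct | split).
#' Rows follow the tree/partition leaf order.
#' @param partition a [CladePartition-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePartition <- function(partition, path) {
  df <- data.frame(
    leaf_label = names(partition@labels),
    cluster_label = unname(partition@labels),
    provenance = unname(partition@provenance[partition@labels])
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
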