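#' Derive categorical annotation keys
#'
#' Collapses free-text annotations to short categorical states: by default
#' the first \code{keyLength} characters (3, following the convention of
#' comparing annotation prefixes), or the first capture group of an
#' optional regular expression.
#'
#' @param annotations named character vector, leaf label -> annotation.
#' @param keyLength number of leading characters to keep (default 3).
#' @param pattern optional regex; if given, the first capture group is the
#'   key and \code{keyLength} is ignored.
#' @return named character vector, leaf label -> key.
#' @export
annotationKeys <- function(annotations, keyLength = 3L, pattern = NULL) {
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    stop("annotations must be named by leaf label")
  }
  if (any(!nzchar(annotations))) stop("empty annotation strings")
  keys <- if (is.null(pattern)) {
    substr(annotations, 1L, keyLength)
  } else {
    m <- regmatches(annotations, regexec(pattern, annotations))
    bad <- lengths(m) < 2L
    if (any(bad)) {
      stop("pattern did not match annotations for: ",
           paste(names(annotations)[bad], collapse = ", "))
    }
    vapply(m, `[`, character(1), 2L)
  }
  stats::setNames(as.character(keys), names(annotations))
}

#' Fitch small-parsimony score
#'
#' Minimum number of categorical state changes on the tree explaining the
#' observed leaf states, by the bottom-up Fitch recurrence: a node's state
#' set is the intersection of its children's sets if non-empty, otherwise
#' their union, counting one change whenever the intersection is empty.
#' At multifurcations the same intersection-if-nonempty-else-union rule is
#' applied over all children jointly (exact on binary trees; a documented
#' generalization on polytomies).
#'
#' @param tree a rooted \code{phylo} tree (polytomies allowed).
#' @param states named character vector, leaf label -> state. Every leaf
#'   must have a state unless \code{dropUncovered} is set, in which case
#'   the tree is restricted to the covered leaves first.
#' @param dropUncovered logical; drop leaves without a state instead of
#'   failing.
#' @return non-negative integer.
#' @examples
#' tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
#' fitchParsimony(tr, c(A = "x", B = "x", C = "x", D = "y", E = "y"))  # 1
#' @export
fitchParsimony <- function(tree, states, dropUncovered = FALSE) {
  if (is.null(names(states))) stop("states must be named by leaf label")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) {
    if (!dropUncovered) {
      stop("no state for leaves: ", paste(miss, collapse = ", "),
           " (set dropUncovered = TRUE to restrict to covered leaves)")
    }
    tree <- ape::keep.tip(tree, setdiff(tree$tip.label, miss))
  }
  nTip <- length(tree$tip.label)
  if (nTip == 1L) return(0L)
  uni <- sort(unique(as.character(states)))
  stateSets <- vector("list", nTip + tree$Nnode)
  for (i in seq_len(nTip)) {
    stateSets[[i]] <- match(as.character(states[[tree$tip.label[i]]]), uni)
  }
  edge <- stats::reorder(tree, "postorder")$edge
  changes <- 0L
  children <- split(edge[, 2], edge[, 1])
  for (node in unique(edge[, 1])) {           # postorder over internal nodes
    sets <- stateSets[children[[as.character(node)]]]
    inter <- Reduce(intersect, sets)
    if (length(inter)) {
      stateSets[[node]] <- inter
    } else {
      stateSets[[node]] <- sort(unique(unlist(sets)))
      changes <- changes + 1L
    }
  }
  changes
}

#' Parsimony randomization test of tree/annotation concordance
#'
#' Compares the observed Fitch parsimony score of the annotation keys on
#' the tree against the null distribution obtained by uniformly permuting
#' the leaf -> state assignment. A small p-value means the annotations are
#' far more clustered on the tree than chance allows. The add-one estimate
#' \eqn{p = (1 + \#\{null \le observed\}) / (nPerm + 1)} is used, so p is
#' never exactly zero.
#'
#' @param tree a rooted \code{phylo} tree.
#' @param states named character vector, leaf label -> categorical state
#'   (see [annotationKeys()]).
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param dropUncovered passed to [fitchParsimony()]; applied once up
#'   front so the null permutes only covered leaves.
#' @return list with elements \code{observed}, \code{null} (integer vector
#'   of length \code{nPerm}), \code{p}, \code{nPerm}, \code{seed}.
#' @export
parsimonyRandomization <- function(tree, states, nPerm = 999L, seed = 42L,
                                   dropUncovered = FALSE) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) {
    if (!dropUncovered) {
      stop("no state for leaves: ", paste(miss, collapse = ", "))
    }
    tree <- ape::keep.tip(tree, setdiff(tree$tip.label, miss))
  }
  states <- states[tree$tip.label]
  observed <- fitchParsimony(tree, states)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i) {
    perm <- stats::setNames(sample(unname(states)), names(states))
    fitchParsimony(tree, perm)
  }, integer(1))
  list(observed = observed,
       null = null,
       p = (1 + sum(null <= observed)) / (nPerm + 1),
       nPerm = nPerm,
       seed = as.integer(seed))
}

#' Export a permutation null distribution as TSV
#' @param result list from [parsimonyRandomization()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeParsimonyNull <- function(result, path) {
  utils::write.table(
    data.frame(permutation = seq_along(result$null), score = result$null),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
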