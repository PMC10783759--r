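# Independent brute-force oracles. These deliberately avoid the code paths
# used by the package (no cophenetic, no phangorn::Descendants): distances
# come from shortest paths on the edge graph, clades from a hand-rolled
# recursion over the edge table, parsimony from exhaustive enumeration.

randomTestTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  tr
}

# patristic distances via igraph shortest paths over the undirected edge graph
oraclePatristic <- function(tree) {
  n <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g, v = as.character(1:n), to = as.character(1:n))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# every clade's tip-label set, by direct recursion on the edge table
oracleClades <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tipsBelow <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tipsBelow))
  }
  nodes <- c(seq_len(n), as.integer(names(kids)))
  lapply(nodes, function(v) sort(tipsBelow(v)))
}

# maximal clades contained in a leaf subset, as an order-free set of sets
oracleMaximalContained <- function(tree, leafset) {
  cl <- oracleClades(tree)
  contained <- Filter(function(s) all(s %in% leafset), cl)
  contained <- unique(contained)
  maximal <- Filter(function(s) {
    !any(vapply(contained, function(t2) {
      length(t2) > length(s) && all(s %in% t2)
    }, logical(1)))
  }, contained)
  # canonical form for comparison
  sort(vapply(maximal, function(s) paste(s, collapse = ","), character(1)))
}

canonicalSets <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1)))
}

# exhaustive small parsimony: minimize changes over all internal-state
# assignments
oracleFitch <- function(tree, states) {
  n <- length(tree$tip.label)
  uni <- sort(unique(as.character(states)))
  nodeState <- integer(n + tree$Nnode)
  nodeState[seq_len(n)] <- match(as.character(states[tree$tip.label]), uni)
  internals <- (n + 1L):(n + tree$Nnode)
  grid <- expand.grid(rep(list(seq_along(uni)), length(internals)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    nodeState[internals] <- as.integer(grid[r, ])
    changes <- sum(nodeState[tree$edge[, 1]] != nodeState[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
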