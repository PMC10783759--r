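---
title: "Tree-based subfamily detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based subfamily detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subfam)
```

## The problem

Protein families commonly split into functional subfamilies that appear as
tight clades in a phylogenetic tree: groups of sequences with short mutual
distances, hanging off the backbone on long stem branches. Manually cutting
a tree into such groups requires choosing a distance threshold, and the
result is sensitive to that ad hoc choice. `subfam` automates the cut: the
only inputs are a rooted tree with branch lengths and, optionally, a
leaf-annotation table used for an independent concordance test.

## The pipeline

1. **Patristic distance matrix (PDM).** Entry \((i, j)\) is the sum of
   branch lengths on the unique path between leaves \(i\) and \(j\); rows
   follow the tree's tip order.
2. **Embedding.** The PDM is consumed as a precomputed metric by UMAP
   (uwot), producing an \(n \times d\) point cloud (default \(d = 2\)).
   UMAP's local-density normalization turns tight clades into compact,
   well-separated blobs, which is what makes the next stage's model
   selection behave: the mixture stage counts blobs, not raw branch-length
   structure. For trees with fewer than 8 leaves, neighborhood-graph
   methods are unreliable and classical metric scaling (`cmdscale`) of the
   PDM is used instead; the route taken is recorded in the run metadata.
3. **Gaussian mixture sweep.** One full-covariance Gaussian mixture is
   fitted per component count \(k = 1..k_{max}\) (default
   \(\min(n - 1, 50)\)) and scored by
   \[ \mathrm{BIC}(k) = p \ln n - 2 \ln \hat L, \qquad
      p = (k - 1) + k d + k d (d + 1) / 2 , \]
   lower being better. The minimum-BIC model wins, ties going to the
   smaller \(k\); hard maximum-posterior labels (integers from 0) are
   carried forward.
4. **Monophyletic cluster maximization.** Each mixture cluster is checked
   for monophyly on the rooted tree. A non-monophyletic cluster with base
   label \(B\) is recursively decomposed into the maximal clades of the
   tree contained in it; because the clades of a rooted tree form a laminar
   family, this decomposition is unique, its parts are disjoint and cover
   the cluster. Parts are labeled \(B.0, B.1, \dots\) in extraction order
   (size descending, ties toward the part holding the lexicographically
   smallest leaf).
5. **Divergence scoring.** Each final cluster gets
   \(\log(\mathrm{MPD} / \ell_{sub})\), where MPD is the mean patristic
   distance over unordered leaf pairs in the cluster and \(\ell_{sub}\)
   the branch from the cluster's MRCA to its parent. Strongly negative
   scores flag tight clusters on long stems — candidates for strong
   purifying selection. The score is invariant under global rescaling of
   branch lengths.
6. **Annotation concordance (optional).** Annotations are collapsed to
   categorical keys (first 3 characters by default), the Fitch parsimony
   score of the keys on the tree is computed, and compared against the
   null distribution obtained by uniformly permuting the leaf-to-key
   assignment; \(p = (1 + \#\{null \le obs\}) / (n_{perm} + 1)\).

## Parameters that matter

| parameter | default | notes |
|---|---|---|
| embedding dimension `d` | 2 | 2–10 allowed; 2 suffices for cluster counting and is plottable |
| UMAP neighborhood | min(15, n − 1) | library default, clamped |
| UMAP `min_dist` | 0.1 | library default |
| `kMax` | min(n − 1, 50) | sweeping far beyond the plausible cluster count is harmless, the BIC curve is U-shaped |
| log base | natural | base 10 available; changes scale, not ranking |
| annotation key length | 3 | configurable; regex extractor available |
| master seed | 42 | derives all per-stage seeds; identical config + seed gives byte-identical outputs |

## Numerical choices

* **Covariance regularization.** The likelihood of an unconstrained
  Gaussian mixture is unbounded: a component can collapse onto a single
  point with vanishing covariance, and with a small fixed diagonal floor
  (say \(10^{-6}\)) BIC will happily select dozens of such degenerate
  components — on embedded trees this failure is systematic, not
  hypothetical. The sweep therefore fits under mclust's conjugate
  (normal-inverse-Wishart) prior, which scales regularization to the data
  covariance and keeps the likelihood bounded. The reported BIC is still
  \(p \ln n - 2 \ln \hat L\) with the full-covariance parameter count.
* **Initialization and determinism.** mclust's model-based hierarchical
  initialization is deterministic, so the sweep needs no random restarts;
  the pipeline is exactly reproducible for a fixed seed (the embedding is
  the only seeded stochastic stage).
* **Tie-breaks.** Equal BIC: smaller \(k\) (parsimony). Equal-size clades
  during decomposition: the one containing the lexicographically smallest
  leaf label is extracted first.
* **Degenerate inputs.** Duplicate leaf labels, missing or negative branch
  lengths, and unrooted input are hard errors (midpoint rooting is opt-in
  and recorded in metadata). Zero-length branches are allowed. Undefined
  divergence scores are reported as missing values with reason codes
  (`singleton`, `root-cluster`, `zero-subtending`), never as infinities.
* **Polytomies in the parsimony test.** Fitch is generalized as
  intersection-if-nonempty-else-union over all children of a node, one
  change counted per empty intersection; exact on binary trees, a
  documented approximation on multifurcations.

## The synthetic generator

`simulatePlantedTree()` emulates the regime the pipeline targets: discrete
subfamilies separated by long branches. Each planted clade is a tight
radiation — random-split topology, internal branches drawn
Exp(mean = 0.01 × height), terminal branches extended so tips sit at depth
about the clade height with ±10% jitter — and the clades hang off a
caterpillar or balanced backbone with stems of length `stemLength`. With
the defaults (height 0.02, stem 1.0) the between-clade patristic scale
exceeds the within-clade scale 50-fold, the separation regime of a tree
with clear subfamilies. A single-clade tree (`nClades = 1`) has no long
internal branches at all and serves as the negative control: a correct
pipeline should report one cluster.

What the generator deliberately does **not** emulate: rate heterogeneity
across clades, paraphyletic annotation noise, gradual (threshold-free)
cluster boundaries, and within-clade substructure such as deep coalescent
splits. Passing the planted-partition tests therefore shows the pipeline
counts and delimits *well-separated* clades correctly; it does not certify
behavior on trees whose subfamily boundaries are intrinsically ambiguous —
on real data the BIC sweep tends to over-split rather than merge when
separation is weak, and singleton clusters should be read with care.

## Validation problem sizes

The test suite exercises: planted trees with 2–6 clades of 8–15 leaves
(10 seeds per configuration) plus 40-leaf single-clade negative controls;
1000 random clade-decomposition cases against an exhaustive
maximal-contained-clade oracle; 100 random trees against a shortest-path
patristic oracle and a double-loop MPD oracle; Gaussian mixtures with
1–5 components, 100 points each at 20σ separation, 10 seeds per count;
200 random Fitch cases against exhaustive internal-state minimization; and
permutation tests with 999 (power) / 99 (calibration) permutations. The
same quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Monophyly is evaluated on the rooted tree; results depend on correct
  rooting, which is why unrooted input is rejected rather than silently
  rooted.
* The mixture stage sees only the embedded geometry: extremely unequal
  cluster sizes or strong within-clade substructure can shift the selected
  \(k\) by one or two; the monophyly-maximization stage then still returns
  clean clades, but their granularity follows the mixture.
* UMAP coordinates are implementation-defined: reproducibility is
  guaranteed for a fixed seed and library version, not across versions.
* The divergence log ratio is undefined for singletons and the root
  cluster; downstream analyses should treat those as missing, not zero.
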