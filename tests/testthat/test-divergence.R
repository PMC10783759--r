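toyTree <- function() ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")

test_that("mean pairwise distance matches hand-computed values", {
  pdm <- patristicMatrix(toyTree())
  expect_equal(meanPairwiseDistance(pdm, c("A", "B")), 3)
  expect_equal(meanPairwiseDistance(pdm, c("A", "B", "C")), 32 / 3)
  expect_equal(meanPairwiseDistance(pdm, "A"), 0)
  expect_error(meanPairwiseDistance(pdm, c("A", "Z")), "unknown")
})

test_that("mean pairwise distance equals a double-loop brute force", {
  for (i in 1:20) {
    tr <- randomTestTree(sample(4:15, 1), seed = 3000 + i)
    pdm <- patristicMatrix(tr)
    set.seed(i)
    sub <- sample(tr$tip.label, sample(2:length(tr$tip.label), 1))
    acc <- 0
    for (a in seq_along(sub)) for (b in seq_along(sub)) {
      if (a < b) acc <- acc + pdm[sub[a], sub[b]]
    }
    expect_lt(abs(meanPairwiseDistance(pdm, sub) -
                  acc / choose(length(sub), 2)), 1e-9)
  }
})

test_that("subtending branch length reads the MRCA's parent edge", {
  tr <- toyTree()
  expect_equal(subtendingBranchLength(tr, c("A", "B")), 3)
  expect_equal(subtendingBranchLength(tr, "C"), 4)   # a leaf's own branch
  full <- subtendingBranchLength(tr, tr$tip.label)
  expect_true(is.na(full))
  expect_identical(attr(full, "reason"), "root-cluster")
  expect_error(subtendingBranchLength(tr, c("A", "C")), "not monophyletic")
})

test_that("log ratio follows the MPD/subtending orientation and reason codes", {
  expect_equal(logRatio(3, 3), 0)
  b <- 0.37
  expect_equal(logRatio(exp(1) * b, b), 1)
  expect_equal(logRatio(100, 10, base = 10), 1)
  # tight cluster on a long stem is strongly negative
  expect_lt(logRatio(0.01, 10), -6)
  s <- logRatio(0, 5)
  expect_true(is.na(s) && attr(s, "reason") == "singleton")
  z <- logRatio(2, 0)
  expect_true(is.na(z) && attr(z, "reason") == "zero-subtending")
  r <- logRatio(2, subtendingBranchLength(toyTree(), toyTree()$tip.label))
  expect_true(is.na(r) && attr(r, "reason") == "root-cluster")
  expect_error(logRatio(-1, 2), "non-negative")
})

test_that("divergence report composes the three operations per cluster", {
  tr <- toyTree()
  pdm <- patristicMatrix(tr)
  part <- maximizeMonophyly(tr, c(A = 0, B = 0, C = 1, D = 1))
  rep1 <- divergenceReport(tr, pdm, part)
  expect_equal(nrow(rep1), 2)
  expect_true(all(rep1$defined))
  expect_equal(rep1$mpd, c(3, 9))
  expect_equal(rep1$subtending_length, c(3, 6))
  expect_equal(rep1$log_ratio, c(log(1), log(9 / 6)))

  whole <- maximizeMonophyly(tr, setNames(rep(0, 4), tr$tip.label))
  rep2 <- divergenceReport(tr, pdm, whole)
  expect_false(rep2$defined)
  expect_identical(rep2$reason, "root-cluster")

  withSingleton <- maximizeMonophyly(tr, c(A = 0, B = 0, C = 1, D = 2))
  rep3 <- divergenceReport(tr, pdm, withSingleton)
  expect_identical(rep3$reason[rep3$cluster == "1"], "singleton")
  expect_identical(rep3$n_tips, c(2L, 1L, 1L))
})

test_that("log ratio is invariant under branch-length rescaling", {
  for (i in 1:5) {
    tr <- randomTestTree(10, seed = 4000 + i)
    pdm <- patristicMatrix(tr)
    set.seed(i)
    mix <- setNames(sample(0:1, 10, replace = TRUE), tr$tip.label)
    part <- maximizeMonophyly(tr, mix)
    r1 <- divergenceReport(tr, pdm, part)
    sc <- tr
    sc$edge.length <- sc$edge.length * 137.5
    r2 <- divergenceReport(sc, patristicMatrix(sc), part)
    expect_equal(r2$mpd, r1$mpd * 137.5, tolerance = 1e-9)
    ok <- r1$defined
    expect_equal(r2$log_ratio[ok], r1$log_ratio[ok], tolerance = 1e-9)
  }
})

test_that("lengthening the subtending branch strictly lowers the score", {
  tr <- toyTree()
  part <- maximizeMonophyly(tr, c(A = 0, B = 0, C = 1, D = 1))
  base <- divergenceReport(tr, patristicMatrix(tr), part)
  longer <- tr
  stemEdge <- which(longer$edge[, 2] == ape::getMRCA(longer, c("A", "B")))
  longer$edge.length[stemEdge] <- longer$edge.length[stemEdge] * 4
  after <- divergenceReport(longer, patristicMatrix(longer), part)
  expect_lt(after$log_ratio[after$cluster == "0"],
            base$log_ratio[base$cluster == "0"])
})
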