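test_that("annotation keys default to 3-character prefixes", {
  ann <- c(L1 = "porin_OmpA", L2 = "porin_OmpC", L3 = "efflux_TolC")
  expect_identical(unname(annotationKeys(ann)), c("por", "por", "eff"))
  expect_identical(unname(annotationKeys(ann, keyLength = 5)),
                   c("porin", "porin", "efflu"))
  expect_identical(unname(annotationKeys(ann, pattern = "^([a-z]+)_")),
                   c("porin", "porin", "efflux"))
  expect_error(annotationKeys(c(L1 = "abc"), pattern = "^X(Y)"), "did not match")
  expect_error(annotationKeys(unname(ann)), "named")
})

test_that("Fitch parsimony matches hand-worked cases", {
  tr5 <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  expect_identical(fitchParsimony(tr5, c(A = "x", B = "x", C = "x", D = "x", E = "x")), 0L)
  expect_identical(fitchParsimony(tr5, c(A = "x", B = "x", C = "x", D = "y", E = "y")), 1L)
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_identical(fitchParsimony(tr2, c(A = "x", B = "y")), 1L)
  expect_error(fitchParsimony(tr5, c(A = "x", B = "x")), "no state")
  expect_identical(
    fitchParsimony(tr5, c(A = "x", B = "x", C = "y"), dropUncovered = TRUE), 1L)
})

test_that("Fitch equals exhaustive internal-state minimization", {
  for (i in 1:40) {
    n <- sample(4:8, 1)
    tr <- randomTestTree(n, seed = 5000 + i)
    set.seed(i)
    st <- setNames(sample(letters[1:3], n, replace = TRUE), tr$tip.label)
    expect_identical(as.integer(fitchParsimony(tr, st)),
                     as.integer(oracleFitch(tr, st)))
  }
})

test_that("parsimony score is bounded and invariant under state relabeling", {
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tr <- randomTestTree(n, seed = 6000 + i)
    set.seed(i)
    st <- setNames(sample(c("u", "v", "w"), n, replace = TRUE), tr$tip.label)
    sc <- fitchParsimony(tr, st)
    expect_gte(sc, 0L)
    expect_lte(sc, n - 1L)
    if (length(unique(st)) == 1L) expect_identical(sc, 0L)
    swapped <- c(u = "w", v = "u", w = "v")[st]
    names(swapped) <- names(st)
    expect_identical(fitchParsimony(tr, swapped), sc)
  }
})

test_that("randomization test flags planted concordance and keeps its seed contract", {
  sim <- simulatePlantedTree(2, c(12, 12), seed = 21)
  states <- setNames(paste0("s", sim$partition), names(sim$partition))
  res <- parsimonyRandomization(sim$tree, states, nPerm = 199, seed = 21)
  expect_identical(res$observed, 1L)
  expect_lte(res$p, 0.01)
  expect_length(res$null, 199)
  res2 <- parsimonyRandomization(sim$tree, states, nPerm = 199, seed = 21)
  expect_identical(res2$null, res$null)

  # constant states: every permutation ties the observed score, so p = 1
  const <- setNames(rep("s", length(sim$partition)), names(sim$partition))
  expect_equal(parsimonyRandomization(sim$tree, const, nPerm = 1, seed = 1)$p, 1)
})

test_that("random labels are not flagged in the large majority of repeats", {
  sim <- simulatePlantedTree(2, c(10, 10), seed = 22)
  hits <- 0L
  for (s in 1:10) {
    set.seed(s + 700)
    st <- setNames(sample(c("a", "b"), 20, replace = TRUE), names(sim$partition))
    p <- parsimonyRandomization(sim$tree, st, nPerm = 99, seed = s)$p
    if (p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("null distribution TSV export is complete", {
  sim <- simulatePlantedTree(2, c(6, 6), seed = 23)
  st <- setNames(paste0("s", sim$partition), names(sim$partition))
  res <- parsimonyRandomization(sim$tree, st, nPerm = 25, seed = 3)
  tf <- tempfile()
  writeParsimonyNull(res, tf)
  expect_equal(nrow(read.delim(tf)), 25)
})
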