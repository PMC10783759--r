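test_that("newick parsing, validation and hard errors behave as specified", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):3,(C:4,D:5):6);", tf)
  tr <- readPhyloTree(tf)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_true(ape::is.rooted(tr))

  # 2-leaf tree: fine for distances, rejected by the clustering pipeline
  writeLines("(A:1,B:2);", tf)
  tr2 <- readPhyloTree(tf)
  expect_equal(patristicMatrix(tr2)["A", "B"], 3)
  expect_error(runPipeline(tr2), "at least 4 leaves")

  writeLines("(A:1,A:2);", tf)
  expect_error(readPhyloTree(tf), "duplicate leaf labels: A")

  writeLines("((A:1,B:2):3,(C,D:5):6);", tf)  # C has no branch length
  expect_error(readPhyloTree(tf), "branch length")

  writeLines("((A:1,B:-2):3,(C:4,D:5):6);", tf)
  expect_error(readPhyloTree(tf), "negative")

  # unrooted (basal trifurcation): rejected unless midpoint rooting is asked
  writeLines("(A:1,B:2,(C:4,D:5):6);", tf)
  expect_error(readPhyloTree(tf), "unrooted")
  trMid <- readPhyloTree(tf, midpointRoot = TRUE)
  expect_true(ape::is.rooted(trMid))
  expect_true(attr(trMid, "midpointRooted"))
})

test_that("nexus trees are read with translate tables resolved", {
  tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  tf <- tempfile(fileext = ".nex")
  ape::write.nexus(tr, file = tf, translate = TRUE)
  back <- readPhyloTree(tf)           # auto-detected from #NEXUS header
  expect_setequal(back$tip.label, c("A", "B", "C", "D"))
  expect_equal(patristicMatrix(back)["A", "C"], 14)
})

test_that("patristic matrix matches hand-computed path sums", {
  tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  pdm <- patristicMatrix(tr)
  expect_equal(pdm["A", "C"], 14)
  expect_equal(pdm["B", "D"], 16)
  expect_equal(pdm["C", "D"], 9)
  expect_equal(pdm, t(pdm))
  expect_equal(unname(diag(pdm)), rep(0, 4))
  expect_identical(rownames(pdm), tr$tip.label)
})

test_that("patristic matrix equals the path-enumeration oracle on random trees", {
  for (i in 1:30) {
    tr <- randomTestTree(sample(4:20, 1), seed = i)
    pdm <- patristicMatrix(tr)
    expect_lt(max(abs(pdm - oraclePatristic(tr)[rownames(pdm), colnames(pdm)])), 1e-9)
  }
})

test_that("patristic matrices satisfy the four-point condition", {
  for (i in 1:10) {
    tr <- randomTestTree(10, seed = 100 + i)
    pdm <- patristicMatrix(tr)
    scale <- max(pdm)
    quads <- utils::combn(rownames(pdm), 4)
    for (q in seq_len(min(ncol(quads), 30))) {
      l <- quads[, q]
      s <- sort(c(pdm[l[1], l[2]] + pdm[l[3], l[4]],
                  pdm[l[1], l[3]] + pdm[l[2], l[4]],
                  pdm[l[1], l[4]] + pdm[l[2], l[3]]))
      expect_lt(s[3] - s[2], 1e-6 * scale)
    }
  }
})

test_that("clustered-tree output carries labels and round-trips the tree", {
  tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  part <- c(A = "0", B = "0", C = "1", D = "1")
  nwk <- tempfile(fileext = ".nwk")
  writeClusteredTree(tr, part, nwk, format = "newick")
  txt <- readLines(nwk)
  expect_match(txt, "A|0", fixed = TRUE)
  expect_match(txt, "C|1", fixed = TRUE)

  back <- ape::read.tree(nwk)
  back$tip.label <- sub("\\|[0-9.]+$", "", back$tip.label)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  # same topology and branch lengths after stripping the label suffix
  o <- match(tr$tip.label, back$tip.label)
  expect_lt(max(abs(patristicMatrix(back)[tr$tip.label, tr$tip.label] -
                    patristicMatrix(tr))), 1e-9)

  nex <- tempfile(fileext = ".nex")
  writeClusteredTree(tr, part, nex, format = "nexus")
  lines <- readLines(nex)
  expect_true(any(grepl("[&!color=#", lines, fixed = TRUE)))
  # two clusters -> exactly two distinct colors
  cols <- regmatches(lines, regexpr("#[0-9A-Fa-f]{6}", lines))
  expect_length(unique(cols), 2)

  expect_error(writeClusteredTree(tr, c(A = "0"), nwk), "mismatch")
  expect_error(writeClusteredTree(tr, character(0), nwk), "empty")
})

test_that("round-trip through write/read preserves branch lengths to 1e-9", {
  for (i in 1:5) {
    tr <- randomTestTree(12, seed = 400 + i)
    tf <- tempfile(fileext = ".nwk")
    ape::write.tree(tr, file = tf, digits = 15)
    back <- readPhyloTree(tf)
    expect_lt(max(abs(patristicMatrix(back)[tr$tip.label, tr$tip.label] -
                      patristicMatrix(tr))), 1e-9)
  }
})
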