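#' Run the full subfamily clustering pipeline
#'
#' Executes the stages in order: read/validate tree, patristic distance
#' matrix, low-dimensional embedding, Gaussian-mixture BIC sweep,
#' monophyletic cluster maximization, divergence scoring, and (when
#' annotations are supplied) the Fitch parsimony randomization test.
#' One master seed deterministically derives the per-stage seeds, so a run
#' with identical config and seed reproduces its outputs byte for byte.
#'
#' @param tree a \code{phylo} tree, or a path to a newick/nexus file.
#' @param format file format when \code{tree} is a path ("auto", "newick",
#'   "nexus").
#' @param seed master seed (default 42).
#' @param d embedding dimensionality (default 2).
#' @param kMax mixture sweep upper bound; default \code{min(n - 1, 50)}.
#' @param logBase base of the divergence log ratio (default natural log).
#' @param midpointRoot allow midpoint rooting of unrooted input.
#' @param annotations optional named character vector leaf -> annotation
#'   string (or a 2-column TSV path: leaf_label, annotation).
#' @param keyLength annotation key length for the parsimony test.
#' @param nPerm permutations for the parsimony test.
#' @param outDir optional output directory; when given, all result files
#'   are written there atomically (staged in a temporary subdirectory that
#'   is renamed into place only on success).
#' @param ... further arguments passed to [embedDistances()].
#' @return a [SubfamilyRun-class] object.
#' @examples
#' sim <- simulatePlantedTree(3, 8, seed = 7)
#' run <- runPipeline(sim$tree, seed = 7)
#' nClusters(run)
#' @export
runPipeline <- function(tree, format = "auto", seed = 42L, d = 2L, kMax = NULL,
                        logBase = exp(1), midpointRoot = FALSE,
                        annotations = NULL, keyLength = 3L, nPerm = 999L,
                        outDir = NULL, ...) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage, since) {
    now <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(now - since, 3)
    now
  }
  seeds <- deriveStageSeeds(seed)

  if (is.character(tree)) {
    tree <- readPhyloTree(tree, format = format, midpointRoot = midpointRoot)
  } else {
    assertRootedTree(tree, minTips = 2L)
  }
  if (length(tree$tip.label) < 4L) {
    stop("clustering pipeline needs at least 4 leaves")
  }
  if (is.character(annotations) && length(annotations) == 1L && file.exists(annotations)) {
    tab <- utils::read.delim(annotations, header = TRUE, stringsAsFactors = FALSE)
    annotations <- stats::setNames(as.character(tab[[2]]), tab[[1]])
  }
  t1 <- tick("read", t0)

  pdm <- patristicMatrix(tree)
  t2 <- tick("pdm", t1)

  embedding <- embedDistances(pdm, d = d, seed = seeds[["embed"]], ...)
  t3 <- tick("embed", t2)

  sweep <- sweepGmm(embedding, kMax = kMax, seed = seeds[["mixture"]])
  t4 <- tick("mixture", t3)

  mixLabels <- clusterLabels(sweep)
  nonMono <- sum(!vapply(split(names(mixLabels), mixLabels),
                         function(m) isMonophyletic(tree, m), logical(1)))
  partition <- maximizeMonophyly(tree, mixLabels)
  final <- split(names(partition@labels), partition@labels)
  stopifnot(all(vapply(final, function(m) isMonophyletic(tree, m), logical(1))))
  t5 <- tick("mcim", t4)

  divergence <- divergenceReport(tree, pdm, partition, base = logBase)
  t6 <- tick("divergence", t5)

  annot <- list()
  if (!is.null(annotations)) {
    keys <- annotationKeys(annotations, keyLength = keyLength)
    annot <- parsimonyRandomization(tree, keys, nPerm = nPerm,
                                    seed = seeds[["permutation"]],
                                    dropUncovered = TRUE)
    tick("validate", t6)
  }

  reasons <- table(divergence$reason[divergence$reason != ""])
  metadata <- list(
    package_version = as.character(utils::packageVersion("subfam")),
    config = list(seed = as.integer(seed), d = as.integer(d),
                  kMax = if (is.null(kMax)) NA_integer_ else as.integer(kMax),
                  logBase = logBase, keyLength = as.integer(keyLength),
                  nPerm = as.integer(nPerm), midpointRoot = midpointRoot,
                  embed_method = attr(embedding, "method"),
                  embed_params = attr(embedding, "params"),
                  midpoint_applied = isTRUE(attr(tree, "midpointRooted"))),
    stage_seeds = as.list(seeds),
    timings = as.list(timings),
    counts = list(
      n_leaves = length(tree$tip.label),
      selected_k = sweep@selectedK,
      mixture_clusters = length(unique(mixLabels)),
      nonmonophyletic_clusters = nonMono,
      final_clusters = length(unique(partition@labels)),
      undefined_scores = as.list(reasons)
    )
  )

  run <- new("SubfamilyRun", tree = tree, pdm = pdm, embedding = embedding,
             sweep = sweep, partition = partition, divergence = divergence,
             annotation = annot, metadata = metadata)
  if (!is.null(outDir)) writeRunOutputs(run, outDir)
  run
}

# one master seed -> fixed per-stage seeds, all < 2^31
deriveStageSeeds <- function(seed) {
  set.seed(as.integer(seed))
  stats::setNames(sample.int(2147483646L, 3L),
                  c("embed", "mixture", "permutation"))
}

#' Write all outputs of a run to a directory
#'
#' Emits clusters.tsv, divergence.tsv, bic_curve.tsv, embedding.tsv,
#' annotated trees (newick + nexus with FigTree color comments),
#' metadata.json, run.log and, when a parsimony test was run,
#' permutation_null.tsv. Files are staged in a temporary sibling directory
#' and renamed into place, so a failed run leaves no partial output.
#'
#' @param run a [SubfamilyRun-class] object.
#' @param outDir target directory (created if needed).
#' @return \code{outDir}, invisibly.
#' @export
writeRunOutputs <- function(run, outDir) {
  parent <- dirname(normalizePath(outDir, mustWork = FALSE))
  dir.create(parent, recursive = TRUE, showWarnings = FALSE)
  stage <- file.path(parent, paste0(".stage-", basename(outDir), "-", Sys.getpid()))
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE), add = TRUE)

  writePartition(run@partition, file.path(stage, "clusters.tsv"))
  writeDivergence(run@divergence, file.path(stage, "divergence.tsv"))
  writeBicCurve(run@sweep, file.path(stage, "bic_curve.tsv"))
  writeEmbedding(run@embedding, file.path(stage, "embedding.tsv"))
  writeClusteredTree(run@tree, run@partition,
                     file.path(stage, "annotated_tree.nwk"), format = "newick")
  writeClusteredTree(run@tree, run@partition,
                     file.path(stage, "annotated_tree.nex"), format = "nexus")
  if (length(run@annotation)) {
    writeParsimonyNull(run@annotation, file.path(stage, "permutation_null.tsv"))
    summaryJson <- run@annotation[c("observed", "p", "nPerm", "seed")]
    jsonlite::write_json(summaryJson, file.path(stage, "parsimony_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run@metadata, file.path(stage, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- run@metadata
  logLines <- c(
    sprintf("leaves=%d", md$counts$n_leaves),
    sprintf("stage=%s wall=%.3fs", names(md$timings), unlist(md$timings)),
    sprintf("selected_k=%d mixture_clusters=%d nonmonophyletic=%d final_clusters=%d",
            md$counts$selected_k, md$counts$mixture_clusters,
            md$counts$nonmonophyletic_clusters, md$counts$final_clusters)
  )
  writeLines(logLines, file.path(stage, "run.log"))

  if (dir.exists(outDir)) unlink(outDir, recursive = TRUE)
  if (!file.rename(stage, outDir)) {   # cross-device fallback
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(stage, full.names = TRUE), outDir, overwrite = TRUE)
    unlink(stage, recursive = TRUE)
  }
  ok <- TRUE
  invisible(outDir)
}
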