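#' Sweep Gaussian mixture models and select by BIC
#'
#' Fits one full-covariance Gaussian mixture per component count
#' k = 1..\code{kMax} to the embedded points and scores each fit with the
#' Bayesian Information Criterion on the scale
#' \deqn{BIC(k) = p \ln n - 2 \ln \hat L,}
#' where the parameter count for a full-covariance mixture in d dimensions
#' is \eqn{p = (k - 1) + k d + k d (d + 1) / 2} (weights, means,
#' covariances). The model with the lowest BIC among converged fits is
#' selected, ties resolved toward smaller k; hard labels are the
#' maximum-posterior component per point, relabeled to consecutive
#' integers starting at 0.
#'
#' Fitting is delegated to \pkg{mclust} (EM with deterministic model-based
#' hierarchical initialization) under its conjugate prior
#' (\code{\link[mclust]{priorControl}}), which keeps the mixture likelihood
#' bounded: without it, components can collapse onto single points with
#' arbitrarily small covariance, and BIC would select those degenerate
#' fits. The sweep is deterministic; \code{seed} is recorded (and set) for
#' interface uniformity with the stochastic stages.
#'
#' @param embedding n x d coordinate matrix (rownames = leaf labels), as
#'   returned by [embedDistances()].
#' @param kMax largest component count to sweep; default
#'   \code{min(n - 1, 50)}.
#' @param seed integer seed, recorded in the result.
#' @return a [GmmSweep-class] object.
#' @import mclust
#' @examples
#' pts <- simulateMixturePoints(3, n = 60, separation = 10, sigma = 0.5, seed = 1)
#' sw <- sweepGmm(pts$points, kMax = 6)
#' selectedK(sw)
#' @export
sweepGmm <- function(embedding, kMax = NULL, seed = 42L) {
  X <- as.matrix(embedding)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 2L) stop("need at least 2 points")
  if (any(!is.finite(X))) stop("embedding has non-finite coordinates")
  if (is.null(kMax)) kMax <- min(n - 1L, 50L)
  kMax <- as.integer(kMax)
  if (kMax < 1L) stop("kMax must be >= 1")
  if (kMax >= n) stop("kMax = ", kMax, " must be smaller than the number of points n = ", n)

  set.seed(seed)
  bicTab <- suppressWarnings(
    mclust::mclustBIC(X, G = seq_len(kMax), modelNames = "VVV",
                      prior = mclust::priorControl(), verbose = FALSE)
  )
  mbic <- as.numeric(bicTab[, "VVV"])   # mclust scale: 2 lnL - p ln n
  ks <- seq_len(kMax)
  p <- (ks - 1) + ks * d + ks * d * (d + 1) / 2
  loglik <- (mbic + p * log(n)) / 2
  bic <- p * log(n) - 2 * loglik        # = -mbic, the reported scale
  converged <- is.finite(bic)
  if (!any(converged)) {
    stop("no mixture fit converged for any k in 1..", kMax,
         " (n = ", n, ", d = ", d, ")")
  }
  best <- min(bic[converged])
  selK <- ks[converged][which(bic[converged] <= best + 1e-12)[1L]]

  fit <- suppressWarnings(
    mclust::Mclust(X, G = selK, modelNames = "VVV",
                   prior = mclust::priorControl(), verbose = FALSE)
  )
  if (is.null(fit)) stop("refit of the selected model (k = ", selK, ") failed")
  raw <- fit$classification
  # map to consecutive 0-based labels; components left empty by the
  # prior-regularized fit are dropped from the labeling
  labels <- stats::setNames(match(raw, sort(unique(raw))) - 1L, rownames(X))

  new("GmmSweep",
      table = data.frame(k = ks, loglik = loglik, bic = bic, converged = converged),
      selectedK = as.integer(selK),
      labels = labels,
      d = as.integer(d),
      seed = as.integer(seed))
}

#' Write the BIC curve of a sweep as TSV
#'
#' @param sweep a [GmmSweep-class] object (or \code{SubfamilyRun}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBicCurve <- function(sweep, path) {
  utils::write.table(bicCurve(sweep), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
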