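#' Column-wise cross-correlation of two basis matrices
#'
#' H[i, j] is the Pearson correlation between column i of B1 and column j
#' of B2; zero-variance columns correlate 0 with everything.
#'
#' @param B1,B2 matrices of identical shape with k columns each.
#' @return A k x k correlation matrix.
#' @export
crossCorrelationMatrix <- function(B1, B2) {
  if (!all(dim(B1) == dim(B2))) stop("B1 and B2 must have the same shape")
  H <- suppressWarnings(stats::cor(B1, B2))
  H[!is.finite(H)] <- 0
  H
}

#' Dissimilarity of two factorization bases
#'
#' \deqn{diss(B_1, B_2) = \frac{1}{2k}\Big(2k - \sum_j \max_i h_{ij}
#'   - \sum_i \max_j h_{ij}\Big)}
#' over the cross-correlation matrix H: zero when the columns match up to
#' permutation, approaching one when no column of either basis correlates
#' with any column of the other. Symmetric in its arguments.
#'
#' @param B1,B2 basis matrices of identical shape.
#' @return A real value in [0, 1] (up to correlation noise).
#' @export
dissimilarity <- function(B1, B2) {
  H <- crossCorrelationMatrix(B1, B2)
  k <- ncol(H)
  (2 * k - sum(apply(H, 2L, max)) - sum(apply(H, 1L, max))) / (2 * k)
}

#' Instability of a set of factorization bases
#'
#' \deqn{\Upsilon(k) = \frac{2}{\tau(\tau-1)} \sum_{i<j} diss(B_i, B_j),}
#' the mean pairwise dissimilarity over tau random restarts; a stable rank
#' reproduces the same basis (up to column permutation) from every
#' restart and scores near 0.
#'
#' @param bases list of >= 2 basis matrices of identical shape.
#' @return Mean pairwise dissimilarity in [0, 1].
#' @export
instability <- function(bases) {
  tau <- length(bases)
  if (tau < 2L) stop("need at least 2 basis matrices")
  total <- 0
  for (i in seq_len(tau - 1L))
    for (j in seq(i + 1L, tau))
      total <- total + dissimilarity(bases[[i]], bases[[j]])
  total / choose(tau, 2L)
}

#' Instability-based rank selection
#'
#' Fits `tau` randomly initialized models at every candidate rank, scores
#' each rank by the instability of its basis matrices, and returns the
#' rank minimizing the curve (ties broken toward the smallest rank).
#'
#' @param X training [AnnotationMatrix-class] (or matrix with `nl`).
#' @param couplings list of [CouplingMatrix-class].
#' @param alpha regularization weight used for every fit.
#' @param kGrid candidate ranks.
#' @param tau restarts per rank (>= 2).
#' @param seed base seed; the tau * length(kGrid) restart seeds are derived
#'   from it and recorded in the returned curve.
#' @param iterations iteration budget per fit.
#' @param ... further arguments passed to [mprnmf()].
#' @return list(bestK, curve) where curve is an
#'   [InstabilityCurve-class].
#' @export
selectRank <- function(X, couplings = list(), alpha = 1,
                       kGrid = seq(40L, 64L, by = 4L), tau = 10L,
                       seed = 1L, iterations = 100L, ...) {
  kGrid <- sort(as.integer(kGrid))
  tau <- as.integer(tau)
  if (tau < 2L) stop("tau must be >= 2")
  seeds <- deriveSeeds(seed, tau * length(kGrid))
  ups <- numeric(length(kGrid))
  for (ki in seq_along(kGrid)) {
    ss <- seeds[(ki - 1L) * tau + seq_len(tau)]
    bases <- lapply(ss, function(s)
      basisMatrix(mprnmf(X, couplings, k = kGrid[ki], alpha = alpha,
                         iterations = iterations, seed = s, ...)))
    ups[ki] <- instability(bases)
  }
  curve <- new("InstabilityCurve", k = kGrid, upsilon = ups, tau = tau,
               seeds = as.integer(seeds))
  list(bestK = kGrid[which.min(ups)], curve = curve)
}

#' Fmax sensitivity sweep over the regularization weight
#'
#' Fits one model per alpha on the training annotations and evaluates each
#' on held-out lncRNA annotations: scores of training positives are zeroed
#' (they are not recoveries) and Fmax is computed against the hidden truth
#' sets via [fmaxCurve()].
#'
#' @param X training [AnnotationMatrix-class].
#' @param couplings list of [CouplingMatrix-class].
#' @param alphaGrid regularization weights to sweep.
#' @param k factorization rank.
#' @param truth named list: hidden true term sets per evaluated lncRNA.
#' @param grid score threshold grid for the Fmax sweep.
#' @param seed,iterations,restarts fit controls (one common seed: the
#'   sweep isolates alpha).
#' @return data.frame (alpha, fmax).
#' @export
sweepAlpha <- function(X, couplings, alphaGrid = seq(0.1, 1.9, by = 0.2),
                       k, truth, grid = seq(0, 1, by = 0.01), seed = 1L,
                       iterations = 100L, restarts = 1L) {
  f <- vapply(alphaGrid, function(a) {
    fit <- mprnmf(X, couplings, k = k, alpha = a, iterations = iterations,
                  seed = seed, restarts = restarts)
    S <- heldOutScores(fit, X)
    fmaxCurve(S, truth, grid)@fmax
  }, 0)
  data.frame(alpha = alphaGrid, fmax = f)
}

#' Held-out prediction scores
#'
#' Min-max-scaled model scores with the entries already positive in the
#' training matrix set to 0, so only novel (held-out) associations can be
#' predicted.
#'
#' @param model a fitted [FactorModel-class].
#' @param trainX the training [AnnotationMatrix-class].
#' @return terms x lncRNAs score matrix.
#' @export
heldOutScores <- function(model, trainX) {
  S <- predictScores(model)
  trainL <- trainX@X[, seq_along(trainX@lncIds), drop = FALSE]
  S[trainL == 1] <- 0
  S
}
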