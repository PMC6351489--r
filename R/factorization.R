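#' Coupling matrix of a view
#'
#' Zeroes the within-class blocks of the bi-colored matrix, keeping only
#' the cross-class associations: \eqn{C^* = [[0, Y], [Y', 0]]}. This is the
#' operator through which each view partially regularizes the feature
#' matrix.
#'
#' @param view a [BipartiteView-class].
#' @return A [CouplingMatrix-class].
#' @export
buildCoupling <- function(view) {
  nl <- length(view@lncIds); ng <- length(view@geneIds)
  C <- matrix(0, nl + ng, nl + ng)
  C[seq_len(nl), nl + seq_len(ng)] <- view@Y
  C[nl + seq_len(ng), seq_len(nl)] <- t(view@Y)
  ids <- c(view@lncIds, view@geneIds)
  dimnames(C) <- list(ids, ids)
  new("CouplingMatrix", Cmat = C, lncIds = view@lncIds, geneIds = view@geneIds,
      name = view@name)
}

.couplingList <- function(couplings) {
  if (is(couplings, "CouplingMatrix")) couplings <- list(couplings)
  lapply(couplings, function(cp) {
    if (is(cp, "CouplingMatrix")) cp@Cmat
    else if (is(cp, "BipartiteView")) buildCoupling(cp)@Cmat
    else as.matrix(cp)
  })
}

#' Partially regularized NMF objective
#'
#' \deqn{J = \|X - BF\|_F^2 - \alpha \sum_i tr(F C_i^* F')}
#' The trace term rewards agreement between the lncRNA and gene feature
#' blocks along each view's associations (tr(F C* F') = 2 tr(F_l Y F_g')),
#' so it enters with a negative sign; with alpha = 0 the objective is the
#' plain squared Frobenius reconstruction error.
#'
#' @param X binary annotation matrix (terms x entities) or
#'   [AnnotationMatrix-class].
#' @param B,F nonnegative factors (terms x k, k x entities).
#' @param couplings list of [CouplingMatrix-class] (or raw matrices); may
#'   be empty.
#' @param alpha nonnegative regularization weight.
#' @return The objective value (finite scalar).
#' @export
mprObjective <- function(X, B, F, couplings = list(), alpha = 0) {
  X <- .asAnnotationInput(X)
  .assertFinite(X, "X"); .assertFinite(B, "B"); .assertFinite(F, "F")
  if (alpha < 0) stop("alpha must be nonnegative")
  J <- sum((X - B %*% F)^2)
  if (alpha > 0 && length(couplings)) {
    for (C in .couplingList(couplings))
      J <- J - alpha * sum((F %*% C) * F)   # tr(F C F')
  }
  J
}

#' Multiplicative update of the basis matrix
#'
#' One Lee-Seung step \eqn{B \leftarrow B \odot (X F') / (B F F')}
#' (elementwise; denominator guarded by 1e-12). The damped "sqrt" variant
#' multiplies by the elementwise square root of the same ratio. Zero
#' entries of B stay zero.
#'
#' @param B,F current factors.
#' @param X annotation matrix (terms x entities).
#' @param variant "standard" or "sqrt".
#' @return The updated basis matrix.
#' @export
updateBasis <- function(B, F, X, variant = c("standard", "sqrt")) {
  variant <- match.arg(variant)
  X <- .asAnnotationInput(X)
  if (nrow(B) != nrow(X) || ncol(F) != ncol(X) || ncol(B) != nrow(F))
    stop("factor/annotation shapes do not conform")
  ratio <- (X %*% t(F)) / (B %*% F %*% t(F) + .EPS)
  if (variant == "sqrt") ratio <- sqrt(ratio)
  B2 <- B * ratio
  dimnames(B2) <- dimnames(B)
  B2
}

#' Multiplicative update of the feature matrix
#'
#' One step \eqn{F \leftarrow F \odot (B'X + \alpha \sum_i F C_i^*) /
#' (B'B F)} followed by renormalization of every entity column onto the
#' k-simplex (the l1/sparsity constraint). A column driven entirely to zero
#' is reset to uniform 1/k with a warning before normalization. Zero
#' entries otherwise stay zero.
#'
#' @param B,F current factors.
#' @param X annotation matrix (terms x entities).
#' @param couplings list of [CouplingMatrix-class] (or raw matrices).
#' @param alpha nonnegative regularization weight.
#' @param variant "standard" or "sqrt" (damped) multiplicative step.
#' @param normalize renormalize columns to sum 1 (the model's constraint;
#'   disable only to inspect the raw multiplicative step).
#' @return The updated feature matrix.
#' @export
updateFeatures <- function(B, F, X, couplings = list(), alpha = 0,
                           variant = c("standard", "sqrt"),
                           normalize = TRUE) {
  variant <- match.arg(variant)
  X <- .asAnnotationInput(X)
  if (nrow(B) != nrow(X) || ncol(F) != ncol(X) || ncol(B) != nrow(F))
    stop("factor/annotation shapes do not conform")
  if (alpha < 0) stop("alpha must be nonnegative")
  num <- t(B) %*% X
  if (alpha > 0 && length(couplings))
    for (C in .couplingList(couplings)) num <- num + alpha * (F %*% C)
  ratio <- num / (t(B) %*% B %*% F + .EPS)
  if (variant == "sqrt") ratio <- sqrt(ratio)
  F2 <- F * ratio
  dimnames(F2) <- dimnames(F)
  if (normalize) {
    cs <- colSums(F2)
    dead <- cs <= 0
    if (any(dead)) {
      warning(sum(dead), " feature column(s) collapsed to zero; reset to uniform")
      F2[, dead] <- 1 / nrow(F2)
      cs[dead] <- 1
    }
    F2 <- sweep(F2, 2L, cs, "/")
  }
  F2
}

#' Fit the multi-view partially regularized NMF
#'
#' Alternates the multiplicative updates of [updateBasis()] and
#' [updateFeatures()] from a uniform(0, 1) random initialization (feature
#' columns normalized onto the simplex) until the iteration budget is
#' exhausted or the relative objective change falls below `tol`. The
#' objective is recorded at initialization and after every completed
#' iteration.
#'
#' @param X [AnnotationMatrix-class] or binary terms-by-entities matrix
#'   (lncRNA columns first).
#' @param couplings list of [CouplingMatrix-class], one per association
#'   view; may be empty (plain NMF).
#' @param k factorization rank, < min(n_o, n_l + n_g).
#' @param alpha nonnegative regularization weight shared across views.
#' @param iterations maximum iterations (default 100).
#' @param seed RNG seed for the random initialization.
#' @param tol early-stop threshold on |dJ| / |J| (default 1e-6).
#' @param variant multiplicative-update variant, see [updateBasis()].
#' @param nl number of lncRNA columns; taken from X when it is an
#'   [AnnotationMatrix-class].
#' @param restarts number of random initializations; the fit with the
#'   lowest final objective is kept (the multiplicative updates only find
#'   local optima, so a few restarts are standard practice). Restart seeds
#'   are derived deterministically from `seed`; the winning seed is
#'   recorded in the model.
#' @return A [FactorModel-class].
#' @examples
#' inst <- generateInstance(20, 40, 12, plantedK = 3, noise = 0.1,
#'                          maskFraction = 0.2, seed = 7)
#' fitNoReg <- mprnmf(inst@trainX, k = 3, alpha = 0, iterations = 50,
#'                    seed = 1)
#' tail(objectiveHistory(fitNoReg), 1)
#' @export
mprnmf <- function(X, couplings = list(), k, alpha = 1, iterations = 100L,
                   seed = 1L, tol = 1e-6,
                   variant = c("standard", "sqrt"), nl = NULL,
                   restarts = 1L) {
  variant <- match.arg(variant)
  if (restarts > 1L) {
    seeds <- deriveSeeds(seed, restarts)
    fits <- lapply(seeds, function(s)
      mprnmf(X, couplings, k = k, alpha = alpha, iterations = iterations,
             seed = s, tol = tol, variant = variant, nl = nl))
    finals <- vapply(fits, function(f)
      f@objectiveHistory[length(f@objectiveHistory)], 0)
    return(fits[[which.min(finals)]])
  }
  if (is(X, "AnnotationMatrix")) {
    termIds <- X@termIds; lncIds <- X@lncIds; geneIds <- X@geneIds
    Xm <- X@X
  } else {
    Xm <- as.matrix(X)
    if (is.null(nl)) stop("nl (number of lncRNA columns) required for plain matrices")
    termIds <- rownames(Xm) %||% paste0("o", seq_len(nrow(Xm)))
    ids <- colnames(Xm) %||% paste0("e", seq_len(ncol(Xm)))
    lncIds <- ids[seq_len(nl)]; geneIds <- ids[-seq_len(nl)]
  }
  n_o <- nrow(Xm); n <- ncol(Xm)
  k <- as.integer(k)
  if (k < 1L || k >= min(n_o, n))
    stop("k must satisfy 1 <= k < min(n_o, n_l + n_g)")
  if (alpha < 0) stop("alpha must be nonnegative")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  Cs <- .couplingList(couplings)

  init <- withSeed(seed, list(
    B = matrix(stats::runif(n_o * k), n_o, k),
    F = matrix(stats::runif(k * n), k, n)))
  B <- init$B
  F <- sweep(init$F, 2L, colSums(init$F), "/")

  J <- mprObjective(Xm, B, F, Cs, alpha)
  history <- numeric(iterations + 1L)
  history[1L] <- J
  done <- 0L
  for (it in seq_len(iterations)) {
    B <- updateBasis(B, F, Xm, variant = variant)
    F <- suppressWarnings(
      updateFeatures(B, F, Xm, Cs, alpha, variant = variant))
    Jnew <- mprObjective(Xm, B, F, Cs, alpha)
    if (!is.finite(Jnew))
      stop("objective became non-finite at iteration ", it)
    history[it + 1L] <- Jnew
    done <- it
    if (abs(Jnew - J) / max(abs(J), .EPS) < tol) break
    J <- Jnew
  }
  dimnames(B) <- list(termIds, NULL)
  dimnames(F) <- list(NULL, c(lncIds, geneIds))
  new("FactorModel", B = B, F = F, k = k, alpha = alpha,
      objectiveHistory = history[seq_len(done + 1L)],
      seed = as.integer(seed), termIds = termIds, lncIds = lncIds,
      geneIds = geneIds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn predictScores Scores are \eqn{B F_l} (basis times the lncRNA
#'   feature block), optionally min-max scaled to [0, 1] over the whole
#'   matrix so a common threshold grid applies.
#' @param rescale min-max scale the score matrix to [0, 1] (default TRUE).
#' @export
setMethod("predictScores", "FactorModel", function(object, rescale = TRUE) {
  S <- object@B %*% featureL(object)
  dimnames(S) <- list(object@termIds, object@lncIds)
  if (rescale) {
    rng <- range(S)
    S <- if (rng[2] > rng[1]) (S - rng[1]) / (rng[2] - rng[1])
         else S * 0
  }
  S
})
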