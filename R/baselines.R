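#' Label propagation on a homogeneous network
#'
#' Minimizes \eqn{\theta\, tr(\hat X L \hat X') + (1-\theta)\|\hat X - X\|^2}
#' over predicted associations \eqn{\hat X}, where L is the normalized
#' Laplacian of the network. Solved either in closed form,
#' \eqn{\hat X = (1-\theta) X (\theta L + (1-\theta) I)^{-1}}, or by the
#' fixed-point iteration \eqn{\hat X \leftarrow \theta \hat X \bar W +
#' (1-\theta) X} (contractive for any \eqn{\theta < 1}); the two agree to
#' numerical tolerance.
#'
#' @param X label matrix, terms x entities.
#' @param Wbar symmetrically normalized adjacency
#'   ([normalizeAdjacency()]).
#' @param theta mixing parameter in (0, 1); larger values weight network
#'   smoothness over fit to the known labels.
#' @param method "closed" (dense solve) or "iterative".
#' @param tol,maxIter iterative-solver controls.
#' @return A [PropagationResult-class] with method "lp".
#' @export
labelPropagation <- function(X, Wbar, theta = 0.5,
                             method = c("closed", "iterative"),
                             tol = 1e-12, maxIter = 10000L) {
  method <- match.arg(method)
  X <- .asAnnotationInput(X)
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (ncol(X) != nrow(Wbar)) stop("X columns must match the network order")
  Xhat <- .propagate(X, Wbar, theta, method, tol, maxIter)
  new("PropagationResult", scores = Xhat, method = "lp",
      params = list(theta = theta, solver = method))
}

.propagate <- function(X, Wbar, theta, method, tol, maxIter) {
  n <- nrow(Wbar)
  if (method == "closed") {
    # theta*L + (1-theta)*I = I - theta*Wbar
    (1 - theta) * X %*% solve(diag(n) - theta * Wbar)
  } else {
    Xhat <- X
    for (i in seq_len(maxIter)) {
      Xnew <- theta * Xhat %*% Wbar + (1 - theta) * X
      if (max(abs(Xnew - Xhat)) < tol) return(Xnew)
      Xhat <- Xnew
    }
    Xhat
  }
}

#' Label propagation on the bi-colored network
#'
#' The same objective as [labelPropagation()] applied to the normalized
#' adjacency of a bi-colored matrix, so gene annotation signal flows into
#' the lncRNA columns through the cross-class associations Y.
#'
#' @param X label matrix over both classes, terms x (n_l + n_g), lncRNA
#'   columns first.
#' @param C a [BiColoredMatrix-class].
#' @inheritParams labelPropagation
#' @return A [PropagationResult-class] with method "bicolored".
#' @export
bicoloredLabelPropagation <- function(X, C, theta = 0.5,
                                      method = c("closed", "iterative"),
                                      tol = 1e-12, maxIter = 10000L) {
  method <- match.arg(method)
  X <- .asAnnotationInput(X)
  Wbar <- normalizeAdjacency(C)
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (ncol(X) != nrow(Wbar)) stop("X columns must match n_l + n_g")
  Xhat <- .propagate(X, Wbar, theta, method, tol, maxIter)
  new("PropagationResult", scores = Xhat, method = "bicolored",
      params = list(theta = theta, solver = method))
}

#' Dual label propagation
#'
#' Minimizes \eqn{\|\hat X - X\|^2 + \beta\, tr(\hat X_g L_g \hat X_g') +
#' \gamma\, tr(\hat X_l L_l \hat X_l')}: the two entity classes are
#' smoothed independently over their own normalized Laplacians, giving the
#' decoupled closed forms \eqn{\hat X_l = X_l(\gamma L_l + I)^{-1}} and
#' \eqn{\hat X_g = X_g(\beta L_g + I)^{-1}}. Note this formulation carries
#' no lncRNA-gene coupling term.
#'
#' @param X label matrix, terms x (n_l + n_g), lncRNA columns first.
#' @param Lg,Ll normalized Laplacians of the gene and lncRNA networks
#'   ([laplacianMatrix()]).
#' @param beta,gamma nonnegative smoothing weights for the gene and lncRNA
#'   blocks.
#' @return A [PropagationResult-class] with method "dlp".
#' @export
dualLabelPropagation <- function(X, Lg, Ll, beta = 0.5, gamma = 0.5) {
  X <- .asAnnotationInput(X)
  if (beta < 0 || gamma < 0) stop("beta and gamma must be nonnegative")
  nl <- nrow(Ll); ng <- nrow(Lg)
  if (ncol(X) != nl + ng) stop("X columns must equal n_l + n_g")
  Xl <- X[, seq_len(nl), drop = FALSE]
  Xg <- X[, nl + seq_len(ng), drop = FALSE]
  Xhat <- cbind(Xl %*% solve(gamma * Ll + diag(nl)),
                Xg %*% solve(beta * Lg + diag(ng)))
  dimnames(Xhat) <- dimnames(X)
  new("PropagationResult", scores = Xhat, method = "dlp",
      params = list(beta = beta, gamma = gamma))
}

#' Truncated KATZ scores of a bi-colored network
#'
#' \deqn{S = \sum_{p=1}^{maxLen} \beta^p C^p,} a weighted count of paths of
#' length up to `maxLen`. With `maxLen = Inf` the closed form
#' \eqn{(I - \beta C)^{-1} - I} is used and requires
#' \eqn{\beta \rho(C) < 1}.
#'
#' @param C a [BiColoredMatrix-class] (or symmetric matrix).
#' @param beta path-damping factor > 0.
#' @param maxLen maximum path length (default 3), or Inf.
#' @return The symmetric score matrix S.
#' @export
katzScores <- function(C, beta = 0.01, maxLen = 3L) {
  Cm <- if (is(C, "BiColoredMatrix")) C@Cmat else as.matrix(C)
  if (beta < 0) stop("beta must be positive")
  if (is.infinite(maxLen)) {
    rho <- max(abs(eigen(Cm, symmetric = TRUE, only.values = TRUE)$values))
    if (beta * rho >= 1)
      stop("series diverges: beta * spectral radius >= 1")
    return(solve(diag(nrow(Cm)) - beta * Cm) - diag(nrow(Cm)))
  }
  S <- matrix(0, nrow(Cm), ncol(Cm), dimnames = dimnames(Cm))
  P <- diag(nrow(Cm))
  for (p in seq_len(maxLen)) {
    P <- P %*% Cm
    S <- S + beta^p * P
  }
  S
}

#' KATZ-based lncRNA-term predictions
#'
#' Applies the lncRNA-gene block of the KATZ score matrix to the gene
#' annotations: the score of (term o, lncRNA l) is
#' \eqn{\sum_g S_{lg}[l, g] X[o, g]}, i.e. the prediction matrix is
#' \eqn{X_g S_{lg}'}.
#'
#' @param C a [BiColoredMatrix-class].
#' @param X annotation matrix over both classes
#'   ([AnnotationMatrix-class] or matrix, lncRNA columns first).
#' @param beta,maxLen see [katzScores()].
#' @return A [PropagationResult-class] with method "katz"; scores are
#'   terms x lncRNAs.
#' @export
katzPredict <- function(C, X, beta = 0.01, maxLen = 3L) {
  nl <- length(C@lncIds); ng <- length(C@geneIds)
  Xm <- .asAnnotationInput(X)
  if (ncol(Xm) != nl + ng) stop("X columns must equal n_l + n_g")
  S <- katzScores(C, beta, maxLen)
  Slg <- S[seq_len(nl), nl + seq_len(ng), drop = FALSE]
  Xg <- Xm[, nl + seq_len(ng), drop = FALSE]
  scores <- Xg %*% t(Slg)
  dimnames(scores) <- list(rownames(Xm), C@lncIds)
  new("PropagationResult", scores = scores, method = "katz",
      params = list(beta = beta, maxLen = maxLen))
}
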