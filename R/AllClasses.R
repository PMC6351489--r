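#' @import methods
NULL

.isBinary <- function(m) all(m %in% c(0, 1))

#' Weighted undirected network over one entity class
#'
#' Holds a symmetric nonnegative adjacency matrix with zero diagonal over a
#' single class of entities (genes of a protein-protein interaction network,
#' or lncRNAs of a co-expression network), together with the entity
#' identifiers that define the row/column order.
#'
#' @slot ids character vector of entity identifiers (row/column order).
#' @slot W symmetric nonnegative numeric adjacency matrix, zero diagonal.
#' @export
setClass("EntityNetwork", representation(ids = "character", W = "matrix"))

setValidity("EntityNetwork", function(object) {
  W <- object@W
  if (nrow(W) != length(object@ids) || ncol(W) != length(object@ids))
    return("adjacency dimensions do not match the number of ids")
  if (anyDuplicated(object@ids)) return("duplicate entity ids")
  if (any(!is.finite(W))) return("non-finite adjacency entries")
  if (any(W < 0)) return("negative edge weights are not allowed")
  if (!isSymmetric(unname(W), tol = 1e-12)) return("adjacency must be symmetric")
  if (any(diag(W) != 0)) return("self-loops (non-zero diagonal) are not allowed")
  TRUE
})

#' Construct an EntityNetwork
#'
#' @param ids character vector of entity identifiers.
#' @param W symmetric nonnegative adjacency matrix with zero diagonal.
#' @return An [EntityNetwork-class] object.
#' @export
entityNetwork <- function(ids, W) {
  W <- as.matrix(W)
  dimnames(W) <- list(ids, ids)
  new("EntityNetwork", ids = as.character(ids), W = W)
}

#' One view of lncRNA-gene associations
#'
#' A nonnegative \eqn{n_l \times n_g} matrix linking lncRNAs (rows) to genes
#' (columns) under one data view: Pearson co-expression or shared-disease
#' Jaccard similarity.
#'
#' @slot name view label (e.g. "coexpression", "disease").
#' @slot lncIds,geneIds entity identifiers defining the row/column order.
#' @slot Y nonnegative numeric matrix, lncRNAs by genes.
#' @export
setClass("BipartiteView", representation(
  name = "character", lncIds = "character", geneIds = "character",
  Y = "matrix"))

setValidity("BipartiteView", function(object) {
  if (nrow(object@Y) != length(object@lncIds)) return("Y rows != #lncRNAs")
  if (ncol(object@Y) != length(object@geneIds)) return("Y cols != #genes")
  if (any(!is.finite(object@Y))) return("non-finite association values")
  if (any(object@Y < 0)) return("association values must be nonnegative")
  TRUE
})

#' Construct a BipartiteView
#'
#' @param name view label.
#' @param lncIds,geneIds entity identifiers.
#' @param Y nonnegative lncRNA-by-gene association matrix.
#' @return A [BipartiteView-class] object.
#' @export
bipartiteView <- function(name, lncIds, geneIds, Y) {
  Y <- as.matrix(Y)
  dimnames(Y) <- list(lncIds, geneIds)
  new("BipartiteView", name = name, lncIds = as.character(lncIds),
      geneIds = as.character(geneIds), Y = Y)
}

#' Bi-colored network matrix
#'
#' The single adjacency over both entity classes with block layout
#' \deqn{C = [[W_l, Y], [Y', W_g]],} lncRNAs indexed first.
#'
#' @slot Cmat symmetric nonnegative matrix of order \eqn{n_l + n_g}.
#' @slot lncIds,geneIds identifiers for the two blocks.
#' @export
setClass("BiColoredMatrix", representation(
  Cmat = "matrix", lncIds = "character", geneIds = "character"))

setValidity("BiColoredMatrix", function(object) {
  n <- length(object@lncIds) + length(object@geneIds)
  if (nrow(object@Cmat) != n || ncol(object@Cmat) != n)
    return("matrix order does not equal n_l + n_g")
  if (any(object@Cmat < 0)) return("entries must be nonnegative")
  if (!isSymmetric(unname(object@Cmat), tol = 1e-12)) return("C must be symmetric")
  TRUE
})

#' Coupling matrix of one association view
#'
#' The partial-regularization operator \eqn{C^* = [[0, Y], [Y', 0]]}: the
#' bi-colored matrix of a view with its within-class blocks zeroed, so that
#' only the cross-class associations regularize the factorization.
#'
#' @slot Cmat symmetric matrix with exactly zero diagonal blocks.
#' @slot lncIds,geneIds identifiers for the two blocks.
#' @slot name view label the coupling was built from.
#' @export
setClass("CouplingMatrix", representation(
  Cmat = "matrix", lncIds = "character", geneIds = "character",
  name = "character"))

setValidity("CouplingMatrix", function(object) {
  nl <- length(object@lncIds); ng <- length(object@geneIds)
  if (nrow(object@Cmat) != nl + ng || ncol(object@Cmat) != nl + ng)
    return("matrix order does not equal n_l + n_g")
  if (!isSymmetric(unname(object@Cmat), tol = 1e-12)) return("C* must be symmetric")
  if (nl > 0 && any(object@Cmat[seq_len(nl), seq_len(nl)] != 0))
    return("lncRNA diagonal block must be zero")
  if (ng > 0 && any(object@Cmat[nl + seq_len(ng), nl + seq_len(ng)] != 0))
    return("gene diagonal block must be zero")
  TRUE
})

#' Binary ontology-by-entity annotation matrix
#'
#' Rows are ontology terms, columns are entities with the lncRNA columns
#' first and the gene columns second (the single index convention used by
#' every matrix in the package).
#'
#' @slot X binary matrix, terms by entities.
#' @slot termIds,lncIds,geneIds identifiers defining row/column order.
#' @export
setClass("AnnotationMatrix", representation(
  X = "matrix", termIds = "character", lncIds = "character",
  geneIds = "character"))

setValidity("AnnotationMatrix", function(object) {
  if (nrow(object@X) != length(object@termIds)) return("X rows != #terms")
  if (ncol(object@X) != length(object@lncIds) + length(object@geneIds))
    return("X cols != n_l + n_g")
  if (!.isBinary(object@X)) return("annotation entries must be 0/1")
  TRUE
})

#' Construct an AnnotationMatrix
#'
#' @param X binary matrix, terms in rows, entities in columns with lncRNA
#'   columns first.
#' @param termIds,lncIds,geneIds identifiers.
#' @return An [AnnotationMatrix-class] object.
#' @export
annotationMatrix <- function(X, termIds, lncIds, geneIds) {
  X <- as.matrix(X)
  dimnames(X) <- list(termIds, c(lncIds, geneIds))
  new("AnnotationMatrix", X = X, termIds = as.character(termIds),
      lncIds = as.character(lncIds), geneIds = as.character(geneIds))
}

#' Fitted partially regularized NMF model
#'
#' The nonnegative factors of \eqn{X \approx BF} with the feature matrix
#' column-blocked as \eqn{F = [F_l | F_g]}, plus fitting metadata.
#'
#' @slot B nonnegative basis matrix, terms by rank.
#' @slot F nonnegative feature matrix, rank by entities; each column sums
#'   to one (simplex constraint).
#' @slot k factorization rank.
#' @slot alpha regularization weight shared across views.
#' @slot objectiveHistory objective value at initialization and after each
#'   completed iteration.
#' @slot seed RNG seed that produced the random initialization.
#' @slot termIds,lncIds,geneIds identifiers matching the training matrix.
#' @export
setClass("FactorModel", representation(
  B = "matrix", F = "matrix", k = "integer", alpha = "numeric",
  objectiveHistory = "numeric", seed = "integer",
  termIds = "character", lncIds = "character", geneIds = "character"))

setValidity("FactorModel", function(object) {
  if (any(object@B < 0) || any(object@F < 0))
    return("factors must be nonnegative")
  if (ncol(object@B) != object@k || nrow(object@F) != object@k)
    return("factor inner dimension != k")
  cs <- colSums(object@F)
  if (any(abs(cs - 1) > 1e-9)) return("feature columns must sum to 1")
  TRUE
})

#' Label/score propagation result
#'
#' @slot scores real score matrix, same shape as the propagated label matrix.
#' @slot method method name ("lp", "bicolored", "dlp", "katz").
#' @slot params named list of the parameters used.
#' @export
setClass("PropagationResult", representation(
  scores = "matrix", method = "character", params = "list"))

#' Instability curve across candidate ranks
#'
#' @slot k candidate ranks.
#' @slot upsilon instability \eqn{\Upsilon(k)} per rank, in [0, 1].
#' @slot tau number of random restarts per rank.
#' @slot seeds the restart seeds used (length tau * length(k)).
#' @export
setClass("InstabilityCurve", representation(
  k = "integer", upsilon = "numeric", tau = "integer", seeds = "integer"))

#' Threshold-swept evaluation report
#'
#' @slot curve data.frame with columns t, recall, precision, f.
#' @slot fmax maximum F-measure over the threshold grid.
#' @slot bestT smallest threshold attaining fmax.
#' @slot counts per-lncRNA (tp, fp, fn) at bestT.
#' @slot nAnnotated number of lncRNAs with at least one true positive at
#'   bestT.
#' @export
setClass("EvaluationReport", representation(
  curve = "data.frame", fmax = "numeric", bestT = "numeric",
  counts = "data.frame", nAnnotated = "integer"))

#' Coupled synthetic benchmark instance
#'
#' A jointly structured instance (expression, disease sets, PPI,
#' annotations) with planted latent function modules shared by lncRNAs and
#' genes, so that co-expression, disease overlap, network connectivity and
#' GO annotation all reflect the same hidden grouping.
#'
#' @slot exprL,exprG expression matrices (entities by samples).
#' @slot lncDiseases,geneDiseases named lists mapping each entity to its
#'   disease-identifier set.
#' @slot ppi gene-gene [EntityNetwork-class].
#' @slot truthX full [AnnotationMatrix-class] (ground truth).
#' @slot trainX truthX with a masked fraction of lncRNA annotations zeroed.
#' @slot mask data.frame (term, lnc) of the hidden positives.
#' @slot moduleL,moduleG planted module index of each lncRNA / gene.
#' @slot plantedK number of planted modules.
#' @slot seed generator seed.
#' @export
setClass("SyntheticInstance", representation(
  exprL = "matrix", exprG = "matrix",
  lncDiseases = "list", geneDiseases = "list",
  ppi = "EntityNetwork", truthX = "AnnotationMatrix",
  trainX = "AnnotationMatrix", mask = "data.frame",
  moduleL = "integer", moduleG = "integer",
  plantedK = "integer", seed = "integer"))

setValidity("SyntheticInstance", function(object) {
  if (any(object@trainX@X > object@truthX@X))
    return("trainX must be elementwise <= truthX")
  if (nrow(object@mask) > 0) {
    idx <- cbind(match(object@mask$term, object@truthX@termIds),
                 match(object@mask$lnc, object@truthX@lncIds))
    if (any(object@truthX@X[idx] != 1) || any(object@trainX@X[idx] != 0))
      return("masked pairs must be 1 in truthX and 0 in trainX")
  }
  if (!all(seq_len(object@plantedK) %in% object@moduleL) ||
      !all(seq_len(object@plantedK) %in% object@moduleG))
    return("every planted module needs at least one lncRNA and one gene")
  TRUE
})

setMethod("show", "EntityNetwork", function(object) {
  cat("EntityNetwork with", length(object@ids), "vertices and",
      sum(object@W[upper.tri(object@W)] > 0), "edges\n")
})

setMethod("show", "BipartiteView", function(object) {
  cat(sprintf("BipartiteView '%s': %d lncRNAs x %d genes, %d non-zero\n",
              object@name, nrow(object@Y), ncol(object@Y),
              sum(object@Y > 0)))
})

setMethod("show", "AnnotationMatrix", function(object) {
  cat(sprintf(
    "AnnotationMatrix: %d terms x (%d lncRNAs + %d genes), %d positives\n",
    length(object@termIds), length(object@lncIds), length(object@geneIds),
    sum(object@X)))
})

setMethod("show", "FactorModel", function(object) {
  J <- object@objectiveHistory
  cat(sprintf(
    "FactorModel: rank %d, alpha %.3g, %d iterations, J %.6g -> %.6g\n",
    object@k, object@alpha, length(J) - 1L, J[1], J[length(J)]))
})

setMethod("show", "InstabilityCurve", function(object) {
  cat("InstabilityCurve over k =", paste(object@k, collapse = ", "),
      sprintf("(tau = %d)\n", object@tau))
  print(stats::setNames(round(object@upsilon, 4), object@k))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport: Fmax %.4f at t = %.3g (%d lncRNAs annotated)\n",
    object@fmax, object@bestT, object@nAnnotated))
})

setMethod("show", "SyntheticInstance", function(object) {
  cat(sprintf(
    "SyntheticInstance: %d lncRNAs, %d genes, %d terms, %d planted modules, %d masked pairs\n",
    length(object@truthX@lncIds), length(object@truthX@geneIds),
    length(object@truthX@termIds), object@plantedK, nrow(object@mask)))
})
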