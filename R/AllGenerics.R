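#' Adjacency matrix of a network object
#'
#' @param x an [EntityNetwork-class] or [BiColoredMatrix-class].
#' @return The (symmetric, nonnegative) numeric adjacency matrix.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname adjacency
#' @export
setMethod("adjacency", "EntityNetwork", function(x) x@W)

#' @rdname adjacency
#' @export
setMethod("adjacency", "BiColoredMatrix", function(x) x@Cmat)

#' @rdname adjacency
#' @export
setMethod("adjacency", "CouplingMatrix", function(x) x@Cmat)

#' Entity identifiers of a network object
#'
#' @param x an object carrying entity ids.
#' @return Character vector of identifiers (lncRNAs first for two-class
#'   objects).
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @rdname entityIds
#' @export
setMethod("entityIds", "EntityNetwork", function(x) x@ids)

#' @rdname entityIds
#' @export
setMethod("entityIds", "BiColoredMatrix", function(x) c(x@lncIds, x@geneIds))

#' @rdname entityIds
#' @export
setMethod("entityIds", "AnnotationMatrix", function(x) c(x@lncIds, x@geneIds))

#' Association matrix of a bipartite view
#'
#' @param x a [BipartiteView-class].
#' @return The nonnegative lncRNA-by-gene matrix.
#' @export
setGeneric("viewMatrix", function(x) standardGeneric("viewMatrix"))

#' @rdname viewMatrix
#' @export
setMethod("viewMatrix", "BipartiteView", function(x) x@Y)

#' Annotation matrix accessors
#'
#' `annotations()` returns the binary term-by-entity matrix; `termIds()`,
#' `lncIds()` and `geneIds()` the identifier vectors.
#'
#' @param x an [AnnotationMatrix-class] (or, for the id accessors, any
#'   object carrying those slots).
#' @return A matrix or character vector.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname annotations
#' @export
setMethod("annotations", "AnnotationMatrix", function(x) x@X)

#' @rdname annotations
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname annotations
#' @export
setMethod("termIds", "AnnotationMatrix", function(x) x@termIds)

#' @rdname annotations
#' @export
setGeneric("lncIds", function(x) standardGeneric("lncIds"))

#' @rdname annotations
#' @export
setMethod("lncIds", "AnnotationMatrix", function(x) x@lncIds)

#' @rdname annotations
#' @export
setMethod("lncIds", "BipartiteView", function(x) x@lncIds)

#' @rdname annotations
#' @export
setMethod("lncIds", "FactorModel", function(x) x@lncIds)

#' @rdname annotations
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname annotations
#' @export
setMethod("geneIds", "AnnotationMatrix", function(x) x@geneIds)

#' @rdname annotations
#' @export
setMethod("geneIds", "BipartiteView", function(x) x@geneIds)

#' @rdname annotations
#' @export
setMethod("geneIds", "FactorModel", function(x) x@geneIds)

#' Factor model accessors
#'
#' `basisMatrix()` returns the term-by-rank basis B, `featureMatrix()` the
#' rank-by-entity feature matrix F, `featureL()`/`featureG()` its lncRNA and
#' gene column blocks, and `objectiveHistory()` the recorded objective
#' values.
#'
#' @param x a [FactorModel-class].
#' @return A matrix or numeric vector.
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname basisMatrix
#' @export
setMethod("basisMatrix", "FactorModel", function(x) x@B)

#' @rdname basisMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname basisMatrix
#' @export
setMethod("featureMatrix", "FactorModel", function(x) x@F)

#' @rdname basisMatrix
#' @export
setGeneric("featureL", function(x) standardGeneric("featureL"))

#' @rdname basisMatrix
#' @export
setMethod("featureL", "FactorModel", function(x)
  x@F[, seq_along(x@lncIds), drop = FALSE])

#' @rdname basisMatrix
#' @export
setGeneric("featureG", function(x) standardGeneric("featureG"))

#' @rdname basisMatrix
#' @export
setMethod("featureG", "FactorModel", function(x)
  x@F[, length(x@lncIds) + seq_along(x@geneIds), drop = FALSE])

#' @rdname basisMatrix
#' @export
setGeneric("objectiveHistory", function(x) standardGeneric("objectiveHistory"))

#' @rdname basisMatrix
#' @export
setMethod("objectiveHistory", "FactorModel", function(x) x@objectiveHistory)

#' Symmetrically normalized adjacency
#'
#' Computes \eqn{\bar W = D^{-1/2} W D^{-1/2}} where D is the diagonal
#' degree matrix; vertices of degree zero keep zero rows/columns.
#'
#' @param x an [EntityNetwork-class], [BiColoredMatrix-class], or a plain
#'   symmetric nonnegative matrix.
#' @return A symmetric matrix of the same order.
#' @export
setGeneric("normalizeAdjacency", function(x) standardGeneric("normalizeAdjacency"))

#' Symmetric normalized Laplacian
#'
#' Computes \eqn{L = I - D^{-1/2} W D^{-1/2}}, the smoothness operator used
#' by all propagation baselines; positive semidefinite for any valid
#' network.
#'
#' @param x an [EntityNetwork-class], [BiColoredMatrix-class], or a plain
#'   symmetric nonnegative matrix.
#' @return A symmetric positive semidefinite matrix.
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))

#' Predicted lncRNA-ontology scores of a fitted model
#'
#' @param object a fitted [FactorModel-class].
#' @param ... further arguments passed to methods.
#' @return A nonnegative term-by-lncRNA score matrix.
#' @export
setGeneric("predictScores", function(object, ...) standardGeneric("predictScores"))
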