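#' Pearson co-expression network
#'
#' Connects entities i and j with weight r_ij when the Pearson correlation
#' of their expression profiles reaches the threshold. Negative
#' correlations are dropped by default (the downstream factorization needs
#' nonnegative matrices); set `useAbsolute = TRUE` to use |r| instead.
#' Zero-variance profiles correlate 0 with everything.
#'
#' @param expr numeric matrix, entities x samples (>= 2 samples).
#' @param threshold correlation threshold in [0, 1].
#' @param useAbsolute use |r| for edge inclusion and weight.
#' @return An [EntityNetwork-class].
#' @export
buildCoexpressionNetwork <- function(expr, threshold = 0.5,
                                     useAbsolute = FALSE) {
  if (ncol(expr) < 2L) stop("need >= 2 samples per entity")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  r <- suppressWarnings(stats::cor(t(expr)))
  r[!is.finite(r)] <- 0                       # zero-variance entities
  if (useAbsolute) r <- abs(r)
  W <- ifelse(r >= threshold, r, 0)
  diag(W) <- 0
  entityNetwork(rownames(expr), W)
}

#' lncRNA-gene co-expression view
#'
#' The first association view: Y1[l, g] = r(l, g) when the lncRNA-gene
#' expression correlation reaches the threshold, else 0. Both matrices must
#' share the same sample columns (count and order).
#'
#' @param exprL,exprG expression matrices (lncRNAs / genes by samples).
#' @param threshold correlation threshold in [0, 1].
#' @param useAbsolute use |r| instead of dropping negative correlations.
#' @return A [BipartiteView-class] named "coexpression".
#' @export
buildExpressionView <- function(exprL, exprG, threshold = 0.5,
                                useAbsolute = FALSE) {
  if (ncol(exprL) != ncol(exprG))
    stop("lncRNA and gene matrices must share the same samples")
  if (!is.null(colnames(exprL)) && !is.null(colnames(exprG)) &&
      !identical(colnames(exprL), colnames(exprG)))
    stop("sample columns differ between lncRNA and gene matrices")
  r <- suppressWarnings(stats::cor(t(exprL), t(exprG)))
  r[!is.finite(r)] <- 0
  if (useAbsolute) r <- abs(r)
  Y <- ifelse(r >= threshold, r, 0)
  bipartiteView("coexpression", rownames(exprL), rownames(exprG), Y)
}

#' Shared-disease Jaccard view
#'
#' The second association view: Y2[l, g] = |D_l intersect D_g| /
#' |D_l union D_g| over the disease sets of each lncRNA and gene; two empty
#' sets give 0 (absence of evidence is non-association).
#'
#' @param lncDiseases,geneDiseases named lists mapping each entity id to a
#'   character vector of disease identifiers (possibly empty).
#' @return A [BipartiteView-class] named "disease".
#' @export
buildDiseaseView <- function(lncDiseases, geneDiseases) {
  lncIds <- names(lncDiseases); geneIds <- names(geneDiseases)
  Y <- matrix(0, length(lncIds), length(geneIds))
  for (i in seq_along(lncIds)) {
    dl <- unique(lncDiseases[[i]])
    for (j in seq_along(geneIds)) {
      dg <- unique(geneDiseases[[j]])
      u <- length(union(dl, dg))
      if (u > 0) Y[i, j] <- length(intersect(dl, dg)) / u
    }
  }
  bipartiteView("disease", lncIds, geneIds, Y)
}

#' Largest connected component of a network
#'
#' Returns the sub-network induced by the largest connected component
#' (ties broken toward the component containing the smallest vertex
#' index). The surviving ids are the index map used to subset all coupled
#' matrices, via [filterAnnotationGenes()] / [filterViewGenes()].
#'
#' @param net an [EntityNetwork-class] with >= 1 vertex.
#' @return An [EntityNetwork-class] over the surviving vertices (original
#'   relative order preserved).
#' @export
largestConnectedComponent <- function(net) {
  if (length(net@ids) == 0L) stop("empty network")
  g <- igraph::graph_from_adjacency_matrix(net@W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) # smallest first-entity index wins
    best <- best[which.min(vapply(best, function(b)
      min(which(comp$membership == b)), 0L))]
  keep <- which(comp$membership == best)
  entityNetwork(net@ids[keep], net@W[keep, keep, drop = FALSE])
}

#' Restrict an annotation matrix to surviving genes
#'
#' After the PPI connectivity filter, gene columns outside the surviving
#' set are dropped; lncRNA columns are never filtered.
#'
#' @param X an [AnnotationMatrix-class].
#' @param geneIds gene ids to keep, in the filtered-network order.
#' @return An [AnnotationMatrix-class].
#' @export
filterAnnotationGenes <- function(X, geneIds) {
  stopifnot(all(geneIds %in% X@geneIds))
  keep <- length(X@lncIds) + match(geneIds, X@geneIds)
  annotationMatrix(X@X[, c(seq_along(X@lncIds), keep), drop = FALSE],
                   X@termIds, X@lncIds, geneIds)
}

#' @rdname filterAnnotationGenes
#' @param view a [BipartiteView-class] whose gene columns are subset the
#'   same way.
#' @export
filterViewGenes <- function(view, geneIds) {
  stopifnot(all(geneIds %in% view@geneIds))
  bipartiteView(view@name, view@lncIds, geneIds,
                view@Y[, match(geneIds, view@geneIds), drop = FALSE])
}

.normalizeAdjacencyMatrix <- function(W) {
  d <- rowSums(W)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)   # degree-0 vertices keep zero rows
  W * outer(s, s)
}

#' @rdname normalizeAdjacency
#' @export
setMethod("normalizeAdjacency", "EntityNetwork", function(x)
  .normalizeAdjacencyMatrix(x@W))

#' @rdname normalizeAdjacency
#' @export
setMethod("normalizeAdjacency", "BiColoredMatrix", function(x)
  .normalizeAdjacencyMatrix(x@Cmat))

#' @rdname normalizeAdjacency
#' @export
setMethod("normalizeAdjacency", "matrix", function(x)
  .normalizeAdjacencyMatrix(x))

#' @rdname laplacianMatrix
#' @export
setMethod("laplacianMatrix", "EntityNetwork", function(x)
  diag(length(x@ids)) - normalizeAdjacency(x))

#' @rdname laplacianMatrix
#' @export
setMethod("laplacianMatrix", "BiColoredMatrix", function(x)
  diag(nrow(x@Cmat)) - normalizeAdjacency(x))

#' @rdname laplacianMatrix
#' @export
setMethod("laplacianMatrix", "matrix", function(x)
  diag(nrow(x)) - .normalizeAdjacencyMatrix(x))

#' Assemble one view of the bi-colored network
#'
#' Stacks the within-class networks and a cross-class view into the block
#' matrix \eqn{C_i = [[W_l, Y_i], [Y_i', W_g]]}.
#'
#' @param netL lncRNA co-expression [EntityNetwork-class].
#' @param netG gene (PPI) [EntityNetwork-class].
#' @param view the [BipartiteView-class] supplying the cross block.
#' @return A [BiColoredMatrix-class].
#' @export
assembleBicolored <- function(netL, netG, view) {
  if (!identical(netL@ids, view@lncIds) || !identical(netG@ids, view@geneIds))
    stop("entity ids of the networks and the view do not match")
  C <- rbind(cbind(netL@W, view@Y), cbind(t(view@Y), netG@W))
  ids <- c(netL@ids, netG@ids)
  dimnames(C) <- list(ids, ids)
  new("BiColoredMatrix", Cmat = C, lncIds = netL@ids, geneIds = netG@ids)
}
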