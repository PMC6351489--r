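#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of entity
#' identifiers; all remaining cells must be numeric. Entity order is kept
#' as in the file.
#'
#' @param path TSV file path.
#' @return Numeric matrix, entities in rows (rownames = entity ids),
#'   samples in columns.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("expression file needs an id column and >=1 sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate entity id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row '%s', column '%s'",
                 ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write an expression matrix to TSV
#'
#' @param expr numeric matrix with entity rownames and sample colnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeExpression <- function(expr, path) {
  df <- data.frame(id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted edge list into an EntityNetwork
#'
#' Rows are "idA idB [weight]" (tab-separated, no header); a missing third
#' column means weight 1. The graph is undirected and simple: duplicate
#' pairs in either orientation keep the maximum weight, and self-loops are
#' dropped with a warning. Vertex order follows first appearance in the
#' file.
#'
#' @param path TSV file path.
#' @return An [EntityNetwork-class].
#' @export
readEdgeList <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (!ncol(df) %in% c(2L, 3L))
    stop("edge list must have 2 or 3 columns")
  w <- if (ncol(df) == 3L) suppressWarnings(as.numeric(df[[3L]])) else
    rep(1, nrow(df))
  if (anyNA(w)) stop("non-numeric edge weight at line ", which(is.na(w))[1L])
  if (any(w < 0)) stop("negative edge weight at line ", which(w < 0)[1L])
  a <- df[[1L]]; b <- df[[2L]]
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  ids <- unique(c(rbind(df[[1L]], df[[2L]])))
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(a)) {
    W[a[i], b[i]] <- max(W[a[i], b[i]], w[i])
    W[b[i], a[i]] <- W[a[i], b[i]]
  }
  entityNetwork(ids, W)
}

#' Write an EntityNetwork as an edge list TSV
#'
#' One row per undirected edge, "idA idB weight"; isolated vertices are not
#' representable in this format.
#'
#' @param net an [EntityNetwork-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeEdgeList <- function(net, path) {
  W <- net@W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  df <- data.frame(a = net@ids[idx[, 1L]], b = net@ids[idx[, 2L]],
                   w = format(W[idx], digits = 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column (entity, label) pair list
#'
#' Pairs are deduplicated; the first-seen order of entities (and labels) is
#' preserved so downstream matrices index entities deterministically.
#'
#' @param path TSV file path, no header.
#' @return data.frame with columns `entity` and `label` (character).
#' @export
readPairList <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(entity = character(), label = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("expected 2 columns at line ", which(nf != 2L)[1L])
  df <- data.frame(entity = vapply(parts, `[`, "", 1L),
                   label = vapply(parts, `[`, "", 2L))
  df[!duplicated(df), , drop = FALSE]
}

#' Write a pair list to TSV
#'
#' @param pairs data.frame with columns `entity` and `label`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePairList <- function(pairs, path) {
  utils::write.table(pairs[, c("entity", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read GMT-format annotation sets as (entity, label) pairs
#'
#' Each GMT line is "set-name<TAB>description<TAB>member1<TAB>member2...";
#' the set name is taken as the ontology term and members as entities.
#'
#' @param path GMT file path.
#' @return data.frame with columns `entity` and `label`, deduplicated in
#'   first-seen order.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) stop("GMT line ", which(short)[1L], " has < 3 fields")
  df <- do.call(rbind, lapply(parts, function(p)
    data.frame(entity = p[-(1:2)], label = p[1L])))
  df[!duplicated(df), , drop = FALSE]
}

#' Build an AnnotationMatrix from entity-term pair lists
#'
#' Assembles the binary ontology-by-entity matrix with lncRNA columns first
#' and gene columns second. Row (term) order is first appearance across the
#' lncRNA then gene pairs unless an explicit universe is given.
#'
#' @param lncPairs,genePairs data.frames with columns `entity`, `label`
#'   (as from [readPairList()] / [readGmt()]).
#' @param lncIds,geneIds optional explicit entity orders; default
#'   first-seen order from the pair lists.
#' @param termIds optional explicit term universe/order.
#' @return An [AnnotationMatrix-class].
#' @export
pairsToAnnotationMatrix <- function(lncPairs, genePairs,
                                    lncIds = NULL, geneIds = NULL,
                                    termIds = NULL) {
  if (is.null(lncIds)) lncIds <- unique(lncPairs$entity)
  if (is.null(geneIds)) geneIds <- unique(genePairs$entity)
  if (is.null(termIds))
    termIds <- unique(c(lncPairs$label, genePairs$label))
  X <- matrix(0, length(termIds), length(lncIds) + length(geneIds))
  fill <- function(pairs, colOffset, colIds) {
    keep <- pairs$entity %in% colIds & pairs$label %in% termIds
    p <- pairs[keep, , drop = FALSE]
    X[cbind(match(p$label, termIds),
            colOffset + match(p$entity, colIds))] <<- 1
  }
  fill(lncPairs, 0L, lncIds)
  fill(genePairs, length(lncIds), geneIds)
  annotationMatrix(X, termIds, lncIds, geneIds)
}

#' Flatten a score matrix into a ranked prediction table
#'
#' @param scores term-by-lncRNA matrix with dimnames.
#' @return data.frame (lncRNA, term, score) sorted by descending score;
#'   ties broken by lncRNA then term id for a deterministic order.
#' @export
scoresToRanking <- function(scores) {
  df <- data.frame(
    lncRNA = rep(colnames(scores), each = nrow(scores)),
    term = rep(rownames(scores), times = ncol(scores)),
    score = as.vector(scores))
  df[order(-df$score, df$lncRNA, df$term), , drop = FALSE]
}

#' Write ranked lncRNA-term predictions to TSV
#'
#' Output columns are "lncRNA GO_term score", sorted by descending score,
#' scores printed with at least 6 significant digits.
#'
#' @param scores data.frame (lncRNA, term, score) or a term-by-lncRNA score
#'   matrix (flattened via [scoresToRanking()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePredictions <- function(scores, path) {
  if (is.matrix(scores)) scores <- scoresToRanking(scores)
  if (anyNA(scores$score)) stop("NaN/NA scores are not allowed")
  .assertFinite(scores$score, "score column")
  scores <- scores[order(-scores$score, scores$lncRNA, scores$term), ,
                   drop = FALSE]
  out <- data.frame(lncRNA = scores$lncRNA, GO_term = scores$term,
                    score = formatC(scores$score, digits = 8, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by [writePredictions()]
#'
#' @param path file path.
#' @return data.frame (lncRNA, term, score) in file (ranked) order.
#' @export
readPredictions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses =
                            c("character", "character", "numeric"))
  names(df) <- c("lncRNA", "term", "score")
  df
}

#' Sparse triplet serialization of a matrix
#'
#' Writes non-zero entries as "row_id col_id value" rows (TSV, with a
#' header) so large mostly-empty view/network matrices stay readable.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSparseTriplets <- function(m, path) {
  idx <- which(m != 0, arr.ind = TRUE)
  df <- data.frame(row = rownames(m)[idx[, 1L]],
                   col = colnames(m)[idx[, 2L]],
                   value = format(m[idx], digits = 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSparseTriplets
#' @param rowIds,colIds full identifier vectors (triplet files do not carry
#'   all-zero rows/columns).
#' @return For the reader, the dense matrix with the given dimnames.
#' @export
readSparseTriplets <- function(path, rowIds, colIds) {
  df <- utils::read.delim(path, header = TRUE, colClasses =
                            c("character", "character", "numeric"))
  m <- matrix(0, length(rowIds), length(colIds),
              dimnames = list(rowIds, colIds))
  if (nrow(df)) m[cbind(match(df[[1L]], rowIds), match(df[[2L]], colIds))] <-
      df[[3L]]
  m
}

#' Write a synthetic instance as the standard TSV bundle
#'
#' Materializes a [SyntheticInstance-class] in the generic exchange formats
#' (expression TSVs, PPI edge list, disease and annotation pair lists) plus
#' a JSON manifest recording sizes, the seed and the masked pairs.
#'
#' @param instance a [SyntheticInstance-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeInstance <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeExpression(instance@exprL, p("expr_lncrna.tsv"))
  writeExpression(instance@exprG, p("expr_gene.tsv"))
  writeEdgeList(instance@ppi, p("ppi.tsv"))
  setsToPairs <- function(sets) {
    data.frame(entity = rep(names(sets), lengths(sets)),
               label = unlist(sets, use.names = FALSE))
  }
  writePairList(setsToPairs(instance@lncDiseases), p("lnc_disease.tsv"))
  writePairList(setsToPairs(instance@geneDiseases), p("gene_disease.tsv"))
  X <- instance@trainX
  lncBlock <- X@X[, seq_along(X@lncIds), drop = FALSE]
  geneBlock <- X@X[, length(X@lncIds) + seq_along(X@geneIds), drop = FALSE]
  blockToPairs <- function(block, colIds) {
    idx <- which(block == 1, arr.ind = TRUE)
    data.frame(entity = colIds[idx[, 2L]], label = X@termIds[idx[, 1L]])
  }
  writePairList(blockToPairs(lncBlock, X@lncIds), p("lnc_annotations.tsv"))
  writePairList(blockToPairs(geneBlock, X@geneIds), p("gene_annotations.tsv"))
  truthL <- instance@truthX@X[, seq_along(X@lncIds), drop = FALSE]
  tp <- which(truthL == 1, arr.ind = TRUE)
  writePairList(data.frame(entity = X@lncIds[tp[, 2L]],
                           label = X@termIds[tp[, 1L]]),
                p("lnc_annotations_truth.tsv"))
  manifest <- list(
    n_l = length(X@lncIds), n_g = length(X@geneIds),
    n_o = length(X@termIds), planted_k = instance@plantedK,
    seed = instance@seed,
    mask = instance@mask)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(p("manifest.json"))
}
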