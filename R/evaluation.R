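#' Per-lncRNA confusion counts at one threshold
#'
#' For each evaluated lncRNA, TP = |P intersect T|, FP = |P \ T|,
#' FN = |T \ P| over its predicted and true term sets; every term must
#' belong to the declared universe.
#'
#' @param predicted named list of predicted term sets (one per lncRNA).
#' @param truth named list of true term sets over the same lncRNAs.
#' @param universe character vector of all admissible terms.
#' @return data.frame (id, tp, fp, fn), one row per lncRNA in `predicted`.
#' @export
confusionCounts <- function(predicted, truth, universe) {
  ids <- names(predicted)
  allTerms <- unique(c(unlist(predicted), unlist(truth)))
  if (!all(allTerms %in% universe))
    stop("term(s) outside the universe: ",
         paste(utils::head(setdiff(allTerms, universe), 3L), collapse = ", "))
  res <- lapply(ids, function(i) {
    p <- unique(predicted[[i]]); t <- unique(truth[[i]])
    c(tp = length(intersect(p, t)), fp = length(setdiff(p, t)),
      fn = length(setdiff(t, p)))
  })
  data.frame(id = ids, do.call(rbind, res))
}

#' Micro-averaged recall and precision
#'
#' TP/FP/FN are summed over all lncRNAs before dividing:
#' recall = sum(TP)/(sum(TP)+sum(FN)), precision = sum(TP)/(sum(TP)+sum(FP)).
#' Degenerate denominators use the total conventions precision = 1 when
#' nothing is predicted and recall = 0 when there are no true terms (a
#' message is emitted when either triggers).
#'
#' @param counts data.frame with columns tp, fp, fn
#'   (from [confusionCounts()]).
#' @return named numeric c(recall, precision).
#' @export
recallPrecision <- function(counts) {
  if (!nrow(counts)) stop("empty count list")
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  if (tp + fn == 0) {
    message("no true terms: recall set to 0 by convention")
    recall <- 0
  } else recall <- tp / (tp + fn)
  if (tp + fp == 0) {
    message("no predictions: precision set to 1 by convention")
    precision <- 1
  } else precision <- tp / (tp + fp)
  c(recall = recall, precision = precision)
}

.predictedSets <- function(scores, t) {
  lapply(seq_len(ncol(scores)), function(j)
    rownames(scores)[scores[, j] >= t])
}

#' Threshold-swept Fmax evaluation
#'
#' Sweeps the score threshold over `grid`; at each t the predicted term
#' set of lncRNA i is every term scoring >= t, micro-averaged recall and
#' precision are computed over the lncRNAs possessing at least one true
#' term, and \eqn{Fmax = \max_t 2RP/(R+P)} (smallest maximizing t on
#' ties). lncRNAs without true terms are excluded from evaluation, as in
#' benchmark construction from curated annotated lncRNAs.
#'
#' @param scores terms x lncRNAs score matrix in [0, 1], with dimnames.
#' @param truth named list of true term sets per lncRNA (ids must appear
#'   in the score columns).
#' @param grid nonempty threshold grid within [0, 1].
#' @return An [EvaluationReport-class].
#' @examples
#' s <- matrix(c(0.9, 0.4), 2, 1, dimnames = list(c("o1", "o2"), "l1"))
#' report <- fmaxCurve(s, list(l1 = "o1"), grid = c(0.1, 0.5, 0.9))
#' report@fmax   # 1: o1 alone is predicted at t = 0.5
#' @export
fmaxCurve <- function(scores, truth, grid = seq(0, 1, by = 0.01)) {
  if (!length(grid)) stop("empty threshold grid")
  truth <- truth[lengths(truth) > 0]
  ids <- names(truth)
  if (!all(ids %in% colnames(scores)))
    stop("truth lncRNA(s) missing from score columns")
  S <- scores[, ids, drop = FALSE]
  universe <- rownames(scores)
  curve <- do.call(rbind, lapply(grid, function(t) {
    pred <- stats::setNames(.predictedSets(S, t), ids)
    counts <- confusionCounts(pred, truth, universe)
    rp <- suppressMessages(recallPrecision(counts))
    f <- if (rp[1] + rp[2] > 0) 2 * rp[1] * rp[2] / (rp[1] + rp[2]) else 0
    data.frame(t = t, recall = rp[[1]], precision = rp[[2]], f = f)
  }))
  rownames(curve) <- NULL
  # smallest maximizing threshold; ties resolved within a numerical
  # tolerance so that float-level differences between algebraically equal
  # F values do not move the reported threshold
  best <- which(curve$f >= max(curve$f) - 1e-12)[1L]
  bestT <- curve$t[best]
  predBest <- stats::setNames(.predictedSets(S, bestT), ids)
  countsBest <- confusionCounts(predBest, truth, universe)
  new("EvaluationReport", curve = curve, fmax = curve$f[best],
      bestT = bestT, counts = countsBest,
      nAnnotated = sum(countsBest$tp >= 1L))
}

#' Number of correctly annotated lncRNAs at a threshold
#'
#' Counts the lncRNAs predicted with at least one true term at score
#' threshold t.
#'
#' @param scores terms x lncRNAs score matrix with dimnames.
#' @param truth named list of true term sets.
#' @param t score threshold.
#' @return Integer count.
#' @export
annotatedCount <- function(scores, truth, t) {
  truth <- truth[lengths(truth) > 0]
  ids <- names(truth)
  S <- scores[, ids, drop = FALSE]
  sum(vapply(seq_along(ids), function(j)
    length(intersect(rownames(S)[S[, j] >= t], truth[[j]])) >= 1L,
    NA))
}

#' Rank-based AUROC of a score set
#'
#' The Mann-Whitney statistic: the probability that a uniformly drawn
#' positive outscores a uniformly drawn negative (ties count 1/2).
#'
#' @param posScores,negScores numeric score vectors of the positive and
#'   negative pairs.
#' @return AUROC in [0, 1].
#' @export
rankAUC <- function(posScores, negScores) {
  np <- length(posScores); nn <- length(negScores)
  if (np == 0L || nn == 0L) stop("need at least one positive and one negative")
  r <- rank(c(posScores, negScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Extract truth term sets from an annotation matrix
#'
#' Convenience converter: the lncRNA columns of a (truth) annotation
#' matrix as a named list of term sets, optionally restricted to given
#' lncRNAs.
#'
#' @param X an [AnnotationMatrix-class].
#' @param lncs optional subset of lncRNA ids.
#' @return Named list of character term sets.
#' @export
truthSets <- function(X, lncs = NULL) {
  if (is.null(lncs)) lncs <- X@lncIds
  sets <- lapply(lncs, function(l)
    X@termIds[X@X[, match(l, c(X@lncIds, X@geneIds))] == 1])
  stats::setNames(sets, lncs)
}
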