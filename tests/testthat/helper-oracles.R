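# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately use scalar loops / enumeration and never call the
# package's vectorized implementations.

oracleUpdateBasis <- function(B, F, X, eps = 1e-12) {
  out <- B
  num <- matrix(0, nrow(B), ncol(B))
  den <- matrix(0, nrow(B), ncol(B))
  for (i in seq_len(nrow(B))) for (q in seq_len(ncol(B))) {
    for (j in seq_len(ncol(X))) {
      num[i, q] <- num[i, q] + X[i, j] * F[q, j]
      bf <- 0
      for (p in seq_len(ncol(B))) bf <- bf + B[i, p] * F[p, j]
      den[i, q] <- den[i, q] + bf * F[q, j]
    }
    out[i, q] <- B[i, q] * num[i, q] / (den[i, q] + eps)
  }
  out
}

oracleUpdateFeatures <- function(B, F, X, couplings, alpha, eps = 1e-12) {
  k <- nrow(F); n <- ncol(F)
  out <- F
  for (q in seq_len(k)) for (j in seq_len(n)) {
    num <- 0
    for (i in seq_len(nrow(B))) num <- num + B[i, q] * X[i, j]
    for (C in couplings)
      for (m in seq_len(n)) num <- num + alpha * F[q, m] * C[m, j]
    den <- 0
    for (p in seq_len(k)) {
      btb <- 0
      for (i in seq_len(nrow(B))) btb <- btb + B[i, q] * B[i, p]
      den <- den + btb * F[p, j]
    }
    out[q, j] <- F[q, j] * num / (den + eps)
  }
  out
}

oracleObjective <- function(X, B, F, couplings, alpha) {
  J <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    bf <- 0
    for (p in seq_len(nrow(F))) bf <- bf + B[i, p] * F[p, j]
    J <- J + (X[i, j] - bf)^2
  }
  for (C in couplings) {
    tr <- 0
    for (q in seq_len(nrow(F)))
      for (a in seq_len(ncol(F))) for (b in seq_len(ncol(F)))
        tr <- tr + F[q, a] * C[a, b] * F[q, b]
    J <- J - alpha * tr
  }
  J
}

oraclePearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracleCrossCorrelation <- function(B1, B2) {
  k <- ncol(B1)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    H[i, j] <- oraclePearson(B1[, i], B2[, j])
  H
}

oracleDissimilarity <- function(B1, B2) {
  H <- oracleCrossCorrelation(B1, B2)
  k <- ncol(H)
  colMax <- vapply(seq_len(k), function(j) max(H[, j]), 0)
  rowMax <- vapply(seq_len(k), function(i) max(H[i, ]), 0)
  (2 * k - sum(colMax) - sum(rowMax)) / (2 * k)
}

oracleConfusion <- function(pred, truth, universe) {
  tp <- sum(vapply(universe, function(o) o %in% pred && o %in% truth, NA))
  fp <- sum(vapply(universe, function(o) o %in% pred && !o %in% truth, NA))
  fn <- sum(vapply(universe, function(o) !o %in% pred && o %in% truth, NA))
  c(tp = tp, fp = fp, fn = fn)
}

# exhaustive Fmax: recompute micro recall/precision at every grid point
oracleFmax <- function(scores, truth, grid) {
  best <- -Inf; bestT <- NA_real_
  for (t in grid) {
    tp <- 0; fp <- 0; fn <- 0
    for (l in names(truth)) {
      pred <- rownames(scores)[scores[, l] >= t]
      cc <- oracleConfusion(pred, truth[[l]], rownames(scores))
      tp <- tp + cc["tp"]; fp <- fp + cc["fp"]; fn <- fn + cc["fn"]
    }
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    p <- if (tp + fp > 0) tp / (tp + fp) else 1
    f <- if (r + p > 0) 2 * r * p / (r + p) else 0
    if (f > best + 1e-12) { best <- f; bestT <- t }
  }
  list(fmax = unname(best), bestT = bestT)
}

# breadth-first-search connected components over an adjacency matrix
oracleComponents <- function(W) {
  n <- nrow(W)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# beta-weighted count of walks of length 1..maxLen between all vertex pairs
oracleKatz <- function(W, beta, maxLen) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  walks <- function(path, len) {
    v <- path[length(path)]
    w <- prod(W[cbind(path[-length(path)], path[-1L])])
    S[path[1L], v] <<- S[path[1L], v] + beta^len * w
    if (len < maxLen)
      for (u in which(W[v, ] > 0)) walks(c(path, u), len + 1L)
  }
  for (s in seq_len(n)) for (u in which(W[s, ] > 0)) walks(c(s, u), 1L)
  S
}

matpow <- function(M, p) {
  R <- diag(nrow(M))
  for (i in seq_len(p)) R <- R %*% M
  R
}

# small random fixtures -------------------------------------------------

randomFactors <- function(nO, n, k, seed) {
  withr::local_seed(seed)
  B <- matrix(runif(nO * k), nO, k)
  F <- matrix(runif(k * n), k, n)
  F <- sweep(F, 2, colSums(F), "/")
  list(B = B, F = F)
}

randomCoupling <- function(nl, ng, seed) {
  withr::local_seed(seed)
  Y <- matrix(runif(nl * ng), nl, ng) * (matrix(runif(nl * ng), nl, ng) < 0.4)
  buildCoupling(bipartiteView("v", paste0("l", 1:nl), paste0("g", 1:ng), Y))
}

randomNetwork <- function(n, seed, p = 0.3) {
  withr::local_seed(seed)
  A <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < p)
  A[lower.tri(A, diag = TRUE)] <- 0
  entityNetwork(paste0("v", seq_len(n)), A + t(A))
}

smallInstance <- function(seed = 1, noise = 0.1, maskFraction = 0.2,
                          nL = 20, nG = 40, nO = 12, plantedK = 3) {
  generateInstance(nL, nG, nO, plantedK = plantedK, noise = noise,
                   maskFraction = maskFraction, seed = seed)
}

instanceCouplings <- function(inst, threshold = 0.5) {
  v1 <- buildExpressionView(inst@exprL, inst@exprG, threshold)
  v2 <- buildDiseaseView(inst@lncDiseases, inst@geneDiseases)
  list(coexpression = buildCoupling(v1), disease = buildCoupling(v2))
}

maskIndex <- function(inst) {
  cbind(match(inst@mask$term, inst@truthX@termIds),
        match(inst@mask$lnc, inst@truthX@lncIds))
}
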