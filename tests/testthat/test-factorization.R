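test_that("coupling matrices zero the diagonal blocks", {
  v <- bipartiteView("v", "l1", "g1", matrix(1, 1, 1))
  expect_equal(adjacency(buildCoupling(v)),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)

  v0 <- bipartiteView("v", c("l1", "l2"), "g1", matrix(0, 2, 1))
  expect_equal(sum(adjacency(buildCoupling(v0))), 0)

  cp <- randomCoupling(4, 6, seed = 3)
  C <- adjacency(cp)
  expect_true(isSymmetric(unname(C)))
  expect_equal(C[1:4, 1:4], matrix(0, 4, 4), ignore_attr = TRUE)
  expect_equal(C[5:10, 5:10], matrix(0, 6, 6), ignore_attr = TRUE)
})

test_that("objective reduces to reconstruction error and obeys the trace identity", {
  f <- randomFactors(6, 8, 3, seed = 1)
  X <- f$B %*% f$F
  expect_equal(mprObjective(X, f$B, f$F, alpha = 0), 0, tolerance = 1e-12)
  expect_equal(mprObjective(X, f$B, 0 * f$F, alpha = 1), sum(X^2))

  # tr(F C* F') = 2 tr(F_l Y F_g') on random inputs
  for (seed in 1:10) {
    withr::local_seed(seed)
    nl <- 4; ng <- 6; k <- 3
    Y <- matrix(runif(nl * ng), nl, ng)
    F <- matrix(runif(k * (nl + ng)), k, nl + ng)
    cp <- buildCoupling(bipartiteView("v", paste0("l", 1:nl),
                                      paste0("g", 1:ng), Y))
    Fl <- F[, 1:nl, drop = FALSE]
    Fg <- F[, nl + 1:ng, drop = FALSE]
    lhs <- sum((F %*% adjacency(cp)) * F)
    rhs <- 2 * sum(diag(Fl %*% Y %*% t(Fg)))
    expect_equal(lhs, rhs, tolerance = 1e-10)
    # and the objective uses it with a negative sign
    B <- matrix(runif(5 * k), 5, k)
    X <- matrix(runif(5 * (nl + ng)), 5, nl + ng)
    expect_equal(mprObjective(X, B, F, list(cp), alpha = 0.7),
                 sum((X - B %*% F)^2) - 0.7 * lhs, tolerance = 1e-10)
  }
  expect_error(mprObjective(matrix(NaN, 2, 2), diag(2), diag(2)),
               "non-finite")
})

test_that("multiplicative updates match the scalar-loop oracles", {
  for (seed in 1:10) {
    withr::local_seed(seed)
    nO <- 4; n <- 5; k <- 3; nl <- 2
    B <- matrix(runif(nO * k), nO, k)
    F <- matrix(runif(k * n), k, n)
    X <- matrix(rbinom(nO * n, 1, 0.4), nO, n)
    cp <- randomCoupling(nl, n - nl, seed = seed + 100)

    expect_equal(updateBasis(B, F, X),
                 oracleUpdateBasis(B, F, X), tolerance = 1e-12)
    expect_equal(updateFeatures(B, F, X, list(cp), alpha = 1,
                                normalize = FALSE),
                 oracleUpdateFeatures(B, F, X, list(adjacency(cp)), 1),
                 tolerance = 1e-12)
    expect_equal(mprObjective(X, B, F, list(cp), alpha = 0.5),
                 oracleObjective(X, B, F, list(adjacency(cp)), 0.5),
                 tolerance = 1e-10)
  }
})

test_that("exact factorizations are fixed points of the updates", {
  for (seed in 1:5) {
    f <- randomFactors(7, 9, 3, seed = seed)
    X <- f$B %*% f$F
    expect_equal(updateBasis(f$B, f$F, X), f$B, tolerance = 1e-10)
    expect_equal(updateFeatures(f$B, f$F, X, alpha = 0), f$F,
                 tolerance = 1e-10)
  }
  # zeros are preserved multiplicatively
  f <- randomFactors(6, 8, 3, seed = 77)
  B <- f$B; B[2, ] <- 0
  X <- B %*% f$F
  expect_equal(updateBasis(B, f$F, X)[2, ], rep(0, 3))
  F <- f$F; F[1, 3] <- 0
  F <- sweep(F, 2, colSums(F), "/")
  expect_equal(updateFeatures(B, F, B %*% F, alpha = 0)[1, 3], 0)
})

test_that("the sqrt update variant damps but keeps the same fixed points", {
  f <- randomFactors(6, 8, 3, seed = 5)
  X <- f$B %*% f$F
  expect_equal(updateBasis(f$B, f$F, X, variant = "sqrt"), f$B,
               tolerance = 1e-10)
  withr::local_seed(6)
  B2 <- matrix(runif(18), 6, 3)
  std <- updateBasis(B2, f$F, X)
  damped <- updateBasis(B2, f$F, X, variant = "sqrt")
  expect_equal(damped, B2 * sqrt(std / B2), tolerance = 1e-10)
})

test_that("fitting is deterministic under seed and records the objective", {
  inst <- smallInstance(seed = 2)
  cps <- instanceCouplings(inst)
  m1 <- mprnmf(inst@trainX, cps, k = 3, alpha = 0.1, iterations = 40,
               seed = 9)
  m2 <- mprnmf(inst@trainX, cps, k = 3, alpha = 0.1, iterations = 40,
               seed = 9)
  expect_identical(objectiveHistory(m1), objectiveHistory(m2))
  expect_identical(basisMatrix(m1), basisMatrix(m2))
  expect_lte(length(objectiveHistory(m1)), 41L)  # init + <= iterations
  expect_true(all(featureMatrix(m1) >= 0))
  expect_equal(colSums(featureMatrix(m1)),
               rep(1, ncol(featureMatrix(m1))), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(mprnmf(inst@trainX, cps, k = 100, seed = 1), "k must")
})

test_that("a noiseless planted instance is reconstructed nearly exactly", {
  inst <- smallInstance(seed = 3, noise = 0, maskFraction = 0)
  fit <- mprnmf(inst@truthX, k = 3, alpha = 0, iterations = 100, seed = 4)
  X <- annotations(inst@truthX)
  rel <- sqrt(sum((X - basisMatrix(fit) %*% featureMatrix(fit))^2) /
                sum(X^2))
  expect_lt(rel, 0.05)
})

test_that("nonnegativity is preserved along the whole update path", {
  inst <- smallInstance(seed = 8)
  cps <- instanceCouplings(inst)
  X <- annotations(inst@trainX)
  f <- randomFactors(nrow(X), ncol(X), 4, seed = 10)
  B <- f$B; F <- f$F
  for (it in 1:25) {
    B <- updateBasis(B, F, X)
    F <- updateFeatures(B, F, X, cps, alpha = 0.2)
    expect_true(all(B >= 0) && all(F >= 0))
  }
})

test_that("consistent column permutation permutes the fitted features", {
  inst <- smallInstance(seed = 6)
  X <- annotations(inst@trainX)
  n <- ncol(X)
  cp <- instanceCouplings(inst)[[1]]
  C <- adjacency(cp)
  withr::local_seed(60)
  perm <- sample(n)
  # equivariance of the update maps: permuting entity columns of X, F and
  # the coupling consistently permutes the F update and leaves B alone
  f <- randomFactors(nrow(X), n, 3, seed = 61)
  F1 <- updateFeatures(f$B, f$F, X, list(C), alpha = 0.3)
  F2 <- updateFeatures(f$B, f$F[, perm], X[, perm], list(C[perm, perm]),
                       alpha = 0.3)
  expect_equal(F2, F1[, perm], tolerance = 1e-12)
  B1 <- updateBasis(f$B, f$F, X)
  B2 <- updateBasis(f$B, f$F[, perm], X[, perm])
  expect_equal(B2, B1, tolerance = 1e-12)
})

test_that("prediction scores are B F_l, min-max scaled", {
  inst <- smallInstance(seed = 14)
  fit <- mprnmf(inst@trainX, instanceCouplings(inst), k = 3, alpha = 0.1,
                iterations = 30, seed = 2)
  raw <- predictScores(fit, rescale = FALSE)
  expect_equal(raw, basisMatrix(fit) %*% featureL(fit), ignore_attr = TRUE)
  S <- predictScores(fit)
  expect_equal(range(S), c(0, 1))
  expect_equal(S, (raw - min(raw)) / (max(raw) - min(raw)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # degenerate all-equal scores rescale to zero
  m <- new("FactorModel", B = matrix(0, 4, 2),
           F = matrix(0.5, 2, 3), k = 2L, alpha = 0, seed = 1L,
           objectiveHistory = c(1, 1),
           termIds = paste0("o", 1:4), lncIds = c("l1", "l2"),
           geneIds = "g1")
  expect_equal(unname(predictScores(m)), matrix(0, 4, 2))
})
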