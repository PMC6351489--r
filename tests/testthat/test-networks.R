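test_that("co-expression edges follow the thresholded Pearson rule", {
  e <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  net <- buildCoexpressionNetwork(e, threshold = 0.5)
  W <- adjacency(net)
  expect_equal(W["a", "b"], 1)       # perfectly correlated
  expect_equal(W["a", "c"], 0)       # r = -1 dropped
  expect_equal(W["b", "c"], 0)

  net2 <- buildCoexpressionNetwork(e, threshold = 0.5, useAbsolute = TRUE)
  expect_equal(adjacency(net2)["a", "c"], 1)

  expect_error(buildCoexpressionNetwork(e[, 1, drop = FALSE], 0.5),
               "2 samples")

  # zero-variance entity correlates 0 with everything
  e2 <- rbind(e, d = c(5, 5, 5))
  expect_equal(sum(adjacency(buildCoexpressionNetwork(e2, 0.1))["d", ]), 0)

  # random case vs entrywise oracle
  withr::local_seed(8)
  E <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("e", 1:10), NULL))
  W <- adjacency(buildCoexpressionNetwork(E, 0.5))
  for (i in 1:9) for (j in (i + 1):10) {
    r <- oraclePearson(E[i, ], E[j, ])
    expect_equal(W[i, j], if (r >= 0.5) r else 0, tolerance = 1e-12)
  }
})

test_that("expression view thresholds the lncRNA-gene correlations", {
  l <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("l1", NULL))
  g <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  Y <- viewMatrix(buildExpressionView(l, g, 0.5))
  expect_equal(Y["l1", "g1"], 1)
  expect_equal(Y["l1", "g2"], 0)
  expect_error(buildExpressionView(l, g[, 1:3, drop = FALSE], 0.5),
               "samples")

  withr::local_seed(13)
  L <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("l", 1:5), NULL))
  G <- matrix(rnorm(7 * 8), 7, 8, dimnames = list(paste0("g", 1:7), NULL))
  Y <- viewMatrix(buildExpressionView(L, G, 0.3))
  for (i in 1:5) for (j in 1:7) {
    r <- oraclePearson(L[i, ], G[j, ])
    expect_equal(Y[i, j], if (r >= 0.3) r else 0, tolerance = 1e-12)
  }
})

test_that("disease view is the pairwise Jaccard index", {
  lnc <- list(l1 = c("d1", "d2"), l2 = c("d1", "d2", "d3"), l3 = character())
  gene <- list(g1 = c("d1", "d2"), g2 = c("d2", "d3", "d4"),
               g3 = character())
  Y <- viewMatrix(buildDiseaseView(lnc, gene))
  expect_equal(Y["l1", "g1"], 1)
  expect_equal(Y["l2", "g2"], 0.5)          # |{d2,d3}| / |{d1..d4}|
  expect_equal(Y["l3", "g3"], 0)            # both empty -> 0
  expect_equal(Y["l3", "g1"], 0)            # disjoint
})

test_that("largest connected component matches a BFS oracle", {
  # 3-node component beats 2-node component
  W <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  W["a", "b"] <- W["b", "a"] <- 1
  W["b", "c"] <- W["c", "b"] <- 1
  W["d", "e"] <- W["e", "d"] <- 1
  lcc <- largestConnectedComponent(entityNetwork(letters[1:5], W))
  expect_identical(entityIds(lcc), c("a", "b", "c"))

  # connected graph -> identity
  net <- randomNetwork(8, seed = 2, p = 0.8)
  expect_identical(adjacency(largestConnectedComponent(net)),
                   adjacency(net))

  # random sparse graphs vs BFS
  for (seed in 1:5) {
    net <- randomNetwork(15, seed = 500 + seed, p = 0.08)
    comp <- oracleComponents(adjacency(net))
    sizes <- table(comp)
    big <- as.integer(names(sizes)[sizes == max(sizes)])
    expected <- entityIds(net)[comp == big[1]]  # first = smallest index
    expect_identical(entityIds(largestConnectedComponent(net)), expected)
  }
  expect_error(largestConnectedComponent(entityNetwork(character(),
                                                       matrix(0, 0, 0))),
               "empty")
})

test_that("adjacency normalization and Laplacian follow D^-1/2 W D^-1/2", {
  two <- entityNetwork(c("a", "b"), matrix(c(0, 1, 1, 0), 2))
  expect_equal(normalizeAdjacency(two), matrix(c(0, 1, 1, 0), 2),
               ignore_attr = TRUE)
  expect_equal(laplacianMatrix(two), matrix(c(1, -1, -1, 1), 2),
               ignore_attr = TRUE)

  tri <- entityNetwork(c("a", "b", "c"),
                       matrix(1, 3, 3) - diag(3))
  Wb <- normalizeAdjacency(tri)
  expect_equal(unname(Wb[upper.tri(Wb)]), rep(0.5, 3))

  # edgeless graph: L = I, isolated vertices keep zero rows
  iso <- entityNetwork(c("a", "b"), matrix(0, 2, 2))
  expect_equal(normalizeAdjacency(iso), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(laplacianMatrix(iso), diag(2), ignore_attr = TRUE)

  for (seed in 1:5) {
    net <- randomNetwork(12, seed = 600 + seed)
    W <- adjacency(net)
    d <- rowSums(W)
    Dhalf <- diag(ifelse(d > 0, 1 / sqrt(d), 0))
    expect_equal(normalizeAdjacency(net), Dhalf %*% W %*% Dhalf,
                 tolerance = 1e-12, ignore_attr = TRUE)
    L <- laplacianMatrix(net)
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)                 # PSD
    if (all(oracleComponents(W) == 1))         # null vector D^{1/2} 1
      expect_equal(max(abs(L %*% sqrt(d))), 0, tolerance = 1e-8)
  }
})

test_that("normalization and Laplacian are permutation equivariant", {
  net <- randomNetwork(10, seed = 77)
  withr::local_seed(78)
  perm <- sample(10)
  permNet <- entityNetwork(entityIds(net)[perm],
                           adjacency(net)[perm, perm])
  expect_equal(normalizeAdjacency(permNet),
               normalizeAdjacency(net)[perm, perm], tolerance = 1e-12)
  expect_equal(laplacianMatrix(permNet),
               laplacianMatrix(net)[perm, perm], tolerance = 1e-12)
})

test_that("bi-colored assembly has the exact block layout", {
  nl <- entityNetwork("l1", matrix(0, 1, 1))
  ng <- entityNetwork("g1", matrix(0, 1, 1))
  v <- bipartiteView("v", "l1", "g1", matrix(0.5, 1, 1))
  C <- assembleBicolored(nl, ng, v)
  expect_equal(adjacency(C), matrix(c(0, 0.5, 0.5, 0), 2),
               ignore_attr = TRUE)

  netL <- randomNetwork(4, seed = 90)
  netG <- randomNetwork(6, seed = 91)
  withr::local_seed(92)
  Y <- matrix(runif(24), 4, 6)
  v <- bipartiteView("v", entityIds(netL), entityIds(netG), Y)
  C <- adjacency(assembleBicolored(netL, netG, v))
  expect_true(isSymmetric(unname(C)))
  expect_equal(C[1:4, 1:4], adjacency(netL), ignore_attr = TRUE)
  expect_equal(C[5:10, 5:10], adjacency(netG), ignore_attr = TRUE)
  expect_equal(C[1:4, 5:10], Y, ignore_attr = TRUE)

  # zero view -> block diagonal
  v0 <- bipartiteView("v", entityIds(netL), entityIds(netG),
                      matrix(0, 4, 6))
  C0 <- adjacency(assembleBicolored(netL, netG, v0))
  expect_equal(C0[1:4, 5:10], matrix(0, 4, 6), ignore_attr = TRUE)

  expect_error(assembleBicolored(netL, netG,
                                 bipartiteView("v", "x", "y",
                                               matrix(0, 1, 1))),
               "ids")
})

test_that("gene filtering re-indexes annotations and views consistently", {
  inst <- smallInstance(seed = 44)
  keep <- inst@truthX@geneIds[seq(1, 40, by = 2)]
  Xf <- filterAnnotationGenes(inst@truthX, keep)
  expect_identical(geneIds(Xf), keep)
  expect_identical(lncIds(Xf), inst@truthX@lncIds)  # lncRNAs never filtered
  v <- buildDiseaseView(inst@lncDiseases, inst@geneDiseases)
  vf <- filterViewGenes(v, keep)
  expect_equal(viewMatrix(vf), viewMatrix(v)[, keep])
})
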