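#' Generate a coupled synthetic benchmark instance
#'
#' Plants `plantedK` latent function modules shared by lncRNAs and genes
#' and derives every data layer from the same hidden grouping, emulating
#' the joint structure the method assumes: module-mates show correlated
#' expression, overlapping disease sets, dense PPI connectivity (genes),
#' and share a disjoint block of GO terms.
#'
#' Expression: each module owns a latent profile over `nSamples` samples;
#' the profiles are mutually orthogonal after centering, so at noise = 0
#' within-module Pearson correlation is exactly 1 and cross-module exactly
#' 0. An entity's profile is its module profile plus noise * N(0, 1).
#' Diseases: each module owns a disjoint pool of `diseasesPerModule`
#' diseases; a member carries a uniform fraction in [1 - noise/2, 1] of the
#' pool (the full pool at noise = 0) plus Poisson(noise * 3) background
#' diseases from a shared background pool. PPI: gene pairs are connected
#' with probability `withinP` within modules and `crossP` across.
#' Annotations: the `nO` terms are split into `plantedK` contiguous
#' disjoint blocks; every member of a module carries all of its block's
#' terms. A fraction of the lncRNA positives is hidden from the training
#' matrix via [maskAnnotations()].
#'
#' @param nL,nG,nO numbers of lncRNAs, genes, ontology terms.
#' @param plantedK number of planted modules,
#'   <= min(nL, nG, nO, nSamples - 1).
#' @param noise noise level in [0, 1] scaling all corruption channels.
#' @param maskFraction fraction of lncRNA annotations hidden, in [0, 1).
#' @param seed generator seed.
#' @param nSamples expression samples (default 30).
#' @param withinP,crossP PPI edge probabilities within / across modules.
#' @param diseasesPerModule module disease-pool size (default 8).
#' @return A [SyntheticInstance-class].
#' @examples
#' inst <- generateInstance(20, 40, 12, plantedK = 3, noise = 0,
#'                          maskFraction = 0, seed = 1)
#' cor(inst@exprL[1, ], inst@exprL[which(inst@moduleL == inst@moduleL[1])[2], ])
#' @export
generateInstance <- function(nL, nG, nO, plantedK, noise = 0.1,
                             maskFraction = 0.2, seed = 1L,
                             nSamples = 30L, withinP = 0.6, crossP = 0.02,
                             diseasesPerModule = 8L) {
  if (plantedK > min(nL, nG, nO))
    stop("plantedK must be <= min(nL, nG, nO)")
  if (plantedK > nSamples - 1L)
    stop("plantedK must be < nSamples for orthogonal module profiles")
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  if (maskFraction < 0 || maskFraction >= 1)
    stop("maskFraction must lie in [0, 1)")
  seed <- as.integer(seed)

  inst <- withSeed(seed, {
    lncIds <- paste0("l", seq_len(nL))
    geneIds <- paste0("g", seq_len(nG))
    termIds <- paste0("o", seq_len(nO))

    # module assignment; first plantedK entities of each class pin one
    # member per module so no module is empty
    modL <- c(seq_len(plantedK),
              sample.int(plantedK, nL - plantedK, replace = TRUE))
    modG <- c(seq_len(plantedK),
              sample.int(plantedK, nG - plantedK, replace = TRUE))

    # orthogonal centered module profiles: cross-module Pearson exactly 0
    Z <- matrix(stats::rnorm(nSamples * plantedK), nSamples, plantedK)
    Z <- sweep(Z, 2L, colMeans(Z))
    Q <- qr.Q(qr(Z)) * sqrt(nSamples)    # unit-variance-ish latent signals

    makeExpr <- function(mod, ids) {
      E <- t(Q[, mod, drop = FALSE]) +
        noise * matrix(stats::rnorm(length(mod) * nSamples),
                       length(mod), nSamples)
      dimnames(E) <- list(ids, paste0("s", seq_len(nSamples)))
      E
    }
    exprL <- makeExpr(modL, lncIds)
    exprG <- makeExpr(modG, geneIds)

    pools <- lapply(seq_len(plantedK), function(m)
      paste0("d", (m - 1L) * diseasesPerModule + seq_len(diseasesPerModule)))
    background <- paste0("bg", seq_len(20L))
    drawDiseases <- function(m) {
      pool <- pools[[m]]
      fr <- stats::runif(1, 1 - noise / 2, 1)
      keep <- sample(pool, max(1L, round(fr * length(pool))))
      nbg <- stats::rpois(1, noise * 3)
      unique(c(keep, if (nbg > 0) sample(background, min(nbg, 20L))))
    }
    lncDiseases <- stats::setNames(lapply(modL, drawDiseases), lncIds)
    geneDiseases <- stats::setNames(lapply(modG, drawDiseases), geneIds)

    same <- outer(modG, modG, "==")
    p <- ifelse(same, withinP, crossP)
    U <- matrix(stats::runif(nG * nG), nG, nG)
    A <- (U < p) * 1
    A[lower.tri(A, diag = TRUE)] <- 0
    W <- A + t(A)
    ppi <- entityNetwork(geneIds, W)

    termMod <- rep(seq_len(plantedK), length.out = nO)
    termMod <- sort(termMod)             # contiguous disjoint blocks
    truth <- outer(termMod, c(modL, modG), "==") * 1
    truthX <- annotationMatrix(truth, termIds, lncIds, geneIds)
    list(modL = modL, modG = modG, exprL = exprL, exprG = exprG,
         lncDiseases = lncDiseases, geneDiseases = geneDiseases,
         ppi = ppi, truthX = truthX)
  })

  maskSeed <- deriveSeeds(seed, 1L)
  masked <- maskAnnotations(inst$truthX, maskFraction, maskSeed)
  new("SyntheticInstance",
      exprL = inst$exprL, exprG = inst$exprG,
      lncDiseases = inst$lncDiseases, geneDiseases = inst$geneDiseases,
      ppi = inst$ppi, truthX = inst$truthX, trainX = masked$train,
      mask = masked$mask, moduleL = as.integer(inst$modL),
      moduleG = as.integer(inst$modG), plantedK = as.integer(plantedK),
      seed = seed)
}

#' Hide a fraction of lncRNA annotations
#'
#' Exactly floor(fraction * number of lncRNA-block positives) entries are
#' chosen uniformly without replacement under the seed and zeroed in the
#' returned training matrix; gene columns are untouched.
#'
#' @param X a binary [AnnotationMatrix-class].
#' @param fraction fraction in [0, 1) of lncRNA positives to hide.
#' @param seed RNG seed.
#' @return list(train = [AnnotationMatrix-class],
#'   mask = data.frame(term, lnc)).
#' @export
maskAnnotations <- function(X, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  nl <- length(X@lncIds)
  lncBlock <- X@X[, seq_len(nl), drop = FALSE]
  pos <- which(lncBlock == 1, arr.ind = TRUE)
  nHide <- floor(fraction * nrow(pos))
  if (nHide == 0L)
    return(list(train = X, mask = data.frame(term = character(),
                                             lnc = character())))
  hide <- withSeed(seed, sample.int(nrow(pos), nHide))
  Xt <- X@X
  Xt[pos[hide, , drop = FALSE]] <- 0
  list(train = annotationMatrix(Xt, X@termIds, X@lncIds, X@geneIds),
       mask = data.frame(term = X@termIds[pos[hide, 1L]],
                         lnc = X@lncIds[pos[hide, 2L]]))
}
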