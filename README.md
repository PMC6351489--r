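# MPrNMF

Multi-view partially regularized nonnegative matrix factorization for
predicting Gene Ontology (GO) functions of long non-coding RNAs
(lncRNAs).

## The problem

Most lncRNAs have no experimentally determined function, while the GO
annotations of protein-coding genes are comparatively rich. Network-based
methods transfer annotation signal from genes to lncRNAs through
lncRNA–gene association networks (co-expression, shared disease links),
usually after fusing all evidence into a single "bi-colored" network — a
fusion that can destroy the structure of the individual data types.

MPrNMF avoids the fusion step. Each data type yields its own lncRNA–gene
association view `Y_i` (here: thresholded Pearson co-expression and
disease-set Jaccard similarity). The known ontology-by-entity annotation
matrix `X` (lncRNA columns first, then genes) is factorized as `X ≈ BF`
with nonnegative basis `B` (terms × k) and features `F = [F_l | F_g]`
(k × entities, each column on the simplex), while every view separately
pulls coupled lncRNA/gene features together through its cross-class
coupling matrix `C_i* = [[0, Y_i], [Y_i', 0]]`:

    min_{B,F ≥ 0}  J = ‖X − BF‖²_F  −  α Σ_i tr(F C_i* F′)
                   s.t. each column of F sums to 1

The trace term equals `2 tr(F_l Y_i F_g′)`, so it rewards agreement
between the latent features of associated lncRNA–gene pairs in every view
at once ("partial" regularization: only the cross-class blocks enter, not
the within-class networks). The objective is optimized by Lee–Seung-style
multiplicative updates

    B ← B ⊙ (X F′) ⁄ (B F F′)
    F ← F ⊙ (B′X + α Σ_i F C_i*) ⁄ (B′B F),  then column renormalization

and predicted lncRNA–term scores are `B F_l`, min–max scaled to [0, 1].

The package also provides:

* **Network construction** — Pearson co-expression networks, Jaccard
  disease views, largest-connected-component filtering, symmetric
  adjacency normalization `D^{-1/2} W D^{-1/2}` and normalized Laplacians,
  bi-colored block matrices.
* **Baselines** — label propagation on one network, label propagation on
  the bi-colored network, dual label propagation, and truncated KATZ
  path-count scores.
* **Rank selection** — the instability criterion: for each candidate k,
  τ random restarts are fitted and `Υ(k)` is the mean pairwise
  dissimilarity of their basis matrices (via column cross-correlations);
  the k minimizing `Υ` is selected.
* **Evaluation** — threshold-swept micro-averaged Recall/Precision/Fmax
  and the count of lncRNAs correctly annotated with at least one term.
* **Synthetic benchmark generator** — coupled instances with planted
  function modules that simultaneously shape expression correlation,
  disease-set overlap, PPI connectivity and GO annotations, with a
  held-out mask of lncRNA annotations for recovery experiments.

## Worked example

```r
library(MPrNMF)

# a coupled synthetic instance: 50 lncRNAs, 150 genes, 40 GO terms,
# 6 planted function modules, 20% of lncRNA annotations held out
inst <- generateInstance(50, 150, 40, plantedK = 6, noise = 0.1,
                         maskFraction = 0.2, seed = 1)

v1 <- buildExpressionView(inst@exprL, inst@exprG, threshold = 0.5)
v2 <- buildDiseaseView(inst@lncDiseases, inst@geneDiseases)
couplings <- list(buildCoupling(v1), buildCoupling(v2))

fit <- mprnmf(inst@trainX, couplings, k = 6, alpha = 0.1,
              iterations = 100, seed = 1, restarts = 3)
fit
#> FactorModel: rank 6, alpha 0.1, 26 iterations, J 1955.86 -> -417.912

# recovery of the held-out annotations
S <- heldOutScores(fit, inst@trainX)
hidden <- split(inst@mask$term, inst@mask$lnc)
fmaxCurve(S, hidden, seq(0, 1, by = 0.01))
#> EvaluationReport: Fmax 1.0000 at t = 0.01 (40 lncRNAs annotated)

# instability-based rank selection recovers the planted rank
selectRank(inst@trainX, couplings, alpha = 0.1, kGrid = c(2, 4, 6, 8, 10),
           tau = 10, seed = 1, restarts = 3)$bestK
#> [1] 6
```

The Fmax of 1.0 means every one of the 66 hidden lncRNA–term pairs is
separated from the non-associations by a common score threshold (already
at t = 0.01: held-out pairs score high while true negatives score ~0); on
noisier or real data this value drops and the curve (`@curve`) shows the
recall/precision trade-off.

A command-line front end over the same functions lives at
`inst/cli/mprnmf.R` (subcommands `simulate`, `build`, `fit`, `select-k`,
`baseline`, `evaluate`).

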