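---
title: "Methods: graph-regularized NMF for drug-miRNA association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-regularized NMF for drug-miRNA association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small-molecule drugs can up- or down-regulate specific miRNAs, and curated
catalogues of such effects are sparse: a few hundred verified pairs over tens
of drugs and hundreds of miRNAs, with every unobserved pair recorded as 0.
Treating those zeros as confident negatives is wrong — most are simply
untested — so the task is best posed as completing a sparse bipartite
adjacency matrix under the guilt-by-association assumption that similar drugs
affect similar miRNAs. `gnmfdma` implements a three-stage pipeline for this
completion problem:

1. **Similarity fusion.** Up to four drug-drug similarity sources (chemical
   structure, indication phenotype, side effect, gene functional consistency)
   and two miRNA-miRNA sources (indication phenotype, gene functional
   consistency) are combined by an element-wise weighted mean,
   $S = \sum_i \omega_i S_i / \sum_i \omega_i$, with unit weights by default.
   Computing the raw per-source similarities from SMILES strings, side-effect
   ontologies or gene sets is out of scope: they are consumed as matrices.

2. **Weighted K-nearest-known-neighbour repair (WKNKN).** For each drug
   $d_l$, the $K$ most similar drugs *with at least one recorded
   association* contribute their interaction profiles,
   $$Y_d(d_l) = \frac{\sum_{i=1}^{K}\alpha^{i-1}\,S_D(d_i,d_l)\,Y(d_i)}
                     {\sum_{i=1}^{K} S_D(d_i,d_l)},$$
   with neighbours indexed in descending similarity and a rank-decay
   $\alpha \in (0,1]$. The symmetric construction over miRNA columns gives
   $Y_m$; the two estimates are averaged and merged with the observed matrix
   by element-wise maximum, so observed 1s are never altered and entries can
   only grow. Note the denominator deliberately carries the similarities but
   not the decay: with $\alpha<1$ the profile is a damped rather than convex
   combination. This asymmetry is part of the method's definition and is
   implemented exactly; "fixing" it to a normalized weighted mean changes
   the output.

3. **Graph-regularized collaborative NMF.** Each entity space is reduced to
   its local geometry by a $p$-nearest-neighbour mask $G$ ($G_{ij}=1$ for
   mutual neighbours, $0.5$ one-sided, $0$ otherwise), the masked similarity
   $S^* = S \circ G$ yields the Laplacian $L = D - S^*$ with
   $D_{ii} = \sum_l S^*_{il}$, and the repaired matrix is factorized as
   $Y \approx W^\top H$ with $k$-dimensional non-negative factors by
   minimizing
   $$\|Y - W^\top H\|_F^2
     + \lambda\left[\operatorname{tr}(W L_d W^\top)
     + \operatorname{tr}(H L_m H^\top)\right]
     + \beta\left[\|W\|_F^2 + \|H\|_F^2\right].$$
   The graph terms pull similar entities toward nearby latent positions
   (they equal $\tfrac12\sum_{ij} S^*_{ij}\|w_i-w_j\|^2$); the Tikhonov term
   keeps factor magnitudes bounded. Minimization uses the multiplicative
   update rules
   $$W \leftarrow W \circ \frac{H Y^\top + \lambda W S_D^*}
                              {H H^\top W + \beta W + \lambda W D_d},\qquad
     H \leftarrow H \circ \frac{W Y + \lambda H S_M^*}
                              {W W^\top H + \beta H + \lambda H D_m},$$
   which preserve non-negativity exactly and decrease the objective
   monotonically. Predicted scores are $Y^* = W^\top H$; for each drug the
   highest-scoring unknown miRNAs are its candidates.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `K` | neighbours used in the repair | 3 | counted among *known* entities only |
| `alpha` | rank-decay of neighbour weights | 0.9 | in $(0,1]$; 1 = pure similarity weighting |
| `p` | neighbourhood size of the graph mask | 5 | must satisfy $p \le n-1$ |
| `k` | latent dimensionality | 35 | must satisfy $k < \min(n,m)$ |
| `lam` | graph-regularization weight $\lambda$ | 1 | 0 disables the manifold term |
| `beta` | Tikhonov weight $\beta$ | 0.02 | 0 disables shrinkage |
| `tol` | convergence threshold | 1e-4 | max per-column squared change of `W` and `H` |
| `max_iter` | iteration cap | 1000 | non-convergence is a warning, not an error |

These defaults are the operating point reported for this method class on the
curated corpus scale (tens of drugs, hundreds of miRNAs, ~6% density); on
substantially different data `k`, `lam` and `beta` should be re-selected by
cross-validation on training folds only.

## Numerical and design choices

* **Similarity diagonals are defined as 1** at ingest. All similarity
  measures consumed here are reflexive; forcing the diagonal also makes
  fusion closed (the mean of unit diagonals is a unit diagonal).
* **Neighbourhood tie-breaks are by ascending index**, both in the graph
  mask and in the repair, so results are deterministic. The mask is purely
  rank-based and therefore invariant to monotone transforms of similarity.
* **Self-exclusion:** an entity is never its own neighbour; `G_ii = 1` is
  retained so that the masked similarity stays a valid similarity matrix
  (the diagonal cancels in $L = D - S^*$ anyway).
* **Known-only neighbours in the repair**: entities with all-zero profiles
  contribute nothing and are skipped when ranking neighbours
  (`known_only = FALSE` switches to ranking all entities). During
  cross-validation the repair sees only the masked training matrix, so
  held-out labels cannot leak through neighbour profiles.
* **Initialization** is i.i.d. uniform on $(0,1)$ scaled by
  $\sqrt{\overline{Y}/k}$, seeded; identical seeds give bit-identical fits.
* **A denominator guard** `eps = 1e-12` is added to the update-rule
  denominators, which can otherwise reach exact zero (e.g. an all-zero
  column after masking). Setting `eps = 0` recovers the textbook rules on
  strictly positive data, and with `lam = beta = 0` the trajectory then
  coincides with classical multiplicative-update NMF from the same start.
* **Update order** is Gauss-Seidel (`W` first, then `H` from the updated
  `W`); `jacobi = TRUE` gives the simultaneous variant of the derivation.
* **Convergence** is read as: the largest squared per-column change of `W`
  and of `H` both at or below `tol`, on raw unnormalized columns.
* **Top-fraction recovery** uses $\lceil q\,m \rceil$ ranks per drug;
  candidate rankings break score ties by miRNA id, lexicographically.

## Evaluation protocol

`gnmf_cv()` partitions the known pairs into five equal folds (sizes differ
by at most one), masks one fold at a time, runs the pipeline on the masked
matrix and scores all pairs. Positives of a fold are its held-out pairs;
negatives are **all pairs that are zero in the full known matrix**, the
standard convention when no verified negatives exist. Per-fold AUC is the
tie-corrected rank statistic; the report aggregates mean ± sd across folds
and also exposes a pooled-scores AUC. Threshold metrics (Sen, Pre, Acc, F1)
are computed at the cutoff achieving at least 85% specificity within each
fold.

Two consequences of the negative universe deserve emphasis. First, because
unknown-but-true associations sit in the negative set, measured AUC slightly
understates the true ranking quality. Second, precision at fixed specificity
scales with the negative:positive ratio — with ~10,000 negatives per ~140
positives, 15% false-positive rate means precision is necessarily small.
Reported precision values are therefore only comparable between runs that
share the same universe; protocols that sample a balanced negative set
produce much higher, and mutually incomparable, precision numbers.

## The synthetic benchmark

`generate_dataset()` emulates the statistical structure the model assumes,
at the curated-corpus scale (defaults: 40 drugs, 300 miRNAs, 6% density):

* latent factors with squared-normal entries — non-negative and
  heavy-tailed, giving the skewed per-drug association counts of real
  catalogues rather than a flat degree distribution;
* associations as the top-quantile indicator of the planted score matrix
  $W_0^\top H_0$;
* similarities as cosine similarity of latent factor columns, blended with
  independent symmetric uniform noise at weight `noise` (0.2 by default),
  so the four drug views and two miRNA views are independently corrupted
  looks at one geometry.

What passing tests on this benchmark show: the solver minimizes the stated
objective monotonically and deterministically; the repair and graph
construction match their defining formulas exactly; informative similarities
measurably improve cross-validated ranking over permuted (misaligned)
similarities. What they do not show: performance on real catalogues. The
synthetic truth is *exactly* low-rank and its associations are a noiseless
threshold of that truth, so the factorization alone is unusually strong
here, and the hardest negatives are near-threshold pairs that are maximally
similar to true positives. On such data the neighbour repair can even
slightly reduce cross-validated AUC (the acceptance script reports the
repaired, ablated and permuted-similarity AUCs side by side), whereas on
real, noisier catalogues the repair is the component that protects novel
drugs and miRNAs with sparse profiles. Conclusions about the repair's value
on real data must come from real data.

Problem sizes used in the shipped checks were chosen to exercise every code
path at desk scale: oracle comparisons on matrices up to 12 entities,
solver-behaviour checks on the 40 × 300 default benchmark, and a
full-protocol run at 39 × 286 with 664 positives.

## Known limitations

* The six raw similarity matrices are inputs; no kernel computation or
  missing-entity imputation is provided — entities without similarity
  support are rejected.
* Multiplicative updates converge to a stationary point, not a certified
  global optimum; different seeds can give slightly different scores
  (the CV report records the seed of every fit).
* Dense linear algebra throughout: appropriate for hundreds of entities,
  not for tens of thousands.
* The 85%-specificity metrics depend on the negative-universe convention,
  as discussed above.
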