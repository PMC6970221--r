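---
title: "Stability-optimized multiple-holdout inference for sparse PLS and regularized kernel CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-optimized multiple-holdout inference for sparse PLS and regularized kernel CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvholdout)
```

## The problem

Many questions in biological psychiatry and imaging epidemiology take the
form "which combination of variables in one high-dimensional view of a
cohort co-varies with which combination of variables in another?" — for
example, voxelwise gray-matter volumes (hundreds of thousands of features)
against item-level questionnaire and demographic data (a few hundred
features), measured on the same few hundred participants. Partial least
squares (PLS) and canonical correlation analysis (CCA) answer this by
finding per-view weight vectors $u$ and $v$ such that the subject scores
$Xu$ and $Yv$ have maximal covariance (PLS) or correlation (CCA). With far
more features than samples, unregularized fits overfit badly and their
dense weight vectors resist interpretation. `mvholdout` implements two
regularized fixes and — more importantly — a resampling framework that makes
their results testable and stable.

## The two model cores

**Sparse PLS.** One latent effect solves

$$\max_{u, v}\; u^\top X^\top Y v \quad \text{s.t.}\quad
  \|u\|_2 = 1,\; \|u\|_1 \le c_u,\; \|v\|_2 = 1,\; \|v\|_1 \le c_v,$$

a penalized rank-one matrix decomposition. The L1 budgets $c_u \in
[1, \sqrt p]$ and $c_v \in [1, \sqrt q]$ control sparsity: at $c = 1$ a
single variable survives, at $c = \sqrt d$ the constraint is inactive and
the solution is the leading singular-vector pair of $X^\top Y$. The
combination of a unit L2 sphere with an L1 ball acts like an elastic net:
sparse solutions that can still share weight across correlated variables.
`spls_fit()` alternates the closed-form updates
$u \leftarrow \mathcal P_{c_u}(X^\top Y v)$ and
$v \leftarrow \mathcal P_{c_v}(Y^\top X u)$, where $\mathcal P_c$
(`l1_constrained_unit()`) soft-thresholds and renormalizes with the smallest
threshold that meets the budget, found by bisection. Design choices worth
knowing:

* **Initialization** is the leading right singular vector of $X^\top Y$ —
  deterministic, so the thousands of fits inside the resampling loops are
  exactly reproducible without random restarts.
* **Bisection** runs to a relative threshold tolerance of $10^{-12}$ (at
  most 200 iterations). A looser tolerance visibly breaks the monotonicity
  of the alternating objective, which we assert in the tests.
* **Tie-break** in the one-variable limit: the lowest index among
  equal-magnitude maxima, so results do not depend on storage order.
* **Convergence** is declared when neither weight vector moves by more than
  `tol` (default $10^{-6}$) in L2 norm; non-convergence within `max_iter`
  (default 500) returns the current iterate flagged `converged = FALSE`.

**Regularized kernel CCA.** With linear kernels $K_x = XX^\top$,
$K_y = YY^\top$ built from centered data, `kcca_fit()` maximizes
$\alpha^\top K_x K_y \beta$ subject to

$$(1-\kappa_x)\,\alpha^\top K_x^2 \alpha + \kappa_x\,\alpha^\top K_x \alpha = 1$$

and the analogous $y$ constraint. The two regularization parameters
$\kappa \in [0, 1]$ interpolate smoothly between maximizing correlation
($\kappa = 0$, classical CCA) and maximizing covariance ($\kappa = 1$,
PLS). We solve the problem as an SVD in the Cholesky-whitened basis of the
constraint matrices, which is equivalent to the usual generalized
eigenproblem but deterministic and numerically tame at these sizes. A
jitter of $10^{-9}\,\mathrm{tr}(K)/n$ on each constraint diagonal
guarantees solvability and is escalated tenfold (up to three times) if the
factorization fails. Primal weights are recovered as
$w = X^\top\alpha / \|X^\top\alpha\|_2$. The exact normalization convention
of published regularized-CCA variants differs between sources; the
constraint form above is this package's reconstruction of the
correlation-to-covariance interpolation and is isolated in `kcca_fit()` so
an alternative convention is a drop-in replacement.

Successive effects are extracted for both families by **projection
deflation**, $X \leftarrow X(I - uu^\top)$ applied to each view with its own
weight vector, after which the deflated matrix is exactly orthogonal to the
extracted direction. Only the leading eigenpair is used per KCCA effect, so
the two model families move through the framework identically.

## The multiple-holdout framework

`run_holdout()` wraps either core in the procedure that is the actual point
of this package:

1. **Outer splits.** The sample is split `n_outer_splits` times (default
   10) into an optimization set (80%) and a holdout set (20%).
2. **Nested preprocessing.** Confound removal (OLS residualization per
   feature, `fit_confound_model()`) and mean-centering (optionally
   unit-variance scaling) are fitted on training rows only and applied to
   the corresponding validation/holdout rows. Nothing computed from
   held-out rows ever enters a fit — the test suite asserts this bitwise.
3. **Inner splits and the joint criterion.** Within each optimization set,
   `n_inner_splits` (default 50) random training/validation splits evaluate
   every hyperparameter grid cell. Cells are ranked separately by mean
   signed validation correlation (generalizability) and by the stability of
   the fitted weights across the inner fits — chance-corrected support
   overlap for SPLS, mean absolute weight correlation for KCCA, averaged
   over the two views — and the cell with the smallest rank sum wins. Ties
   go to the higher validation correlation, then to the more regularized
   cell. The rank-sum combination is a deliberate reconstruction: it is the
   simplest scale-free way to weight the two criteria equally, and it lives
   in one function (`select_hyperparams()`) so it can be swapped.
4. **Holdout permutation test.** The selected cell is refitted on the whole
   optimization set and evaluated on the untouched holdout:
   `holdout_permutation_test()` permutes the holdout rows of the y view
   (re-pairing one view is enough to break the cross-view coupling) and
   reports $p = (1 + \#\{r_{\text{perm}} \ge r_{\text{obs}}\}) /
   (n_{\text{perm}} + 1)$. The test is one-sided because the sign
   convention fixes the training correlation to be nonnegative; validation
   and holdout correlations stay signed, so anti-generalization counts
   against a model rather than for it.
5. **Across-split decision.** An effect is significant when the smallest
   per-split p-value survives Bonferroni correction across the outer
   splits (`min(p) < alpha / n_outer_splits`); a majority rule is available
   as an alternative. Note a practical floor: with $B$ permutations the
   smallest achievable p-value is $1/(B+1)$, so few permutations plus many
   splits make Bonferroni deliberately conservative — with 99 permutations
   and 5 splits no effect can be declared significant at $\alpha = 0.05$ at
   all. The 1000-permutation default keeps the floor well below the
   corrected threshold.
6. **Reporting and deflation.** The reported model comes from the split
   with the best rank-sum combination of holdout correlation and stability
   (`choose_best_split()`). If the effect is significant, both views are
   deflated *within each split* using that split's optimization-set weights
   (holdout rows are deflated with the same training-derived weights, so
   the leakage guarantee survives deflation), and the search repeats until
   the first non-significant effect — which is returned, flagged — or
   `max_effects`.

A failed split (degenerate fits in every grid cell) is dropped with a
warning as long as at least 80% of the outer splits survive; otherwise the
run aborts.

**Confound handling.** The default residualizes within every training set,
which is the leakage-free choice. `global_confound_removal = TRUE`
residualizes once on the full sample before splitting — simpler, matches
common practice, but lets holdout rows influence the residualization map;
it exists for comparison, not as a recommendation. Categorical confounds
(e.g. scanner site) must arrive indicator-coded; the package keeps the
numeric-matrix contract uniform rather than guessing encodings.

## The synthetic generator, and what passing tests mean

`simulate_paired_views()` plants `n_effects` shared latent factors
$z_k \sim \mathcal N(0,1)$ in both views:
$X = \sum_k s_k z_k u_k^\top + C G_x + E$, with sparse unit weight vectors
whose supports are disjoint across effects within a view, equal-magnitude
(random-sign) nonzero entries, strictly decreasing strengths $s_k$ for
identifiable ordering, i.i.d. Gaussian noise, and optional Gaussian
confounds loading on every feature. Options exist for heavy-tailed latents
(Student-t) and geometrically decaying weight magnitudes.

This emulates exactly the structure the models assume — linear, sparse,
homoscedastic — and none of the structure real neuroimaging data adds:
spatial autocorrelation among voxels, bounded/discrete questionnaire items,
site and batch effects beyond linear confounds, heteroscedastic noise.
Passing recovery tests therefore demonstrates that the estimation machinery
is correct and calibrated under its own assumptions; it does not promise
comparable effect sizes or support-recovery rates on real cohort data.

## Numerical and testing choices

Problem sizes in the test suite and acceptance script were chosen so the
whole suite runs on a laptop-class single core in a few minutes: oracle
equivalences on 20-sample instances (50 replicates), permutation
calibration with 500 null replicates at 199 permutations, global-null
framework calibration with 200 datasets of $n = 60$, $p = q = 8$ under a
reduced scheme (5 outer × 10 inner splits, 3×3 grid, 99 permutations), and
parameter recovery at $n = 500$, $p = q = 100$ with two planted effects of
strengths 3 and 2 over a 5-point logarithmic budget grid. The recovery run
asserts support F1 ≥ 0.9 and latent-score correlation ≥ 0.9 for the first
effect and F1 ≥ 0.8 for the second after deflation; these are properties
the implementation meets under the generator's stated conditions, not tuned
targets.

Other conventions: sample alignment across view files takes the ID
intersection in x-file order; missing values are rejected rather than
imputed (the models assume complete matrices); all randomness flows from a
single master seed through deterministic child seeds, so a rerun with the
same configuration is bitwise identical; grid cells whose fits degenerate
in more than half the inner splits are marked invalid rather than imputed.

## Known limitations

* Only linear kernels ship for KCCA; the kernel step is isolated so a
  nonlinear kernel is a drop-in, but out-of-sample centering for nonlinear
  kernels is not implemented.
* Stability-selection variants (keep variables selected in a proportion of
  subsamples) and bootstrap confidence intervals for weights are out of
  scope; the stability measures here serve hyperparameter selection only.
* The rank-sum joint criterion and the chance-corrected overlap are
  reconstructions of ideas that appear in the literature in several
  variants; both are single functions by design.
* Two-view only; no group-sparsity penalties.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_paired_views(
  n = 200, p = 30, q = 20, n_effects = 1,
  support_fraction = 0.2, effect_strengths = 3, seed = 1
)
cfg <- holdout_config(
  model = "spls", n_outer_splits = 5, n_inner_splits = 10,
  grid = list(x = c(1.5, 2.5, 4), y = c(1.5, 2.5, 4)),
  n_permutations = 199, max_effects = 2, seed = 2
)
res <- run_holdout(sim$data, cfg)
res
tidy(res)
glance(res)
autoplot(res)                  # holdout correlations by effect and split
autoplot(res, type = "latent") # best-split holdout latent space
```
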