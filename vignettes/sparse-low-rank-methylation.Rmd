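---
title: "Methods: sparse plus low-rank regression for methylation–expression mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse plus low-rank regression for methylation–expression mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrr)
```

## The model and its assumptions

`slrr` fits the multi-response decomposition

$$Y = XB + L + e,$$

with $Y$ ($n \times q$) gene expression, $X$ ($n \times p$) DNA methylation
beta values, $B$ ($p \times q$) the methylation-to-expression coefficient
matrix, $L$ ($n \times q$) an expression-heterogeneity (EH) term, and
$e_{ij} \sim N(0, \sigma^2)$ noise. Two structural assumptions make the
decomposition identifiable in practice:

* **Sparsity of $B$** — each gene's expression responds to a small number of
  CpG sites, so most entries of $B$ are zero.
* **Low rank of $L$** — the hidden drivers of expression (tumor subtype,
  batch, DNA sequence changes, cellular state) are few, so the EH term is a
  low-rank matrix. Writing $L = WH$ shows this is equivalent to a linear
  mixed model with unobserved model matrix, which is why absorbing the
  confounders into $L$ removes both spurious and masked associations.

The rank and $\ell_1$ budgets are imposed through their convex surrogates,
giving the penalized objective

$$\min_{B, L}\; \tfrac12\lVert Y - XB - L\rVert_F^2
  + \rho \lVert B\rVert_1 + \lambda \lVert L\rVert_*,$$

with the nuclear norm $\lVert L \rVert_*$ (sum of singular values) as the
convex relaxation of rank. The noise variance $\sigma^2$ is not a model
parameter of the solver; the residual $Y - X\hat B - \hat L$ plays the role
of $e$, and `summary()` reports a plug-in $\hat\sigma$.

## The alternating solver

Both blocks of the objective admit exact minimizers, so `slrr()` alternates:

1. **L-step.** For fixed $B$, the minimizer is singular value thresholding
   of the residual, $L = S_\lambda(Y - XB)$, where $S_\lambda$ soft-thresholds
   the singular values: $S_\lambda(W) = U\,\mathrm{diag}((d_i - \lambda)_+)V^T$.
   Implemented in `svt_prox()` with a dense LAPACK SVD — the package targets
   desk-scale cohorts (hundreds of samples, up to a few thousand features),
   where randomized or truncated SVDs buy nothing.
2. **B-step.** For fixed $L$, the problem separates into $q$ independent
   Lasso regressions of $Y_j - L_j$ on $X$, solved by cyclic coordinate
   descent with soft-threshold updates (`lasso_column()`). Each column is
   warm-started at its previous solution; the Gram matrix $X^TX$ is formed
   once per fit. The inner loop keeps $X^TXb$ incrementally and, between
   full sweeps, cycles over the active set only — convergence is declared
   only when a *full* sweep moves no coordinate by `cd_tol`.

Because each block update is an exact minimization, the objective trace is
non-increasing; the solver treats an increase beyond a $10^{-8}$
(relative) slack as an internal error rather than a warning, since it can
only arise from an implementation bug. The same argument guarantees
convergence of the trace for this convex problem regardless of block order;
the L-step is taken first so that the first iterate from the $B = 0, L = 0$
start is $S_\lambda(Y)$.

### Tuning parameters

| parameter | default | meaning |
|---|---|---|
| `rho` | user-set | $\ell_1$ weight; `rho >= max|Xc'Yc|` forces $B = 0$ |
| `lambda` | user-set | nuclear-norm weight; `lambda >= σ₁(residual)` forces $L = 0$ |
| `tol` | 1e-6 | relative objective-change stopping rule |
| `max_iter` | 100 | outer iterations |
| `cd_tol` | 1e-7 | max absolute coordinate change per full sweep |
| `cd_max_iter` | 1000 | coordinate-descent sweeps per column problem |
| `rank_tol` | 1e-8 | relative singular-value cutoff for the reported rank |
| `center` | TRUE | column-center $Y$ and $X$ before fitting |

No explicit intercept is carried; column centering absorbs it, and the
stored offsets let `predict()` return to the data scale. `rank_tol` is
relative to $\max(\sigma_1, 1)$, so a singular value of $10^{-12}$ next to
one of $10$ never counts toward the rank.

### Choosing the penalties

How to tune $\rho$ and $\lambda$ is genuinely open — no external rule is
prescribed — so the package offers two documented conventions rather than a
hidden one:

* `default_penalties()` — the rule used in all of the package's simulation
  studies: $\rho = 0.1 \cdot \max|X_c^T Y_c|$ and
  $\lambda = 0.25 \cdot \sigma_1(Y_c)$. Both anchors are the smallest
  penalty that zeroes the corresponding block entirely, so fixed fractions
  of them transfer across problem sizes and noise levels without retuning.
* `select_penalties()` — a slower BIC-type search over geometric ladders
  descending from those anchors, scoring
  $nq\log(\mathrm{RSS}/nq) + \log(nq)\,(\mathrm{nnz}(B) + \mathrm{rank}(L)(n+q))$,
  i.e. one parameter per active coefficient and $n + q$ per heterogeneity
  factor. This selector is pragmatic tooling for real cohorts, not part of
  the estimation theory.

Because only the *ranking* of $|\hat B_{ij}|$ feeds the association tables
and ROC analyses, results are fairly insensitive to $\rho$ over an order of
magnitude; $\lambda$ mainly controls the estimated number of heterogeneity
factors (and thereby the cluster count downstream).

## The synthetic-data generator

`simulate_meth_expr()` emulates the generative model used in the package's
support-recovery study:

* $X$: i.i.d. Bernoulli(0.25) binary methylation states — "methylated /
  unmethylated" calls rather than continuous beta values;
* $B$: exactly `round(0.02·p·q)` non-zero entries at uniformly chosen
  positions, values i.i.d. standard Gaussian. The exact-count convention
  (instead of per-entry Bernoulli thinning) makes nnz deterministic and
  testable;
* $L$: a loading matrix $H$ ($n \times K$, i.i.d. $N(0,1)$) is drawn once
  and each of the $q$ columns is $\sqrt{\tau} H z$, $z \sim N(0, I_K)$ —
  i.e. column covariance $\tau H H^T$, rank at most $K$;
* $e$: i.i.d. $N(0, \sigma_e^2)$.

Defaults where the study design leaves them open: $n = 200$, $p = q = 100$,
$K = 3$, $\tau = 1$, $\sigma_e = 1$ — a moderately confounded regime in
which the EH term carries about as much per-entry variance as the noise and
is comparable to the methylation signal. A single seed drives four named
substreams (X, B, H/L, e), so changing one component's parameter never
perturbs the other draws, and the session RNG is left untouched.

**What the generator does not emulate:** continuous beta-value
distributions (real promoter CpGs are bimodal in $[0,1]$, not binary),
correlation between neighbouring sites, count-derived heteroscedastic
expression noise, and confounders correlated with $X$ itself (the planted
$H$ is independent of methylation). Passing the recovery tests therefore
shows that the estimator separates sparse from low-rank structure under the
stated model — not that it is robust to every artefact of array data.

Support recovery is scored by `support_recovery_roc()`: every entry of
$\hat B$ is scored by $|\hat B_{ij}|$ against the label $B_{ij} \ne 0$, the
threshold sweep treats tied scores as one step, and AUROC is the trapezoidal
area. In the package's study conditions (5 replicates each) the easy regime
($n = 200$, $p = q = 50$, $K = 2$, $\tau = 1$, $\sigma_e = 0.5$) attains
mean AUROC ≈ 0.89, and moving to $p > \max(n, q)$ ($n = 50$, $p = 100$)
degrades it to ≈ 0.78 — the expected overfitting direction when sites
outnumber samples and genes. These problem sizes were chosen as the smallest
that cleanly exhibit both effects.

## Preprocessing conventions

The cohort funnel encodes fixed filtration rules plus a few conventions the
rules leave open:

* **Missingness**: a site missing in *more than* 70% of samples is dropped;
  survivors are mean-imputed per site. Mean imputation is the package's
  choice (nothing more elaborate is warranted before a regression that
  centers columns anyway). Chromosome-based exclusion is deliberately not
  bundled into this filter.
* **Promoter window**: $[-2000, +500]$ bp around the TSS, *closed* on both
  boundaries; upstream offsets are negative. Unannotated sites are dropped
  and counted.
* **Clinical**: strict `< 30` days (or missing) removal, so exactly 30 days
  survives.
* **Sample intersection**: sorted common IDs, identical row order in both
  matrices.
* **DE gene selection**: the test is unspecified upstream, so the package
  uses the assumption-light Wilcoxon rank-sum with BH adjustment plus a
  $|\log_2 FC| \ge 1$ filter on group means with pseudo-count 1;
  `alpha >= 1` disables the significance filter (for pipelines that select
  genes elsewhere).

All filters are idempotent, never alter retained non-missing values, and
log their drop/imputation counts in a `filter_log` attribute (echoed by the
CLI) so the funnel is auditable.

## Downstream analyses

* `top_associations()` ranks by $|\hat B_{ij}|$, globally (top-n) or per
  gene (top-d sites per gene). Ties are broken by `(site_id, gene_id)`
  lexicographic order so output is bitwise reproducible. No p-values are
  attached — the model provides none for $B$, by design.
* `cluster_samples()` operationalizes "samples sharing the same rank
  structure form a group" as k-means (20 restarts, fixed seed) with
  $k = \mathrm{rank}(\hat L)$ on the rows of $U_k D_k$ — the samples'
  coordinates in the heterogeneity factor space, the standard reading of
  low-rank-representation subtyping. The map from a low-rank matrix to a
  discrete partition is under-determined; k-means on the scaled left
  singular subspace is the package's documented choice. $k$ is floored at 1
  ($\hat L = 0$ gives one cluster).
* `subtype_differential_sites()` tests each site one-vs-rest per cluster
  (two-sided rank-sum) and flags sites significant in **more than**
  `min_clusters = 2` clusters at $p < 10^{-10}$. The extreme threshold is
  used raw — adjusting a $10^{-10}$ cutoff across a few hundred thousand
  tests changes little, and BH-adjusted values are emitted alongside for
  transparency. Clusters with fewer than 2 members (or complements smaller
  than 2) are excluded with a warning.

## Numerical edge cases

* `svt_prox(M, 0)` returns `M` exactly (no SVD reconstruction error is
  introduced at $\lambda = 0$).
* All-zero design columns are pinned at zero in coordinate descent rather
  than producing 0/0.
* `rho` or `lambda` of `Inf` (or merely large enough) collapse the fit to
  its two component methods — independent Lasso regressions and one
  singular value thresholding respectively — and the implementation
  reproduces those limits to $10^{-6}$, which the tests exercise.
* Coordinate-descent non-convergence (hitting `cd_max_iter`) is a warning
  with the best iterate returned, propagated once per fit rather than per
  column.
* ROC construction refuses an all-zero or all-nonzero true support, where
  the curve is undefined.

## Limitations

* No inference on $B$: no p-values or confidence intervals are provided;
  ranking by magnitude is the supported interface, and users should treat
  the top of the list as candidates for orthogonal validation.
* The penalties are not auto-tuned by theory; the two documented selectors
  are conventions.
* Dense SVD per outer iteration bounds practical problem sizes to a few
  thousand genes/sites on one core.
* The subtype count equals the numerical rank of $\hat L$, which inherits
  $\lambda$'s influence; interpret cluster counts jointly with the singular
  spectrum (`plot(fit)`).
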