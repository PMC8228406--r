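# slrr — sparse plus low-rank regression for methylation–expression mapping

DNA methylation at promoter CpG sites regulates gene expression, and aberrant
methylation is a hallmark of heterogeneous tumors such as gastric cancer. But
expression is also driven by *hidden* factors — tumor subtype, batch, DNA
sequence changes, cellular state — and a naive site-by-gene association scan
both misses real links and invents spurious ones. `slrr` is for analysts with
paired methylation (beta values, samples × CpG sites) and expression
(samples × genes) matrices who want methylation–expression associations that
are adjusted for this expression heterogeneity, plus a molecular subtyping of
the samples as a by-product.

## The model

Expression is decomposed as

    Y = X B + L + e

where `Y` (n × q) is expression, `X` (n × p) is methylation, `B` (p × q) is a
**sparse** coefficient matrix (each gene is influenced by few sites), `L`
(n × q) is a **low-rank** matrix absorbing expression heterogeneity (few
hidden factors), and `e` is Gaussian noise. The estimate minimizes the convex
objective

    ½‖Y − XB − L‖²_F + ρ‖B‖₁ + λ‖L‖₊

(`‖·‖₊` the nuclear norm) by alternating two exact block updates:

1. **L-step** — singular value thresholding: `L ← S_λ(Y − XB)`, the SVD of
   the residual with singular values soft-thresholded by λ;
2. **B-step** — q independent Lasso problems, one per gene column, solved by
   warm-started cyclic coordinate descent.

Both updates are exact minimizers, so the objective decreases monotonically.
After the fit, associations are ranked by |B| (the model performs no
significance test on B), and samples are clustered into `rank(L)` groups by
k-means on the scaled left singular subspace of L; subtype-associated CpG
sites are those differentially methylated (one-vs-rest rank-sum, p < 1e-10)
in more than two of the resulting clusters.

## Worked example

```r
library(slrr)

sim <- simulate_meth_expr(n = 200, p = 50, q = 50, k = 2, tau = 1,
                          sigma_e = 0.5, seed = 1)
pen <- default_penalties(sim$Y, sim$X)   # rho = 0.1·max|Xc'Yc|, lambda = 0.25·σ₁(Yc)
fit <- slrr(sim$Y, sim$X, rho = pen$rho, lambda = pen$lambda)
fit
#> Sparse + low-rank regression fit
#>   samples: 200  sites: 50  genes: 50
#>   rho = 9.408035  lambda = 32.50974
#>   nnz(B) = 111 (4.44% of 2500 entries)
#>   rank(L) = 2
#>   6 iterations, converged, final objective 7723.907

support_recovery_roc(coef(fit), sim$B_true)
#> Support-recovery ROC: AUROC = 0.8859 over 113 threshold steps

head(top_associations(fit, top_n = 5))
#>   site_id gene_id coefficient abs_coefficient rank
#> 1 cg00043   g0039    2.345453        2.345453    1
#> 2 cg00006   g0026    2.159590        2.159590    2
#> 3 cg00034   g0039    1.292325        1.292325    3
#> 4 cg00039   g0034    1.185456        1.185456    4
#> 5 cg00021   g0020   -1.170654        1.170654    5

cluster_samples(fit, seed = 1)
#> Sample clustering from the low-rank heterogeneity term
#>   k = 2 clusters over 200 samples
#> cluster
#>   1   2
#>  95 105
```

The generator planted 50 non-zero coefficients (2% of 2500) and two hidden
factors; the fit recovers the planted rank exactly, ranks the true
associations near the top (AUROC 0.89), and splits the samples along the
dominant heterogeneity factor. On real cohorts the same pipeline runs through
the preprocessing filters first: `filter_missing_sites()` (drop sites missing
in >70% of samples, mean-impute the rest), `filter_promoter_sites()`
(−2 kb … +0.5 kb around the TSS), `filter_clinical()` (≥30 days follow-up),
`intersect_samples()`, and `select_de_genes()` (tumor-vs-normal rank-sum +
BH + fold-change filter).

A command-line interface mirrors the R API for shell pipelines:

```sh
slrr simulate --n 200 --p 50 --q 50 --k 2 --seed 1 --out-dir sim/
slrr fit --x sim/X.tsv --y sim/Y.tsv --rho 9.4 --lambda 32.5 --out-dir fit/
slrr associations --b fit/B_triplets.tsv --top-n 1000 --out assoc.tsv
slrr cluster --l fit/L.tsv --seed 1 --out labels.tsv
slrr subtype-sites --meth sim/X.tsv --labels labels.tsv --out sites.tsv
```

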