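# Shared test utilities and tiny independent oracles.

rmat <- function(n, p, seed, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n * p, sd = sd), n, p)
}

named <- function(m, rprefix = "s", cprefix = "f") {
  dimnames(m) <- list(paste0(rprefix, seq_len(nrow(m))),
                      paste0(cprefix, seq_len(ncol(m))))
  m
}

# nuclear-norm proximal objective 1/2||M - C||_F^2 + lambda * ||C||_*,
# evaluated directly by SVD -- the oracle for svt_prox optimality checks
prox_objective <- function(M, C, lambda) {
  0.5 * sum((M - C)^2) + lambda * sum(svd(C, nu = 0, nv = 0)$d)
}

# lasso objective for oracle comparisons
lasso_objective <- function(y, X, b, rho) {
  r <- y - X %*% b
  0.5 * sum(r * r) + rho * sum(abs(b))
}

# univariate lasso by dense grid search (independent of soft-thresholding)
lasso_grid_1d <- function(y, x, rho, lim = 5, step = 1e-4) {
  grid <- seq(-lim, lim, by = step)
  obj <- 0.5 * colSums((y - outer(drop(x), grid))^2) + rho * abs(grid)
  grid[which.min(obj)]
}

# ROC by brute-force threshold enumeration over every distinct score
roc_brute_force <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(c(Inf, th), function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !labels) / sum(!labels),
      tpr = sum(pred & labels) / sum(labels))
  }, c(fpr = 0, tpr = 0)))
  auroc <- sum(diff(pts[, "fpr"]) *
                 (head(pts[, "tpr"], -1) + tail(pts[, "tpr"], -1)) / 2)
  list(fpr = pts[, "fpr"], tpr = pts[, "tpr"], auroc = auroc)
}

# cluster labelings are equivalent iff they induce the same partition
same_partition <- function(a, b) {
  identical(outer(a, a, `==`), outer(b, b, `==`))
}
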