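# Synthetic paired methylation/expression data with planted sparse effects
# and a low-rank hidden-factor term, plus support-recovery evaluation.

#' Simulate paired methylation and expression data
#'
#' Generates a dataset from the model `Y = X B + L + e`:
#' \itemize{
#'   \item `X`: n x p binary methylation states, i.i.d. Bernoulli(`meth_prob`);
#'   \item `B`: p x q coefficients with exactly `round(sparsity * p * q)`
#'     non-zero positions drawn uniformly without replacement, values i.i.d.
#'     standard Gaussian;
#'   \item `L`: hidden-factor (expression heterogeneity) term.  A factor
#'     loading matrix `H` (n x k, i.i.d. N(0,1)) is drawn once; each of the q
#'     columns of `L` is then `sqrt(tau) * H %*% z` with `z ~ N(0, I_k)`,
#'     i.e. a zero-mean Gaussian with covariance `tau * H H'`.  `k = 0`
#'     gives `L = 0`;
#'   \item `e`: i.i.d. Gaussian noise with standard deviation `sigma_e`.
#' }
#' The four components use independent substreams derived from `seed`, so
#' e.g. changing `sigma_e` never perturbs the draw of `X` or `B`.
#'
#' @param n,p,q samples, CpG sites, genes.
#' @param k number of hidden factors (rank of the planted heterogeneity
#'   term); `k = 0` disables it.
#' @param meth_prob per-entry probability of the methylated state (default
#'   0.25).
#' @param sparsity fraction of non-zero entries of `B` (default 0.02);
#'   `round(sparsity * p * q)` must be at least 1.
#' @param tau variance scale of the hidden-factor term.
#' @param sigma_e noise standard deviation.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return object of class `"slrr_sim"`: list with matrices `X`, `B_true`,
#'   `G = X B_true`, `L_true`, `e`, `Y` (satisfying `Y = G + L_true + e`
#'   exactly) and the echoed `config`.
#' @examples
#' sim <- simulate_meth_expr(n = 50, p = 30, q = 20, k = 2, seed = 7)
#' sum(sim$B_true != 0)  # round(0.02 * 30 * 20) = 12
#' @export
simulate_meth_expr <- function(n = 200L, p = 100L, q = 100L, k = 3L,
                               meth_prob = 0.25, sparsity = 0.02,
                               tau = 1, sigma_e = 1, seed = 1L) {
  stopifnot(n >= 1L, p >= 1L, q >= 1L, k >= 0L,
            meth_prob > 0, meth_prob < 1, sparsity > 0, sparsity <= 1,
            tau >= 0, sigma_e >= 0)
  nnz <- round(sparsity * p * q)
  if (nnz < 1L) {
    stop("sparsity * p * q rounds to zero non-zero coefficients; increase ",
         "sparsity or the matrix dimensions", call. = FALSE)
  }
  local_seed(substream_seed(seed, 1L))
  X <- matrix(as.double(stats::runif(n * p) < meth_prob), n, p)
  dimnames(X) <- list(sprintf("s%03d", seq_len(n)),
                      sprintf("cg%05d", seq_len(p)))

  set.seed(substream_seed(seed, 2L))
  B <- matrix(0, p, q)
  pos <- sample.int(p * q, nnz)
  B[pos] <- stats::rnorm(nnz)
  dimnames(B) <- list(colnames(X), sprintf("g%04d", seq_len(q)))

  set.seed(substream_seed(seed, 3L))
  if (k > 0L) {
    H <- matrix(stats::rnorm(n * k), n, k)
    Z <- matrix(stats::rnorm(k * q), k, q)
    L <- sqrt(tau) * (H %*% Z)
  } else {
    H <- matrix(0, n, 0L)
    L <- matrix(0, n, q)
  }

  set.seed(substream_seed(seed, 4L))
  e <- matrix(stats::rnorm(n * q, sd = sigma_e), n, q)

  G <- X %*% B
  Y <- G + L + e
  dimnames(Y) <- dimnames(L) <- dimnames(e) <- dimnames(G) <-
    list(rownames(X), colnames(B))
  structure(
    list(X = X, B_true = B, G = G, L_true = L, e = e, Y = Y, H = H,
         config = list(n = n, p = p, q = q, k = k, meth_prob = meth_prob,
                       sparsity = sparsity, tau = tau, sigma_e = sigma_e,
                       seed = seed)),
    class = "slrr_sim")
}

#' @export
print.slrr_sim <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic methylation/expression dataset\n")
  cat(sprintf("  n = %d samples, p = %d sites, q = %d genes\n",
              cfg$n, cfg$p, cfg$q))
  cat(sprintf("  nnz(B_true) = %d (%.1f%%), k = %d hidden factors, tau = %g, sigma_e = %g\n",
              sum(x$B_true != 0), 100 * mean(x$B_true != 0), cfg$k, cfg$tau,
              cfg$sigma_e))
  invisible(x)
}

#' ROC for coefficient support recovery
#'
#' Scores every entry of the estimated coefficient matrix by its absolute
#' value and sweeps a threshold against the true support (`B_true != 0`).
#' Equal scores are treated as a single threshold step, so constant scores
#' give the chance diagonal (AUROC 0.5).
#'
#' @param B_hat estimated p x q coefficient matrix.
#' @param B_true true coefficient matrix of the same dimension.
#' @return object of class `"recovery_roc"`: list with non-decreasing `fpr`
#'   and `tpr` paths from (0,0) to (1,1), the descending `thresholds`
#'   (starting at `Inf`), and the trapezoidal `auroc`.
#' @export
support_recovery_roc <- function(B_hat, B_true) {
  if (!all(dim(B_hat) == dim(B_true))) {
    stop("B_hat and B_true must have identical dimensions", call. = FALSE)
  }
  labels <- as.vector(B_true != 0)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: true support is ",
         if (n_pos == 0L) "empty" else "the full matrix", call. = FALSE)
  }
  scores <- abs(as.vector(B_hat))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; lab <- labels[ord]
  # collapse tied scores into single threshold steps
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(lab)[last]
  fp <- cumsum(!lab)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auroc = auroc,
                 thresholds = c(Inf, s[last])),
            class = "recovery_roc")
}

#' @export
print.recovery_roc <- function(x, ...) {
  cat(sprintf("Support-recovery ROC: AUROC = %.4f over %d threshold steps\n",
              x$auroc, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.recovery_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("Support recovery (AUROC %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}

#' Support-recovery study over a grid of simulation settings
#'
#' For each setting and replicate this generates a dataset (replicate `r`
#' uses seed `setting$seed + r - 1`), fits the sparse plus low-rank model,
#' and records the support-recovery AUROC.  Non-convergence is recorded per
#' row, never fatal.
#'
#' @param settings a list of setting lists; each may contain any arguments
#'   of [simulate_meth_expr()] (missing entries take that function's
#'   defaults).
#' @param rho,lambda penalties used for every fit.
#' @param replicates replicate datasets per setting.
#' @param ... further arguments passed to [slrr()].
#' @return data frame with one row per (setting, replicate): the setting
#'   parameters, `replicate`, `seed`, `converged` and `auroc`.
#' @export
simulation_grid <- function(settings, rho, lambda, replicates = 1L, ...) {
  stopifnot(is.list(settings), length(settings) >= 1L, replicates >= 1L)
  rows <- vector("list", length(settings) * replicates)
  i <- 0L
  for (s in seq_along(settings)) {
    base <- settings[[s]]
    for (r in seq_len(replicates)) {
      args <- utils::modifyList(
        as.list(formals(simulate_meth_expr))[
          c("n", "p", "q", "k", "meth_prob", "sparsity", "tau", "sigma_e",
            "seed")],
        base)
      args <- lapply(args, eval)
      args$seed <- args$seed + r - 1L
      sim <- do.call(simulate_meth_expr, args)
      fit <- slrr(sim$Y, sim$X, rho = rho, lambda = lambda, ...)
      roc <- support_recovery_roc(fit$B, sim$B_true)
      i <- i + 1L
      rows[[i]] <- data.frame(setting = s, n = args$n, p = args$p,
                              q = args$q, k = args$k, tau = args$tau,
                              sigma_e = args$sigma_e,
                              sparsity = args$sparsity,
                              replicate = r, seed = args$seed,
                              converged = fit$converged, auroc = roc$auroc)
    }
  }
  do.call(rbind, rows)
}
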