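# Core operations of the sparse + low-rank decomposition:
#   objective   f(B, L) = 1/2 ||Y - XB - L||_F^2 + rho ||B||_1 + lambda ||L||_*
#   svt_prox    prox of the nuclear norm (SVD + soft-thresholded spectrum)
#   lasso_cd    cyclic coordinate descent on a single Lasso column problem

#' Penalized objective of the sparse plus low-rank model
#'
#' Evaluates
#' \deqn{\tfrac12 \|Y - XB - L\|_F^2 + \rho \|B\|_1 + \lambda \|L\|_*}
#' where \eqn{\|B\|_1} is the element-wise L1 norm and \eqn{\|L\|_*} the
#' nuclear norm (sum of singular values).
#'
#' @param Y n x q expression matrix.
#' @param X n x p methylation matrix.
#' @param B p x q coefficient matrix.
#' @param L n x q low-rank component: a `"low_rank"` object or a plain matrix.
#' @param rho L1 penalty weight (>= 0).
#' @param lambda nuclear-norm penalty weight (>= 0).
#' @return scalar objective value, always >= 0 for valid penalties.
#' @export
slrr_objective <- function(Y, X, B, L, rho, lambda) {
  Lm <- if (inherits(L, "low_rank")) L$values else L
  if (anyNA(Y) || anyNA(X) || anyNA(B) || anyNA(Lm)) {
    stop("missing values in objective inputs; preprocess the data first ",
         "(filter_missing_sites)", call. = FALSE)
  }
  if (nrow(Y) != nrow(X)) {
    stop("sample dimension mismatch: Y has ", nrow(Y), " rows, X has ",
         nrow(X), call. = FALSE)
  }
  if (ncol(X) != nrow(B)) {
    stop("site dimension mismatch: X has ", ncol(X), " columns, B has ",
         nrow(B), " rows", call. = FALSE)
  }
  if (ncol(Y) != ncol(B) || ncol(Y) != ncol(Lm) || nrow(Y) != nrow(Lm)) {
    stop("gene dimension mismatch among Y (", nrow(Y), "x", ncol(Y),
         "), B (", nrow(B), "x", ncol(B), "), L (", nrow(Lm), "x", ncol(Lm),
         ")", call. = FALSE)
  }
  stopifnot(rho >= 0, lambda >= 0)
  R <- Y - X %*% B - Lm
  d <- if (inherits(L, "low_rank")) L$singular_values
       else if (lambda > 0) svd(Lm, nu = 0, nv = 0)$d else 0
  0.5 * sum(R * R) + rho * sum(abs(B)) + lambda * sum(d)
}

#' Singular value thresholding (nuclear-norm proximal operator)
#'
#' Computes \eqn{S_\lambda(M) = U \, \mathrm{diag}((d_i - \lambda)_+) \, V^T},
#' the unique minimizer of \eqn{\tfrac12\|M - L\|_F^2 + \lambda \|L\|_*}.
#' This is the exact L-update of the alternating solver: with B fixed,
#' `L = svt_prox(Y - X B, lambda)`.
#'
#' @param M numeric matrix with finite entries.
#' @param lambda shrinkage level (>= 0); singular values at or below `lambda`
#'   are set to zero.
#' @param rank_tol relative cutoff used to drop numerically zero shrunk
#'   singular values and to compute the stored numerical rank.
#' @return a `"low_rank"` object (see [low_rank()]).
#' @examples
#' svt_prox(diag(c(3, 1)), 2)$values  # diag(1, 0)
#' @export
svt_prox <- function(M, lambda, rank_tol = 1e-8) {
  if (!is.matrix(M) || !is.numeric(M) || !all(is.finite(M))) {
    stop("M must be a finite numeric matrix", call. = FALSE)
  }
  stopifnot(length(lambda) == 1L, lambda >= 0)
  if (lambda == 0) {
    return(low_rank(M, rank_tol = rank_tol))
  }
  s <- svd(M)
  d <- pmax(s$d - lambda, 0)
  keep <- d > rank_tol * max(max(d), 1)
  r <- sum(keep)
  vals <- if (r == 0L) {
    matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  } else {
    out <- s$u[, seq_len(r), drop = FALSE] %*%
      (d[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
    dimnames(out) <- dimnames(M)
    out
  }
  structure(list(values = vals,
                 singular_values = d[keep],
                 numerical_rank = r),
            class = "low_rank")
}

#' Lasso for one response column by cyclic coordinate descent
#'
#' Minimizes \eqn{\tfrac12\|y - Xb\|_2^2 + \rho\|b\|_1} with soft-threshold
#' coordinate updates, starting from `b_init` (warm start).  One such problem
#' is solved per gene in the B-update of [slrr()]; the column problems are
#' independent given L.
#'
#' @param y numeric response vector, length n.
#' @param X numeric n x p design matrix.
#' @param rho L1 penalty weight (>= 0).  At
#'   `rho >= max |x_j' y|` the solution is exactly zero.
#' @param b_init warm-start coefficients (default zero).
#' @param cd_tol stop when the largest absolute coordinate change in a full
#'   sweep falls below this.
#' @param cd_max_iter maximum number of full sweeps; hitting it raises a
#'   warning and returns the best iterate.
#' @return numeric coefficient vector, length p.
#' @export
lasso_column <- function(y, X, rho, b_init = NULL, cd_tol = 1e-7,
                         cd_max_iter = 1000L) {
  stopifnot(is.numeric(y), is.matrix(X), nrow(X) == length(y), rho >= 0)
  fit <- lasso_cd_gram(crossprod(X), drop(crossprod(X, y)),
                       b_init %||% numeric(ncol(X)), rho, cd_tol, cd_max_iter)
  if (!fit$converged) {
    warning("coordinate descent reached cd_max_iter = ", cd_max_iter,
            " sweeps without meeting cd_tol; returning best iterate",
            call. = FALSE)
  }
  fit$b
}

# Gram-form coordinate descent: XtX (p x p), Xty (length p).  Columns with
# zero norm are pinned at zero.  Shared by lasso_column() and the fit loop,
# where XtX is computed once per fit, not once per column.  The running
# vector s = XtX %*% b is updated incrementally, so coordinates whose value
# does not move cost O(1); between full sweeps, inner sweeps cycle over the
# active (non-zero) set only.  Convergence is declared only when a FULL
# sweep moves no coordinate by cd_tol or more.
lasso_cd_gram <- function(XtX, Xty, b, rho, cd_tol, cd_max_iter) {
  p <- length(Xty)
  if (p == 0L) return(list(b = b, sweeps = 0L, converged = TRUE))
  g <- diag(XtX)
  usable <- which(g > 0)
  b[g <= 0] <- 0
  s <- as.vector(XtX %*% b)
  sweeps <- 0L
  converged <- FALSE
  sweep_once <- function(idx) {
    delta <- 0
    for (j in idx) {
      z <- Xty[j] - s[j] + g[j] * b[j]
      bj <- soft_threshold(z, rho) / g[j]
      d <- bj - b[j]
      if (d != 0) {
        b[j] <<- bj
        s <<- s + XtX[, j] * d
        ad <- abs(d)
        if (ad > delta) delta <- ad
      }
    }
    delta
  }
  while (sweeps < cd_max_iter) {
    delta <- sweep_once(usable)
    sweeps <- sweeps + 1L
    if (delta < cd_tol) { converged <- TRUE; break }
    while (sweeps < cd_max_iter) {
      act <- usable[b[usable] != 0]
      if (length(act) == 0L) break
      delta <- sweep_once(act)
      sweeps <- sweeps + 1L
      if (delta < cd_tol) break
    }
  }
  list(b = b, sweeps = sweeps, converged = converged)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a
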