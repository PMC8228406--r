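#' Fit the sparse plus low-rank regression model
#'
#' Decomposes gene expression `Y` (n samples x q genes) into a methylation
#' effect `X B`, a low-rank expression-heterogeneity term `L`, and noise, by
#' minimizing the convex objective
#' \deqn{\tfrac12 \|Y - XB - L\|_F^2 + \rho \|B\|_1 + \lambda \|L\|_*.}
#'
#' Starting from `B = 0`, `L = 0`, each outer iteration performs the two
#' exact block updates
#' \enumerate{
#'   \item `L <- svt_prox(Y - X B, lambda)` (singular value thresholding);
#'   \item for each gene `j`, `B[, j] <- ` Lasso of `Y[, j] - L[, j]` on `X`
#'     with penalty `rho`, warm-started at the previous `B[, j]`.
#' }
#' Exact block minimization makes the objective trace non-increasing; an
#' increase beyond floating-point slack signals a bug and raises an error.
#' Iteration stops when the relative objective change drops below `tol` or
#' after `max_iter` outer iterations.
#'
#' By default `Y` and `X` are column mean-centered before fitting (the model
#' carries no explicit intercept; centering absorbs it) and the offsets are
#' stored so [predict.slrr()] can map back to the original scale.
#'
#' @param Y numeric n x q expression matrix (samples x genes).
#' @param X numeric n x p methylation matrix (samples x CpG sites), complete
#'   (no missing values; see [filter_missing_sites()]).
#' @param rho L1 penalty on `B`; larger values give a sparser coefficient
#'   matrix.  `rho >= max|X'Y|` (after centering) forces `B = 0`.
#' @param lambda nuclear-norm penalty on `L`; larger values give lower rank.
#'   `lambda >=` the largest singular value of the current residual forces
#'   `L = 0`.
#' @param max_iter maximum outer iterations.
#' @param tol relative objective-change convergence threshold.
#' @param cd_tol,cd_max_iter coordinate-descent controls passed to the inner
#'   Lasso solver (see [lasso_column()]).
#' @param rank_tol relative singular-value cutoff for the reported rank of L.
#' @param center column-center `Y` and `X` before fitting (default `TRUE`).
#' @param seed reserved for randomized sub-steps; the default solver is
#'   deterministic and ignores it (stored for reproducibility records).
#' @return an object of class `"slrr"`, a list with components:
#' \describe{
#'   \item{B}{p x q sparse coefficient matrix (sites x genes).}
#'   \item{L}{`"low_rank"` object: fitted expression-heterogeneity term, its
#'     singular values and numerical rank.}
#'   \item{objective}{objective value after each outer iteration
#'     (non-increasing).}
#'   \item{n_iter, converged}{iteration count and convergence flag.}
#'   \item{nnz}{number of non-zero entries of B.}
#'   \item{column_means_Y, column_means_X}{centering offsets (zero-length
#'     when `center = FALSE`).}
#'   \item{fitted.values, residuals}{`X B + L` (plus offsets) and
#'     `Y - fitted` on the original scale.}
#'   \item{config}{echo of all tuning parameters.}
#' }
#' @seealso [svt_prox()], [lasso_column()], [select_penalties()],
#'   [top_associations()], [cluster_samples()]
#' @examples
#' sim <- simulate_meth_expr(n = 60, p = 20, q = 10, k = 2, seed = 1)
#' fit <- slrr(sim$Y, sim$X, rho = 2, lambda = 5)
#' fit
#' @export
slrr <- function(Y, X, rho, lambda, max_iter = 100L, tol = 1e-6,
                 cd_tol = 1e-7, cd_max_iter = 1000L, rank_tol = 1e-8,
                 center = TRUE, seed = NULL) {
  stopifnot(is.matrix(Y), is.matrix(X), rho >= 0, lambda >= 0, tol > 0,
            max_iter >= 1L)
  if (anyNA(Y) || anyNA(X)) {
    stop("Y/X contain missing values; preprocess first (filter_missing_sites)",
         call. = FALSE)
  }
  check_aligned(Y, X)
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)

  my <- mx <- numeric(0)
  Yw <- Y; Xw <- X
  if (center) {
    my <- colMeans(Y); mx <- colMeans(X)
    Yw <- sweep(Y, 2L, my)
    Xw <- sweep(X, 2L, mx)
  }

  XtX <- crossprod(Xw)
  B <- matrix(0, p, q, dimnames = list(colnames(X), colnames(Y)))
  L <- matrix(0, n, q, dimnames = dimnames(Y))
  sv <- numeric(0)
  obj <- numeric(0)
  f_prev <- Inf
  converged <- FALSE
  n_iter <- 0L
  cd_fail <- 0L

  for (it in seq_len(max_iter)) {
    XB <- Xw %*% B
    Lr <- svt_prox(Yw - XB, lambda, rank_tol = rank_tol)
    L <- Lr$values
    sv <- Lr$singular_values

    Ytil <- Yw - L
    XtY <- crossprod(Xw, Ytil)
    for (j in seq_len(q)) {
      cd <- lasso_cd_gram(XtX, XtY[, j], B[, j], rho, cd_tol, cd_max_iter)
      B[, j] <- cd$b
      if (!cd$converged) cd_fail <- cd_fail + 1L
    }

    R <- Ytil - Xw %*% B
    f <- 0.5 * sum(R * R) + rho * sum(abs(B)) + lambda * sum(sv)
    if (f > f_prev + 1e-8 * max(1, abs(f_prev))) {
      stop("objective increased at iteration ", it, " (", f_prev, " -> ", f,
           "); this indicates an implementation bug in the block updates",
           call. = FALSE)
    }
    obj <- c(obj, f)
    n_iter <- it
    if (is.finite(f_prev) &&
        abs(f_prev - f) < tol * max(abs(f_prev), 1e-10)) {
      converged <- TRUE
      break
    }
    f_prev <- f
  }
  if (cd_fail > 0L) {
    warning(cd_fail, " Lasso column problem(s) hit cd_max_iter without ",
            "meeting cd_tol", call. = FALSE)
  }

  fitted <- Xw %*% B + L
  if (center) fitted <- sweep(fitted, 2L, my, "+")
  structure(
    list(B = B,
         L = structure(list(values = L, singular_values = sv,
                            numerical_rank = rank_count(sv, rank_tol)),
                       class = "low_rank"),
         objective = obj,
         n_iter = n_iter,
         converged = converged,
         nnz = sum(B != 0),
         column_means_Y = my,
         column_means_X = mx,
         fitted.values = fitted,
         residuals = Y - fitted,
         dims = c(n = n, p = p, q = q),
         config = list(rho = rho, lambda = lambda, max_iter = max_iter,
                       tol = tol, cd_tol = cd_tol,
                       cd_max_iter = cd_max_iter, rank_tol = rank_tol,
                       center = center, seed = seed),
         call = match.call()),
    class = "slrr")
}

#' @export
print.slrr <- function(x, ...) {
  d <- x$dims
  cat("Sparse + low-rank regression fit\n")
  cat("  samples:", d["n"], " sites:", d["p"], " genes:", d["q"], "\n")
  cat("  rho =", x$config$rho, " lambda =", x$config$lambda, "\n")
  cat("  nnz(B) =", x$nnz, sprintf("(%.2f%% of %d entries)",
      100 * x$nnz / (d["p"] * d["q"]), d["p"] * d["q"]), "\n")
  cat("  rank(L) =", x$L$numerical_rank, "\n")
  cat("  ", x$n_iter, " iterations, ",
      if (x$converged) "converged" else "NOT converged",
      ", final objective ", format(utils::tail(x$objective, 1L)), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.slrr <- function(object, ...) {
  r <- object$residuals
  out <- list(dims = object$dims,
              config = object$config,
              nnz = object$nnz,
              rank = object$L$numerical_rank,
              singular_values = object$L$singular_values,
              objective = utils::tail(object$objective, 1L),
              n_iter = object$n_iter,
              converged = object$converged,
              rss = sum(r * r),
              sigma = sqrt(sum(r * r) /
                             max(1, length(r) - object$nnz -
                                   object$L$numerical_rank)))
  class(out) <- "summary.slrr"
  out
}

#' @export
print.summary.slrr <- function(x, ...) {
  cat("Sparse + low-rank regression (", x$dims["n"], " samples, ",
      x$dims["p"], " sites, ", x$dims["q"], " genes)\n", sep = "")
  cat("Penalties: rho =", x$config$rho, ", lambda =", x$config$lambda, "\n")
  cat("Coefficient matrix B:", x$nnz, "non-zero of",
      x$dims["p"] * x$dims["q"], "entries\n")
  cat("Heterogeneity term L: rank", x$rank, "; singular values",
      paste(signif(utils::head(x$singular_values, 7L), 4), collapse = ", "),
      "\n")
  cat("Residual sum of squares:", format(x$rss),
      " (sigma-hat ", format(signif(x$sigma, 4)), ")\n", sep = "")
  cat(x$n_iter, "outer iterations;",
      if (x$converged) "converged" else "not converged",
      "; final objective", format(x$objective), "\n")
  invisible(x)
}

#' Extract the sparse coefficient matrix
#'
#' @param object fitted `"slrr"` model.
#' @param ... unused.
#' @return p x q numeric matrix of methylation-to-expression coefficients.
#' @export
coef.slrr <- function(object, ...) object$B

#' @export
fitted.slrr <- function(object, ...) object$fitted.values

#' @export
residuals.slrr <- function(object, ...) object$residuals

#' Predict expression from methylation
#'
#' For new samples only the methylation effect `X B` is transferable; the
#' low-rank term `L` is sample-specific and enters predictions only for the
#' training samples (`newX` omitted, equivalent to [fitted.slrr()]).
#'
#' @param object fitted `"slrr"` model.
#' @param newX optional matrix of methylation values for new samples, with
#'   the same p sites (columns) used at fit time.
#' @param ... unused.
#' @return matrix of predicted expression values.
#' @export
predict.slrr <- function(object, newX = NULL, ...) {
  if (is.null(newX)) return(object$fitted.values)
  stopifnot(is.matrix(newX), ncol(newX) == object$dims[["p"]])
  Xw <- if (length(object$column_means_X)) {
    sweep(newX, 2L, object$column_means_X)
  } else newX
  out <- Xw %*% object$B
  if (length(object$column_means_Y)) {
    out <- sweep(out, 2L, object$column_means_Y, "+")
  }
  out
}

#' Diagnostic plots for a fitted model
#'
#' Draws the objective trace across outer iterations and the singular value
#' spectrum of the fitted heterogeneity term L (the elbow of which shows the
#' effective number of hidden factors).
#'
#' @param x fitted `"slrr"` model.
#' @param which subset of `1:2` selecting the panels.
#' @param ... forwarded to [plot()].
#' @return `x`, invisibly.
#' @export
plot.slrr <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1L %in% which) {
    plot(seq_along(x$objective), x$objective, type = "b", pch = 20,
         xlab = "outer iteration", ylab = "penalized objective",
         main = "Convergence", ...)
  }
  if (2L %in% which && length(x$L$singular_values)) {
    plot(seq_along(x$L$singular_values), x$L$singular_values, type = "h",
         lwd = 3, xlab = "component", ylab = "singular value of L",
         main = sprintf("Heterogeneity spectrum (rank %d)",
                        x$L$numerical_rank), ...)
  }
  invisible(x)
}

#' Scale-anchored default penalties
#'
#' Fast data-driven rule used throughout the package's simulation studies:
#' `rho = f_rho * max|Xc' Yc|` (a fixed fraction of the smallest penalty
#' that zeroes B entirely) and `lambda = f_lambda * sigma_1(Yc)` (a fraction
#' of the largest singular value of the centered expression matrix, the
#' smallest value that zeroes L at the first iteration).  Both anchors scale
#' with n, so the rule transfers across problem sizes.  For a slower
#' model-complexity-based choice see [select_penalties()].
#'
#' @param Y,X expression and methylation matrices as in [slrr()].
#' @param f_rho,f_lambda fractions of the two anchors (defaults 0.1 and
#'   0.25).
#' @return list with components `rho` and `lambda`.
#' @export
default_penalties <- function(Y, X, f_rho = 0.1, f_lambda = 0.25) {
  Yc <- sweep(Y, 2L, colMeans(Y))
  Xc <- sweep(X, 2L, colMeans(X))
  list(rho = f_rho * max(abs(crossprod(Xc, Yc))),
       lambda = f_lambda * svd(Yc, nu = 0, nv = 0)$d[1L])
}

#' Penalty selection by a BIC-type score over a default grid
#'
#' Convenience helper for choosing `(rho, lambda)` when no external guidance
#' exists.  Candidate grids are geometric ladders anchored at the data scale:
#' `rho` descends from `rho_max = max|X'Y|` (the smallest value at which
#' `B = 0`) and `lambda` from half the largest singular value of `Y`, both
#' after centering.  Each pair is scored by
#' `n*q*log(RSS/(n*q)) + log(n*q) * (nnz(B) + rank(L)*(n+q))`,
#' a BIC-style complexity trade-off counting one parameter per active
#' coefficient and `n + q` per heterogeneity factor.  This selector is
#' pragmatic tooling, not part of the estimation theory; for simulation
#' studies fixed penalties are usually preferable.
#'
#' @param Y,X expression and methylation matrices as in [slrr()].
#' @param n_rho,n_lambda ladder lengths (successive halvings).
#' @param ... further arguments passed to [slrr()] (e.g. `max_iter`).
#' @return list with `rho`, `lambda`, the scored `grid` (a data frame), and
#'   the refitted best model `fit`.
#' @export
select_penalties <- function(Y, X, n_rho = 5L, n_lambda = 4L, ...) {
  Yc <- sweep(Y, 2L, colMeans(Y))
  Xc <- sweep(X, 2L, colMeans(X))
  rho_max <- max(abs(crossprod(Xc, Yc)))
  sig1 <- svd(Yc, nu = 0, nv = 0)$d[1L]
  rhos <- rho_max * 0.5^(seq_len(n_rho) - 1L)
  lambdas <- sig1 * 0.5^seq_len(n_lambda)
  nq <- length(Y)
  grid <- expand.grid(rho = rhos, lambda = lambdas)
  grid$score <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    f <- slrr(Y, X, rho = grid$rho[i], lambda = grid$lambda[i], ...)
    rss <- sum(f$residuals^2)
    grid$score[i] <- nq * log(max(rss, 1e-12) / nq) +
      log(nq) * (f$nnz + f$L$numerical_rank * (nrow(Y) + ncol(Y)))
    if (is.null(best) || grid$score[i] < best$score) {
      best <- list(score = grid$score[i], fit = f,
                   rho = grid$rho[i], lambda = grid$lambda[i])
    }
  }
  list(rho = best$rho, lambda = best$lambda, grid = grid, fit = best$fit)
}
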