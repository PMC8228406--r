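# Alternating solver: degenerate regimes, monotone convergence, limit
# equivalences, and recovery on a noiseless instance.

test_that("dominating penalties collapse the fit to the trivial solution", {
  Y <- named(rmat(10, 4, seed = 21), "s", "g")
  X <- named(matrix(0, 10, 3), "s", "cg")
  lam <- svd(Y)$d[1] + 1
  fit <- slrr(Y, X, rho = 1, lambda = lam, center = FALSE)
  expect_identical(unname(fit$B), matrix(0, 3, 4))
  expect_identical(unname(fit$L$values), matrix(0, 10, 4))
  expect_equal(fit$objective[1], 0.5 * sum(Y^2))
  expect_lte(fit$n_iter, 2L)
  expect_true(fit$converged)
})

test_that("noiseless sparse signal is recovered with small residual", {
  set.seed(22)
  n <- 100; p <- 50; q <- 20
  X <- named(matrix(as.double(runif(n * p) < 0.25), n, p), "s", "cg")
  B_star <- matrix(0, p, q)
  B_star[sample(p * q, 40)] <- rnorm(40, sd = 2)
  Y <- named(X %*% B_star, "s", "g")
  lam <- svd(Y)$d[1] * 2   # keeps L pinned at zero
  fit <- slrr(Y, X, rho = 0.01, lambda = lam, center = FALSE)
  expect_identical(fit$L$numerical_rank, 0L)
  expect_lt(norm(Y - X %*% fit$B, "F") / norm(Y, "F"), 0.05)
  # trace values agree with the standalone objective evaluator
  final <- slrr_objective(Y, X, fit$B, fit$L, 0.01, lam)
  expect_equal(unname(tail(fit$objective, 1)), final, tolerance = 1e-10)
})

test_that("objective trace is non-increasing across seeds and penalties", {
  for (seed in 1:4) {
    sim <- simulate_meth_expr(n = 60, p = 30, q = 20, k = 2, seed = seed)
    pen <- default_penalties(sim$Y, sim$X)
    fit <- slrr(sim$Y, sim$X, rho = pen$rho, lambda = pen$lambda)
    expect_true(all(diff(fit$objective) <= 1e-8 * pmax(1,
      abs(head(fit$objective, -1)))))
    if (fit$converged) {
      tr <- tail(fit$objective, 2)
      expect_lt(abs(diff(tr)) / max(abs(tr[1]), 1e-10), fit$config$tol)
    }
  }
})

test_that("lambda -> Inf reduces the fit to independent Lasso regressions", {
  sim <- simulate_meth_expr(n = 40, p = 15, q = 8, k = 2, seed = 31)
  rho <- 1.5
  fit <- slrr(sim$Y, sim$X, rho = rho, lambda = 1e9, center = FALSE)
  expect_identical(unname(fit$L$values), matrix(0, 40, 8))
  B_ref <- vapply(seq_len(8), function(j) {
    lasso_column(sim$Y[, j], sim$X, rho, cd_tol = 1e-10)
  }, numeric(15))
  expect_lt(max(abs(fit$B - B_ref)), 1e-6)
})

test_that("rho -> Inf reduces the fit to one singular value thresholding", {
  sim <- simulate_meth_expr(n = 40, p = 15, q = 8, k = 2, seed = 32)
  lam <- 3
  fit <- slrr(sim$Y, sim$X, rho = 1e9, lambda = lam, center = FALSE)
  expect_identical(unname(fit$B), matrix(0, 15, 8))
  L_ref <- svt_prox(sim$Y, lam)
  expect_lt(max(abs(fit$L$values - L_ref$values)), 1e-6)
  expect_identical(fit$L$numerical_rank, L_ref$numerical_rank)
})

test_that("unpenalized single iteration reproduces the L-step residual", {
  sim <- simulate_meth_expr(n = 20, p = 6, q = 5, k = 1, seed = 33)
  fit <- slrr(sim$Y, sim$X, rho = 0, lambda = 0, max_iter = 1L,
              center = FALSE)
  # with rho = lambda = 0 the first L-step absorbs Y - X B exactly (B = 0)
  expect_equal(fit$L$values, unname(sim$Y) * 1, ignore_attr = TRUE)
})

test_that("column problems are independent of response ordering", {
  sim <- simulate_meth_expr(n = 50, p = 20, q = 10, k = 2, seed = 34)
  pen <- default_penalties(sim$Y, sim$X)
  fit1 <- slrr(sim$Y, sim$X, rho = pen$rho, lambda = pen$lambda)
  perm <- c(7, 3, 10, 1, 5, 2, 9, 4, 8, 6)
  fit2 <- slrr(sim$Y[, perm], sim$X, rho = pen$rho, lambda = pen$lambda)
  # permuting responses permutes the solution (up to SVD round-off)
  expect_equal(fit2$B, fit1$B[, perm], tolerance = 1e-6)
  expect_equal(fit2$L$values, fit1$L$values[, perm], tolerance = 1e-6)
  # given L, the column problems are separable: re-solving any column on its
  # own reproduces the fitted coefficients regardless of processing order
  Yc <- sweep(sim$Y, 2, colMeans(sim$Y))
  Xc <- sweep(sim$X, 2, colMeans(sim$X))
  for (j in sample(ncol(Yc))) {
    expect_equal(
      unname(lasso_column(Yc[, j] - fit1$L$values[, j], Xc, pen$rho,
                          b_init = fit1$B[, j])),
      unname(fit1$B[, j]), tolerance = 1e-6)
  }
})

test_that("centering stores offsets and predict maps back to data scale", {
  sim <- simulate_meth_expr(n = 50, p = 20, q = 10, k = 2, seed = 35)
  fit <- slrr(sim$Y, sim$X, rho = 2, lambda = 10)
  expect_equal(fit$column_means_Y, colMeans(sim$Y))
  expect_equal(fit$column_means_X, colMeans(sim$X))
  expect_equal(fitted(fit) + residuals(fit), sim$Y)
  expect_identical(predict(fit), fitted(fit))
  pr <- predict(fit, newX = sim$X)
  expect_equal(pr, sweep(sweep(sim$X, 2, colMeans(sim$X)) %*% fit$B, 2,
                         colMeans(sim$Y), "+"))
  off <- slrr(sim$Y, sim$X, rho = 2, lambda = 10, center = FALSE)
  expect_length(off$column_means_Y, 0)
})

test_that("misaligned or incomplete inputs are rejected", {
  sim <- simulate_meth_expr(n = 20, p = 5, q = 4, k = 1, sparsity = 0.1,
                            seed = 36)
  expect_error(slrr(sim$Y[1:10, ], sim$X, rho = 1, lambda = 1),
               "dimension mismatch")
  Yna <- sim$Y; Yna[2, 2] <- NA
  expect_error(slrr(Yna, sim$X, rho = 1, lambda = 1), "missing values")
  Xs <- sim$X; rownames(Xs) <- rev(rownames(Xs))
  expect_error(slrr(sim$Y, Xs, rho = 1, lambda = 1), "not aligned")
})

test_that("print, summary and coef expose the fit", {
  sim <- simulate_meth_expr(n = 30, p = 10, q = 6, k = 1, seed = 37)
  fit <- slrr(sim$Y, sim$X, rho = 1, lambda = 5)
  expect_identical(coef(fit), fit$B)
  expect_output(print(fit), "Sparse \\+ low-rank regression")
  s <- summary(fit)
  expect_s3_class(s, "summary.slrr")
  expect_output(print(s), "rank")
  expect_equal(s$rss, sum(residuals(fit)^2))
})

test_that("penalty helpers anchor to the data scale", {
  sim <- simulate_meth_expr(n = 40, p = 12, q = 8, k = 1, seed = 38)
  pen <- default_penalties(sim$Y, sim$X, f_rho = 1, f_lambda = 1)
  # f_rho = 1 is the smallest penalty that zeroes B in one Lasso pass
  fit <- slrr(sim$Y, sim$X, rho = pen$rho + 1e-8, lambda = 1e9)
  expect_identical(fit$nnz, 0L)
  sel <- select_penalties(sim$Y, sim$X, n_rho = 2, n_lambda = 2,
                          max_iter = 20)
  expect_true(all(c("rho", "lambda", "grid", "fit") %in% names(sel)))
  expect_identical(nrow(sel$grid), 4L)
  expect_s3_class(sel$fit, "slrr")
})
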