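# Association ranking, low-rank subtyping, subtype-associated sites.

test_that("top associations are ranked by magnitude with stable ties", {
  B <- matrix(c(0.5, -0.9, 0.2, 0, 0.1, 0.2), 3, 2,
              dimnames = list(paste0("site", 1:3), paste0("gene", 1:2)))
  tab <- top_associations(B, top_n = 2)
  expect_identical(tab$site_id, c("site2", "site1"))
  expect_identical(tab$gene_id, c("gene1", "gene1"))
  expect_equal(tab$coefficient, c(-0.9, 0.5))
  expect_identical(tab$rank, 1:2)
  # tie at |0.2| broken lexicographically by (site_id, gene_id)
  full <- top_associations(B, top_n = 5)
  expect_identical(full$site_id[3:4], c("site3", "site3"))
  expect_identical(full$gene_id[3:4], c("gene1", "gene2"))
  # top_n = nnz returns every non-zero association
  expect_identical(nrow(top_associations(B, top_n = 5)), 5L)
  expect_warning(all_of_them <- top_associations(B, top_n = 99),
                 "exceeds")
  expect_identical(nrow(all_of_them), 5L)
})

test_that("per-gene mode returns the top d sites per gene column", {
  B <- matrix(c(3, 2, 1, 0, 0.5, 0, 0, 0, 0), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("g", 1:3)))
  tab <- top_associations(B, per_gene_d = 2)
  expect_identical(nrow(tab), 3L)  # two sites for g1, one for g2, none g3
  expect_identical(tab$site_id, c("s1", "s2", "s2"))
  expect_identical(tab$gene_id, c("g1", "g1", "g2"))
  one <- top_associations(matrix(c(0, 4), 2, 1,
                                 dimnames = list(c("a", "b"), "g")),
                          per_gene_d = 3)
  expect_identical(nrow(one), 1L)
  expect_error(top_associations(B), "exactly one")
  expect_error(top_associations(B, top_n = 1, per_gene_d = 1), "exactly one")
})

test_that("association ranking is deterministic across repeated calls", {
  set.seed(13)
  B <- matrix(sample(c(0, 0.4, -0.4, 1), 60, replace = TRUE), 10, 6,
              dimnames = list(sprintf("cg%02d", 1:10), sprintf("g%d", 1:6)))
  t1 <- top_associations(B, top_n = 12)
  t2 <- top_associations(B, top_n = 12)
  expect_identical(t1, t2)
  expect_true(all(diff(t1$abs_coefficient) <= 0))
})

test_that("a zero heterogeneity term yields a single cluster", {
  cl <- cluster_samples(matrix(0, 8, 5), seed = 3)
  expect_identical(cl$k, 1L)
  expect_identical(unname(cl$labels), rep(1L, 8))
})

test_that("rank-2 block structure is recovered exactly", {
  # rows 1-10 follow u1 v1', rows 11-20 follow u2 v2' with orthogonal
  # factors: the embedding collapses to two points, k-means must split them
  v1 <- c(rep(1, 5), rep(0, 5)); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(rep(0, 5), rep(1, 5)); v2 <- v2 / sqrt(sum(v2^2))
  L <- rbind(matrix(rep(3 * v1, each = 10), 10, 10),
             matrix(rep(2 * v2, each = 10), 10, 10))
  rownames(L) <- sprintf("s%02d", 1:20)
  cl <- cluster_samples(L, seed = 1)
  expect_identical(cl$k, 2L)
  truth <- rep(1:2, each = 10)
  expect_true(same_partition(unname(cl$labels), truth))
})

test_that("clustering is reproducible and equivariant to sample order", {
  sim <- simulate_meth_expr(n = 40, p = 10, q = 20, k = 3, tau = 4,
                            seed = 8)
  cl1 <- cluster_samples(sim$L_true, seed = 7)
  cl2 <- cluster_samples(sim$L_true, seed = 7)
  expect_identical(cl1$labels, cl2$labels)
  perm <- sample(40)
  clp <- cluster_samples(sim$L_true[perm, ], seed = 7)
  expect_true(same_partition(unname(clp$labels), unname(cl1$labels)[perm]))
  # guard: more requested clusters than samples
  wide <- low_rank(matrix(rnorm(10), 2, 5), singular_values = c(5, 4, 3))
  expect_error(cluster_samples(wide, seed = 1), "clusters from")
})

test_that("planted cluster shifts are flagged as subtype-associated sites", {
  set.seed(91)
  n_per <- 60; k <- 4
  labels <- rep(1:k, each = n_per)
  beta <- matrix(runif(n_per * k * 3, 0.25, 0.45), n_per * k, 3,
                 dimnames = list(sprintf("s%03d", 1:(n_per * k)),
                                 c("cgA", "cgB", "cgC")))
  # site cgA: hypermethylated in clusters 2 and 3, hypomethylated in 4 --
  # three clusters separate strongly one-vs-rest, the baseline one does not
  beta[labels == 2, "cgA"] <- beta[labels == 2, "cgA"] + 0.35
  beta[labels == 3, "cgA"] <- beta[labels == 3, "cgA"] + 0.35
  beta[labels == 4, "cgA"] <- beta[labels == 4, "cgA"] - 0.23
  beta <- pmin(pmax(beta, 0), 1)
  res <- subtype_differential_sites(beta, labels)
  expect_true(res$flagged[1])          # cgA differential in > 2 clusters
  expect_false(any(res$flagged[2:3]))  # null sites stay unflagged
  expect_identical(dim(res$p_values), c(3L, 4L))
  # degenerate threshold flags every tested site
  all_res <- subtype_differential_sites(beta, labels, p_threshold = 1,
                                        min_clusters = 0L)
  expect_true(all(all_res$flagged))
})

test_that("subtype p-values are invariant to sample order", {
  set.seed(92)
  beta <- matrix(runif(60 * 2), 60, 2,
                 dimnames = list(sprintf("s%02d", 1:60), c("cg1", "cg2")))
  labels <- rep(1:3, each = 20)
  r1 <- subtype_differential_sites(beta, labels)
  perm <- sample(60)
  r2 <- subtype_differential_sites(beta[perm, ], labels[perm])
  expect_equal(r1$p_values, r2$p_values)
})

test_that("degenerate clusterings are handled with warnings", {
  beta <- matrix(runif(20), 10, 2,
                 dimnames = list(paste0("s", 1:10), c("a", "b")))
  expect_warning(res <- subtype_differential_sites(beta, rep(1L, 10)),
                 "single cluster")
  expect_false(any(res$flagged))
  # a singleton cluster is excluded from testing
  expect_warning(res2 <- subtype_differential_sites(beta,
                                                    c(rep(1L, 9), 2L)),
                 "fewer than 2")
  expect_true(all(is.na(res2$p_values[, "cluster2"])))
})
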