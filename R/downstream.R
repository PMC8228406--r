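# Post-fit analyses: ranking methylation-expression associations by
# coefficient magnitude, subtyping samples from the low-rank heterogeneity
# term, and locating CpG sites that are differentially methylated across the
# resulting subtypes.

#' Rank methylation-expression associations by coefficient magnitude
#'
#' The model provides no significance test on B; associations are ranked by
#' `|coefficient|`.  Either the global top `top_n` entries are returned, or
#' the top `per_gene_d` sites for each gene.  Ties in magnitude are broken
#' by `(site_id, gene_id)` lexicographic order so repeated calls are
#' bitwise identical.
#'
#' @param B p x q coefficient matrix (sites x genes), e.g. `coef(fit)`, with
#'   dimnames; or a fitted `"slrr"` object.
#' @param top_n global number of associations to return.
#' @param per_gene_d number of top sites per gene.  Exactly one of `top_n`
#'   and `per_gene_d` must be given.
#' @return data frame with columns `site_id`, `gene_id`, `coefficient`,
#'   `abs_coefficient`, `rank` (1-based, dense), sorted by decreasing
#'   magnitude.
#' @export
top_associations <- function(B, top_n = NULL, per_gene_d = NULL) {
  if (inherits(B, "slrr")) B <- B$B
  stopifnot(is.matrix(B))
  if (is.null(top_n) == is.null(per_gene_d)) {
    stop("give exactly one of top_n or per_gene_d", call. = FALSE)
  }
  sites <- rownames(B) %||% sprintf("site%d", seq_len(nrow(B)))
  genes <- colnames(B) %||% sprintf("gene%d", seq_len(ncol(B)))
  nz <- which(B != 0, arr.ind = TRUE)
  tab <- data.frame(site_id = sites[nz[, 1L]], gene_id = genes[nz[, 2L]],
                    coefficient = B[nz], abs_coefficient = abs(B[nz]),
                    row.names = NULL)
  ord <- order(-tab$abs_coefficient, tab$site_id, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  if (!is.null(top_n)) {
    stopifnot(top_n >= 1L)
    if (top_n > nrow(tab)) {
      warning("top_n = ", top_n, " exceeds the ", nrow(tab),
              " non-zero coefficients; returning all of them", call. = FALSE)
      top_n <- nrow(tab)
    }
    tab <- tab[seq_len(top_n), , drop = FALSE]
  } else {
    stopifnot(per_gene_d >= 1L)
    keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$gene_id),
                          function(i) i[seq_len(min(per_gene_d, length(i)))]),
                   use.names = FALSE)
    tab <- tab[sort(keep), , drop = FALSE]
  }
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Cluster samples from the low-rank heterogeneity term
#'
#' The rank of the fitted L estimates the number of expression-heterogeneity
#' groups, so samples are partitioned into `k = max(rank(L), 1)` clusters.
#' The embedding is the top-k left singular vectors of L scaled by their
#' singular values (the samples' coordinates in the heterogeneity factor
#' space); clusters come from k-means with 20 restarts under a fixed seed.
#'
#' @param L a `"low_rank"` object (e.g. `fit$L`), a fitted `"slrr"` object,
#'   or a plain matrix.
#' @param rank_tol relative singular-value cutoff determining k.
#' @param seed RNG seed for the k-means restarts.
#' @return object of class `"sample_clustering"`: list with integer `labels`
#'   (1..k, named by sample), `k`, the n x k `embedding`, and `seed`.
#' @export
cluster_samples <- function(L, rank_tol = 1e-8, seed = 1L) {
  if (inherits(L, "slrr")) L <- L$L
  M <- if (inherits(L, "low_rank")) L$values else L
  stopifnot(is.matrix(M))
  k <- max(numerical_rank(L, rank_tol), 1L)
  n <- nrow(M)
  if (n < k) {
    stop("cannot form ", k, " clusters from ", n, " samples", call. = FALSE)
  }
  s <- svd(M, nu = min(k, n), nv = 0)
  emb <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  rownames(emb) <- rownames(M)
  local_seed(seed)
  labels <- if (k == 1L) {
    rep(1L, n)
  } else {
    stats::kmeans(emb, centers = k, nstart = 20L, iter.max = 100L)$cluster
  }
  labels <- as.integer(labels)
  names(labels) <- rownames(M)
  structure(list(labels = labels, k = as.integer(k),
                 embedding = emb, seed = seed),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("Sample clustering from the low-rank heterogeneity term\n")
  cat("  k =", x$k, "clusters over", length(x$labels), "samples\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Subtype-associated differentially methylated CpG sites
#'
#' For each site and each cluster (one-vs-rest), a two-sided Wilcoxon
#' rank-sum test compares the cluster's beta values against all remaining
#' samples.  A site is flagged as subtype-associated when the number of
#' clusters with `p < p_threshold` exceeds `min_clusters` (with the
#' defaults: differential methylation in more than two clusters at
#' p < 1e-10).  The extreme default threshold is used raw; BH-adjusted
#' p-values (across all site x cluster tests) are reported alongside for
#' transparency.
#'
#' @param meth samples x sites methylation matrix, aligned with the
#'   clustering.
#' @param clustering a `"sample_clustering"` object from [cluster_samples()]
#'   (or an integer vector of cluster labels).
#' @param p_threshold per-test significance threshold (default 1e-10).
#' @param min_clusters flag a site when strictly more than this many
#'   clusters are significant (default 2).
#' @return object of class `"subtype_sites"`: list with matrices `p_values`
#'   and `p_adjusted` (sites x clusters), integer `n_significant_clusters`,
#'   logical `flagged`, and a summary data frame `table`.
#' @export
subtype_differential_sites <- function(meth, clustering, p_threshold = 1e-10,
                                       min_clusters = 2L) {
  labels <- if (inherits(clustering, "sample_clustering")) {
    clustering$labels
  } else {
    as.integer(clustering)
  }
  stopifnot(length(labels) == nrow(meth), p_threshold >= 0,
            p_threshold <= 1)
  validate_methylation(meth, allow_missing = FALSE)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) {
    warning("a single cluster admits no differential test; nothing flagged",
            call. = FALSE)
    empty <- matrix(NA_real_, ncol(meth), length(clusters),
                    dimnames = list(colnames(meth), clusters))
    return(structure(list(p_values = empty, p_adjusted = empty,
                          n_significant_clusters = rep(0L, ncol(meth)),
                          flagged = rep(FALSE, ncol(meth)),
                          table = data.frame(site_id = colnames(meth),
                                             n_significant_clusters = 0L,
                                             flagged = FALSE)),
                     class = "subtype_sites"))
  }
  sizes <- table(factor(labels, levels = clusters))
  testable <- clusters[sizes >= 2L & (length(labels) - sizes) >= 2L]
  if (length(testable) < length(clusters)) {
    warning(length(clusters) - length(testable),
            " cluster(s) with fewer than 2 samples (or complement < 2) ",
            "excluded from testing", call. = FALSE)
  }
  P <- matrix(NA_real_, ncol(meth), length(clusters),
              dimnames = list(colnames(meth), paste0("cluster", clusters)))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    if (!cl %in% testable) next
    inside <- labels == cl
    for (j in seq_len(ncol(meth))) {
      P[j, ci] <- stats::wilcox.test(meth[inside, j], meth[!inside, j],
                                     exact = FALSE)$p.value
    }
  }
  Padj <- P
  Padj[!is.na(P)] <- stats::p.adjust(P[!is.na(P)], method = "BH")
  n_sig <- rowSums(P < p_threshold, na.rm = TRUE)
  flagged <- n_sig > min_clusters
  structure(list(p_values = P, p_adjusted = Padj,
                 n_significant_clusters = as.integer(n_sig),
                 flagged = flagged,
                 table = data.frame(site_id = colnames(meth),
                                    n_significant_clusters = as.integer(n_sig),
                                    flagged = flagged, row.names = NULL)),
            class = "subtype_sites")
}

#' @export
print.subtype_sites <- function(x, ...) {
  cat("Subtype-associated CpG site scan:", nrow(x$p_values), "sites x",
      ncol(x$p_values), "clusters\n")
  cat(" ", sum(x$flagged), "site(s) flagged (differential in more than",
      "min_clusters clusters)\n")
  if (any(x$flagged)) {
    print(utils::head(x$table[x$flagged, , drop = FALSE], 10L))
  }
  invisible(x)
}
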