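# Cohort preprocessing: the filtration funnel turning raw paired matrices,
# site annotation and clinical data into model-ready aligned inputs.  All
# filters are idempotent and only remove rows/columns or impute missing
# entries; retained non-missing values are never altered.  Each filter
# attaches a "filter_log" attribute with its drop/imputation counts so the
# funnel is auditable.

#' Drop high-missingness CpG sites and impute the rest
#'
#' Removes every site whose fraction of missing beta values exceeds
#' `max_missing_fraction` (strictly), then fills the remaining missing
#' entries with the per-site mean of the observed values.
#'
#' @param meth samples x sites methylation matrix, possibly with `NA`s.
#' @param max_missing_fraction drop threshold in (0, 1]; default 0.7 (a site
#'   missing in more than 70% of samples is removed).
#' @return complete methylation matrix; attribute `"filter_log"` records
#'   `sites_dropped` and `values_imputed`.
#' @export
filter_missing_sites <- function(meth, max_missing_fraction = 0.7) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction <= 1)
  validate_methylation(meth, allow_missing = TRUE)
  miss_frac <- colMeans(is.na(meth))
  keep <- miss_frac <= max_missing_fraction
  if (!any(keep)) {
    stop("all ", ncol(meth), " sites exceed the missingness threshold",
         call. = FALSE)
  }
  out <- meth[, keep, drop = FALSE]
  n_imputed <- sum(is.na(out))
  if (n_imputed > 0L) {
    for (j in which(colSums(is.na(out)) > 0L)) {
      nas <- is.na(out[, j])
      out[nas, j] <- mean(out[!nas, j])
    }
  }
  attr(out, "filter_log") <- list(sites_dropped = sum(!keep),
                                  values_imputed = n_imputed)
  out
}

#' Restrict methylation sites to gene promoter windows
#'
#' Keeps CpG sites whose signed distance to the nearest transcription start
#' site lies within the closed interval
#' `[-upstream_bp, +downstream_bp]` (negative = upstream).  Sites without an
#' annotation row are dropped and counted.
#'
#' @param meth samples x sites methylation matrix.
#' @param annot data frame with columns `site_id`, `chromosome`,
#'   `tss_offset` (signed base pairs relative to the TSS).
#' @param upstream_bp,downstream_bp promoter window half-widths in base
#'   pairs; defaults 2000 upstream and 500 downstream.
#' @return reduced methylation matrix; attribute `"filter_log"` records
#'   `sites_unannotated` and `sites_outside_window`.
#' @export
filter_promoter_sites <- function(meth, annot, upstream_bp = 2000L,
                                  downstream_bp = 500L) {
  stopifnot(is.data.frame(annot),
            all(c("site_id", "tss_offset") %in% names(annot)))
  if (anyDuplicated(annot$site_id)) {
    stop("duplicate site_id in annotation", call. = FALSE)
  }
  off <- annot$tss_offset[match(colnames(meth), annot$site_id)]
  unannotated <- is.na(off)
  in_window <- !unannotated & off >= -upstream_bp & off <= downstream_bp
  if (!any(in_window)) {
    stop("no methylation site falls inside the promoter window", call. = FALSE)
  }
  out <- meth[, in_window, drop = FALSE]
  attr(out, "filter_log") <- list(
    sites_unannotated = sum(unannotated),
    sites_outside_window = sum(!in_window & !unannotated))
  out
}

#' Filter clinical records by follow-up duration
#'
#' Removes samples with missing follow-up or follow-up shorter than
#' `min_follow_up_days` (strict `<`, so exactly 30 days is kept under the
#' default).
#'
#' @param clin data frame with columns `sample_id`, `follow_up_days`
#'   (nonnegative integer or `NA`) and optionally `group_label`.
#' @param min_follow_up_days minimum retained follow-up (default 30 days).
#' @return filtered clinical data frame (possibly empty, with a warning).
#' @export
filter_clinical <- function(clin, min_follow_up_days = 30L) {
  stopifnot(is.data.frame(clin),
            all(c("sample_id", "follow_up_days") %in% names(clin)))
  if (anyDuplicated(clin$sample_id)) {
    stop("duplicate sample_id in clinical table", call. = FALSE)
  }
  keep <- !is.na(clin$follow_up_days) &
    clin$follow_up_days >= min_follow_up_days
  out <- clin[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no clinical records survive the follow-up filter", call. = FALSE)
  }
  attr(out, "filter_log") <- list(samples_dropped = sum(!keep))
  out
}

#' Align methylation and expression matrices on common samples
#'
#' Restricts both matrices (and, when given, the clinical table's samples)
#' to the sorted set of shared sample IDs, in identical row order.
#'
#' @param meth,expr samples x features matrices with sample IDs as rownames.
#' @param clin optional clinical data frame (`sample_id` column); when
#'   supplied, only its samples are retained.
#' @return list with aligned `meth` and `expr` matrices.
#' @export
intersect_samples <- function(meth, expr, clin = NULL) {
  ids <- intersect(rownames(meth), rownames(expr))
  if (!is.null(clin)) ids <- intersect(ids, clin$sample_id)
  ids <- sort(ids)
  if (length(ids) == 0L) {
    stop("no samples shared between the methylation and expression ",
         "datasets", call. = FALSE)
  }
  list(meth = meth[ids, , drop = FALSE], expr = expr[ids, , drop = FALSE])
}

#' Select differentially expressed genes between tumor and normal samples
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of tumor versus normal
#' expression with Benjamini-Hochberg adjustment across genes; a gene is
#' kept when its adjusted p-value is below `alpha` and the absolute log2
#' fold change of the group means (computed with a pseudo-count of 1) is at
#' least `min_abs_logfc`.
#'
#' @param expr samples x genes expression matrix.
#' @param labels character/factor per sample, values `"tumor"` or
#'   `"normal"`, aligned with `rownames(expr)`.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param min_abs_logfc minimum |log2 fold change| (default 1).
#' @return expression matrix reduced to the selected genes; attribute
#'   `"de_table"` holds the per-gene statistics (p, adjusted p, log2 FC,
#'   kept flag).
#' @export
select_de_genes <- function(expr, labels, alpha = 0.05, min_abs_logfc = 1.0) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(expr),
            all(labels %in% c("tumor", "normal")))
  n_t <- sum(labels == "tumor"); n_n <- sum(labels == "normal")
  if (n_t < 2L || n_n < 2L) {
    stop("need at least 2 samples per group (tumor: ", n_t, ", normal: ",
         n_n, ")", call. = FALSE)
  }
  tum <- labels == "tumor"
  pvals <- vapply(seq_len(ncol(expr)), function(j) {
    stats::wilcox.test(expr[tum, j], expr[!tum, j], exact = FALSE)$p.value
  }, numeric(1))
  log2fc <- log2((colMeans(expr[tum, , drop = FALSE]) + 1) /
                   (colMeans(expr[!tum, , drop = FALSE]) + 1))
  padj <- stats::p.adjust(pvals, method = "BH")
  # alpha >= 1 disables the significance filter entirely
  keep <- (if (alpha >= 1) TRUE else padj < alpha) &
    abs(log2fc) >= min_abs_logfc
  de <- data.frame(gene_id = colnames(expr), p_value = pvals,
                   p_adjusted = padj, log2_fold_change = log2fc,
                   kept = keep, row.names = NULL)
  out <- expr[, keep, drop = FALSE]
  attr(out, "de_table") <- de
  out
}
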