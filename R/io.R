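# Tab-separated I/O.  Matrix dialect: UTF-8 TSV, header row of feature IDs,
# first column sample IDs; missing tokens "NA" and "".  B is serialized as a
# sparse triplet table, L densely, the fit report as JSON; numbers use full
# decimal precision so write/read round-trips are exact to ~1e-16.

#' Read a methylation or expression matrix from TSV
#'
#' @param path file path; first column sample IDs, header row of CpG site or
#'   gene IDs.
#' @param kind `"methylation"` (entries validated to be in `[0,1]`, `NA`
#'   preserved for preprocessing) or `"expression"` (finite entries
#'   required).
#' @return numeric matrix with sample rownames and feature colnames.
#' @export
read_matrix <- function(path, kind = c("methylation", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""), check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) {
    stop("matrix file needs a sample-ID column plus at least one feature: ",
         path, call. = FALSE)
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample IDs in ", path, call. = FALSE)
  if (anyDuplicated(names(df)[-1L])) {
    stop("duplicate feature IDs in ", path, call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric cell at sample '", ids[bad[1L, 1L]], "', column '",
         colnames(vals)[bad[1L, 2L]], "' in ", path, call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (kind == "methylation") {
    validate_methylation(num, allow_missing = TRUE)
  } else {
    if (anyNA(num)) {
      stop("missing values in expression matrix ", path, call. = FALSE)
    }
    validate_expression(num)
  }
  num
}

#' Write a matrix in the package's TSV dialect
#'
#' @param x numeric matrix with sample rownames and feature colnames.
#' @param path output file.
#' @param id_col header name of the sample-ID column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_col = "sample_id") {
  df <- data.frame(rownames(x), format_full(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# full-precision decimal formatting (17 significant digits round-trips
# IEEE doubles); keeps NA as NA for write.table's na token
format_full <- function(x) {
  out <- array(NA_character_, dim = dim(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  dimnames(out) <- dimnames(x)
  out
}

#' Read a CpG site annotation table
#'
#' BED-like TSV with columns `chromosome`, `site_id`, `tss_offset` (signed
#' distance in bp to the nearest TSS, negative upstream); extra columns are
#' ignored.
#'
#' @param path file path.
#' @return data frame with `site_id`, `chromosome`, `tss_offset`.
#' @export
read_site_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""), check.names = FALSE)
  need <- c("chromosome", "site_id", "tss_offset")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns ",
         paste(need, collapse = ", "), ": ", path, call. = FALSE)
  }
  df$tss_offset <- as.integer(df$tss_offset)
  if (anyNA(df$tss_offset)) {
    stop("non-integer tss_offset in ", path, call. = FALSE)
  }
  df[, need[c(2L, 1L, 3L)]]
}

#' Read a clinical table
#'
#' TSV with columns `sample_id`, `follow_up_days` (nonnegative integer,
#' possibly missing) and `group_label` (`tumor`/`normal`).
#'
#' @param path file path.
#' @return clinical data frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""), check.names = FALSE)
  need <- c("sample_id", "follow_up_days")
  if (!all(need %in% names(df))) {
    stop("clinical file must have columns sample_id, follow_up_days: ",
         path, call. = FALSE)
  }
  df$follow_up_days <- as.integer(df$follow_up_days)
  df
}

#' Write a fitted model to disk
#'
#' Produces `B_triplets.tsv` (site_id, gene_id, coefficient; non-zero
#' entries only, zero-row file with header when B is all zero), `L.tsv`
#' (dense), and `report.json` (objective trace, rank, nnz, convergence and
#' the full tuning configuration).  Serialization is full-precision, so
#' [read_fit_result()] reconstructs B and L essentially exactly.
#'
#' @param fit fitted `"slrr"` object.
#' @param out_dir output directory (created if absent).
#' @return named character vector of the three paths, invisibly.
#' @export
write_fit_result <- function(fit, out_dir) {
  stopifnot(inherits(fit, "slrr"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(B = file.path(out_dir, "B_triplets.tsv"),
             L = file.path(out_dir, "L.tsv"),
             report = file.path(out_dir, "report.json"))
  nz <- which(fit$B != 0, arr.ind = TRUE)
  trip <- data.frame(
    site_id = rownames(fit$B)[nz[, 1L]] %||% as.character(nz[, 1L]),
    gene_id = colnames(fit$B)[nz[, 2L]] %||% as.character(nz[, 2L]),
    coefficient = sprintf("%.17g", fit$B[nz]))
  ord <- order(trip$site_id, trip$gene_id)
  utils::write.table(trip[ord, , drop = FALSE], paths["B"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(fit$L$values, paths["L"])
  report <- list(
    dims = as.list(fit$dims),
    config = fit$config,
    objective_trace = fit$objective,
    n_iter = fit$n_iter,
    converged = fit$converged,
    nnz = fit$nnz,
    rank_L = fit$L$numerical_rank,
    singular_values_L = fit$L$singular_values,
    column_means_Y = fit$column_means_Y,
    column_means_X = fit$column_means_X)
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

#' Read back a fit written by [write_fit_result()]
#'
#' @param out_dir directory containing `B_triplets.tsv`, `L.tsv`,
#'   `report.json`.
#' @param site_ids,gene_ids optional full ID vectors fixing the dimensions
#'   of the reconstructed B; defaults to the IDs present in the files (B
#'   rows then cover only sites with at least one non-zero coefficient).
#' @return list with `B`, `L` (`"low_rank"`), and the parsed `report`.
#' @export
read_fit_result <- function(out_dir, site_ids = NULL, gene_ids = NULL) {
  trip <- utils::read.delim(file.path(out_dir, "B_triplets.tsv"),
                            sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "numeric"))
  Lm <- read_matrix_generic(file.path(out_dir, "L.tsv"))
  report <- jsonlite::read_json(file.path(out_dir, "report.json"),
                                simplifyVector = TRUE)
  site_ids <- site_ids %||% sort(unique(trip$site_id))
  gene_ids <- gene_ids %||% colnames(Lm)
  B <- matrix(0, length(site_ids), length(gene_ids),
              dimnames = list(site_ids, gene_ids))
  if (nrow(trip) > 0L) {
    B[cbind(match(trip$site_id, site_ids), match(trip$gene_id, gene_ids))] <-
      trip$coefficient
  }
  list(B = B, L = low_rank(Lm, rank_tol = report$config$rank_tol %||% 1e-8),
       report = report)
}

# dense numeric TSV without the methylation/expression range checks
read_matrix_generic <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ""), check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}
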