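# Input containers are plain numeric matrices with mandatory dimnames:
# rownames = sample IDs, colnames = CpG site IDs (methylation) or gene IDs
# (expression).  Validators below enforce the contracts once at the API
# boundary so numerical code can assume clean inputs.

#' Validate a methylation beta-value matrix
#'
#' Checks that `x` is a numeric samples-by-sites matrix with unique sample and
#' site identifiers and all non-missing entries inside `[0, 1]`.  Missing
#' entries (`NA`) are permitted when `allow_missing = TRUE`; downstream model
#' fitting requires a complete matrix (see [filter_missing_sites()]).
#'
#' @param x numeric matrix, n samples x p CpG sites, rownames = sample IDs,
#'   colnames = site IDs.
#' @param allow_missing logical; tolerate `NA` entries (pre-imputation data).
#' @return `x`, invisibly, after validation.
#' @export
validate_methylation <- function(x, allow_missing = FALSE) {
  validate_ids(x, "methylation")
  v <- x[!is.na(x)]
  if (any(v < 0 | v > 1)) {
    bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)[1L, ]
    stop("methylation beta value outside [0,1] at sample '",
         rownames(x)[bad[1L]], "', site '", colnames(x)[bad[2L]], "'",
         call. = FALSE)
  }
  if (!allow_missing && anyNA(x)) {
    stop("methylation matrix contains missing values; run ",
         "filter_missing_sites() first", call. = FALSE)
  }
  invisible(x)
}

#' Validate an expression matrix
#'
#' @param x numeric matrix, n samples x q genes, rownames = sample IDs,
#'   colnames = gene IDs; all entries finite.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  validate_ids(x, "expression")
  if (!all(is.finite(x))) {
    stop("expression matrix contains non-finite entries", call. = FALSE)
  }
  invisible(x)
}

validate_ids <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " data must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " matrix needs rownames (sample IDs) and colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate sample IDs in ", what, " matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate ", if (what == "methylation") "site" else "gene",
         " IDs in ", what, " matrix", call. = FALSE)
  }
  invisible(x)
}

# Samples must align row-for-row between Y and X before fitting.
check_aligned <- function(Y, X) {
  if (nrow(Y) != nrow(X)) {
    stop("sample dimension mismatch: Y has ", nrow(Y), " rows, X has ",
         nrow(X), call. = FALSE)
  }
  if (!is.null(rownames(Y)) && !is.null(rownames(X)) &&
      !identical(rownames(Y), rownames(X))) {
    stop("sample IDs of Y and X are not aligned; use intersect_samples()",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Low-rank matrix component
#'
#' Wraps an n x q matrix together with its singular spectrum and numerical
#' rank.  Returned by [svt_prox()] and stored in fitted [slrr()] objects as
#' the expression-heterogeneity term.
#'
#' @param values numeric matrix.
#' @param singular_values optional precomputed nonincreasing singular values;
#'   computed by SVD when omitted.
#' @param rank_tol relative cutoff: singular values no larger than
#'   `rank_tol * max(singular value, 1)` do not count toward the rank.
#' @return object of class `"low_rank"`: a list with `values`,
#'   `singular_values` and `numerical_rank`.
#' @export
low_rank <- function(values, singular_values = NULL, rank_tol = 1e-8) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) stop("non-finite entries in low-rank component")
  if (is.null(singular_values)) {
    singular_values <- svd(values, nu = 0, nv = 0)$d
  }
  structure(
    list(values = values,
         singular_values = singular_values,
         numerical_rank = rank_count(singular_values, rank_tol)),
    class = "low_rank")
}

#' @export
print.low_rank <- function(x, ...) {
  cat("Low-rank component: ", nrow(x$values), " x ", ncol(x$values),
      ", numerical rank ", x$numerical_rank, "\n", sep = "")
  cat("Leading singular values:",
      paste(signif(utils::head(x$singular_values, 5L), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.matrix.low_rank <- function(x, ...) x$values

rank_count <- function(d, rank_tol) {
  if (length(d) == 0L) return(0L)
  sum(d > rank_tol * max(max(d), 1))
}

#' Numerical rank of a low-rank component
#'
#' Counts singular values exceeding `rank_tol * max(largest singular value,
#' 1)`.  For a converged fit this is the estimated number of expression
#' heterogeneity factors, and it sets the number of sample clusters used by
#' [cluster_samples()].
#'
#' @param L a `"low_rank"` object (see [low_rank()]), a plain matrix, or a
#'   numeric vector of singular values.
#' @param rank_tol relative singular-value cutoff.
#' @return integer rank.
#' @examples
#' numerical_rank(diag(c(10, 1e-12)))  # 1
#' @export
numerical_rank <- function(L, rank_tol = 1e-8) {
  d <- if (inherits(L, "low_rank")) {
    L$singular_values
  } else if (is.matrix(L)) {
    svd(L, nu = 0, nv = 0)$d
  } else if (is.numeric(L)) {
    L
  } else {
    stop("L must be a low_rank object, a matrix, or singular values")
  }
  as.integer(rank_count(d, rank_tol))
}

# Restore-on-exit seeding so exported functions never leave global RNG state
# behind.  Substreams for independent generator components are derived from
# one user seed via substream_seed().
local_seed <- function(seed, envir = parent.frame()) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  do.call(on.exit, list(bquote(restore_seed(.(old))), add = TRUE),
          envir = envir)
  set.seed(seed)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

substream_seed <- function(seed, offset) {
  as.integer((abs(as.double(seed)) * 48271 + offset * 1299721) %% 2147483629)
}
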