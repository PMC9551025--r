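#' Construct a validated gene-by-sample count matrix
#'
#' The pipeline's expression container: a matrix of raw, non-negative integer
#' counts (genes in rows, samples in columns) together with a per-sample group
#' label, `"case"` or `"control"`. All downstream differential-expression
#' functions take this object.
#'
#' @param counts Numeric matrix of raw counts, genes x samples, with unique
#'   rownames (gene ids) and colnames (sample ids). Entries must be
#'   non-negative integers (integer-valued doubles are accepted).
#' @param group Character vector of `"case"`/`"control"` labels, one per
#'   sample. Either named by sample id or given in column order.
#' @param require_groups If `TRUE` (default), require both groups present with
#'   at least two samples each, the precondition for differential-expression
#'   testing. Set to `FALSE` for purely descriptive uses.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix) and `group` (factor, levels `case`, `control`,
#'   named by sample id).
#' @export
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m, c("case", "case", "control", "control"))
#' cm
count_matrix <- function(counts, group, require_groups = TRUE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene rownames and sample colnames.")
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g) > 0) {
    abort(paste0("Duplicated gene id(s): ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicated sample id(s): ", paste(dup_s, collapse = ", ")))
  }
  if (!is.numeric(counts)) abort("`counts` must be numeric.")
  if (anyNA(counts)) abort("`counts` contains missing values.")
  if (any(counts < 0)) abort("`counts` contains negative entries.")
  if (any(counts != round(counts))) {
    abort("`counts` contains non-integer entries; raw counts are required.")
  }
  storage.mode(counts) <- "double"

  if (!is.null(names(group))) {
    missing <- setdiff(colnames(counts), names(group))
    if (length(missing) > 0) {
      abort(paste0("Sample(s) missing a group label: ",
                   paste(missing, collapse = ", ")))
    }
    group <- group[colnames(counts)]
  } else if (length(group) != ncol(counts)) {
    abort("`group` must have one label per sample.")
  }
  group <- as.character(group)
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad) > 0) {
    abort(paste0("Group labels must be 'case' or 'control'; found: ",
                 paste(bad, collapse = ", ")))
  }
  group <- factor(group, levels = c("case", "control"))
  names(group) <- colnames(counts)
  if (require_groups && any(table(group) < 2)) {
    abort("Both groups must have >= 2 samples for differential testing.")
  }
  structure(list(counts = counts, group = group), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d case, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tidy a count matrix into long format
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `group`, `count`.
#' @method tidy count_matrix
#' @export
tidy.count_matrix <- function(x, ...) {
  tibble(
    gene = rep(rownames(x$counts), times = ncol(x$counts)),
    sample = rep(colnames(x$counts), each = nrow(x$counts)),
    group = rep(as.character(x$group), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
}

#' @method glance count_matrix
#' @export
glance.count_matrix <- function(x, ...) {
  tibble(
    n_genes = nrow(x$counts),
    n_samples = ncol(x$counts),
    n_case = sum(x$group == "case"),
    n_control = sum(x$group == "control"),
    total_counts = sum(x$counts)
  )
}

#' Normalized log2 expression values
#'
#' Divides counts by median-of-ratios size factors and applies `log2(x + 1)`.
#' This is the expression scale used for median dichotomisation in the
#' survival screen; the median split itself is invariant to any monotone
#' transform, so the choice is cosmetic but fixed for reproducibility.
#'
#' @param x A [count_matrix()].
#' @param size_f Optional precomputed size factors (named per sample).
#' @return A numeric matrix, genes x samples, of `log2(count/sf + 1)` values.
#' @export
normalized_log_expression <- function(x, size_f = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(size_f)) size_f <- size_factors(x)
  log2(sweep(x$counts, 2, size_f, "/") + 1)
}
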