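#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth normalisation constants: each sample's counts
#' are compared gene-wise to a pseudo-reference (the per-gene geometric mean
#' across samples, over genes expressed in every sample) and the median ratio
#' is taken. Multiplying one sample's counts by a constant multiplies its
#' factor by the same constant (scale equivariance, exact).
#'
#' @param x A [count_matrix()] or a numeric count matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    abort(paste0("No gene has positive counts in every sample; cannot form ",
                 "the geometric-mean reference. Consider adding a pseudo-count."))
  }
  logref <- rowMeans(log(counts[keep, , drop = FALSE]))
  apply(counts[keep, , drop = FALSE], 2,
        function(col) exp(median(log(col) - logref)))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene overdispersion \eqn{\alpha} under the parameterisation
#' \eqn{Var = \mu + \alpha \mu^2}, estimated from normalized counts as
#' \eqn{\hat\alpha = \max((s^2_w - \hat\mu)/\hat\mu^2, floor)} where
#' \eqn{s^2_w} is the pooled within-group sample variance and \eqn{\hat\mu}
#' the pooled mean. Poisson-like or constant genes hit the floor.
#'
#' @param norm_counts Numeric matrix of normalized counts, genes x samples.
#' @param group Factor/character of two group labels, one per sample.
#' @param floor Lower bound absorbing degenerate estimates (default `1e-8`).
#' @return Named numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(norm_counts, group, floor = 1e-8) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  if (any(table(group) < 2)) abort("Need >= 2 samples per group.")
  idx <- split(seq_along(group), group)
  n1 <- length(idx[[1]]); n2 <- length(idx[[2]])
  m1 <- rowMeans(norm_counts[, idx[[1]], drop = FALSE])
  m2 <- rowMeans(norm_counts[, idx[[2]], drop = FALSE])
  v1 <- apply(norm_counts[, idx[[1]], drop = FALSE], 1, var)
  v2 <- apply(norm_counts[, idx[[2]], drop = FALSE], 1, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha <- ifelse(mu > 0, (s2 - mu) / mu^2, floor)
  pmax(alpha, floor)
}

#' Negative-binomial Wald differential-expression test
#'
#' A self-contained two-group test on raw counts: median-of-ratios size
#' factors, per-gene method-of-moments dispersion with a small floor, log2
#' fold change of pseudo-counted normalized group means
#' (`log2((mean_case + pc) / (mean_control + pc))`), a delta-method standard
#' error from the fitted NB variance `mu + alpha*mu^2`, a two-sided Wald
#' normal p-value, and Benjamini-Hochberg q-values across tested genes.
#' Genes with zero counts in every sample are flagged untested (`NA`
#' statistics).
#'
#' @param x A [count_matrix()] with >= 2 samples in each group.
#' @param pseudo_count Stabilising constant added to both group means before
#'   the log-ratio (default 0.5).
#' @param dispersion_floor Passed to [estimate_dispersion()].
#' @return A tibble, one row per gene: `gene`, `mean_case`, `mean_control`
#'   (normalized means), `dispersion`, `log2_fc`, `se`, `stat`, `p_value`,
#'   `bh_q`, `tested`.
#' @export
#' @examples
#' sim <- simulate_counts(n_genes = 200, n_case = 5, n_control = 5,
#'                        n_up = 10, n_down = 10, lfc = 3, seed = 1)
#' de <- de_test(sim$counts)
#' head(dplyr::arrange(de, p_value))
de_test <- function(x, pseudo_count = 0.5, dispersion_floor = 1e-8) {
  stopifnot(inherits(x, "count_matrix"))
  if (any(table(x$group) < 2)) abort("Need >= 2 samples per group.")
  sf <- size_factors(x)
  norm <- sweep(x$counts, 2, sf, "/")
  case <- x$group == "case"
  n_case <- sum(case); n_ctrl <- sum(!case)
  mean_case <- rowMeans(norm[, case, drop = FALSE])
  mean_ctrl <- rowMeans(norm[, !case, drop = FALSE])
  alpha <- estimate_dispersion(norm, x$group, floor = dispersion_floor)
  tested <- rowSums(x$counts) > 0

  lfc <- log2((mean_case + pseudo_count) / (mean_ctrl + pseudo_count))
  # delta method: Var(log2(mean_g + pc)) ~ Var(mean_g) / ((mean_g + pc) ln2)^2
  v_case <- (mean_case + alpha * mean_case^2) / n_case
  v_ctrl <- (mean_ctrl + alpha * mean_ctrl^2) / n_ctrl
  se <- sqrt(v_case / ((mean_case + pseudo_count) * log(2))^2 +
             v_ctrl / ((mean_ctrl + pseudo_count) * log(2))^2)
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))

  lfc[!tested] <- NA_real_
  se[!tested] <- NA_real_
  stat[!tested] <- NA_real_
  p[!tested] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[tested] <- bh_adjust(p[tested])

  tibble(
    gene = rownames(x$counts),
    mean_case = mean_case,
    mean_control = mean_ctrl,
    dispersion = alpha,
    log2_fc = lfc,
    se = se,
    stat = stat,
    p_value = p,
    bh_q = q,
    tested = tested
  )
}

#' Threshold a differential-expression table into directional DEG sets
#'
#' Applies the screening rule used throughout the pipeline: significance
#' requires raw `p_value` strictly below `p_cut` and `|log2_fc|` of at least
#' `lfc_cut` (the fold-change boundary is inclusive). Untested genes are never
#' called; the universe records all tested genes.
#'
#' @param de A tibble from [de_test()].
#' @param p_cut Raw p-value cutoff, exclusive (default 0.001).
#' @param lfc_cut Absolute log2 fold-change cutoff, inclusive (default 2).
#' @return A `deg_set`: list with character vectors `up`, `down`, `universe`
#'   and the `thresholds` used.
#' @export
filter_degs <- function(de, p_cut = 0.001, lfc_cut = 2) {
  stopifnot(p_cut > 0, lfc_cut > 0)
  tested <- de[de$tested & !is.na(de$p_value), ]
  sig <- tested$p_value < p_cut
  up <- tested$gene[sig & tested$log2_fc >= lfc_cut]
  down <- tested$gene[sig & tested$log2_fc <= -lfc_cut]
  deg_set(up, down, universe = tested$gene,
          thresholds = c(p_cut = p_cut, lfc_cut = lfc_cut))
}

#' Construct a directional DEG set
#'
#' @param up,down Character vectors of up-/down-regulated gene ids
#'   (disjoint).
#' @param universe All tested genes; must contain `up` and `down`.
#' @param thresholds Optional named numeric vector recording the cutoffs.
#' @return An object of class `deg_set`.
#' @export
deg_set <- function(up, down, universe, thresholds = NULL) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  universe <- unique(as.character(universe))
  both <- intersect(up, down)
  if (length(both) > 0) {
    abort(paste0("Gene(s) in both up and down sets: ",
                 paste(both, collapse = ", ")))
  }
  outside <- setdiff(c(up, down), universe)
  if (length(outside) > 0) {
    abort(paste0("DEG(s) outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  structure(list(up = up, down = down, universe = universe,
                 thresholds = thresholds), class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("<deg_set> %d up, %d down, universe %d genes\n",
              length(x$up), length(x$down), length(x$universe)))
  invisible(x)
}

#' @method tidy deg_set
#' @export
tidy.deg_set <- function(x, ...) {
  tibble(
    gene = c(x$up, x$down),
    direction = rep(c("up", "down"), c(length(x$up), length(x$down)))
  )
}

#' @method glance deg_set
#' @export
glance.deg_set <- function(x, ...) {
  tibble(n_up = length(x$up), n_down = length(x$down),
         n_universe = length(x$universe))
}

#' Direction-consistent intersection of two DEG sets
#'
#' The two-cohort consensus: a gene is kept only if called in the same
#' direction in both sets; a gene up in one and down in the other is excluded
#' from both. The universe becomes the intersection of the two tested
#' universes. Commutative and idempotent.
#'
#' @param a,b `deg_set` objects built on a shared gene namespace.
#' @return A `deg_set`.
#' @export
intersect_degs <- function(a, b) {
  stopifnot(inherits(a, "deg_set"), inherits(b, "deg_set"))
  universe <- intersect(a$universe, b$universe)
  if (length(universe) == 0) {
    abort("The two DEG sets share no tested genes (empty universe intersection).")
  }
  deg_set(intersect(a$up, b$up), intersect(a$down, b$down), universe,
          thresholds = a$thresholds)
}
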