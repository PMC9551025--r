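#' Upper-tail hypergeometric probability
#'
#' Exact \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the
#' chance of drawing at least `k` marked items when `n` items are drawn
#' without replacement from `N` of which `K` are marked. This is the shared
#' kernel of over-representation analysis and the drug signature-reversal
#' test. The tail is accumulated in log space from the log-pmf
#' (`lchoose(K,i) + lchoose(N-K,n-i) - lchoose(N,n)`) so that screen-scale
#' values (p ~ 1e-100) do not underflow.
#'
#' @param N Universe size.
#' @param K Number of marked items (e.g. gene-set size within the universe).
#' @param n Number drawn (e.g. query size).
#' @param k Observed overlap. May be a vector.
#' @return `P(X >= k)`, a numeric vector like `k`, each in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_tail(10, 5, 4, 3)   # 55/210
#' hypergeom_tail(6, 3, 3, 3)    # 1/20
hypergeom_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1)
  if (N < 0 || K < 0 || n < 0 || K > N || n > N) {
    abort("Require 0 <= K <= N and 0 <= n <= N.")
  }
  if (any(k < 0) || any(k > n)) abort("Require 0 <= k <= n.")
  vapply(k, function(ki) {
    hi <- min(K, n)
    if (ki <= max(0, n + K - N)) return(1)
    if (ki > hi) return(0)
    i <- ki:hi
    logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(logp)
    min(1, exp(m + log(sum(exp(logp - m)))))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate q-values: \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)}/j},
#' capped at 1 and order-preserving. A thin wrapper over
#' [stats::p.adjust()]`(method = "BH")` kept as a named step of the pipeline.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s propagate).
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Over-representation analysis against a gene-set collection
#'
#' For each set, tests whether the query gene list overlaps it more than
#' expected under uniform sampling from the universe: one [hypergeom_tail()]
#' per set with `K = |set ∩ universe|`, `n = |query|`, `k = |set ∩ query|`,
#' followed by BH adjustment across the collection. Query genes outside the
#' universe are dropped with a warning. The universe should be the genes the
#' upstream assay could actually have called (e.g. all DE-tested genes), not
#' all annotated genes.
#'
#' @param query Character vector of query genes (e.g. the up-regulated DEGs).
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of eligible genes.
#' @return A tibble sorted by `p_value` (ties by `set_name`): `set_name`,
#'   `overlap_k`, `set_size_K`, `query_size_n`, `universe_N`, `p_value`,
#'   `bh_q`, `overlap_genes` (list-column).
#' @export
ora <- function(query, collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0) abort("Empty query gene list.")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the universe were dropped.",
                 length(outside)))
    query <- intersect(query, universe)
    if (length(query) == 0) abort("No query genes remain inside the universe.")
  }
  N <- length(universe)
  n <- length(query)
  res <- purrr::map(collection$sets, function(members) {
    in_univ <- intersect(members, universe)
    hit <- intersect(in_univ, query)
    list(K = length(in_univ), k = length(hit), genes = hit)
  })
  out <- tibble(
    set_name = names(collection$sets),
    overlap_k = unname(vapply(res, `[[`, 0L, "k")),
    set_size_K = unname(vapply(res, `[[`, 0L, "K")),
    query_size_n = n,
    universe_N = N,
    p_value = unname(vapply(res, function(r) hypergeom_tail(N, r$K, n, r$k),
                            numeric(1))),
    overlap_genes = unname(lapply(res, `[[`, "genes"))
  )
  out$bh_q <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_name), ]
  out[, c("set_name", "overlap_k", "set_size_K", "query_size_n",
          "universe_N", "p_value", "bh_q", "overlap_genes")]
}

#' Run ORA separately on the up- and down-regulated DEGs
#'
#' Convenience wrapper mirroring the usual presentation of enrichment results
#' for the two directions, with an option to pool them.
#'
#' @param degs A `deg_set`.
#' @param collection A [gene_set_collection()].
#' @param universe Defaults to the DEG set's tested universe.
#' @param combined If `TRUE`, also analyse up and down pooled.
#' @return A tibble with a leading `direction` column (`"up"`, `"down"`, and
#'   optionally `"combined"`) stacked over [ora()] results; directions with
#'   an empty query are skipped.
#' @export
ora_degs <- function(degs, collection, universe = NULL, combined = FALSE) {
  stopifnot(inherits(degs, "deg_set"))
  universe <- universe %||% degs$universe
  queries <- list(up = degs$up, down = degs$down)
  if (combined) queries$combined <- union(degs$up, degs$down)
  queries <- queries[lengths(queries) > 0]
  purrr::imap(queries, function(q, dir) {
    dplyr::mutate(ora(q, collection, universe), direction = dir,
                  .before = 1)
  }) |>
    purrr::list_rbind()
}
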