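#' Build the score-thresholded DEG interaction subnetwork
#'
#' Keeps interactions with combined score at or above `min_score` (the
#' threshold is inclusive: "minimum required" score 0.7 keeps an edge scored
#' exactly 0.7) whose endpoints are both in the whitelist of genes of
#' interest (typically the intersected DEGs). Whitelist genes left without
#' any qualifying interaction do not appear in the graph.
#'
#' @param edges Canonical edge tibble from [edge_list()] / [read_edges()].
#' @param node_whitelist Character vector of genes allowed as endpoints
#'   (non-empty).
#' @param min_score Minimum combined score in `[0, 1]`, inclusive
#'   (default 0.7).
#' @return An undirected [igraph::graph] with edge attribute
#'   `combined_score`. Empty (zero nodes) with a warning if nothing
#'   qualifies.
#' @export
build_network <- function(edges, node_whitelist, min_score = 0.7) {
  node_whitelist <- unique(as.character(node_whitelist))
  if (length(node_whitelist) == 0) abort("Empty node whitelist.")
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  keep <- edges$combined_score >= min_score &
    edges$gene_a %in% node_whitelist &
    edges$gene_b %in% node_whitelist
  kept <- edges[keep, ]
  if (nrow(kept) == 0) {
    warn("No edges meet the score threshold within the whitelist; empty graph.")
  }
  g <- igraph::graph_from_data_frame(
    kept[, c("gene_a", "gene_b")], directed = FALSE
  )
  igraph::E(g)$combined_score <- kept$combined_score
  g
}

#' Rank hub genes by degree
#'
#' Orders the nodes of a built interaction subnetwork by degree (number of
#' retained interactions), descending, with ties broken by gene id ascending
#' so the ranking is reproducible, and returns the top `top_n`.
#'
#' @param graph An [igraph::graph] from [build_network()].
#' @param top_n Number of hubs to return (default 10).
#' @return A tibble `gene`, `degree`, `rank` of at most `top_n` rows; attrs
#'   `n_nodes` and `n_edges` record the subnetwork size.
#' @export
hub_genes <- function(graph, top_n = 10) {
  if (!is.numeric(top_n) || top_n <= 0) abort("`top_n` must be positive.")
  deg <- igraph::degree(graph)
  ord <- order(-deg, names(deg))
  out <- tibble(gene = names(deg)[ord], degree = as.integer(deg[ord]))
  out <- head(out, top_n)
  out$rank <- seq_len(nrow(out))
  attr(out, "n_nodes") <- igraph::vcount(graph)
  attr(out, "n_edges") <- igraph::ecount(graph)
  out
}

#' Bar chart of hub-gene degrees
#'
#' @param hubs Tibble from [hub_genes()].
#' @return A ggplot object.
#' @export
plot_hub_degrees <- function(hubs) {
  ggplot2::ggplot(hubs, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$degree),
    y = .data$degree
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Degree (retained interactions)",
                  title = "Hub genes by degree") +
    ggplot2::theme_minimal()
}
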