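#' Bidirectional signature-reversal test for one drug
#'
#' Scores how strongly a drug perturbation signature opposes a disease DEG
#' signature: one hypergeometric tail p for the overlap between the drug's
#' down-regulated genes and the disease's up-regulated DEGs (`p_up_rev`),
#' and one for the drug's up-regulated genes against the disease's
#' down-regulated DEGs (`p_down_rev`). Both disease sets and the signature
#' are restricted to the shared universe before testing. A drug is a
#' reversal candidate when either p is strictly below `alpha`. A drug with
#' an empty relevant direction scores p = 1 rather than being dropped, so
#' rankings stay total.
#'
#' @param degs A `deg_set` (the disease signature).
#' @param drug_id Drug identifier (for the output row).
#' @param up,down Character vectors: the drug's up-/down-regulated genes.
#' @param universe Character vector: genes eligible for overlap testing.
#' @param alpha Candidate threshold on either p (default 0.05, strict `<`).
#' @return One-row tibble: `drug_id`, `k_up`, `k_down`, `p_up_rev`,
#'   `p_down_rev`, `best_p`, `candidate`.
#' @export
reversal_test <- function(degs, drug_id, up, down, universe, alpha = 0.05) {
  stopifnot(inherits(degs, "deg_set"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("Empty universe for the reversal test.")
  N <- length(universe)
  dis_up <- intersect(degs$up, universe)
  dis_down <- intersect(degs$down, universe)
  drug_up <- intersect(unique(as.character(up)), universe)
  drug_down <- intersect(unique(as.character(down)), universe)
  k_up <- length(intersect(drug_down, dis_up))
  k_down <- length(intersect(drug_up, dis_down))
  p_up <- hypergeom_tail(N, length(drug_down), length(dis_up), k_up)
  p_down <- hypergeom_tail(N, length(drug_up), length(dis_down), k_down)
  tibble(
    drug_id = as.character(drug_id),
    k_up = k_up, k_down = k_down,
    p_up_rev = p_up, p_down_rev = p_down,
    best_p = min(p_up, p_down),
    candidate = (p_up < alpha) || (p_down < alpha)
  )
}

#' Screen a drug library for signature-reversal candidates
#'
#' Applies [reversal_test()] to every drug in the library against the
#' disease DEG signature, using one shared universe (the intersection of the
#' DE-tested universe and the library's universe) so that p-values are
#' comparable across drugs. Results are ranked by `best_p` ascending, ties
#' by drug id; no multiple-testing correction enters the candidate call
#' (the conventional raw either-p < alpha rule), but a BH-adjusted `bh_q`
#' on `best_p` is emitted for information.
#'
#' @param degs A `deg_set`.
#' @param library A [drug_library()].
#' @param alpha Candidate threshold (default 0.05).
#' @param universe Optional explicit universe override.
#' @return A tibble of [reversal_test()] rows plus `bh_q` and `rank`.
#' @export
#' @examples
#' lib <- drug_library(tibble::tibble(
#'   drug_id = "d1", up = list("g9"), down = list(c("g1", "g2"))
#' ), universe = paste0("g", 1:10))
#' degs <- deg_set(up = c("g1", "g2"), down = "g9",
#'                 universe = paste0("g", 1:10))
#' screen_drugs(degs, lib)
screen_drugs <- function(degs, library, alpha = 0.05, universe = NULL) {
  stopifnot(inherits(degs, "deg_set"), inherits(library, "drug_library"))
  if (nrow(library$signatures) == 0) abort("Empty drug library.")
  universe <- universe %||% intersect(degs$universe, library$universe)
  if (length(universe) == 0) {
    abort("DEG universe and drug-library universe do not overlap.")
  }
  sig <- library$signatures
  out <- purrr::pmap(list(sig$drug_id, sig$up, sig$down),
                     function(id, up, down) {
                       reversal_test(degs, id, up, down, universe,
                                     alpha = alpha)
                     }) |>
    purrr::list_rbind()
  out$bh_q <- bh_adjust(out$best_p)
  out <- out[order(out$best_p, out$drug_id), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Rank drugs that reverse one disease gene
#'
#' The per-gene query pattern used for a prognostic hub gene: restrict to
#' drugs whose opposite-direction signature contains the gene (for a disease
#' up-regulated gene, drugs that down-regulate it), and rank them by the
#' corresponding directional reversal p-value from a full library screen.
#'
#' @param gene_id The disease gene of interest.
#' @param direction Its disease direction, `"up"` or `"down"`.
#' @param library A [drug_library()].
#' @param degs A `deg_set` containing the gene's universe.
#' @param top_n Rows to return (default 10).
#' @param alpha Candidate threshold passed to the screen.
#' @return A tibble `gene`, `drug_id`, `p_value` (the directional reversal
#'   p), `candidate`, at most `top_n` rows, p ascending. Empty (with a
#'   message) if no drug signature contains the gene.
#' @export
drugs_for_gene <- function(gene_id, direction = c("up", "down"), library,
                           degs, top_n = 10, alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(inherits(library, "drug_library"))
  gene_id <- as.character(gene_id)
  scores <- screen_drugs(degs, library, alpha = alpha)
  sig <- library$signatures
  opposite <- if (direction == "up") sig$down else sig$up
  carrier <- sig$drug_id[vapply(opposite, function(g) gene_id %in% g, TRUE)]
  if (length(carrier) == 0) {
    inform(sprintf("Gene '%s' appears in no drug %s-signature.",
                   gene_id, if (direction == "up") "down" else "up"))
    return(tibble(gene = character(), drug_id = character(),
                  p_value = numeric(), candidate = logical()))
  }
  rel <- scores[scores$drug_id %in% carrier, ]
  rel$p_value <- if (direction == "up") rel$p_up_rev else rel$p_down_rev
  rel <- rel[order(rel$p_value, rel$drug_id), ]
  out <- tibble(gene = gene_id, drug_id = rel$drug_id,
                p_value = rel$p_value, candidate = rel$candidate)
  head(out, top_n)
}
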