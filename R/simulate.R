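#' Simulate a two-group negative-binomial count matrix with planted DEGs
#'
#' Draws gene-wise counts from a negative binomial with mean `base_mean` and
#' overdispersion `dispersion` (variance \eqn{\mu + \alpha\mu^2}). The first
#' `n_up` genes get their case-group mean multiplied by `2^lfc` and the next
#' `n_down` genes by `2^-lfc`, planting a known directional signature; all
#' remaining genes are null. Fully deterministic given `seed`.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per group (>= 2 each).
#' @param base_mean Baseline NB mean (default 100).
#' @param dispersion NB overdispersion alpha (default 0.1).
#' @param n_up,n_down Number of planted up-/down-regulated genes.
#' @param lfc Planted log2 fold change (> 0 when any gene is planted).
#' @param seed Integer seed; required.
#' @param gene_ids Optional gene ids (default `g0001`, ...).
#' @param prefix Sample-id prefix pair, case then control.
#' @return List with `counts` (a [count_matrix()]) and `truth`, a list
#'   recording `de_genes_up`, `de_genes_down`, `planted_lfc` (named vector)
#'   and `seed`.
#' @export
simulate_counts <- function(n_genes, n_case, n_control, base_mean = 100,
                            dispersion = 0.1, n_up = 0, n_down = 0, lfc = 0,
                            seed, gene_ids = NULL,
                            prefix = c("case", "ctrl")) {
  stopifnot(dispersion > 0, n_up + n_down <= n_genes, n_up >= 0, n_down >= 0)
  if (n_case < 2 || n_control < 2) abort("Need >= 2 samples per group.")
  if ((n_up + n_down) > 0 && lfc <= 0) abort("Planted genes require lfc > 0.")
  gene_ids <- gene_ids %||% sprintf("g%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  up_genes <- gene_ids[seq_len(n_up)]
  down_genes <- gene_ids[n_up + seq_len(n_down)]

  mu_control <- rep(base_mean, n_genes)
  mu_case <- mu_control
  mu_case[seq_len(n_up)] <- base_mean * 2^lfc
  mu_case[n_up + seq_len(n_down)] <- base_mean * 2^-lfc

  size <- 1 / dispersion
  withr::local_seed(seed)
  counts <- cbind(
    matrix(rnbinom(n_genes * n_case, mu = rep(mu_case, n_case), size = size),
           nrow = n_genes),
    matrix(rnbinom(n_genes * n_control, mu = rep(mu_control, n_control),
                   size = size), nrow = n_genes)
  )
  rownames(counts) <- gene_ids
  colnames(counts) <- c(sprintf("%s_%03d", prefix[1], seq_len(n_case)),
                        sprintf("%s_%03d", prefix[2], seq_len(n_control)))
  group <- rep(c("case", "control"), c(n_case, n_control))
  truth <- list(
    de_genes_up = up_genes,
    de_genes_down = down_genes,
    planted_lfc = setNames(c(rep(lfc, n_up), rep(-lfc, n_down)),
                           c(up_genes, down_genes)),
    seed = seed
  )
  list(counts = count_matrix(counts, group), truth = truth)
}

#' Simulate two independent cohorts sharing planted DEGs
#'
#' Generates two count matrices with independent noise but identical planted
#' truth, the setting of a two-cohort consensus analysis. Optionally plants
#' extra "decoy" DE genes only in the first cohort; a direction-consistent
#' intersection downstream should recover only the shared genes.
#'
#' @param n_genes Genes (shared namespace).
#' @param sizes1,sizes2 Length-2 integer vectors `c(n_case, n_control)`.
#' @param n_up,n_down Shared planted genes per direction.
#' @param n_up_only1,n_down_only1 Extra genes planted only in cohort 1.
#' @param base_mean,dispersion,lfc As in [simulate_counts()].
#' @param seed Integer seed; the two cohorts use seeds derived from it.
#' @return List with `cohort1`, `cohort2` (each a [count_matrix()]) and
#'   `truth` (the shared planted sets plus the cohort-1-only extras).
#' @export
simulate_two_datasets <- function(n_genes, sizes1 = c(10, 10),
                                  sizes2 = c(10, 10), n_up = 0, n_down = 0,
                                  n_up_only1 = 0, n_down_only1 = 0,
                                  base_mean = 100, dispersion = 0.1, lfc = 0,
                                  seed) {
  total_planted <- n_up + n_down + n_up_only1 + n_down_only1
  stopifnot(total_planted <= n_genes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  withr::local_seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2)

  # cohort 1 plants shared + cohort-1-only genes; gene order puts all up
  # genes (shared then extra) first so simulate_counts's leading-block rule
  # plants the right ids
  order1 <- c(seq_len(n_up),                                  # shared up
              n_up + n_down + seq_len(n_up_only1),            # extra up
              n_up + seq_len(n_down),                         # shared down
              n_up + n_down + n_up_only1 + seq_len(n_down_only1),
              setdiff(seq_len(n_genes),
                      seq_len(n_up + n_down + n_up_only1 + n_down_only1)))
  sim1 <- simulate_counts(
    n_genes, sizes1[1], sizes1[2], base_mean, dispersion,
    n_up = n_up + n_up_only1, n_down = n_down + n_down_only1, lfc = lfc,
    seed = seeds[1], gene_ids = gene_ids[order1],
    prefix = c("c1case", "c1ctrl")
  )
  sim2 <- simulate_counts(
    n_genes, sizes2[1], sizes2[2], base_mean, dispersion,
    n_up = n_up, n_down = n_down, lfc = lfc, seed = seeds[2],
    gene_ids = gene_ids, prefix = c("c2case", "c2ctrl")
  )
  truth <- list(
    de_genes_up = gene_ids[seq_len(n_up)],
    de_genes_down = gene_ids[n_up + seq_len(n_down)],
    up_only1 = gene_ids[n_up + n_down + seq_len(n_up_only1)],
    down_only1 = gene_ids[n_up + n_down + n_up_only1 + seq_len(n_down_only1)],
    lfc = lfc,
    seed = seed
  )
  list(cohort1 = sim1$counts, cohort2 = sim2$counts, truth = truth)
}

#' Simulate survival times driven by one gene's expression
#'
#' Event times are exponential with hazard
#' \eqn{h_0 \exp(\beta z)} where \eqn{z = 1} for samples whose expression
#' exceeds the median and 0 otherwise — the dichotomised-covariate model the
#' median-split log-rank screen targets. Censoring is independent
#' exponential, calibrated so each subject is censored with probability
#' `censor_rate` regardless of group (censoring hazard
#' \eqn{h_i \cdot r/(1-r)}).
#'
#' @param expression Named numeric vector of the driving gene's expression,
#'   one value per sample (names become sample ids).
#' @param beta Log hazard ratio of high vs low expression.
#' @param baseline_hazard Baseline exponential hazard \eqn{h_0 > 0}
#'   (default 0.002 per day, median survival ~ 1 year in the low group).
#' @param censor_rate Probability of censoring, in `[0, 1)` (default 0.2).
#' @param seed Integer seed.
#' @return A [clinical_table()] tibble.
#' @export
simulate_survival <- function(expression, beta, baseline_hazard = 0.002,
                              censor_rate = 0.2, seed) {
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be positive.")
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must be in [0, 1).")
  n <- length(expression)
  ids <- names(expression) %||% sprintf("s%04d", seq_len(n))
  z <- as.numeric(expression > median(expression))
  rate <- baseline_hazard * exp(beta * z)
  withr::local_seed(seed)
  t_event <- rexp(n, rate)
  if (censor_rate > 0) {
    t_cens <- rexp(n, rate * censor_rate / (1 - censor_rate))
  } else {
    t_cens <- rep(Inf, n)
  }
  clinical_table(tibble(
    sample_id = ids,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  ))
}

#' Simulate a background interaction network with planted hubs
#'
#' An Erdős–Rényi background (`background_edge_prob` per pair) plus planted
#' hub genes wired to `hub_degree` random partners each. Planted hub edges
#' carry combined scores sampled uniformly in `[0.7, 1]` (so a 0.7 score
#' threshold never severs them); background edges carry mixed scores uniform
#' in `[0.4, 1]`.
#'
#' @param n_genes Number of nodes (ids `g0001`, ... unless `gene_ids` given).
#' @param background_edge_prob Per-pair edge probability of the background.
#' @param hub_ids Character vector of genes to plant as hubs (must be among
#'   the nodes).
#' @param hub_degree Partners per planted hub (< `n_genes`).
#' @param seed Integer seed.
#' @param gene_ids Optional node ids.
#' @param partner_pool Nodes eligible as hub partners (default: all nodes).
#'   Restricting the pool (e.g. to planted disease genes) keeps the hub's
#'   degree inside a downstream whitelist.
#' @return A canonical edge tibble (see [edge_list()]).
#' @export
simulate_network <- function(n_genes, background_edge_prob = 0.01,
                             hub_ids = character(), hub_degree = 0, seed,
                             gene_ids = NULL, partner_pool = NULL) {
  gene_ids <- gene_ids %||% sprintf("g%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  if (hub_degree >= n_genes) abort("`hub_degree` must be < `n_genes`.")
  stopifnot(all(hub_ids %in% gene_ids))
  partner_pool <- partner_pool %||% gene_ids
  stopifnot(all(partner_pool %in% gene_ids))
  withr::local_seed(seed)

  g <- igraph::sample_gnp(n_genes, background_edge_prob)
  bg <- igraph::as_edgelist(g)
  a <- gene_ids[bg[, 1]]
  b <- gene_ids[bg[, 2]]
  score <- runif(length(a), 0.4, 1)

  for (hub in hub_ids) {
    partners <- sample(setdiff(partner_pool, hub), hub_degree)
    a <- c(a, rep(hub, hub_degree))
    b <- c(b, partners)
    score <- c(score, runif(hub_degree, 0.7, 1))
  }
  edge_list(tibble(gene_a = a, gene_b = b, combined_score = score))
}

#' Simulate a CREEDS-style drug-signature library with planted reversers
#'
#' Decoy drugs draw disjoint up/down sets uniformly from the universe.
#' Planted drugs oppose the disease signature: a fraction
#' `overlap_fraction` of their down set is sampled from the disease's
#' up-regulated genes and of their up set from the disease's down-regulated
#' genes, the remainder from unrelated universe genes.
#'
#' @param n_drugs Total drugs (decoys + planted).
#' @param sig_size Genes per direction per drug.
#' @param universe Character vector of eligible genes.
#' @param disease_up,disease_down The planted disease signature the planted
#'   drugs should reverse.
#' @param planted_ids Drug ids to plant (default none; decoys are
#'   `drug_0001`, ...).
#' @param overlap_fraction Fraction of each planted direction drawn from the
#'   opposing disease set, in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `library` (a [drug_library()] with
#'   `universe = universe`) and `truth` (`reversal_drugs`, `seed`).
#' @export
simulate_drug_library <- function(n_drugs, sig_size, universe,
                                  disease_up = character(),
                                  disease_down = character(),
                                  planted_ids = character(),
                                  overlap_fraction = 1, seed) {
  universe <- unique(as.character(universe))
  if (2 * sig_size > length(universe)) {
    abort("`sig_size` too large for the universe (need 2*sig_size distinct genes).")
  }
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            length(planted_ids) <= n_drugs)
  n_decoy <- n_drugs - length(planted_ids)
  ids <- c(sprintf("drug_%04d", seq_len(n_decoy)), planted_ids)
  withr::local_seed(seed)

  draw_planted <- function(target_opposed, other_sets) {
    n_hit <- min(round(overlap_fraction * sig_size), length(target_opposed))
    hit <- sample(target_opposed, n_hit)
    rest_pool <- setdiff(universe, c(target_opposed, other_sets, hit))
    c(hit, sample(rest_pool, sig_size - n_hit))
  }
  up <- vector("list", n_drugs)
  down <- vector("list", n_drugs)
  for (i in seq_len(n_drugs)) {
    if (i <= n_decoy) {
      both <- sample(universe, 2 * sig_size)
      up[[i]] <- both[seq_len(sig_size)]
      down[[i]] <- both[sig_size + seq_len(sig_size)]
    } else {
      down[[i]] <- draw_planted(disease_up, disease_down)
      up[[i]] <- draw_planted(disease_down, c(disease_up, down[[i]]))
    }
  }
  lib <- drug_library(tibble(drug_id = ids, up = up, down = down),
                      universe = universe)
  list(library = lib, truth = list(reversal_drugs = planted_ids, seed = seed))
}

#' Simulate a complete planted study
#'
#' Generates every input of the end-to-end pipeline with known ground truth:
#' two case-control count cohorts sharing planted DEGs (a larger
#' registry-style cohort and a small 10-vs-10 cohort), an interaction
#' network whose planted hubs are wired into the planted DEG module, a
#' clinical table whose hazard follows the first hub gene (the planted
#' prognostic gene), a drug library with planted reversal drugs, and a
#' gene-set collection containing the planted disease module among decoy
#' sets.
#'
#' @param seed Integer seed driving every component.
#' @param n_genes Genes in the shared namespace (default 2000).
#' @param sizes1,sizes2 Cohort sizes (default 100/50 and 10/10).
#' @param n_up,n_down Planted DEGs per direction (default 60 each).
#' @param lfc,base_mean,dispersion NB parameters (defaults 3, 100, 0.1).
#' @param n_hubs Planted hubs, drawn from the planted up genes (default 5).
#' @param hub_degree Planted hub degree (default 30).
#' @param background_edge_prob Background edge probability (default
#'   `2/(n_genes-1)`, mean background degree 2).
#' @param beta Log hazard ratio of the prognostic gene (default `log(4)`).
#' @param censor_rate Censoring probability (default 0.2).
#' @param n_drugs,sig_size,n_planted_drugs Drug library shape (defaults
#'   249, 50, 3).
#' @param overlap_fraction Planted drugs' reversal overlap (default 1).
#' @param n_gene_sets Decoy gene sets for the enrichment stage (default 20).
#' @return List: `cohort1`, `cohort2`, `edges`, `clinical`, `drug_library`,
#'   `gene_sets`, `truth` (planted DEGs, hubs, prognostic gene, reversal
#'   drugs, seed).
#' @export
simulate_study <- function(seed, n_genes = 2000, sizes1 = c(100, 50),
                           sizes2 = c(10, 10), n_up = 60, n_down = 60,
                           lfc = 3, base_mean = 100, dispersion = 0.1,
                           n_hubs = 5, hub_degree = 30,
                           background_edge_prob = 2 / (n_genes - 1),
                           beta = log(4), censor_rate = 0.2, n_drugs = 249,
                           sig_size = 50, n_planted_drugs = 3,
                           overlap_fraction = 1, n_gene_sets = 20) {
  withr::local_seed(seed)
  seeds <- sample.int(.Machine$integer.max, 5)

  cohorts <- simulate_two_datasets(
    n_genes, sizes1 = sizes1, sizes2 = sizes2, n_up = n_up, n_down = n_down,
    base_mean = base_mean, dispersion = dispersion, lfc = lfc,
    seed = seeds[1]
  )
  truth <- cohorts$truth
  planted <- c(truth$de_genes_up, truth$de_genes_down)
  stopifnot(n_hubs <= n_up)
  hubs <- truth$de_genes_up[seq_len(n_hubs)]

  edges <- simulate_network(
    n_genes, background_edge_prob = background_edge_prob, hub_ids = hubs,
    hub_degree = hub_degree, seed = seeds[2],
    gene_ids = sprintf("g%04d", seq_len(n_genes)), partner_pool = planted
  )

  expr <- normalized_log_expression(cohorts$cohort1)
  case_samples <- names(cohorts$cohort1$group)[cohorts$cohort1$group == "case"]
  if (length(hubs) > 0) {
    prognostic <- hubs[1]
    clinical <- simulate_survival(expr[prognostic, case_samples],
                                  beta = beta, censor_rate = censor_rate,
                                  seed = seeds[3])
  } else {
    # null scenario: survival independent of every gene
    prognostic <- NULL
    clinical <- simulate_survival(expr[1, case_samples], beta = 0,
                                  censor_rate = censor_rate, seed = seeds[3])
  }

  drugs <- simulate_drug_library(
    n_drugs, sig_size, universe = sprintf("g%04d", seq_len(n_genes)),
    disease_up = truth$de_genes_up, disease_down = truth$de_genes_down,
    planted_ids = sprintf("planted_drug_%d", seq_len(n_planted_drugs)),
    overlap_fraction = overlap_fraction, seed = seeds[4]
  )

  withr::local_seed(seeds[5])
  sets <- setNames(
    lapply(seq_len(n_gene_sets),
           function(i) sample(sprintf("g%04d", seq_len(n_genes)), 100)),
    sprintf("decoy_set_%02d", seq_len(n_gene_sets))
  )
  if (length(planted) > 0) sets$planted_module <- planted
  gene_sets <- gene_set_collection(sets)

  truth$hub_genes <- hubs
  truth$prognostic_gene <- list(gene = prognostic, beta = beta)
  truth$reversal_drugs <- drugs$truth$reversal_drugs
  truth$seed <- seed
  list(cohort1 = cohorts$cohort1, cohort2 = cohorts$cohort2, edges = edges,
       clinical = clinical, drug_library = drugs$library,
       gene_sets = gene_sets, truth = truth)
}
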