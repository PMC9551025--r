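#' Run the full repurposing workflow from a single configuration
#'
#' Orchestrates the complete analysis: differential expression on two
#' cohorts, direction-consistent DEG intersection, over-representation
#' analysis, score-thresholded interaction subnetwork with degree-ranked
#' hubs, median-split log-rank survival screening of the hubs, the
#' signature-reversal drug screen, and per-gene drug queries for every
#' survival-significant hub. All stage tables are written as TSV under
#' `out_dir` together with a JSON run report; identical config + seed gives
#' identical outputs.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Recognised entries:
#'   \describe{
#'     \item{`seed`}{Integer seed (required with a `simulate` block).}
#'     \item{`simulate`}{Named list of [simulate_study()] arguments (minus
#'       `seed`); when present, inputs are generated rather than read.}
#'     \item{`counts1`, `groups1`, `counts2`, `groups2`}{Paths to the two
#'       cohorts' count TSVs and their sample->group TSVs (columns
#'       `sample_id`, `group`).}
#'     \item{`edges`, `clinical`, `drug_library`, `gene_sets`}{Paths to the
#'       interaction TSV, clinical TSV, drug-signature GMT and (optional)
#'       gene-set GMT.}
#'     \item{`thresholds`}{Optional overrides: `p_cut` (0.001), `lfc_cut`
#'       (2), `min_score` (0.7), `alpha` (0.05), `top_hubs` (10),
#'       `top_drugs_per_gene` (10).}
#'     \item{`out_dir`}{Output directory (required).}
#'   }
#' @return The run report, invisibly: a list with stage counts, the hub
#'   table, survival screen, candidate drugs and per-gene drug tables, also
#'   written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% abort("Config needs an `out_dir`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- utils::modifyList(
    list(p_cut = 0.001, lfc_cut = 2, min_score = 0.7, alpha = 0.05,
         top_hubs = 10, top_drugs_per_gene = 10),
    config$thresholds %||% list()
  )

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      if (is.null(config$seed)) abort("A `simulate` block requires a `seed`.")
      do.call(simulate_study, c(list(seed = config$seed), config$simulate))
    } else {
      read_group <- function(path) {
        df <- readr::read_tsv(path, col_types = readr::cols(),
                              progress = FALSE, show_col_types = FALSE)
        setNames(as.character(df$group), as.character(df$sample_id))
      }
      list(
        cohort1 = read_counts(config$counts1, read_group(config$groups1)),
        cohort2 = read_counts(config$counts2, read_group(config$groups2)),
        edges = read_edges(config$edges),
        clinical = read_clinical(config$clinical),
        drug_library = read_drug_library(config$drug_library),
        gene_sets = if (!is.null(config$gene_sets)) read_gmt(config$gene_sets),
        truth = NULL
      )
    }
  })

  de1 <- stage("deg", de_test(inputs$cohort1))
  de2 <- stage("deg", de_test(inputs$cohort2))
  degs1 <- filter_degs(de1, th$p_cut, th$lfc_cut)
  degs2 <- filter_degs(de2, th$p_cut, th$lfc_cut)
  inter <- stage("intersect", intersect_degs(degs1, degs2))

  enrich <- if (!is.null(inputs$gene_sets) &&
                (length(inter$up) + length(inter$down)) > 0) {
    stage("enrichment", ora_degs(inter, inputs$gene_sets))
  }

  degs_all <- union(inter$up, inter$down)
  hubs <- stage("network", {
    if (length(degs_all) == 0) {
      tibble(gene = character(), degree = integer(), rank = integer())
    } else {
      g <- build_network(inputs$edges, degs_all, min_score = th$min_score)
      hub_genes(g, top_n = th$top_hubs)
    }
  })

  surv <- stage("survival", {
    if (nrow(hubs) == 0) {
      tibble(gene = character(), n = integer(), n_high = integer(),
             n_low = integer(), statistic = numeric(), p_value = numeric(),
             bh_q = numeric(), significant = logical())
    } else {
      gene_survival_screen(inputs$cohort1, inputs$clinical, hubs$gene)
    }
  })

  drugs <- stage("repurposing", {
    if (length(degs_all) == 0) {
      tibble(drug_id = character(), k_up = integer(), k_down = integer(),
             p_up_rev = numeric(), p_down_rev = numeric(),
             best_p = numeric(), candidate = logical(), bh_q = numeric(),
             rank = integer())
    } else {
      screen_drugs(inter, inputs$drug_library, alpha = th$alpha)
    }
  })

  sig_hubs <- surv$gene[surv$significant]
  per_gene <- stage("drugs_for_gene", {
    purrr::map(sig_hubs, function(g) {
      dir <- if (g %in% inter$up) "up" else if (g %in% inter$down) "down"
      else return(NULL)
      drugs_for_gene(g, dir, inputs$drug_library, inter,
                     top_n = th$top_drugs_per_gene, alpha = th$alpha)
    }) |> purrr::list_rbind()
  })

  wr <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      flat <- df
      for (col in names(flat)) {
        if (is.list(flat[[col]])) {
          flat[[col]] <- vapply(flat[[col]], paste, "", collapse = ";")
        }
      }
      readr::write_tsv(flat, file.path(out_dir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
  }
  wr(de1, "de_cohort1"); wr(de2, "de_cohort2")
  wr(tidy(inter), "degs_intersected")
  wr(enrich, "enrichment")
  wr(hubs, "hub_genes")
  wr(surv, "survival_screen")
  wr(drugs, "drug_screen")
  wr(per_gene, "drugs_for_significant_hubs")

  report <- list(
    seed = config$seed,
    thresholds = th,
    n_degs_cohort1 = list(up = length(degs1$up), down = length(degs1$down)),
    n_degs_cohort2 = list(up = length(degs2$up), down = length(degs2$down)),
    n_degs_intersected = list(up = length(inter$up),
                              down = length(inter$down)),
    network = list(n_nodes = attr(hubs, "n_nodes") %||% 0L,
                   n_edges = attr(hubs, "n_edges") %||% 0L),
    hub_genes = hubs$gene,
    significant_hubs = sig_hubs,
    n_candidate_drugs = sum(drugs$candidate),
    candidate_drugs = drugs$drug_id[drugs$candidate]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(report = report, de1 = de1, de2 = de2, degs1 = degs1,
                 degs2 = degs2, intersected = inter, enrichment = enrich,
                 hubs = hubs, survival = surv, drugs = drugs,
                 drugs_per_gene = per_gene, truth = inputs$truth))
}

#' Volcano plot of a differential-expression table
#'
#' @param de Tibble from [de_test()].
#' @param p_cut,lfc_cut Thresholds drawn as guides and used to colour
#'   significant genes (defaults 0.001 and 2).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, p_cut = 0.001, lfc_cut = 2) {
  df <- de[de$tested & !is.na(de$p_value), ]
  df$call <- "not significant"
  df$call[df$p_value < p_cut & df$log2_fc >= lfc_cut] <- "up"
  df$call[df$p_value < p_cut & df$log2_fc <= -lfc_cut] <- "down"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            "not significant" = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 p-value", colour = NULL) +
    ggplot2::theme_minimal()
}
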