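#' Kaplan-Meier product-limit estimate
#'
#' The standard nonparametric survival estimator under independent
#' censoring: at each observed death time \eqn{t_j} with \eqn{d_j} deaths
#' among \eqn{n_j} at risk, the survival probability is multiplied by
#' \eqn{1 - d_j/n_j}. Censored times shrink later risk sets but contribute no
#' factor; at tied times, deaths are processed before censorings (a subject
#' censored at \eqn{t} is still at risk for a death at \eqn{t}). With no
#' censoring the curve equals 1 minus the empirical CDF of the death times.
#'
#' @param clinical A [clinical_table()] tibble (`sample_id`, `time`, `event`)
#'   with at least one record.
#' @return An object of class `km_curve`: list with `time` (ascending
#'   distinct death times), `survival`, `n_risk`, `n_event`, `n_censor`
#'   (censorings in `[t_j, t_{j+1})`), and `n_total`.
#' @export
#' @examples
#' cl <- tibble::tibble(sample_id = letters[1:4], time = 1:4,
#'                      event = c(1, 0, 1, 1))
#' km <- km_estimate(cl)
#' tidy(km)
km_estimate <- function(clinical) {
  clinical <- clinical_table(clinical)
  if (nrow(clinical) == 0) abort("Clinical table has no records.")
  death_times <- sort(unique(clinical$time[clinical$event == 1]))
  n_total <- nrow(clinical)
  n_risk <- integer(length(death_times))
  n_event <- integer(length(death_times))
  surv <- numeric(length(death_times))
  s <- 1
  for (j in seq_along(death_times)) {
    t <- death_times[j]
    n_risk[j] <- sum(clinical$time >= t)  # ties: censored at t still at risk
    n_event[j] <- sum(clinical$time == t & clinical$event == 1)
    s <- s * (1 - n_event[j] / n_risk[j])
    surv[j] <- s
  }
  brk <- c(death_times, Inf)
  n_censor <- vapply(seq_along(death_times), function(j) {
    sum(clinical$event == 0 & clinical$time >= brk[j] &
          clinical$time < brk[j + 1])
  }, integer(1))
  structure(list(time = death_times, survival = surv, n_risk = n_risk,
                 n_event = n_event, n_censor = n_censor, n_total = n_total),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d death times; final S = %.3f\n",
              x$n_total, length(x$time),
              if (length(x$survival)) x$survival[length(x$survival)] else 1))
  invisible(x)
}

#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) {
  tibble(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
         n_censor = x$n_censor, survival = x$survival)
}

#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  tibble(n_total = x$n_total, n_events = sum(x$n_event),
         median_survival = median_survival(x))
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest death time at which the estimated survival drops to 0.5 or
#' below. `NA` when the curve never reaches 0.5 (the median is then not
#' identified).
#'
#' @param km A `km_curve` from [km_estimate()].
#' @return A single time, or `NA_real_`.
#' @export
median_survival <- function(km) {
  stopifnot(inherits(km, "km_curve"))
  at <- which(km$survival <= 0.5)
  if (length(at) == 0) NA_real_ else km$time[min(at)]
}

#' Step plot of one or more Kaplan-Meier curves
#'
#' @param object A `km_curve`, or a named list of them (e.g. the high/low
#'   expression strata).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  autoplot_km_list(list(all = object))
}

#' @rdname autoplot.km_curve
#' @param curves Named list of `km_curve` objects.
#' @export
autoplot_km_list <- function(curves) {
  df <- purrr::imap(curves, function(km, nm) {
    td <- tidy(km)
    # prepend the (0, 1) origin so the step starts at full survival
    dplyr::bind_rows(tibble(time = 0, survival = 1),
                     td[, c("time", "survival")]) |>
      dplyr::mutate(stratum = nm)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' The standard O-E chi-square test: at each pooled death time the observed
#' deaths in group 1 are compared with the expectation under the null of a
#' common hazard, with the hypergeometric variance of the 2x2 risk table;
#' the summed discrepancy squared over the summed variance is referred to a
#' 1-df chi-square. Symmetric under swapping the two groups.
#'
#' @param group Character/factor with exactly two levels, one per clinical
#'   record (aligned with `clinical` rows, or named by sample id).
#' @param clinical A [clinical_table()] tibble.
#' @return An object of class `logrank_result`: `statistic`, `p_value`, and
#'   a per-group tibble of `n`, `observed`, `expected`.
#' @export
logrank_test <- function(group, clinical) {
  clinical <- clinical_table(clinical)
  if (!is.null(names(group))) {
    missing <- setdiff(clinical$sample_id, names(group))
    if (length(missing) > 0) {
      abort(paste0("Group label missing for sample(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    group <- group[clinical$sample_id]
  }
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) abort("Exactly two groups are required.")
  if (any(table(group) == 0)) abort("One group has no subjects.")
  if (sum(clinical$event) == 0) abort("No events observed in the pooled data.")

  g1 <- group == levels(group)[1]
  death_times <- sort(unique(clinical$time[clinical$event == 1]))
  o_minus_e <- 0
  v_sum <- 0
  o1 <- 0; e1 <- 0
  for (t in death_times) {
    at_risk <- clinical$time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(clinical$time == t & clinical$event == 1)
    d1_j <- sum(clinical$time == t & clinical$event == 1 & g1)
    e_j <- d_j * n1_j / n_j
    v_j <- if (n_j > 1) {
      d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    } else 0
    o1 <- o1 + d1_j
    e1 <- e1 + e_j
    o_minus_e <- o_minus_e + (d1_j - e_j)
    v_sum <- v_sum + v_j
  }
  stat <- if (v_sum > 0) o_minus_e^2 / v_sum else 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  d_total <- sum(clinical$event)
  structure(list(
    statistic = stat,
    p_value = p,
    groups = tibble(
      group = levels(group),
      n = as.integer(table(group)),
      observed = c(o1, d_total - o1),
      expected = c(e1, d_total - e1)
    )
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4f (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @method tidy logrank_result
#' @export
tidy.logrank_result <- function(x, ...) x$groups

#' @method glance logrank_result
#' @export
glance.logrank_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = 1, p_value = x$p_value)
}

#' Median-split expression labels
#'
#' Dichotomises an expression vector at its median: strictly greater than the
#' median is `"high"`, everything else (including values tied with the
#' median) is `"low"`. Errors on a constant vector, where no split exists.
#'
#' @param expr Numeric vector, optionally named by sample; length >= 2.
#' @return Character vector of `"high"`/`"low"`, same names as `expr`.
#' @export
dichotomize_by_median <- function(expr) {
  if (length(expr) < 2) abort("Need >= 2 samples to dichotomise.")
  if (anyNA(expr)) abort("Missing expression values.")
  med <- median(expr)
  lab <- ifelse(expr > med, "high", "low")
  if (length(unique(lab)) < 2) {
    abort("Expression vector cannot be split at its median (constant or degenerate).")
  }
  names(lab) <- names(expr)
  lab
}

#' Log-rank survival screen over a gene list
#'
#' For each gene: take its normalized log2 expression across the samples
#' shared between the expression data and the clinical table, split samples
#' at the median ([dichotomize_by_median()]), and compare high vs low
#' survival with [logrank_test()]. Raw p-values drive the 0.05 significance
#' call, matching the usual single-gene reporting convention; a BH column is
#' emitted for information only.
#'
#' @param expr A [count_matrix()] (normalized internally) or a numeric
#'   expression matrix, genes x samples.
#' @param clinical A [clinical_table()] tibble.
#' @param genes Genes to screen (default: all rows of `expr`).
#' @return A tibble sorted by `p_value`: `gene`, `n`, `n_high`, `n_low`,
#'   `statistic`, `p_value`, `bh_q`, `significant` (raw p < 0.05). Genes
#'   absent from the matrix are skipped with a warning; genes that cannot be
#'   median-split or have no events get `NA` statistics.
#' @export
gene_survival_screen <- function(expr, clinical, genes = NULL) {
  if (inherits(expr, "count_matrix")) expr <- normalized_log_expression(expr)
  expr <- as.matrix(expr)
  clinical <- clinical_table(clinical)
  genes <- genes %||% rownames(expr)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0) {
    warn(paste0("Gene(s) absent from the expression matrix, skipped: ",
                paste(head(absent, 5), collapse = ", ")))
    genes <- setdiff(genes, absent)
  }
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (length(shared) < 2) {
    abort("Fewer than two samples shared between expression and clinical data.")
  }
  clinical <- clinical[match(shared, clinical$sample_id), ]
  rows <- purrr::map(genes, function(g) {
    ev <- expr[g, shared]
    res <- tryCatch({
      lab <- dichotomize_by_median(ev)
      lr <- logrank_test(lab, clinical)
      list(stat = lr$statistic, p = lr$p_value,
           n_high = sum(lab == "high"), n_low = sum(lab == "low"))
    }, error = function(e) list(stat = NA_real_, p = NA_real_,
                                n_high = NA_integer_, n_low = NA_integer_))
    tibble(gene = g, n = length(shared), n_high = res$n_high,
           n_low = res$n_low, statistic = res$stat, p_value = res$p)
  })
  out <- purrr::list_rbind(rows)
  out$bh_q <- bh_adjust(out$p_value)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out[order(out$p_value, out$gene), ]
}
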