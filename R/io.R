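#' Read a raw count table with group labels
#'
#' Reads a TSV or CSV whose first column holds gene ids and whose header holds
#' sample ids, and attaches case/control labels from `group_map`.
#'
#' @param path Path to a tab- or comma-separated counts file (delimiter
#'   auto-detected from the extension; `.csv` means comma, anything else tab).
#' @param group_map Named character vector mapping every sample id to
#'   `"case"` or `"control"`, or a data frame with columns `sample_id` and
#'   `group`.
#' @param require_groups Passed to [count_matrix()].
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, group_map, require_groups = TRUE) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2) abort("Counts file must have a gene column plus samples.")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) abort("Counts file has non-numeric count entries.")
  rownames(mat) <- genes
  if (is.data.frame(group_map)) {
    group_map <- setNames(as.character(group_map$group),
                          as.character(group_map$sample_id))
  }
  count_matrix(mat, group_map, require_groups = require_groups)
}

#' Write a count matrix to TSV
#'
#' @param x A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  df <- tibble::as_tibble(x$counts, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# ---- gene set collections (GMT) ----------------------------------------

new_gene_set_collection <- function(sets, description = NULL) {
  if (is.null(description)) {
    description <- setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description),
            class = "gene_set_collection")
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene members). Names must be
#'   unique, members are deduplicated and must be non-empty.
#' @param description Optional named character vector of set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("Gene set names must be present and unique.")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    abort(paste0("Empty gene set(s): ", paste(empty, collapse = ", ")))
  }
  new_gene_set_collection(sets, description)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @method tidy gene_set_collection
#' @export
tidy.gene_set_collection <- function(x, ...) {
  tibble(
    set_name = rep(names(x$sets), lengths(x$sets)),
    gene = unlist(x$sets, use.names = FALSE)
  )
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Members are deduplicated; an empty
#' file yields an empty collection.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(new_gene_set_collection(setNames(list(), character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.",
                  short[1]))
  }
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    abort(paste0("Duplicated set name(s) in GMT: ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  desc <- setNames(vapply(fields, `[[`, "", 2), nm)
  sets <- setNames(lapply(fields, function(f) unique(f[-(1:2)])), nm)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param x A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$description[[nm]] %||% "", x$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# ---- interaction edge lists --------------------------------------------

#' Construct a validated interaction edge list
#'
#' Canonicalises an undirected weighted edge list: self-loops are dropped with
#' a warning, `(A,B)` and `(B,A)` collapse to one row (keeping the maximum
#' score on conflict), and scores on the STRING 0-1000 integer scale are
#' auto-detected (any score > 1) and divided by 1000. The normalisation is
#' idempotent: a list already on the 0-1 scale is left untouched.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `combined_score`
#'   (the first three columns are used positionally if names differ).
#' @return A tibble with columns `gene_a`, `gene_b` (lexicographically
#'   ordered within each row), `combined_score` in `[0, 1]`.
#' @export
edge_list <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3) abort("Edge table needs gene_a, gene_b, combined_score.")
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  s <- as.numeric(edges[[3]])
  if (anyNA(s)) abort("Non-numeric combined_score in edge table.")
  if (any(s < 0) || any(s > 1000)) {
    abort("combined_score outside [0, 1000].")
  }
  if (any(s > 1)) s <- s / 1000  # STRING exports 0-1000 integers
  loops <- a == b
  if (any(loops)) {
    warn(sprintf("Dropped %d self-loop edge(s).", sum(loops)))
    a <- a[!loops]; b <- b[!loops]; s <- s[!loops]
  }
  if (length(a) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  combined_score = numeric()))
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  tibble(gene_a = lo, gene_b = hi, combined_score = s) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(combined_score = max(.data$combined_score),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Read a STRING-style edge TSV
#'
#' Expects columns `gene_a`, `gene_b`, `combined_score` (header optional in
#' spirit: the first three columns are used). See [edge_list()] for the
#' dialect rules.
#'
#' @param path Path to a tab-separated edge file.
#' @return A canonical edge tibble.
#' @export
read_edges <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  edge_list(df)
}

#' Write an edge list to TSV
#' @param x Edge tibble from [edge_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

# ---- clinical survival tables ------------------------------------------

#' Validate a clinical survival table
#'
#' @param x Data frame with columns `sample_id`, `time` (non-negative,
#'   e.g. days of overall survival) and `event` (1 = death observed,
#'   0 = censored).
#' @return A validated tibble with exactly those columns.
#' @export
clinical_table <- function(x) {
  x <- as_tibble(x)
  need <- c("sample_id", "time", "event")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("Clinical table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- x[need]
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) abort("Duplicated sample ids in clinical table.")
  if (anyNA(x$time) || any(x$time < 0)) abort("Survival times must be >= 0.")
  if (!all(x$event %in% c(0, 1))) abort("`event` must be 0 (censored) or 1 (death).")
  x$event <- as.integer(x$event)
  x
}

#' Read a clinical survival TSV
#' @param path Path to a TSV with columns `sample_id`, `time`, `event`.
#' @return A validated clinical tibble.
#' @export
read_clinical <- function(path) {
  clinical_table(readr::read_tsv(path, col_types = readr::cols(),
                                 progress = FALSE, show_col_types = FALSE))
}

# ---- drug signature libraries ------------------------------------------

#' Construct a drug-signature library
#'
#' A CREEDS-style library: per drug, the genes up- and down-regulated by the
#' perturbation, plus the universe of genes eligible for overlap testing.
#'
#' @param signatures Tibble (or data frame) with columns `drug_id`, `up`,
#'   `down`; `up`/`down` are list-columns of character vectors.
#' @param universe Character vector of eligible genes. Defaults to the union
#'   of all signature genes.
#' @return An object of class `drug_library`.
#' @export
drug_library <- function(signatures, universe = NULL) {
  signatures <- as_tibble(signatures)
  stopifnot(all(c("drug_id", "up", "down") %in% names(signatures)))
  signatures$drug_id <- as.character(signatures$drug_id)
  if (anyDuplicated(signatures$drug_id)) {
    abort("Duplicated drug ids in signature library.")
  }
  signatures$up <- lapply(signatures$up, function(g) unique(as.character(g)))
  signatures$down <- lapply(signatures$down, function(g) unique(as.character(g)))
  for (i in seq_len(nrow(signatures))) {
    both <- intersect(signatures$up[[i]], signatures$down[[i]])
    if (length(both) > 0) {
      abort(sprintf("Drug '%s' lists gene(s) %s in both up and down sets.",
                    signatures$drug_id[i], paste(both, collapse = ", ")))
    }
  }
  all_genes <- unique(unlist(c(signatures$up, signatures$down)))
  if (is.null(universe)) {
    universe <- all_genes
  } else {
    universe <- unique(as.character(universe))
    outside <- setdiff(all_genes, universe)
    if (length(outside) > 0) {
      abort(paste0("Signature gene(s) outside the stated universe: ",
                   paste(head(outside, 5), collapse = ", ")))
    }
  }
  structure(list(signatures = signatures, universe = universe),
            class = "drug_library")
}

#' @export
print.drug_library <- function(x, ...) {
  cat(sprintf("<drug_library> %d drugs, universe of %d genes\n",
              nrow(x$signatures), length(x$universe)))
  invisible(x)
}

#' @export
length.drug_library <- function(x) nrow(x$signatures)

#' @method tidy drug_library
#' @export
tidy.drug_library <- function(x, ...) {
  sig <- x$signatures
  tibble(
    drug_id = rep(sig$drug_id, lengths(sig$up) + lengths(sig$down)),
    direction = unlist(purrr::map2(lengths(sig$up), lengths(sig$down),
                                   ~ c(rep("up", .x), rep("down", .y)))),
    gene = unlist(purrr::map2(sig$up, sig$down, c))
  )
}

#' Read a drug-signature library from suffixed GMT
#'
#' Each drug contributes two GMT sets named `<drug_id>_up` and
#' `<drug_id>_down`. A drug with only one direction present gets an empty set
#' for the other, with a warning.
#'
#' @param path Path to the GMT file.
#' @param universe Optional explicit universe; defaults to the union of all
#'   signature genes.
#' @return A [drug_library()].
#' @export
read_drug_library <- function(path, universe = NULL) {
  gsc <- read_gmt(path)
  nm <- names(gsc$sets)
  suffixed <- grepl("_(up|down)$", nm)
  if (any(!suffixed)) {
    abort(paste0("Drug library GMT set name(s) without _up/_down suffix: ",
                 paste(head(nm[!suffixed], 5), collapse = ", ")))
  }
  drug <- sub("_(up|down)$", "", nm)
  dir <- sub("^.*_(up|down)$", "\\1", nm)
  drugs <- unique(drug)
  up <- setNames(vector("list", length(drugs)), drugs)
  down <- setNames(vector("list", length(drugs)), drugs)
  for (i in seq_along(nm)) {
    if (dir[i] == "up") up[[drug[i]]] <- gsc$sets[[i]]
    else down[[drug[i]]] <- gsc$sets[[i]]
  }
  lonely <- drugs[vapply(drugs, function(d) is.null(up[[d]]) || is.null(down[[d]]),
                         TRUE)]
  if (length(lonely) > 0) {
    warn(paste0("Drug(s) with only one signature direction (other treated as ",
                "empty): ", paste(lonely, collapse = ", ")))
  }
  up <- lapply(up, function(g) g %||% character())
  down <- lapply(down, function(g) g %||% character())
  drug_library(tibble(drug_id = drugs, up = unname(up), down = unname(down)),
               universe = universe)
}

#' Write a drug-signature library to suffixed GMT
#' @param x A [drug_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_library <- function(x, path) {
  stopifnot(inherits(x, "drug_library"))
  sig <- x$signatures
  lines <- character(0)
  for (i in seq_len(nrow(sig))) {
    # GMT requires >= 1 member per line; an empty direction is encoded by
    # omitting its line and re-read as empty (with the lonely-drug warning)
    if (length(sig$up[[i]]) > 0) {
      lines <- c(lines, paste(c(paste0(sig$drug_id[i], "_up"), "",
                                sig$up[[i]]), collapse = "\t"))
    }
    if (length(sig$down[[i]]) > 0) {
      lines <- c(lines, paste(c(paste0(sig$drug_id[i], "_down"), "",
                                sig$down[[i]]), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
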