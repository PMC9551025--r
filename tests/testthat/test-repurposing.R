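make_degs20 <- function() {
  deg_set(up = paste0("g", 1:5), down = paste0("g", 6:10),
          universe = paste0("g", 1:20))
}

test_that("the reversal test reproduces enumerated hypergeometric values", {
  degs <- make_degs20()
  # drug.down overlaps disease.up in 3 of 5 genes
  r <- reversal_test(degs, "d1", up = character(),
                     down = c("g1", "g2", "g3", "g16", "g17"),
                     universe = degs$universe)
  expect_equal(r$k_up, 3L)
  expect_equal(r$p_up_rev, 1126 / 15504, tolerance = 1e-14)
  expect_false(r$p_up_rev < 0.05)

  # perfect reversal: drug.down == disease.up
  r2 <- reversal_test(degs, "d2", up = character(), down = paste0("g", 1:5),
                      universe = degs$universe)
  expect_equal(r2$p_up_rev, 1 / 15504, tolerance = 1e-14)
  expect_true(r2$candidate)

  # zero overlap in both directions
  r3 <- reversal_test(degs, "d3", up = "g20", down = "g19",
                      universe = degs$universe)
  expect_equal(r3$p_up_rev, 1)
  expect_equal(r3$p_down_rev, 1)
  expect_false(r3$candidate)

  expect_error(reversal_test(degs, "d", "g1", "g2", character()), "universe")
})

test_that("the reversal test is invariant under gene relabeling", {
  degs <- make_degs20()
  drug_up <- c("g7", "g8")
  drug_down <- c("g1", "g2", "g15")
  r <- reversal_test(degs, "d", drug_up, drug_down, degs$universe)

  withr::with_seed(50, {
    perm <- setNames(sample(paste0("h", 1:20)), paste0("g", 1:20))
  })
  degs2 <- deg_set(perm[degs$up], perm[degs$down], perm[degs$universe])
  r2 <- reversal_test(degs2, "d", perm[drug_up], perm[drug_down],
                      perm[degs$universe])
  expect_equal(r2$p_up_rev, r$p_up_rev)
  expect_equal(r2$p_down_rev, r$p_down_rev)
})

test_that("reversal p strictly decreases as the overlap grows", {
  degs <- make_degs20()
  others <- paste0("g", 11:20)
  p_at_k <- vapply(0:5, function(k) {
    down <- c(paste0("g", seq_len(k)), others[seq_len(5 - k)])
    reversal_test(degs, "d", character(), down, degs$universe)$p_up_rev
  }, numeric(1))
  expect_true(all(diff(p_at_k) < 0))
})

test_that("screen_drugs ranks, flags and re-derives the candidate rule", {
  universe <- sprintf("g%04d", 1:500)
  disease <- deg_set(universe[1:30], universe[31:60], universe)
  sim <- simulate_drug_library(40, 15, universe, disease$up, disease$down,
                               planted_ids = "planted_rev",
                               overlap_fraction = 1, seed = 61)
  scr <- screen_drugs(disease, sim$library)
  expect_equal(scr$drug_id[1], "planted_rev")
  expect_true(scr$candidate[1])
  expect_true(all(diff(scr$best_p) >= 0))

  # candidate decisions match an independent re-evaluation with phyper
  sig <- sim$library$signatures
  for (i in sample(nrow(scr), 10)) {
    row <- scr[i, ]
    s <- sig[sig$drug_id == row$drug_id, ]
    k_up <- length(intersect(s$down[[1]], disease$up))
    p_up <- phyper(k_up - 1, length(intersect(s$down[[1]], universe)),
                   500 - length(intersect(s$down[[1]], universe)),
                   30, lower.tail = FALSE)
    k_down <- length(intersect(s$up[[1]], disease$down))
    p_down <- phyper(k_down - 1, length(intersect(s$up[[1]], universe)),
                     500 - length(intersect(s$up[[1]], universe)),
                     30, lower.tail = FALSE)
    expect_equal(row$p_up_rev, p_up, tolerance = 1e-12)
    expect_equal(row$candidate, (p_up < 0.05) || (p_down < 0.05))
  }

  # empty disease signature: all p = 1, no candidates
  empty <- deg_set(character(), character(), universe)
  scr0 <- screen_drugs(empty, sim$library)
  expect_true(all(scr0$p_up_rev == 1 & scr0$p_down_rev == 1))
  expect_false(any(scr0$candidate))
})

test_that("per-gene drug queries filter by containment and rank by p", {
  universe <- paste0("g", 1:50)
  degs <- deg_set(paste0("g", 1:10), paste0("g", 11:20), universe)
  lib <- drug_library(tibble::tibble(
    drug_id = c("carrier_strong", "carrier_weak", "noncarrier"),
    up = list(character(), character(), character()),
    down = list(paste0("g", 1:8),          # strong reverser, contains g1
                c("g1", paste0("g", 40:45)),  # weak, contains g1
                paste0("g", 2:9))             # does not contain g1
  ), universe = universe)
  res <- drugs_for_gene("g1", "up", lib, degs)
  expect_equal(res$drug_id, c("carrier_strong", "carrier_weak"))
  expect_true(all(diff(res$p_value) >= 0))

  # gene in no signature: empty table with a notice
  expect_message(none <- drugs_for_gene("g30", "up", lib, degs),
                 "no drug")
  expect_equal(nrow(none), 0)

  # exactly 10 carrier drugs -> a 10-row table
  lib10 <- drug_library(tibble::tibble(
    drug_id = sprintf("d%02d", 1:12),
    up = replicate(12, character(), simplify = FALSE),
    down = c(replicate(10, c("g1", "g2"), simplify = FALSE),
             replicate(2, c("g3", "g4"), simplify = FALSE))
  ), universe = universe)
  res10 <- drugs_for_gene("g1", "up", lib10, degs)
  expect_equal(nrow(res10), 10)
})
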