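test_that("generators are pure functions of their seed", {
  a <- simulate_counts(100, 4, 4, n_up = 5, n_down = 5, lfc = 2, seed = 9)
  b <- simulate_counts(100, 4, 4, n_up = 5, n_down = 5, lfc = 2, seed = 9)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  e1 <- simulate_network(50, 0.05, hub_ids = "g0001", hub_degree = 10,
                         seed = 3)
  e2 <- simulate_network(50, 0.05, hub_ids = "g0001", hub_degree = 10,
                         seed = 3)
  expect_identical(e1, e2)

  x <- setNames(rnorm(30), sprintf("s%02d", 1:30))
  s1 <- simulate_survival(x, beta = 1, seed = 5)
  s2 <- simulate_survival(x, beta = 1, seed = 5)
  expect_identical(s1, s2)

  l1 <- simulate_drug_library(10, 5, sprintf("g%03d", 1:100), seed = 7)
  l2 <- simulate_drug_library(10, 5, sprintf("g%03d", 1:100), seed = 7)
  expect_identical(l1$library$signatures, l2$library$signatures)
})

test_that("count generator matches its stated NB moments", {
  # one gene, many samples: mean ~ base_mean, variance ~ mu + alpha mu^2
  sim <- simulate_counts(n_genes = 2, n_case = 5000, n_control = 5000,
                         base_mean = 100, dispersion = 0.1, seed = 21)
  x <- sim$counts$counts[1, ]
  expect_lt(abs(mean(x) - 100) / 100, 0.05)
  expect_lt(abs(var(x) - (100 + 0.1 * 100^2)) / 1100, 0.15)

  # planted up genes shift the case mean by ~2^lfc
  sim <- simulate_counts(n_genes = 2000, n_case = 10, n_control = 10,
                         base_mean = 100, dispersion = 0.1,
                         n_up = 50, n_down = 50, lfc = 3, seed = 22)
  cm <- sim$counts
  case <- cm$group == "case"
  up <- sim$truth$de_genes_up
  ratio <- mean(cm$counts[up, case]) / mean(cm$counts[up, !case])
  expect_lt(abs(ratio - 8) / 8, 0.2)

  # lfc = 0 plants nothing
  sim0 <- simulate_counts(100, 3, 3, seed = 1)
  expect_length(sim0$truth$de_genes_up, 0)
  expect_length(sim0$truth$de_genes_down, 0)
})

test_that("two-cohort generator shares planted truth with independent noise", {
  two <- simulate_two_datasets(300, sizes1 = c(5, 5), sizes2 = c(5, 5),
                               n_up = 10, n_down = 10, n_up_only1 = 5,
                               lfc = 3, seed = 11)
  expect_length(two$truth$de_genes_up, 10)
  expect_length(two$truth$up_only1, 5)
  expect_false(identical(two$cohort1$counts[, 1], two$cohort2$counts[, 1]))
  # both cohorts carry the shared planted shift
  for (cm in list(two$cohort1, two$cohort2)) {
    case <- cm$group == "case"
    r <- mean(cm$counts[two$truth$de_genes_up, case]) /
      mean(cm$counts[two$truth$de_genes_up, !case])
    expect_gt(r, 4)
  }
  # the cohort-1-only genes are null in cohort 2
  case2 <- two$cohort2$group == "case"
  r2 <- mean(two$cohort2$counts[two$truth$up_only1, case2]) /
    mean(two$cohort2$counts[two$truth$up_only1, !case2])
  expect_lt(abs(log2(r2)), 1)
})

test_that("survival generator respects censoring and the exponential rate", {
  x <- setNames(rnorm(2000), sprintf("s%04d", 1:2000))
  # censor_rate = 0: every record is an event
  cl0 <- simulate_survival(x, beta = 0, censor_rate = 0, seed = 2)
  expect_true(all(cl0$event == 1))

  # censoring fraction calibrated to the requested rate
  cl <- simulate_survival(x, beta = log(2), censor_rate = 0.3, seed = 3)
  expect_lt(abs(mean(cl$event == 0) - 0.3), 0.03)

  # beta = 0: median of the KM curve recovers ln(2)/lambda within 5%
  n <- 5000
  cl <- simulate_survival(setNames(rnorm(n), sprintf("s%04d", 1:n)),
                          beta = 0, baseline_hazard = 0.002,
                          censor_rate = 0, seed = 4)
  km <- km_estimate(cl)
  expect_lt(abs(median_survival(km) - log(2) / 0.002) / (log(2) / 0.002),
            0.05)

  expect_error(simulate_survival(x, beta = 1, baseline_hazard = 0, seed = 1),
               "positive")
  expect_error(simulate_survival(x, beta = 1, censor_rate = 1, seed = 1),
               "censor_rate")
})

test_that("network generator plants hubs and respects degenerate settings", {
  # no background + one hub of degree 5 is a star
  e <- simulate_network(20, 0, hub_ids = "g0005", hub_degree = 5, seed = 13)
  expect_equal(nrow(e), 5)
  expect_true(all(e$gene_a == "g0005" | e$gene_b == "g0005"))
  expect_true(all(e$combined_score >= 0.7))

  expect_error(simulate_network(10, 0.1, hub_ids = "g0001", hub_degree = 10,
                                seed = 1), "hub_degree")
})

test_that("drug-library generator plants reversal structure", {
  universe <- sprintf("g%04d", 1:500)
  disease_up <- universe[1:40]
  disease_down <- universe[41:80]
  out <- simulate_drug_library(20, 10, universe, disease_up, disease_down,
                               planted_ids = "revA", overlap_fraction = 1,
                               seed = 31)
  expect_length(out$library, 20)
  sig <- out$library$signatures
  planted <- sig[sig$drug_id == "revA", ]
  expect_length(intersect(planted$down[[1]], disease_up), 10)
  expect_length(intersect(planted$up[[1]], disease_down), 10)

  # overlap_fraction = 0 gives decoy-like planted drugs
  out0 <- simulate_drug_library(5, 10, universe, disease_up, disease_down,
                                planted_ids = "revA", overlap_fraction = 0,
                                seed = 32)
  sig0 <- out0$library$signatures
  p0 <- sig0[sig0$drug_id == "revA", ]
  expect_length(intersect(p0$down[[1]], disease_up), 0)

  expect_error(simulate_drug_library(5, 400, universe, seed = 1),
               "sig_size")
})
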