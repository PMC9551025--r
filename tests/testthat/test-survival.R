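test_that("KM estimator reproduces hand computations", {
  # no censoring: 1 - ECDF
  cl <- tibble::tibble(sample_id = letters[1:4], time = 1:4, event = 1)
  km <- km_estimate(cl)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))

  # censored fixture: S(1)=0.75, S(3)=0.375, S(4)=0
  cl <- tibble::tibble(sample_id = letters[1:4], time = c(1, 2, 3, 4),
                       event = c(1, 0, 1, 1))
  km <- km_estimate(cl)
  expect_equal(km$time, c(1, 3, 4))
  expect_equal(km$survival, c(0.75, 0.375, 0))

  # all censored: no death times, survival stays at 1
  cl <- tibble::tibble(sample_id = letters[1:3], time = 1:3, event = 0)
  km <- km_estimate(cl)
  expect_length(km$time, 0)
  expect_true(is.na(median_survival(km)))

  expect_error(km_estimate(tibble::tibble(sample_id = "a", time = -1,
                                          event = 1)), ">= 0")
})

test_that("KM agrees with survival::survfit on censored data", {
  withr::with_seed(14, {
    cl <- tibble::tibble(
      sample_id = sprintf("s%02d", 1:40),
      time = round(rexp(40, 0.1), 1),
      event = rbinom(40, 1, 0.7)
    )
  })
  km <- km_estimate(cl)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = cl)
  at_deaths <- summary(sf, times = km$time)
  expect_equal(km$survival, at_deaths$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, at_deaths$n.risk)
})

test_that("median survival uses the first time S drops to 0.5 or below", {
  cl <- tibble::tibble(sample_id = letters[1:4], time = 1:4, event = 1)
  expect_equal(median_survival(km_estimate(cl)), 2)  # S(2) = 0.5 exactly

  # curve never reaching 0.5 has no median
  cl <- tibble::tibble(sample_id = letters[1:8], time = 1:8,
                       event = c(1, 1, rep(0, 6)))
  expect_true(is.na(median_survival(km_estimate(cl))))
})

test_that("log-rank reproduces the hand-computed fixture and symmetry", {
  # identical groups: O = E, statistic 0
  cl <- tibble::tibble(sample_id = paste0("s", 1:6),
                       time = c(1, 2, 3, 1, 2, 3),
                       event = c(1, 1, 0, 1, 1, 0))
  lr <- logrank_test(rep(c("A", "B"), each = 3), cl)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)

  # A events at (1,2), B at (3,4): chi-square = 49/17
  cl <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                       time = c(1, 2, 3, 4), event = 1)
  grp <- setNames(c("A", "A", "B", "B"), cl$sample_id)
  lr <- logrank_test(grp, cl)
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)

  # swapping labels leaves statistic and p unchanged
  swapped <- setNames(c("B", "B", "A", "A"), cl$sample_id)
  lr2 <- logrank_test(swapped, cl)
  expect_equal(lr2$statistic, lr$statistic)
  expect_equal(lr2$p_value, lr$p_value)

  expect_error(logrank_test(rep("A", 4), cl), "two groups")
  cl0 <- tibble::tibble(sample_id = c("x", "y"), time = c(1, 2), event = 0)
  expect_error(logrank_test(c("A", "B"), cl0), "No events")
})

test_that("log-rank matches survdiff exactly and a permutation oracle", {
  withr::with_seed(30, {
    cl <- tibble::tibble(
      sample_id = sprintf("s%02d", 1:30),
      time = round(c(rexp(15, 0.05), rexp(15, 0.12)), 1),
      event = rbinom(30, 1, 0.8)
    )
  })
  grp <- rep(c("A", "B"), each = 15)
  lr <- logrank_test(grp, cl)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(cl, g = grp))
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-12)

  p_perm <- perm_logrank_p(grp, cl, B = 4000, seed = 6)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
  # asymptotic chi-square p vs exact permutation p: MC error plus a small
  # finite-sample allowance
  expect_lt(abs(lr$p_value - p_perm), 3 * mc_se + 0.03)
})

test_that("median dichotomisation sends ties to the low group", {
  expect_equal(unname(dichotomize_by_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(unname(dichotomize_by_median(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  expect_error(dichotomize_by_median(c(5, 5, 5, 5)), "median")
  expect_error(dichotomize_by_median(7), ">= 2")
})

test_that("the survival screen finds a planted prognostic gene", {
  n <- 200
  hits <- vapply(1:10, function(seed) {
    withr::with_seed(seed * 100, {
      expr <- matrix(rnorm(20 * n), 20, n,
                     dimnames = list(sprintf("g%02d", 1:20),
                                     sprintf("s%03d", 1:n)))
    })
    cl <- simulate_survival(expr["g07", ], beta = log(4), censor_rate = 0.2,
                            seed = seed)
    scr <- gene_survival_screen(expr, cl)
    scr$gene[1] == "g07"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("the survival screen validates matching and missing genes", {
  expr <- matrix(rnorm(20), 2, 10,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
  cl <- tibble::tibble(sample_id = paste0("s", 1:10),
                       time = 1:10, event = 1)
  expect_warning(scr <- gene_survival_screen(expr, cl, c("g1", "missing")),
                 "absent")
  expect_equal(scr$gene, "g1")

  cl1 <- tibble::tibble(sample_id = "s1", time = 1, event = 1)
  expect_error(gene_survival_screen(expr, cl1), "Fewer than two")
})
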