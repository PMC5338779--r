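test_that("quantile stratification matches sort-and-interpolate quantiles", {
  v <- as.numeric(1:100)
  s <- stratify_quantile(v)
  expect_equal(sum(s == "low"), sum(v <= oracle_quantile7(v, 0.10)))
  expect_equal(sum(s == "high"), sum(v >= oracle_quantile7(v, 0.90)))
  expect_true(abs(sum(s == "low") - 10) <= 1 && abs(sum(s == "high") - 10) <= 1)

  extremes <- stratify_quantile(v, lo = 0, hi = 1)
  expect_equal(sum(extremes == "low"), 1)
  expect_equal(sum(extremes == "high"), 1)

  withr::with_seed(17, {
    u <- runif(20)
    s2 <- stratify_quantile(u)
    expect_identical(s2 == "low", u <= oracle_quantile7(u, 0.10))
    expect_identical(s2 == "high", u >= oracle_quantile7(u, 0.90))
  })
  expect_error(stratify_quantile(rep(1, 20)), "identical",
               class = "channelscreen_validation_error")
  expect_error(stratify_quantile(1:5), ">= 10",
               class = "channelscreen_validation_error")
})

test_that("median split assigns ties to low and honours a supplied median", {
  s <- stratify_median(c(1, 2, 3, 4))
  expect_identical(s, c("low", "low", "high", "high"))
  s2 <- stratify_median(c(3.9, 3.91), median_value = 3.908)
  expect_identical(s2, c("low", "high"))
  expect_identical(stratify_median(c(1, 2, 2, 5))[2:3], c("low", "low"))
})

test_that("KM estimate equals empirical survival without censoring", {
  tbl <- tibble::tibble(sample_id = letters[1:3], time = c(1, 2, 3), event = 1)
  km <- km_estimate(tbl)
  expect_equal(km$curve$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median_survival, 2)  # first time the curve reaches S <= 0.5

  cens <- tibble::tibble(sample_id = letters[1:3], time = c(1, 2, 3), event = 0)
  km_c <- km_estimate(cens)
  expect_true(all(km_c$curve$survival == 1))
  expect_true(is.na(km_c$median_survival))
})

test_that("KM curves match the brute-force product-limit oracle", {
  withr::with_seed(55, {
    for (i in 1:10) {
      tbl <- tibble::tibble(sample_id = sprintf("p%02d", 1:8),
                            time = sample(1:6, 8, replace = TRUE),
                            event = rbinom(8, 1, 0.7))
      if (sum(tbl$event) == 0) tbl$event[1] <- 1
      km <- km_estimate(tbl)
      ora <- oracle_km(tbl$time, tbl$event)
      got <- km$curve[km$curve$n_event > 0, ]
      expect_equal(got$time, ora$time)
      expect_equal(got$survival, ora$survival, tolerance = 1e-12)
      expect_true(all(diff(km$curve$survival) <= 1e-12))
      expect_true(all(km$curve$survival >= 0 & km$curve$survival <= 1))
    }
  })
})

test_that("log-rank is zero for identical strata and symmetric under label swap", {
  base <- tibble::tibble(sample_id = paste0("p", 1:4),
                         time = c(2, 5, 7, 9), event = c(1, 1, 0, 1))
  both <- dplyr::bind_rows(base, dplyr::mutate(base, sample_id = paste0(sample_id, "b")))
  strata <- rep(c("low", "high"), each = 4)
  lr <- logrank_test(both, strata)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  withr::with_seed(8, {
    tbl <- tibble::tibble(sample_id = paste0("p", 1:12),
                          time = rexp(12, 0.01), event = rbinom(12, 1, 0.8))
  })
  s <- rep(c("a", "b"), 6)
  swapped <- ifelse(s == "a", "b", "a")
  expect_equal(logrank_test(tbl, s)$statistic, logrank_test(tbl, swapped)$statistic,
               tolerance = 1e-12)
  # invariant to a common shift of all times
  shifted <- dplyr::mutate(tbl, time = time + 100)
  expect_equal(logrank_test(tbl, s)$statistic, logrank_test(shifted, s)$statistic,
               tolerance = 1e-12)
  expect_error(logrank_test(tbl, rep("a", 12)), "exactly 2",
               class = "channelscreen_validation_error")
})

test_that("exact Mann-Whitney p values match enumeration on small instances", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 0.1)  # 2/20 orderings as or more extreme

  withr::with_seed(19, {
    for (i in 1:10) {
      n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
      x <- rnorm(n1); y <- rnorm(n2)
      got <- mann_whitney(x, y)
      ora <- oracle_mw_exact(x, y)
      expect_equal(got$u, ora$u)
      expect_equal(got$p_value, ora$p, tolerance = 1e-12)
      expect_true(got$exact)
    }
  })
})

test_that("tied Mann-Whitney falls back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 8, 8)
  y <- c(2, 3, 3, 5, 8, 9)
  got <- mann_whitney(x, y)
  expect_false(got$exact)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(got$p_value, ref$p.value)
  even <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(even$u, 9 / 2)  # identical multisets: U = n1 n2 / 2
})

test_that("Kruskal-Wallis agrees with the two-sample normal approximation", {
  withr::with_seed(23, {
    x <- rnorm(15); y <- rnorm(12, 0.5)
  })
  kw <- kruskal_wallis(list(x, y))
  mw <- mann_whitney(x, y)
  expect_equal(kw$p_value, mw$p_value, tolerance = 1e-6)

  shifted <- kruskal_wallis(list(rnorm(20), rnorm(20) + 50))
  expect_lt(shifted$p_value, 1e-4)
  expect_error(kruskal_wallis(list(rep(1, 5), rep(1, 5))),
               class = "channelscreen_validation_error")
})

test_that("mutation association applies the minimum-mutant inclusion rule", {
  m <- withr::with_seed(3, matrix(rlnorm(40, log(10), 0.3), 2, 20,
    dimnames = list(c("gA", "gB"), sprintf("iso%02d", 1:20))))
  # gB is shifted 4-fold in mutants of mutX
  mut_ids <- sprintf("iso%02d", 1:8)
  m["gB", mut_ids] <- m["gB", mut_ids] * 4
  mutations <- dplyr::bind_rows(
    tibble::tibble(isolate_id = colnames(m), mutation = "mutX",
                   status = ifelse(colnames(m) %in% mut_ids, "mutant", "wildtype")),
    tibble::tibble(isolate_id = colnames(m), mutation = "rare",
                   status = c("mutant", "mutant", rep("wildtype", 18))))
  expect_message(res <- mutation_association(expr_from_matrix(m, "CPM"), mutations),
                 "skipped")
  expect_false("rare" %in% res$mutation)  # only 2 mutant isolates
  expect_lt(res$p_value[res$gene_id == "gB" & res$mutation == "mutX"], 0.05)

  # null flag: rejection near the nominal level
  rejects <- withr::with_seed(41, vapply(1:300, function(i) {
    e <- rexp(20)
    mann_whitney(e[1:8], e[9:20])$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(mean(rejects) - 0.05), 0.04)
})
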