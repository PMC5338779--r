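mk_ranked <- function(scores) {
  tb <- tibble::tibble(gene_id = names(scores), score = unname(scores)) |>
    dplyr::arrange(dplyr::desc(score), gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(tb, metric = "signal2noise", class = c("ranked_genes", class(tibble::tibble())))
}

two_class_expr <- function(n_genes = 40, n_tumor = 4, n_control = 4, seed = 1) {
  m <- random_nb_counts(n_genes, n_tumor + n_control, seed = seed)
  meta <- tibble::tibble(sample_id = colnames(m),
                         isolate_id = colnames(m),
                         group = rep(c("tumor", "control"), c(n_tumor, n_control)))
  list(expr = expr_from_matrix(m + 0, "CPM"), meta = meta)
}

test_that("signal2noise is zero at equal means and antisymmetric in the labels", {
  m <- matrix(c(5, 6, 5, 6, 1, 9, 2, 3), 2, 4, byrow = TRUE,
              dimnames = list(c("flat", "var"), paste0("s", 1:4)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         isolate_id = paste0("s", 1:4),
                         group = c("tumor", "tumor", "control", "control"))
  r <- signal2noise_rank(expr_from_matrix(m, "CPM"), meta)
  expect_equal(r$score[r$gene_id == "flat"], 0)

  swapped <- dplyr::mutate(meta, group = ifelse(group == "tumor", "control", "tumor"))
  r2 <- signal2noise_rank(expr_from_matrix(m, "CPM"), swapped)
  expect_equal(setNames(r2$score, r2$gene_id)[r$gene_id], -setNames(r$score, r$gene_id))
  expect_identical(r2$gene_id, rev(r$gene_id))  # distinct scores: order reverses
})

test_that("signal2noise applies the SD floor and matches the independent formula", {
  m <- matrix(c(3, 5, 1, 1), 1, 4, dimnames = list("g", paste0("s", 1:4)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         isolate_id = paste0("s", 1:4),
                         group = c("tumor", "tumor", "control", "control"))
  r <- signal2noise_rank(expr_from_matrix(m, "CPM"), meta)
  expect_equal(r$score, oracle_s2n(c(3, 5), c(1, 1)), tolerance = 1e-12)

  # random instances against the oracle
  tc <- two_class_expr(seed = 6)
  r <- signal2noise_rank(tc$expr, tc$meta)
  mvals <- expr_values(tc$expr)
  for (g in sample(rownames(mvals), 10)) {
    expect_equal(r$score[r$gene_id == g],
                 oracle_s2n(mvals[g, tc$meta$group == "tumor"],
                            mvals[g, tc$meta$group == "control"]),
                 tolerance = 1e-12)
  }
  one <- tc$meta[tc$meta$sample_id %in% c("s01", "s05", "s06", "s07", "s08"), ]
  expect_error(signal2noise_rank(tc$expr[, c("gene_id", one$sample_id)], one),
               "fewer than 2", class = "channelscreen_validation_error")
})

test_that("score ties rank deterministically by gene id", {
  r <- mk_ranked(c(b = 1, a = 1, c = 0))
  expect_identical(r$gene_id, c("a", "b", "c"))
})

test_that("enrichment score hits its analytic extremes", {
  r <- mk_ranked(setNames(seq(10, 1), paste0("g", 1:10)))
  top <- gsea_es(r, "g1")
  expect_equal(top$es, 1)
  expect_identical(top$leading_edge, "g1")

  bottom <- gsea_es(r, c("g9", "g10"))
  expect_lt(bottom$es, 0)
  expect_setequal(bottom$leading_edge, c("g9", "g10"))

  expect_error(gsea_es(r, "absent"), "no members",
               class = "channelscreen_validation_error")
  expect_error(gsea_es(r, paste0("g", 1:10)), "entire",
               class = "channelscreen_validation_error")
})

test_that("running sum matches a position-by-position oracle", {
  scores <- setNames(c(4.2, 3.1, 2.5, 2.0, 1.1, 0.4, -0.3, -1.2, -2.2, -3.5),
                     paste0("g", 1:10))
  r <- mk_ranked(scores)
  set <- c("g2", "g5", "g9")
  res <- gsea_es(r, set)
  hit <- r$gene_id %in% set
  expect_equal(res$running_sum$running, oracle_es_walk(r$score, hit), tolerance = 1e-12)
  expect_equal(res$es, oracle_es(r$score, hit), tolerance = 1e-12)
  # ES is the extremum of its own walk
  expect_equal(res$es, res$running_sum$running[which.max(abs(res$running_sum$running))])
})

test_that("with weight 0 the score is invariant to monotone rescaling", {
  withr::with_seed(31, {
    scores <- sort(rnorm(50), decreasing = TRUE)
  })
  names(scores) <- sprintf("g%02d", 1:50)
  set <- sample(names(scores), 8)
  es0 <- gsea_es(mk_ranked(scores), set, weight_p = 0)$es
  es0_resc <- gsea_es(mk_ranked(exp(scores) * 3), set, weight_p = 0)$es
  expect_equal(es0, es0_resc, tolerance = 1e-12)
})

test_that("ES sign follows the set's rank displacement on random instances", {
  withr::with_seed(77, {
    for (i in 1:20) {
      scores <- sort(rnorm(60), decreasing = TRUE)
      names(scores) <- sprintf("g%02d", 1:60)
      set <- sample(names(scores), 6)
      es <- gsea_es(mk_ranked(scores), set)$es
      expect_equal(es, oracle_es(scores, names(scores) %in% set), tolerance = 1e-12)
    }
  })
})

test_that("permutation p is floored for a planted top set and reproducible", {
  tc <- two_class_expr(n_genes = 60, seed = 12)
  ranked <- signal2noise_rank(tc$expr, tc$meta)
  top_set <- head(ranked$gene_id, 6)
  res <- gsea_permutation_p(tc$expr, tc$meta, top_set, n_perm = 200, seed = 4)
  expect_equal(res$p_value, 1 / 201)
  res2 <- gsea_permutation_p(tc$expr, tc$meta, top_set, n_perm = 200, seed = 4)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$null_es, res2$null_es)
  expect_true(res$nes > 0)
})

test_that("phenotype permutation warns when classes are tiny", {
  tc <- two_class_expr(n_genes = 30, n_tumor = 3, n_control = 3, seed = 9)
  expect_warning(
    gsea_permutation_p(tc$expr, tc$meta, rownames(expr_values(tc$expr))[1:5],
                       n_perm = 100, scheme = "phenotype", seed = 1),
    "few distinct permutations")
})
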