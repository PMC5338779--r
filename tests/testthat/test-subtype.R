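ref_fixture <- function(seed = 2, noise = 0.4) {
  simulate_subtype_reference(n_genes_signature = 60, samples_per_subtype = 5,
                             centroid_separation = 2, noise_sd = noise, seed = seed)
}

test_that("centroids are per-gene medians over each subtype's samples", {
  m <- matrix(c(1, 2, 100, 7, 8, 9), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  labels <- tibble::tibble(sample_id = paste0("s", 1:6),
                           subtype = rep(c("Classical", "Mesenchymal"), each = 3))
  cent <- compute_centroids(expr_from_matrix(m, "CPM"), labels, "g1")
  expect_equal(cent$Classical, 2)   # robust to the 100 outlier
  expect_equal(cent$Mesenchymal, 8)

  # single sample per subtype: centroid is that sample
  one <- labels[c(1, 4), ]
  cent1 <- compute_centroids(expr_from_matrix(m, "CPM"), one, "g1")
  expect_equal(cent1$Classical, 1)

  ref <- ref_fixture()
  cent <- compute_centroids(ref$expr, ref$labels, ref$expr$gene_id)
  mv <- expr_values(ref$expr)
  for (st in unique(ref$labels$subtype)) {
    cols <- ref$labels$sample_id[ref$labels$subtype == st]
    manual <- apply(mv[, cols], 1, function(v) {
      s <- sort(v); n <- length(s)
      if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    })
    expect_equal(setNames(cent[[st]], cent$gene_id), manual)
  }

  expect_error(compute_centroids(expr_from_matrix(m, "CPM"),
                                 labels[1:3, ], "g1"), NA)
  expect_message(compute_centroids(expr_from_matrix(m, "CPM"), labels,
                                   c("g1", "ghost")), "absent from reference")
})

test_that("classification maximizes Spearman correlation with rank invariance", {
  ref <- ref_fixture(noise = 0)
  cent <- compute_centroids(ref$expr, ref$labels, ref$expr$gene_id)
  sample1 <- ref$expr[, c("gene_id", ref$labels$sample_id[1])]
  call <- classify_by_centroid(sample1, cent)
  expect_identical(call$subtype, ref$labels$subtype[1])
  expect_equal(call[[paste0("rho_", call$subtype)]], 1)

  # strictly increasing transform leaves the call and rho unchanged
  mono <- sample1
  mono[[2]] <- exp(mono[[2]] / 3) + 5
  call_mono <- classify_by_centroid(mono, cent)
  expect_identical(call_mono$subtype, call$subtype)
  expect_equal(call_mono[[paste0("rho_", call$subtype)]], 1)

  const <- sample1
  const[[2]] <- rep(1, nrow(const))
  expect_error(classify_by_centroid(const, cent), "constant",
               class = "channelscreen_validation_error")
  expect_error(classify_by_centroid(sample1[1:5, ], cent), "shared",
               class = "channelscreen_validation_error")
})

test_that("per-centroid rho matches a brute-force Spearman evaluation", {
  v <- c(3, 1, 4, 1, 5, 9)
  cents <- structure(tibble::tibble(gene_id = paste0("g", 1:6),
                                    Classical = c(2, 7, 1, 8, 2, 8),
                                    Proneural = c(1, 2, 3, 4, 5, 6)),
                     class = c("subtype_centroids", class(tibble::tibble())))
  x <- expr_from_matrix(matrix(v, 6, 1, dimnames = list(paste0("g", 1:6), "s")), "CPM")
  call <- classify_by_centroid(x, cents, min_shared = 6)
  expect_equal(call$rho_Classical, oracle_spearman(v, cents$Classical), tolerance = 1e-12)
  expect_equal(call$rho_Proneural, oracle_spearman(v, cents$Proneural), tolerance = 1e-12)
  expect_equal(call$margin, max(call$rho_Classical, call$rho_Proneural) -
                 min(call$rho_Classical, call$rho_Proneural))
})

test_that("consensus over replicate calls uses majority then mean rho", {
  calls <- tibble::tibble(subtype = c("Proneural", "Proneural", "Mesenchymal"),
                          rho_Proneural = c(0.9, 0.8, 0.3),
                          rho_Mesenchymal = c(0.2, 0.3, 0.7))
  expect_identical(consensus_call(calls), "Proneural")

  tie <- tibble::tibble(subtype = c("Proneural", "Mesenchymal"),
                        rho_Proneural = c(0.8, 0.8),
                        rho_Mesenchymal = c(0.6, 0.6))
  expect_identical(consensus_call(tie), "Proneural")

  expect_identical(consensus_call(calls[3, ]), "Mesenchymal")

  full_tie <- tibble::tibble(subtype = c("Neural", "Classical"),
                             rho_Neural = c(0.5, 0.5), rho_Classical = c(0.5, 0.5))
  expect_warning(res <- consensus_call(full_tie), "fixed subtype order")
  expect_identical(res, "Classical")
})

test_that("subtype recovery is perfect without noise and at chance without separation", {
  clean <- ref_fixture(noise = 0)
  cent <- compute_centroids(clean$expr, clean$labels, clean$expr$gene_id)
  calls <- classify_by_centroid(clean$expr, cent)
  expect_equal(mean(calls$subtype == clean$labels$subtype), 1)

  flat <- simulate_subtype_reference(n_genes_signature = 60, samples_per_subtype = 10,
                                     centroid_separation = 0, noise_sd = 0.5, seed = 8)
  test <- simulate_subtype_reference(n_genes_signature = 60, samples_per_subtype = 10,
                                     centroid_separation = 0, noise_sd = 0.5, seed = 9)
  cent0 <- compute_centroids(flat$expr, flat$labels, flat$expr$gene_id)
  acc <- mean(classify_by_centroid(test$expr, cent0)$subtype == test$labels$subtype)
  expect_lt(abs(acc - 0.25), 0.15)
})

test_that("hierarchical clustering reproduces hand-evaluated UPGMA and validates", {
  m <- matrix(c(0, 1, 10, 11), 1, 4, dimnames = list("g", paste0("s", 1:4)))
  tree <- hierarchical_cluster(expr_from_matrix(m, "CPM"),
                               metric = "euclidean", linkage = "average")
  expect_equal(sort(tree$hclust$height), c(1, 1, 10))
  expect_match(tree$newick, "^\\(")
  expect_false(is.unsorted(tree$hclust$height))

  # identical samples merge first at height zero
  m2 <- matrix(c(1, 1, 5, 9), 1, 4, dimnames = list("g", paste0("s", 1:4)))
  tree2 <- hierarchical_cluster(expr_from_matrix(m2, "CPM"))
  expect_equal(min(tree2$hclust$height), 0)
  first <- tree2$hclust$merge[1, ]
  expect_setequal(tree2$hclust$labels[-first], c("s1", "s2"))

  # sample order permutation leaves the topology unchanged
  mv <- random_nb_counts(20, 6, seed = 14) + 0
  t1 <- hierarchical_cluster(expr_from_matrix(mv, "CPM"))
  t2 <- hierarchical_cluster(expr_from_matrix(mv[, c(4, 2, 6, 1, 3, 5)], "CPM"))
  d1 <- ape::cophenetic.phylo(t1$phylo)
  d2 <- ape::cophenetic.phylo(t2$phylo)
  expect_equal(d1[rownames(d1), colnames(d1)], d2[rownames(d1), colnames(d1)],
               tolerance = 1e-9)

  expect_error(hierarchical_cluster(expr_from_matrix(mv, "CPM"), metric = "cosine"))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(t1, path)
  expect_s3_class(ape::read.tree(path), "phylo")
})
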