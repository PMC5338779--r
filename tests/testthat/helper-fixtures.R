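# Small programmatic fixtures shared across tests.

random_nb_counts <- function(n_genes, n_samples, seed, mean_log = log(100),
                             sd_log = 1, dispersion = 0.2) {
  withr::with_seed(seed, {
    mu <- exp(rnorm(n_genes, mean_log, sd_log))
    m <- sapply(seq_len(n_samples), function(j) {
      rnbinom(n_genes, mu = mu * runif(1, 0.6, 1.4), size = 1 / dispersion)
    })
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(n_samples)))
    m
  })
}

toy_expr <- function(m, unit = "CPM") {
  expr_from_matrix(m, unit = unit)
}

# a minimal regional profile with known means: one sample per region
toy_regional_profile <- function(means_by_region) {
  genes <- rownames(means_by_region)
  meta <- tibble::tibble(sample_id = paste0(colnames(means_by_region), "_s1"),
                         isolate_id = paste0(colnames(means_by_region), "_s1"),
                         region = colnames(means_by_region))
  m <- means_by_region
  colnames(m) <- meta$sample_id
  aggregate_by_region(expr_from_matrix(m, "FPKM"), meta)
}
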