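#' Configuration for the synthetic differential screen
#'
#' Defines the generative model for a tumor-vs-control RNA-seq count matrix
#' shaped like the study design the screen expects: 20 tumor stem-cell
#' isolates against 5 control neural lines, 2-3 replicates per isolate,
#' negative-binomial counts with lognormal per-gene baselines, a lognormal
#' isolate-level random effect, varying sequencing depth, and a planted
#' subset of tumor-enriched genes whose true log2 effect is recorded.
#'
#' @param n_genes Number of genes.
#' @param n_tumor_isolates,n_control_isolates Isolates per class.
#' @param replicates_per_isolate Either a single integer (2 or 3) or the
#'   vector `c(2, 3)` to draw per isolate.
#' @param fraction_planted Fraction of genes given a true tumor effect.
#' @param planted_log2_effect True log2 fold change of planted genes in
#'   tumor samples.
#' @param nb_dispersion Negative-binomial dispersion (1/size); > 0.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean/sd of the
#'   lognormal per-gene baseline expected count.
#' @param library_size_range Relative sequencing-depth multipliers; each
#'   sample's depth factor is drawn uniformly from this range.
#' @param isolate_effect_sd SD of the lognormal isolate-level random effect.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 1000,
                              n_tumor_isolates = 20,
                              n_control_isolates = 5,
                              replicates_per_isolate = 3,
                              fraction_planted = 0.05,
                              planted_log2_effect = 3,
                              nb_dispersion = 0.1,
                              baseline_log_mean = log(100),
                              baseline_log_sd = 1.5,
                              library_size_range = c(0.7, 1.3),
                              isolate_effect_sd = 0.1,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_tumor_isolates >= 1, n_control_isolates >= 1,
            all(replicates_per_isolate %in% c(2L, 3L)),
            fraction_planted >= 0, fraction_planted <= 1,
            nb_dispersion > 0, baseline_log_sd >= 0, isolate_effect_sd >= 0,
            length(library_size_range) == 2, all(library_size_range > 0))
  structure(as.list(environment()), class = "screen_sim_config")
}

#' Simulate a tumor-vs-control count matrix with planted enriched genes
#'
#' Counts are negative binomial with mean
#' `baseline x isolate_effect x depth x 2^effect` (the effect applying only
#' to planted genes in tumor samples). Replicates of one isolate share the
#' isolate-level perturbation, so replicate averaging is a meaningful stage
#' downstream.
#'
#' @param config A [screen_sim_config()].
#' @return A list with `expr` (an [expr_mat] of counts), `metadata`
#'   (sample_id, group, isolate_id) and `truth` (planted gene IDs and their
#'   true log2 effects).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  n_planted <- round(config$n_genes * config$fraction_planted)
  if (config$fraction_planted > 0 && n_planted < 1) {
    abort("n_genes x fraction_planted < 1: nothing to plant",
          class = "channelscreen_validation_error")
  }
  withr::with_seed(config$seed, {
    genes <- sprintf("gene%04d", seq_len(config$n_genes))
    base_mean <- exp(rnorm(config$n_genes, config$baseline_log_mean, config$baseline_log_sd))
    planted <- sort(sample(config$n_genes, n_planted))
    effect <- numeric(config$n_genes)
    effect[planted] <- config$planted_log2_effect

    iso <- tibble(
      isolate_id = c(sprintf("GSC%02d", seq_len(config$n_tumor_isolates)),
                     sprintf("CTRL%02d", seq_len(config$n_control_isolates))),
      group = rep(c("tumor", "control"),
                  c(config$n_tumor_isolates, config$n_control_isolates)),
      n_rep = if (length(config$replicates_per_isolate) == 1) {
        config$replicates_per_isolate
      } else {
        sample(config$replicates_per_isolate,
               config$n_tumor_isolates + config$n_control_isolates, replace = TRUE)
      }
    )
    meta <- tidyr::uncount(iso, .data$n_rep, .id = "rep") |>
      mutate(sample_id = paste0(.data$isolate_id, "_r", .data$rep)) |>
      select("sample_id", "group", "isolate_id")

    iso_effect <- setNames(exp(rnorm(nrow(iso), 0, config$isolate_effect_sd)), iso$isolate_id)
    depth <- runif(nrow(meta), config$library_size_range[1], config$library_size_range[2])

    counts <- matrix(0L, config$n_genes, nrow(meta),
                     dimnames = list(genes, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      tumor <- meta$group[j] == "tumor"
      mu <- base_mean * iso_effect[[meta$isolate_id[j]]] * depth[j] *
        (if (tumor) 2^effect else 1)
      counts[, j] <- rnbinom(config$n_genes, mu = mu, size = 1 / config$nb_dispersion)
    }
    list(expr = expr_from_matrix(counts, unit = "counts"),
         metadata = meta,
         truth = list(planted_gene_ids = genes[planted],
                      log2_effects = setNames(effect, genes),
                      config = config))
  })
}

#' Write a simulated bundle to disk in pipeline-ready formats
#'
#' Writes the expression table and metadata as TSV plus the ground truth as
#' JSON, in exactly the formats the readers accept, so a simulated dataset
#' can drive [run_pipeline()] end to end.
#'
#' @param sim A list from [simulate_expression()], [simulate_regional()] or
#'   [simulate_subtype_reference()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation_bundle <- function(sim, dir) {
  stopifnot(is.list(sim), inherits(sim$expr, "expr_mat"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expr = file.path(dir, "expression.tsv"))
  write_expression_table(sim$expr, paths[["expr"]])
  meta <- sim$metadata %||% sim$labels
  if (!is.null(meta)) {
    paths[["metadata"]] <- file.path(dir, "metadata.tsv")
    readr::write_tsv(meta, paths[["metadata"]])
  }
  if (!is.null(sim$truth)) {
    paths[["truth"]] <- file.path(dir, "truth.json")
    truth <- sim$truth
    truth$config <- NULL
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(paths)
}

#' Simulate an anatomic-region FPKM table
#'
#' Per-replicate FPKM is lognormal noise around its region-level mean;
#' replicates within a sample and samples within each of the seven anatomic
#' compartments (LE, IT, CT, PZ, PAN, HBV, MVP) provide the two aggregation
#' levels [aggregate_by_region()] expects. With `noise_sd = 0` aggregation
#' recovers `region_means` exactly.
#'
#' @param n_genes Number of genes (ignored when `region_means` is given).
#' @param samples_per_region Samples per region (>= 1).
#' @param region_means Optional tibble with `gene_id` plus one numeric
#'   column per region label; when `NULL`, lognormal means are drawn.
#' @param noise_sd Lognormal noise SD (natural-log scale).
#' @param replicates_per_sample Replicates per sample.
#' @param seed Integer seed.
#' @return A list with `expr` (an [expr_mat] of FPKM), `metadata`
#'   (sample_id, isolate_id, region) and `truth` (the region means).
#' @export
simulate_regional <- function(n_genes = 50, samples_per_region = 5,
                              region_means = NULL, noise_sd = 0.3,
                              replicates_per_sample = 2, seed = 1L) {
  if (samples_per_region < 1) {
    abort("samples_per_region must be >= 1", class = "channelscreen_validation_error")
  }
  withr::with_seed(seed, {
    if (is.null(region_means)) {
      genes <- sprintf("gene%04d", seq_len(n_genes))
      region_means <- bind_cols(
        tibble(gene_id = genes),
        as_tibble(setNames(lapply(.region_levels, function(r) {
          exp(rnorm(n_genes, log(5), 1))
        }), .region_levels))
      )
    }
    missing_regions <- setdiff(.region_levels, names(region_means))
    if (length(missing_regions) > 0) {
      abort(paste0("region_means missing region(s): ", paste(missing_regions, collapse = ", ")),
            class = "channelscreen_validation_error")
    }
    genes <- region_means$gene_id
    mu <- as.matrix(region_means[.region_levels])

    meta <- tidyr::expand_grid(region = .region_levels,
                               s = seq_len(samples_per_region),
                               r = seq_len(replicates_per_sample)) |>
      mutate(isolate_id = sprintf("%s_s%02d", .data$region, .data$s),
             sample_id = sprintf("%s_rep%d", .data$isolate_id, .data$r)) |>
      select("sample_id", "isolate_id", "region")

    vals <- vapply(seq_len(nrow(meta)), function(j) {
      mu[, meta$region[j]] * exp(rnorm(length(genes), 0, noise_sd))
    }, numeric(length(genes)))
    dimnames(vals) <- list(genes, meta$sample_id)
    list(expr = expr_from_matrix(vals, unit = "FPKM"),
         metadata = meta,
         truth = list(region_means = region_means, noise_sd = noise_sd))
  })
}

#' Simulate survival times whose hazard depends on expression
#'
#' Event times are exponential with hazard
#' `baseline_hazard x exp(beta x z)` where `z` is the standardized
#' expression. Each subject is independently censored with probability
#' `censor_rate`, at a time drawn uniformly on (0, event time).
#'
#' @param expression_row Named numeric vector of per-sample expression.
#' @param beta True log-hazard coefficient per SD of expression.
#' @param baseline_hazard Baseline hazard per day (> 0).
#' @param censor_rate Probability a subject is censored, in [0, 1).
#' @param seed Integer seed.
#' @return A survival tibble (`sample_id`, `time`, `event`, `expression`)
#'   with the true coefficient in attribute `truth`.
#' @export
simulate_survival <- function(expression_row, beta, baseline_hazard = 0.002,
                              censor_rate = 0.2, seed = 1L) {
  if (baseline_hazard <= 0) {
    abort("baseline_hazard must be > 0", class = "channelscreen_validation_error")
  }
  stopifnot(censor_rate >= 0, censor_rate < 1, all(is.finite(expression_row)))
  n <- length(expression_row)
  ids <- names(expression_row) %||% sprintf("pt%03d", seq_len(n))
  withr::with_seed(seed, {
    z <- if (sd(expression_row) > 0) {
      as.numeric(scale(expression_row))
    } else {
      rep(0, n)
    }
    hazard <- baseline_hazard * exp(beta * z)
    t_event <- rexp(n, rate = hazard)
    censored <- rbinom(n, 1, censor_rate) == 1
    time <- ifelse(censored, runif(n, 0, t_event), t_event)
    tbl <- tibble(sample_id = ids, time = time,
                  event = as.integer(!censored),
                  expression = unname(expression_row))
    attr(tbl, "truth") <- list(beta = beta, baseline_hazard = baseline_hazard)
    tbl
  })
}

#' Simulate a molecular-subtype reference cohort
#'
#' Subtype centroids are orthogonal mean-shift patterns: the signature genes
#' are split into one block per subtype, and a subtype's centroid raises its
#' own block by `centroid_separation` above a common baseline. Samples are
#' centroid plus Gaussian noise (floored at zero so abundances stay valid).
#'
#' @param n_genes_signature Signature size (default 770).
#' @param n_subtypes Number of subtypes (default 4: Classical, Mesenchymal,
#'   Neural, Proneural).
#' @param samples_per_subtype Reference samples per subtype (>= 2).
#' @param centroid_separation Mean shift of a subtype's own gene block.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return A list with `expr` (an [expr_mat]), `labels` (sample_id,
#'   subtype) and `truth` (true centroids and labels).
#' @export
simulate_subtype_reference <- function(n_genes_signature = 770, n_subtypes = 4,
                                       samples_per_subtype = 10,
                                       centroid_separation = 2, noise_sd = 0.5,
                                       seed = 1L) {
  if (samples_per_subtype < 2) {
    abort("samples_per_subtype must be >= 2 (median centroid needs >= 2 samples)",
          class = "channelscreen_validation_error")
  }
  stopifnot(centroid_separation >= 0, noise_sd >= 0, n_subtypes >= 2)
  subtypes <- if (n_subtypes == 4) .subtype_levels else paste0("subtype", seq_len(n_subtypes))
  withr::with_seed(seed, {
    genes <- sprintf("sig%04d", seq_len(n_genes_signature))
    block <- rep(seq_len(n_subtypes), length.out = n_genes_signature)
    baseline <- 10
    centroids <- vapply(seq_len(n_subtypes), function(k) {
      baseline + centroid_separation * (block == k)
    }, numeric(n_genes_signature))
    colnames(centroids) <- subtypes

    labels <- tibble(
      sample_id = sprintf("ref_%s_%02d",
                          rep(subtypes, each = samples_per_subtype),
                          rep(seq_len(samples_per_subtype), n_subtypes)),
      subtype = rep(subtypes, each = samples_per_subtype)
    )
    vals <- vapply(seq_len(nrow(labels)), function(j) {
      pmax(0, centroids[, labels$subtype[j]] +
             rnorm(n_genes_signature, 0, noise_sd))
    }, numeric(n_genes_signature))
    dimnames(vals) <- list(genes, labels$sample_id)
    list(expr = expr_from_matrix(vals, unit = "CPM"),
         labels = labels,
         truth = list(centroids = bind_cols(tibble(gene_id = genes), as_tibble(centroids)),
                      labels = labels))
  })
}
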