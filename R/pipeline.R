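#' Assemble a pipeline run configuration
#'
#' All stage parameters default to the screen's canonical values: |2| log2
#' fold-change cut, top 40 ranked genes, mean tumor CPM >= 1, 2-fold edge
#' enrichment, 5/1 FPKM abundance bounds, 0.10/0.90 survival quantiles, and
#' the >= 3-mutant-sample inclusion rule. Inputs are file paths; stages
#' whose inputs are absent are skipped.
#'
#' @param counts Path to a raw count table (genes x samples).
#' @param metadata Path to the sample metadata table.
#' @param gene_sets Optional GMT file of gene sets to screen.
#' @param families Optional gene -> family annotation table.
#' @param fpkm,regions Optional regional FPKM table and sample -> region map.
#' @param survival Optional survival table (sample_id, time, event,
#'   expression).
#' @param reference,reference_labels,signature Optional subtype reference
#'   expression, its labels, and a signature gene list (one ID per line).
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param log2fc_threshold,zero_policy,top_k,cpm_min,fold_cut Screen
#'   parameters.
#' @param edge_fold,fpkm_high,fpkm_low Regional parameters.
#' @param surv_lo,surv_hi Survival quantile bounds.
#' @param min_mutant Mutation inclusion rule.
#' @param n_perm,perm_scheme Permutation-null parameters.
#' @param use_tmm Apply TMM scale factors before CPM.
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts, metadata, gene_sets = NULL, families = NULL,
                       fpkm = NULL, regions = NULL, survival = NULL,
                       reference = NULL, reference_labels = NULL, signature = NULL,
                       out_dir = tempfile("channelscreen_run_"),
                       log2fc_threshold = 2, zero_policy = "exclude",
                       top_k = 40, cpm_min = 1, fold_cut = 2,
                       edge_fold = 2, fpkm_high = 5, fpkm_low = 1,
                       surv_lo = 0.10, surv_hi = 0.90, min_mutant = 3,
                       n_perm = 1000, perm_scheme = "gene_set",
                       use_tmm = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

#' Run the end-to-end screening pipeline
#'
#' Stage order: normalization (TMM + CPM + replicate averaging), enrichment
#' screen (fold changes, Signal2Noise ranking, running-sum enrichment with
#' permutation p per gene set, candidate selection, family summary), then —
#' when inputs are present — subtype classification, regional profiling and
#' expression-stratified survival. Every stage writes a TSV into
#' `config$out_dir`; the returned manifest records resolved parameters,
#' per-file md5 digests and collected warnings, and rerunning an identical
#' config on identical inputs reproduces the digests.
#'
#' @param config A [run_config()].
#' @return A list of class `run_manifest` (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  required <- c("counts", "metadata")
  for (f in required) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      abort(paste0("required input '", f, "' missing: ", config[[f]] %||% "NULL"),
            class = "channelscreen_validation_error")
    }
  }
  optional <- c("gene_sets", "families", "fpkm", "regions", "survival",
                "reference", "reference_labels", "signature")
  for (f in optional) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      abort(paste0("configured input '", f, "' does not exist: ", config[[f]]),
            class = "channelscreen_validation_error")
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character()
  outputs <- character()
  stages <- character()
  emit <- function(tbl, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(tbl), path)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(name, code) {
    withCallingHandlers(code, warning = function(w) {
      warnings_seen <<- c(warnings_seen, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    stages <<- c(stages, name)
  }

  counts <- read_expression_table(config$counts, unit = "counts")
  meta <- read_sample_metadata(config$metadata, counts)

  cpm_mat <- NULL
  run_stage("normalize", {
    factors <- if (config$use_tmm) tmm_factors(counts) else NULL
    cpm_mat <- cpm(counts, factors)
    iso_cpm <- average_replicates(cpm_mat, meta)
    emit(as_tibble(iso_cpm), "cpm_isolates")
    if (!is.null(factors)) emit(factors, "tmm_factors")
  })

  tumor_means <- group_means(cpm_mat, meta, "tumor")
  control_means <- group_means(cpm_mat, meta, "control")
  ranked <- NULL
  run_stage("screen", {
    fc <- log2fc_screen(tumor_means, control_means,
                        threshold = config$log2fc_threshold,
                        zero_policy = config$zero_policy)
    emit(fc, "fold_changes")
    ranked <- signal2noise_rank(cpm_mat, meta)
    emit(ranked, "ranking")
    sel <- select_candidates(ranked, tumor_means,
                             top_k = min(config$top_k, nrow(ranked)),
                             cpm_min = config$cpm_min)
    emit(tidy(sel), "selection_audit")
    emit(sel$candidates, "candidates")
    if (!is.null(config$gene_sets)) {
      sets <- read_gene_sets_gmt(config$gene_sets)
      enr <- purrr::map_dfr(names(sets), function(nm) {
        res <- gsea_permutation_p(cpm_mat, meta, sets[[nm]],
                                  n_perm = config$n_perm,
                                  scheme = config$perm_scheme,
                                  seed = config$seed, set_name = nm)
        glance(res)
      })
      emit(enr, "enrichment")
    }
    if (!is.null(config$families)) {
      fam <- read_family_annotation(config$families)
      fc_ex <- log2fc_screen(tumor_means, control_means,
                             threshold = config$log2fc_threshold,
                             zero_policy = "exclude")
      emit(family_enrichment(fc_ex, fam, fold_cut = config$fold_cut),
           "family_enrichment")
    }
  })

  if (!is.null(config$reference) && !is.null(config$reference_labels)) {
    run_stage("subtype", {
      ref <- read_expression_table(config$reference, unit = "CPM")
      labels <- readr::read_tsv(config$reference_labels, show_col_types = FALSE)
      sig <- if (!is.null(config$signature)) readr::read_lines(config$signature) else ref$gene_id
      cent <- compute_centroids(ref, labels, sig)
      calls <- classify_by_centroid(cpm_mat, cent)
      calls <- left_join(calls, select(meta, "sample_id", "isolate_id"), by = "sample_id")
      consensus <- calls |>
        group_by(.data$isolate_id) |>
        dplyr::group_modify(~ tibble(subtype = consensus_call(.x))) |>
        ungroup()
      emit(calls, "subtype_calls")
      emit(consensus, "subtype_consensus")
    })
  }

  if (!is.null(config$fpkm) && !is.null(config$regions)) {
    run_stage("regions", {
      fpkm_mat <- read_expression_table(config$fpkm, unit = "FPKM")
      region_map <- read_sample_metadata(config$regions, fpkm_mat)
      prof <- aggregate_by_region(fpkm_mat, region_map)
      emit(prof$means, "region_means")
      emit(edge_enrichment(prof, fold = config$edge_fold), "edge_enrichment")
      emit(abundance_classes(prof, high = config$fpkm_high, low = config$fpkm_low),
           "abundance_classes")
      if (!is.null(config$families)) {
        fam <- read_family_annotation(config$families)
        emit(family_region_proportions(prof, fam), "family_region_proportions")
      }
    })
  }

  if (!is.null(config$survival)) {
    run_stage("survival", {
      surv <- read_survival_table(config$survival)
      if (!"expression" %in% names(surv)) {
        abort("survival table needs an expression column for stratification",
              class = "channelscreen_validation_error")
      }
      strata <- stratify_quantile(surv$expression, config$surv_lo, config$surv_hi)
      keep <- strata != "excluded"
      lr <- logrank_test(surv[keep, ], strata[keep])
      per_stratum <- purrr::map_dfr(c("low", "high"), function(s) {
        km <- km_estimate(surv[strata == s, ])
        mutate(glance(km), stratum = s)
      })
      emit(tibble(statistic = lr$statistic, df = lr$df, p_value = lr$p_value),
           "logrank")
      emit(per_stratum, "km_summary")
      km_tbl <- purrr::map_dfr(c("low", "high"), function(s) {
        mutate(tidy(km_estimate(surv[strata == s, ])), stratum = s)
      })
      emit(km_tbl, "km_curves")
    })
  }

  manifest <- structure(list(
    config = config[setdiff(names(config), "out_dir")],
    out_dir = config$out_dir,
    version = as.character(utils::packageVersion("channelscreen")),
    stages = stages,
    digests = setNames(as.character(tools::md5sum(outputs)), basename(outputs)),
    warnings = warnings_seen,
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "run_manifest")
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "config")],
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("# run_manifest (channelscreen ", x$version, ")\n", sep = "")
  cat("stages: ", paste(x$stages, collapse = " -> "), "\n", sep = "")
  cat(length(x$digests), " output file(s) in ", x$out_dir, "\n", sep = "")
  if (length(x$warnings) > 0) cat(length(x$warnings), "warning(s) recorded\n")
  invisible(x)
}
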