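#' Aggregate per-sample FPKM into a region-level profile
#'
#' Two-level arithmetic mean: replicate columns are averaged into sample
#' (isolate) values, and sample values are averaged within each anatomic
#' region. Regions from the seven-label vocabulary with no samples are
#' omitted with a warning. Per-sample values are retained so majority-of-
#' samples rules can be evaluated later.
#'
#' @param x An [expr_mat] with unit `"FPKM"`.
#' @param metadata Tibble with `sample_id`, `region` and optionally
#'   `isolate_id` (replicate grouping; defaults to one sample = one
#'   isolate).
#' @return A list of class `regional_profile` with `means` (gene_id + one
#'   column per region), `n_samples` (region, n), and `per_sample` (the
#'   isolate-averaged [expr_mat] plus its region map).
#' @export
aggregate_by_region <- function(x, metadata) {
  check_unit(x, "FPKM", "aggregate_by_region")
  metadata <- validate_metadata(metadata, x)
  if (!"region" %in% names(metadata) || anyNA(metadata$region)) {
    abort("every sample needs a region label", class = "channelscreen_validation_error")
  }
  if (!"isolate_id" %in% names(metadata)) metadata$isolate_id <- metadata$sample_id
  per_sample <- average_replicates(x, metadata)
  iso_meta <- distinct(metadata, .data$isolate_id, .data$region)
  m <- expr_values(per_sample)

  present <- intersect(.region_levels, unique(iso_meta$region))
  absent <- setdiff(unique(iso_meta$region), present)
  omitted <- setdiff(.region_levels, present)
  if (length(omitted) > 0) {
    warn(paste0("region(s) with no samples omitted: ", paste(omitted, collapse = ", ")))
  }
  means <- vapply(present, function(r) {
    cols <- intersect(iso_meta$isolate_id[iso_meta$region == r], colnames(m))
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  means <- matrix(means, nrow = nrow(m), dimnames = list(rownames(m), present))
  n_samples <- tibble(region = present,
                      n = vapply(present, function(r) sum(iso_meta$region == r),
                                 integer(1), USE.NAMES = FALSE))
  structure(list(means = bind_cols(tibble(gene_id = rownames(m)), as_tibble(means)),
                 n_samples = n_samples,
                 per_sample = list(expr = per_sample, regions = iso_meta)),
            class = "regional_profile")
}

region_means_matrix <- function(profile) {
  stopifnot(inherits(profile, "regional_profile"))
  m <- as.matrix(as_tibble(profile$means)[setdiff(names(profile$means), "gene_id")])
  rownames(m) <- profile$means$gene_id
  m
}

#' Flag genes enriched at the tumor edge (LE/IT)
#'
#' Ratio of the mean of the LE and IT region means to the mean of all other
#' region means; a gene is flagged when the ratio is at least `fold`.
#' A zero denominator with positive numerator gives an infinite ratio
#' (flagged); 0/0 is defined as 1 (not flagged) — absence of signal is not
#' enrichment.
#'
#' @param profile A `regional_profile`.
#' @param fold Minimum edge-to-rest fold (default 2; `>=` comparison).
#' @return A tibble (`gene_id`, `edge_mean`, `other_mean`, `ratio`,
#'   `flagged`).
#' @export
edge_enrichment <- function(profile, fold = 2) {
  m <- region_means_matrix(profile)
  edge <- intersect(c("LE", "IT"), colnames(m))
  if (length(edge) == 0) {
    abort("edge_enrichment() needs at least one of the LE/IT regions",
          class = "channelscreen_validation_error")
  }
  other <- setdiff(colnames(m), c("LE", "IT"))
  if (length(other) == 0) {
    abort("edge_enrichment() needs at least one non-edge region",
          class = "channelscreen_validation_error")
  }
  edge_mean <- unname(rowMeans(m[, edge, drop = FALSE]))
  other_mean <- unname(rowMeans(m[, other, drop = FALSE]))
  ratio <- dplyr::case_when(edge_mean == 0 & other_mean == 0 ~ 1,
                            other_mean == 0 ~ Inf,
                            TRUE ~ edge_mean / other_mean)
  tibble(gene_id = rownames(m), edge_mean = edge_mean, other_mean = other_mean,
         ratio = ratio, flagged = ratio >= fold & edge_mean > 0)
}

#' Classify genes by absolute regional abundance
#'
#' `high`: at least `high` FPKM in at least one region; `low`: under `low`
#' FPKM in every region; `intermediate`: everything else. The three classes
#' are mutually exclusive and exhaustive; the boundaries follow the rules
#' exactly (`>= high` is high; strictly `< low` everywhere is low, so a gene
#' sitting exactly at `low` in all regions is intermediate).
#'
#' @param profile A `regional_profile`.
#' @param high High-abundance cut in FPKM (default 5).
#' @param low Low-abundance cut in FPKM (default 1).
#' @return A tibble (`gene_id`, `max_region_mean`, `class`).
#' @export
abundance_classes <- function(profile, high = 5, low = 1) {
  if (high <= low) {
    abort("high cut must exceed low cut", class = "channelscreen_validation_error")
  }
  m <- region_means_matrix(profile)
  mx <- apply(m, 1, max)
  cls <- dplyr::case_when(mx >= high ~ "high",
                          mx < low ~ "low",
                          TRUE ~ "intermediate")
  tibble(gene_id = rownames(m), max_region_mean = mx, class = cls)
}

#' Proportion of family members expressed per region
#'
#' Per family and region, the proportion of member genes whose region mean
#' exceeds `expr_cut` (strict `>`). Families with fewer than `min_family`
#' members in the profile are omitted; genes without annotation are skipped
#' with a warning.
#'
#' @param profile A `regional_profile`.
#' @param families Tibble (`gene_id`, `family`).
#' @param expr_cut Expression cut in FPKM (default 1).
#' @param min_family Minimum family size (default 3).
#' @return A tibble (`family`, `region`, `n_members`, `proportion`).
#' @export
family_region_proportions <- function(profile, families, expr_cut = 1, min_family = 3) {
  m <- region_means_matrix(profile)
  unannotated <- setdiff(rownames(m), families$gene_id)
  if (length(unannotated) > 0) {
    warn(paste0(length(unannotated), " gene(s) without family annotation skipped"))
  }
  long <- as_tibble(profile$means) |>
    tidyr::pivot_longer(-"gene_id", names_to = "region", values_to = "mean_fpkm") |>
    inner_join(as_tibble(families), by = "gene_id")
  long |>
    group_by(.data$family, .data$region) |>
    summarise(n_members = n(),
              proportion = mean(.data$mean_fpkm > expr_cut), .groups = "drop") |>
    filter(.data$n_members >= min_family)
}

#' Classify genes by cell-type specificity
#'
#' `low_abundance` when no cell type reaches `low_cut` mean FPKM;
#' `specific` when the top cell type's mean is at least `ratio_cut` times
#' the second-highest; otherwise `multiple`. The dominance-ratio rule is a
#' declared convention, parameterized.
#'
#' @param celltype_means Tibble with `gene_id` plus one numeric column per
#'   cell type (>= 2 cell types).
#' @param low_cut Low-abundance cut in FPKM (default 1).
#' @param ratio_cut Dominance ratio for a specific call (default 2).
#' @return A tibble (`gene_id`, `class`, `cell_type`) where `cell_type` is
#'   `NA` unless the class is `specific`.
#' @export
cell_type_specificity <- function(celltype_means, low_cut = 1, ratio_cut = 2) {
  celltype_means <- as_tibble(celltype_means)
  stopifnot("gene_id" %in% names(celltype_means))
  types <- setdiff(names(celltype_means), "gene_id")
  if (length(types) < 2) {
    abort("cell_type_specificity() needs >= 2 cell types",
          class = "channelscreen_validation_error")
  }
  m <- as.matrix(celltype_means[types])
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    if (max(v) < low_cut) {
      return(tibble(gene_id = celltype_means$gene_id[i],
                    class = "low_abundance", cell_type = NA_character_))
    }
    o <- order(-v)
    specific <- v[o[1]] >= ratio_cut * v[o[2]]
    tibble(gene_id = celltype_means$gene_id[i],
           class = if (specific) "specific" else "multiple",
           cell_type = if (specific) types[o[1]] else NA_character_)
  })
}

#' @export
print.regional_profile <- function(x, ...) {
  cat("# regional_profile: ", nrow(x$means), " genes x ",
      nrow(x$n_samples), " regions (",
      paste0(x$n_samples$region, "=", x$n_samples$n, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
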