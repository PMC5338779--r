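#' Fold-change screen between tumor and control mean abundances
#'
#' Classifies each gene by `log2(tumor_mean / control_mean)` against a
#' symmetric threshold. Two zero-handling policies are supported:
#' `"exclude"` drops genes with a zero denominator from the fold-change
#' arithmetic (status `excluded_zero_denominator`, no log2fc), while
#' `"replace"` substitutes a pseudo-value (default 0.01) for zero means in
#' either class before taking the ratio. Both policies agree exactly on
#' genes with positive denominators.
#'
#' @param tumor_means,control_means Tibbles (`gene_id`, `mean`) over the
#'   same gene universe, e.g. from [group_means()].
#' @param threshold Absolute log2 fold-change cut for enrichment calls.
#' @param zero_policy `"exclude"` or `"replace"`.
#' @param pseudo Replacement value for zeros under the `"replace"` policy.
#' @return A tibble (`gene_id`, `tumor_mean`, `control_mean`, `log2fc`,
#'   `status`) with `status` one of `tumor_enriched`, `control_enriched`,
#'   `unchanged`, `excluded_zero_denominator`; the policy is recorded in
#'   attribute `zero_policy`.
#' @export
log2fc_screen <- function(tumor_means, control_means, threshold = 2,
                          zero_policy = c("exclude", "replace"), pseudo = 0.01) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(all(c("gene_id", "mean") %in% names(tumor_means)),
            all(c("gene_id", "mean") %in% names(control_means)))
  if (!setequal(tumor_means$gene_id, control_means$gene_id)) {
    abort("tumor and control means must cover the same gene universe",
          class = "channelscreen_validation_error")
  }
  tbl <- inner_join(rename(tumor_means, tumor_mean = "mean"),
                    rename(control_means, control_mean = "mean"),
                    by = "gene_id")
  if (any(tbl$tumor_mean < 0) || any(tbl$control_mean < 0)) {
    abort("negative mean abundance", class = "channelscreen_validation_error")
  }
  if (zero_policy == "exclude") {
    tbl <- mutate(tbl,
      log2fc = dplyr::if_else(.data$control_mean > 0,
                              log2(.data$tumor_mean / .data$control_mean), NA_real_),
      status = dplyr::if_else(.data$control_mean == 0,
                              "excluded_zero_denominator", NA_character_))
  } else {
    tbl <- mutate(tbl,
      log2fc = log2(dplyr::if_else(.data$tumor_mean == 0, pseudo, .data$tumor_mean) /
                      dplyr::if_else(.data$control_mean == 0, pseudo, .data$control_mean)),
      status = NA_character_)
  }
  tbl <- mutate(tbl, status = case_when(
    !is.na(.data$status) ~ .data$status,
    .data$log2fc >= threshold ~ "tumor_enriched",
    .data$log2fc <= -threshold ~ "control_enriched",
    TRUE ~ "unchanged"
  ))
  structure(tbl, zero_policy = zero_policy, threshold = threshold,
            class = class(tibble()))
}

#' Family-level enrichment summary
#'
#' Summarises a fold-change screen per ion-channel family: mean log2 fold
#' change over usable members, the proportion of members with fold change
#' strictly greater than `fold_cut`, and mean tumor abundance. Members
#' excluded for a zero denominator are unusable; families with at most one
#' usable member are omitted, and genes without a family annotation are
#' skipped with a warning.
#'
#' @param fold_changes Result of [log2fc_screen()] computed under the
#'   `"exclude"` zero policy.
#' @param families Tibble (`gene_id`, `family`).
#' @param fold_cut Fold-change cut (linear scale; strict `>`).
#' @return A tibble (`family`, `mean_log2fc`, `prop_above_fold`,
#'   `mean_tumor_mean`, `n_members_used`).
#' @export
family_enrichment <- function(fold_changes, families, fold_cut = 2) {
  if (!identical(attr(fold_changes, "zero_policy"), "exclude")) {
    abort("family_enrichment() requires fold changes computed under the 'exclude' zero policy",
          class = "channelscreen_validation_error")
  }
  unannotated <- setdiff(fold_changes$gene_id, families$gene_id)
  if (length(unannotated) > 0) {
    warn(paste0(length(unannotated), " gene(s) without family annotation skipped"))
  }
  fold_changes |>
    inner_join(families, by = "gene_id") |>
    filter(.data$status != "excluded_zero_denominator") |>
    group_by(.data$family) |>
    summarise(mean_log2fc = mean(.data$log2fc),
              prop_above_fold = mean(2^.data$log2fc > fold_cut),
              mean_tumor_mean = mean(.data$tumor_mean),
              n_members_used = n(), .groups = "drop") |>
    filter(.data$n_members_used > 1)
}
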