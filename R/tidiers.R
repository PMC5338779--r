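#' Tidy a running-sum enrichment result
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @return The running-sum tibble (position, gene_id, score, hit, running).
#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, ...) x$running_sum

#' One-row summary of an enrichment result
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(set_name = x$set_name, es = x$es,
         nes = x$nes %||% NA_real_, p_value = x$p_value %||% NA_real_,
         n_hits = x$n_hits, n_leading_edge = length(x$leading_edge),
         n_perm = x$n_perm %||% NA_integer_,
         scheme = x$scheme %||% NA_character_)
}

#' Tidy a Kaplan-Meier curve
#' @param x A `km_curve`.
#' @param ... Unused.
#' @return The curve tibble (time, n_risk, n_event, n_censor, survival).
#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) x$curve

#' One-row summary of a Kaplan-Meier curve
#' @param x A `km_curve`.
#' @param ... Unused.
#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, median_survival = x$median_survival)
}

#' Tidy a regional profile into long format
#' @param x A `regional_profile`.
#' @param ... Unused.
#' @return A tibble (gene_id, region, mean_fpkm).
#' @method tidy regional_profile
#' @export
tidy.regional_profile <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x$means), -"gene_id",
                      names_to = "region", values_to = "mean_fpkm")
}

#' Tidy a candidate selection: candidates plus the drop audit
#' @param x A `candidate_selection`.
#' @param ... Unused.
#' @return A tibble of all screened genes with a `stage` column
#'   (`candidate`, `below_top_k` or `below_cpm_min`).
#' @method tidy candidate_selection
#' @export
tidy.candidate_selection <- function(x, ...) {
  bind_rows(mutate(select(x$candidates, "gene_id"), stage = "candidate"),
            rename(x$audit, stage = "stage_dropped"))
}

#' One-row summary of a candidate selection
#' @param x A `candidate_selection`.
#' @param ... Unused.
#' @method glance candidate_selection
#' @export
glance.candidate_selection <- function(x, ...) {
  tibble(n_candidates = nrow(x$candidates),
         top_k = x$params$top_k, cpm_min = x$params$cpm_min,
         n_dropped_cpm = sum(x$audit$stage_dropped == "below_cpm_min"))
}
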