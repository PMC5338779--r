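#' Plot the running-sum walk of an enrichment result
#' @param object A `gsea_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  rs <- object$running_sum
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$position, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = dplyr::filter(rs, .data$hit), sides = "b",
                      alpha = 0.5, length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "Rank in ordered gene list", y = "Running enrichment score",
                  title = paste0(object$set_name, ": ES = ", signif(object$es, 3))) +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier curve
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot (step function, starting at S(0) = 1).
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  curve <- bind_rows(tibble(time = 0, survival = 1),
                     select(object$curve, "time", "survival"))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for two expression strata on one panel
#' @param table Survival tibble with `time` and `event`.
#' @param strata Stratum labels, one per row.
#' @return A ggplot.
#' @export
plot_km_strata <- function(table, strata) {
  table <- as_tibble(table)
  curves <- purrr::map_dfr(unique(strata), function(s) {
    km <- km_estimate(table[strata == s, ])
    bind_rows(tibble(time = 0, survival = 1), select(km$curve, "time", "survival")) |>
      mutate(stratum = s)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability", colour = "Stratum") +
    ggplot2::theme_minimal()
}

#' Bubble plot of family-level enrichment
#'
#' Mean log2 fold change against the proportion of family members above the
#' fold cut, bubble size by mean tumor abundance.
#'
#' @param family_summary Result of [family_enrichment()].
#' @return A ggplot.
#' @export
plot_family_enrichment <- function(family_summary) {
  ggplot2::ggplot(family_summary,
                  ggplot2::aes(x = .data$prop_above_fold, y = .data$mean_log2fc,
                               size = .data$mean_tumor_mean)) +
    ggplot2::geom_point(alpha = 0.7, colour = "#e6550d") +
    ggplot2::geom_text(ggplot2::aes(label = .data$family), size = 2.6,
                       vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = "Proportion of members > fold cut",
                  y = "Mean log2 fold change (tumor vs control)",
                  size = "Mean tumor CPM") +
    ggplot2::theme_minimal()
}

#' Heatmap of a regional expression profile
#' @param object A `regional_profile`.
#' @param log_scale Show log2(FPKM + 1).
#' @param ... Unused.
#' @return A ggplot tile map, regions ordered by the anatomic vocabulary.
#' @method autoplot regional_profile
#' @export
autoplot.regional_profile <- function(object, log_scale = TRUE, ...) {
  long <- tidy.regional_profile(object) |>
    mutate(region = factor(.data$region, levels = .region_levels),
           value = if (log_scale) log2(.data$mean_fpkm + 1) else .data$mean_fpkm)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (log_scale) "log2(FPKM+1)" else "FPKM") +
    ggplot2::labs(x = "Anatomic region", y = NULL) +
    ggplot2::theme_minimal()
}
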