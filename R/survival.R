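#' Stratify samples by expression quantiles
#'
#' Labels values at or below the `lo` quantile `"low"`, at or above the
#' `hi` quantile `"high"`, and everything between `"excluded"` — the
#' top/bottom-decile split used for cohort survival comparisons. Quantiles
#' use linear interpolation between order statistics (type 7).
#'
#' @param values Numeric expression vector (>= 10 values).
#' @param lo,hi Quantile bounds, `0 <= lo < hi <= 1`.
#' @return Character vector of labels, same length as `values`.
#' @export
stratify_quantile <- function(values, lo = 0.10, hi = 0.90) {
  stopifnot(is.numeric(values), lo >= 0, hi <= 1, lo < hi)
  if (length(values) < 10) {
    abort("quantile stratification needs >= 10 samples",
          class = "channelscreen_validation_error")
  }
  if (max(values) == min(values)) {
    abort("all expression values identical; strata degenerate",
          class = "channelscreen_validation_error")
  }
  q <- quantile(values, c(lo, hi), type = 7, names = FALSE)
  case_when(values <= q[1] ~ "low",
            values >= q[2] ~ "high",
            TRUE ~ "excluded")
}

#' Stratify samples at the median
#'
#' `"high"` is strictly above the median, `"low"` at or below it; a value
#' exactly equal to the median is low. An externally supplied median (for
#' example one computed on a larger cohort) overrides the computed one.
#'
#' @param values Numeric expression vector (>= 2 values).
#' @param median_value Optional externally supplied median.
#' @return Character vector of `"low"`/`"high"` labels.
#' @export
stratify_median <- function(values, median_value = NULL) {
  stopifnot(is.numeric(values), length(values) >= 2)
  m <- median_value %||% median(values)
  dplyr::if_else(values > m, "high", "low")
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` and returns a tidy curve: at-risk, event and
#' censoring counts with the survival probability after each distinct time.
#' Samples censored exactly at an event time count as at risk for that
#' time (the standard convention). The median is the first time at which
#' the curve reaches 0.5 or below, `NA` if it never does.
#'
#' @param table Survival tibble with `time` and `event` (1 = death,
#'   0 = censored) columns.
#' @return A list of class `km_curve` with `curve` (tibble: time, n_risk,
#'   n_event, n_censor, survival), `median_survival`, `n`, `n_events`.
#' @export
km_estimate <- function(table) {
  table <- validate_survival_table(table)
  if (nrow(table) < 1) {
    abort("survival table is empty", class = "channelscreen_validation_error")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  curve <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, survival = fit$surv)
  med <- curve$time[curve$survival <= 0.5][1]
  structure(list(curve = curve,
                 median_survival = if (is.na(med)) NA_real_ else med,
                 n = nrow(table), n_events = sum(table$event)),
            class = "km_curve")
}

#' Log-rank (Mantel-Cox) test between two survival strata
#'
#' Wraps `survival::survdiff` (rho = 0): observed minus expected events with
#' hypergeometric variance summed over distinct event times, referred to a
#' chi-square distribution with 1 degree of freedom. Exactly two non-empty
#' strata are required.
#'
#' @param table Survival tibble with `time` and `event` columns.
#' @param strata Character/factor vector of stratum labels, one per row
#'   (exactly 2 distinct non-empty strata).
#' @return A one-row tibble (`statistic`, `df`, `p_value`, `n_low`,
#'   `n_high` ... per-stratum n and events).
#' @export
logrank_test <- function(table, strata) {
  table <- as_tibble(table)
  stopifnot(nrow(table) == length(strata))
  lv <- unique(as.character(strata))
  if (length(lv) != 2) {
    abort(paste0("log-rank needs exactly 2 non-empty strata, got ", length(lv)),
          class = "channelscreen_validation_error")
  }
  d <- mutate(table, .stratum = as.character(strata))
  if (sum(d$event) == 0) {
    abort("no events in either stratum; log-rank undefined",
          class = "channelscreen_validation_error")
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ .stratum, data = d)
  stat <- sd_fit$chisq
  tibble(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         strata = paste(lv, collapse = " vs "),
         n = list(setNames(as.integer(sd_fit$n), lv)),
         observed = list(setNames(sd_fit$obs, lv)),
         expected = list(setNames(sd_fit$exp, lv)))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups with average-rank ties. The p-value is
#' exact when the smaller group has at most 8 observations and there are no
#' ties, and otherwise uses the normal approximation with tie correction
#' (no continuity correction, so the two-group case agrees with
#' [kruskal_wallis()]).
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return A one-row tibble (`u`, `p_value`, `exact`, `n_x`, `n_y`).
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact, correct = FALSE)
  )
  tibble(u = unname(wt$statistic), p_value = wt$p.value, exact = exact,
         n_x = length(x), n_y = length(y))
}

#' Kruskal-Wallis test across groups
#'
#' Wraps `stats::kruskal.test` (H with tie correction, chi-square reference
#' with k - 1 degrees of freedom).
#'
#' @param groups A list of numeric vectors, one per group (>= 2 groups,
#'   each non-empty).
#' @return A one-row tibble (`h`, `df`, `p_value`).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2, all(lengths(groups) >= 1))
  v <- unlist(groups, use.names = FALSE)
  if (max(v) == min(v)) {
    abort("all observations identical; H undefined after tie correction",
          class = "channelscreen_validation_error")
  }
  kt <- kruskal.test(groups)
  tibble(h = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Associate gene expression with mutation status across isolates
#'
#' For every mutation carried by at least `min_mutant` isolates (and at
#' least one wildtype isolate), compares each gene's expression between
#' mutant and wildtype isolates with [mann_whitney()]. Mutations below the
#' inclusion rule are skipped and listed in attribute `skipped`.
#'
#' @param x An [expr_mat] of isolate-level expression.
#' @param mutations Tibble (`isolate_id`, `mutation`, `status`) with status
#'   `"mutant"` or `"wildtype"`.
#' @param min_mutant Minimum number of mutant isolates (default 3).
#' @return A tibble (`gene_id`, `mutation`, `n_mutant`, `n_wildtype`, `u`,
#'   `p_value`).
#' @export
mutation_association <- function(x, mutations, min_mutant = 3) {
  stopifnot(inherits(x, "expr_mat"))
  mutations <- as_tibble(mutations)
  stopifnot(all(c("isolate_id", "mutation", "status") %in% names(mutations)))
  if (!all(mutations$status %in% c("mutant", "wildtype"))) {
    abort("mutation status must be 'mutant' or 'wildtype'",
          class = "channelscreen_validation_error")
  }
  m <- expr_values(x)
  skipped <- character()
  out <- purrr::map_dfr(unique(mutations$mutation), function(mu) {
    flags <- filter(mutations, .data$mutation == mu,
                    .data$isolate_id %in% colnames(m))
    mut_ids <- flags$isolate_id[flags$status == "mutant"]
    wt_ids <- flags$isolate_id[flags$status == "wildtype"]
    if (length(mut_ids) < min_mutant || length(wt_ids) < 1) {
      skipped <<- c(skipped, mu)
      return(NULL)
    }
    purrr::map_dfr(rownames(m), function(g) {
      mw <- mann_whitney(m[g, mut_ids], m[g, wt_ids])
      tibble(gene_id = g, mutation = mu,
             n_mutant = length(mut_ids), n_wildtype = length(wt_ids),
             u = mw$u, p_value = mw$p_value)
    })
  })
  if (length(skipped) > 0) {
    message("mutation(s) skipped (< ", min_mutant, " mutant isolates): ",
            paste(skipped, collapse = ", "))
  }
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("# km_curve: n = ", x$n, ", events = ", x$n_events,
      ", median survival = ",
      if (is.na(x$median_survival)) "not reached" else x$median_survival,
      "\n", sep = "")
  invisible(x)
}
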