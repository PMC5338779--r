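#' Rank genes by the Signal2Noise metric
#'
#' Score per gene is `(mu_tumor - mu_control) / (sd_tumor + sd_control)`
#' over isolate-level columns, with each class SD floored at
#' `max(sd, floor_frac * |mu|, abs_floor)` — the conventional adjustment
#' that keeps low-variance genes from dominating. Replicates are averaged
#' to isolate columns first (set `use_replicates = TRUE` to rank on raw
#' replicate columns instead). The list is sorted by descending score with
#' ties broken lexicographically by gene ID, so reruns are deterministic.
#'
#' @param x An [expr_mat] (typically CPM).
#' @param metadata Tibble with `sample_id`, `group`, `isolate_id`.
#' @param floor_frac Relative SD floor (fraction of |mean|).
#' @param abs_floor Absolute SD floor; defaults to `0.2 * floor_frac`.
#' @param use_replicates Rank on replicate-level columns instead of
#'   isolate-averaged columns.
#' @return A tibble (`gene_id`, `score`, `rank`) of class `ranked_genes`
#'   with attribute `metric = "signal2noise"`.
#' @export
signal2noise_rank <- function(x, metadata, floor_frac = 0.2,
                              abs_floor = 0.2 * floor_frac,
                              use_replicates = FALSE) {
  stopifnot(inherits(x, "expr_mat"))
  metadata <- as_tibble(metadata)
  if (!"isolate_id" %in% names(metadata)) metadata$isolate_id <- metadata$sample_id
  if (use_replicates || all(expr_samples(x) %in% metadata$sample_id)) {
    if (!use_replicates) x <- average_replicates(x, metadata)
  }
  m <- expr_values(x)
  col_meta <- if (use_replicates) {
    setNames(metadata$group, metadata$sample_id)
  } else {
    iso <- distinct(metadata, .data$isolate_id, .data$group)
    setNames(iso$group, iso$isolate_id)
  }
  grp <- col_meta[colnames(m)]
  if (anyNA(grp)) {
    abort("matrix columns missing from metadata", class = "channelscreen_validation_error")
  }
  for (g in .group_levels) {
    if (sum(grp == g) < 2) {
      abort(paste0("class '", g, "' has fewer than 2 columns; SD undefined"),
            class = "channelscreen_validation_error")
    }
  }
  score <- s2n_scores(m[, grp == "tumor", drop = FALSE],
                      m[, grp == "control", drop = FALSE],
                      floor_frac, abs_floor)
  tbl <- tibble(gene_id = rownames(m), score = score) |>
    arrange(desc(.data$score), .data$gene_id) |>
    mutate(rank = row_number())
  structure(tbl, metric = "signal2noise", class = c("ranked_genes", class(tibble())))
}

s2n_scores <- function(tumor, control, floor_frac, abs_floor) {
  mu_t <- rowMeans(tumor)
  mu_c <- rowMeans(control)
  sd_t <- apply(tumor, 1, sd)
  sd_c <- apply(control, 1, sd)
  sd_t <- pmax(sd_t, floor_frac * abs(mu_t), abs_floor)
  sd_c <- pmax(sd_c, floor_frac * abs(mu_c), abs_floor)
  unname((mu_t - mu_c) / (sd_t + sd_c))
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list; at a gene-set member ("hit") the sum rises by
#' `|score|^weight_p / sum_hits |score|^weight_p`, at a non-member it falls
#' by `1 / (N - N_hits)`. The enrichment score is the signed extremum of the
#' walk, and the leading edge is the set members at or before the extremum
#' (at or after it, for a negative score).
#'
#' @param ranked A `ranked_genes` tibble from [signal2noise_rank()] (any
#'   tibble with `gene_id` and `score` columns, sorted by descending score).
#' @param gene_set Character vector of member gene IDs.
#' @param weight_p Score weighting exponent (0 = classical Kolmogorov-
#'   Smirnov walk, 1 = standard weighted statistic).
#' @param set_name Label carried into the result.
#' @return A list of class `gsea_result` with elements `set_name`, `es`,
#'   `running_sum` (tibble: position, gene_id, score, hit, running),
#'   `leading_edge`, `n_hits`.
#' @export
gsea_es <- function(ranked, gene_set, weight_p = 1, set_name = "gene_set") {
  stopifnot(all(c("gene_id", "score") %in% names(ranked)))
  genes <- ranked$gene_id
  hit <- genes %in% gene_set
  if (!any(hit)) {
    abort(paste0("gene set '", set_name, "' has no members in the ranked list"),
          class = "channelscreen_validation_error")
  }
  if (all(hit)) {
    abort(paste0("gene set '", set_name, "' covers the entire ranked list"),
          class = "channelscreen_validation_error")
  }
  running <- es_walk(ranked$score, hit, weight_p)
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) genes[hit & seq_along(genes) <= i_ext] else genes[hit & seq_along(genes) >= i_ext]
  structure(list(
    set_name = set_name,
    es = es,
    running_sum = tibble(position = seq_along(genes), gene_id = genes,
                         score = ranked$score, hit = hit, running = running),
    leading_edge = leading,
    n_hits = sum(hit)
  ), class = "gsea_result")
}

# the running sum itself; hit increments weighted by |score|^p
es_walk <- function(scores, hit, weight_p) {
  w <- abs(scores)^weight_p
  denom_hit <- sum(w[hit])
  inc <- if (denom_hit > 0) w / denom_hit else rep(1 / sum(hit), length(scores))
  miss <- 1 / (length(scores) - sum(hit))
  steps <- ifelse(hit, inc, -miss)
  cumsum(steps)
}

#' Permutation p-value and normalized enrichment score
#'
#' Builds a null ES distribution either by permuting class labels and
#' re-ranking (`scheme = "phenotype"`) or by drawing random gene sets of the
#' same size on the fixed observed ranking (`scheme = "gene_set"`, the
#' default — robust when one class is small). The p-value is the one-sided
#' upper tail fraction with +1 smoothing,
#' `(1 + #{null ES >= ES}) / (n_perm + 1)`, and
#' `NES = ES / mean(|null ES| of the same sign)`.
#'
#' @inheritParams signal2noise_rank
#' @inheritParams gsea_es
#' @param n_perm Number of permutations (>= 100).
#' @param scheme `"gene_set"` or `"phenotype"`.
#' @param seed Integer seed for the permutation stream.
#' @return A `gsea_result` with additional elements `nes`, `p_value`,
#'   `n_perm`, `scheme`, `null_es`.
#' @export
gsea_permutation_p <- function(x, metadata, gene_set, n_perm = 1000,
                               scheme = c("gene_set", "phenotype"), seed = 1L,
                               weight_p = 1, set_name = "gene_set") {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 100)
  ranked <- signal2noise_rank(x, metadata)
  res <- gsea_es(ranked, gene_set, weight_p = weight_p, set_name = set_name)
  k <- res$n_hits
  null_es <- withr::with_seed(seed, {
    if (scheme == "gene_set") {
      vapply(seq_len(n_perm), function(i) {
        hit <- logical(nrow(ranked))
        hit[sample.int(nrow(ranked), k)] <- TRUE
        w <- es_walk(ranked$score, hit, weight_p)
        w[which.max(abs(w))]
      }, numeric(1))
    } else {
      md <- as_tibble(metadata)
      if (!"isolate_id" %in% names(md)) md$isolate_id <- md$sample_id
      avg <- if (all(expr_samples(x) %in% md$sample_id)) average_replicates(x, md) else x
      m <- expr_values(avg)
      iso <- distinct(md, .data$isolate_id, .data$group)
      grp <- setNames(iso$group, iso$isolate_id)[colnames(m)]
      if (length(grp) < 7) {
        warn("phenotype permutation with < 7 columns has few distinct permutations; consider scheme = 'gene_set'")
      }
      set_idx <- rownames(m) %in% gene_set
      vapply(seq_len(n_perm), function(i) {
        pg <- sample(grp)
        sc <- s2n_scores(m[, pg == "tumor", drop = FALSE],
                         m[, pg == "control", drop = FALSE], 0.2, 0.04)
        o <- order(-sc, rownames(m))
        w <- es_walk(sc[o], set_idx[o], weight_p)
        w[which.max(abs(w))]
      }, numeric(1))
    }
  })
  res$null_es <- null_es
  res$p_value <- (1 + sum(null_es >= res$es)) / (n_perm + 1)
  same_sign <- null_es[sign(null_es) == sign(res$es)]
  res$nes <- if (length(same_sign) > 0) res$es / mean(abs(same_sign)) else NA_real_
  res$n_perm <- n_perm
  res$scheme <- scheme
  res
}

#' Select screen candidates: top-k ranked genes passing an abundance filter
#'
#' Takes the `top_k` genes from the tumor-enriched (positive) end of the
#' ranking — or by absolute score with `direction = "absolute"` — then keeps
#' those whose mean tumor abundance passes `cpm_min`. Both drop stages are
#' recorded in an audit table.
#'
#' @param ranked A `ranked_genes` tibble.
#' @param tumor_mean_cpm Tibble (`gene_id`, `mean`) of mean tumor CPM.
#' @param top_k Number of top-ranked genes to carry forward.
#' @param cpm_min Minimum mean tumor CPM for a candidate.
#' @param direction `"positive"` (top of the ranking) or `"absolute"`.
#' @return A list of class `candidate_selection` with `candidates` (tibble),
#'   `audit` (gene_id, stage_dropped), and `params`.
#' @export
select_candidates <- function(ranked, tumor_mean_cpm, top_k = 40, cpm_min = 1,
                              direction = c("positive", "absolute")) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "score") %in% names(ranked)))
  if (top_k > nrow(ranked)) {
    abort(paste0("top_k = ", top_k, " exceeds ranked list length ", nrow(ranked)),
          class = "channelscreen_validation_error")
  }
  ord <- if (direction == "positive") {
    ranked
  } else {
    arrange(ranked, desc(abs(.data$score)), .data$gene_id)
  }
  top <- head(ord, top_k)
  below_top <- tibble(gene_id = setdiff(ranked$gene_id, top$gene_id),
                      stage_dropped = "below_top_k")
  top <- left_join(top, rename(tumor_mean_cpm, tumor_mean_cpm = "mean"), by = "gene_id")
  if (anyNA(top$tumor_mean_cpm)) {
    abort("tumor_mean_cpm missing for some ranked genes",
          class = "channelscreen_validation_error")
  }
  keep <- top$tumor_mean_cpm >= cpm_min
  audit <- bind_rows(below_top,
                     tibble(gene_id = top$gene_id[!keep], stage_dropped = "below_cpm_min"))
  structure(list(candidates = top[keep, ],
                 audit = audit,
                 params = list(top_k = top_k, cpm_min = cpm_min, direction = direction)),
            class = "candidate_selection")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("# gsea_result '", x$set_name, "': ES = ", signif(x$es, 4), sep = "")
  if (!is.null(x$nes)) cat(", NES = ", signif(x$nes, 4), sep = "")
  if (!is.null(x$p_value)) cat(", p = ", signif(x$p_value, 4),
                               " (", x$n_perm, " ", x$scheme, " permutations)", sep = "")
  cat("\n", x$n_hits, " set members in a list of ", nrow(x$running_sum),
      "; leading edge of ", length(x$leading_edge), "\n", sep = "")
  invisible(x)
}

#' @export
print.candidate_selection <- function(x, ...) {
  cat("# candidate_selection: ", nrow(x$candidates), " candidate(s) (top_k = ",
      x$params$top_k, ", cpm_min = ", x$params$cpm_min, ")\n", sep = "")
  print(x$candidates)
  invisible(x)
}
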