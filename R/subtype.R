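#' Compute subtype centroids as per-gene medians
#'
#' For each subtype, the centroid is the median expression of each signature
#' gene across that subtype's reference samples. Signature genes absent from
#' the reference are reported once and dropped.
#'
#' @param reference An [expr_mat] of reference cohort expression.
#' @param labels Tibble (`sample_id`, `subtype`) covering the reference
#'   samples.
#' @param signature_genes Character vector of signature gene IDs (nominally
#'   the 770-gene subtype signature).
#' @return A tibble (`gene_id` + one column per subtype) of class
#'   `subtype_centroids`.
#' @export
compute_centroids <- function(reference, labels, signature_genes) {
  stopifnot(inherits(reference, "expr_mat"))
  labels <- as_tibble(labels)
  stopifnot(all(c("sample_id", "subtype") %in% names(labels)))
  missing_genes <- setdiff(signature_genes, reference$gene_id)
  if (length(missing_genes) > 0) {
    message(length(missing_genes), " signature gene(s) absent from reference dropped: ",
            paste(head(missing_genes, 5), collapse = ", "),
            if (length(missing_genes) > 5) ", ..." else "")
  }
  sig <- intersect(signature_genes, reference$gene_id)
  if (length(sig) == 0) {
    abort("no signature genes present in reference", class = "channelscreen_validation_error")
  }
  m <- expr_values(reference)[sig, , drop = FALSE]
  subtypes <- unique(labels$subtype)
  cent <- vapply(subtypes, function(st) {
    cols <- intersect(labels$sample_id[labels$subtype == st], colnames(m))
    if (length(cols) == 0) {
      abort(paste0("subtype '", st, "' has no reference samples"),
            class = "channelscreen_validation_error")
    }
    apply(m[, cols, drop = FALSE], 1, median)
  }, numeric(length(sig)))
  cent <- matrix(cent, nrow = length(sig), dimnames = list(sig, subtypes))
  structure(bind_cols(tibble(gene_id = sig), as_tibble(cent)),
            class = c("subtype_centroids", class(tibble())))
}

#' Assign molecular subtypes by maximal Spearman correlation to centroids
#'
#' Each sample is correlated (Spearman, average-rank ties) with every
#' centroid over the shared signature genes and assigned to the subtype with
#' the largest correlation. Ties are broken by the fixed subtype order
#' (Classical, Mesenchymal, Neural, Proneural, then any others) with a
#' warning. Rank-based correlation makes the call invariant to any strictly
#' monotone per-sample transform of expression.
#'
#' @param x An [expr_mat] of samples to classify (one call per column).
#' @param centroids A `subtype_centroids` tibble from [compute_centroids()].
#' @param min_shared Minimum number of shared signature genes per sample.
#' @return A tibble with `sample_id`, one `rho_<subtype>` column per
#'   subtype, `subtype` (the call) and `margin` (best minus second-best rho).
#' @export
classify_by_centroid <- function(x, centroids, min_shared = 10) {
  stopifnot(inherits(x, "expr_mat"), inherits(centroids, "subtype_centroids"))
  shared <- intersect(x$gene_id, centroids$gene_id)
  if (length(shared) < min_shared) {
    abort(paste0("only ", length(shared), " signature gene(s) shared with centroids (need >= ",
                 min_shared, ")"),
          class = "channelscreen_validation_error")
  }
  subtypes <- setdiff(names(centroids), "gene_id")
  cm <- as.matrix(as_tibble(centroids)[match(shared, centroids$gene_id), subtypes])
  m <- expr_values(x)[shared, , drop = FALSE]
  order_key <- c(match(subtypes, .subtype_levels))
  order_key[is.na(order_key)] <- length(.subtype_levels) + seq_len(sum(is.na(order_key)))

  purrr::map_dfr(colnames(m), function(s) {
    v <- m[, s]
    if (sd(v) == 0) {
      abort(paste0("sample '", s, "' has constant expression; Spearman correlation undefined"),
            class = "channelscreen_validation_error")
    }
    rho <- vapply(seq_along(subtypes), function(k) {
      cor(v, cm[, k], method = "spearman")
    }, numeric(1))
    best <- which(rho == max(rho))
    if (length(best) > 1) {
      warn(paste0("sample '", s, "': tie between subtypes ",
                  paste(subtypes[best], collapse = ", "),
                  "; resolved by fixed subtype order"))
      best <- best[which.min(order_key[best])]
    }
    margin <- if (length(rho) > 1) max(rho) - max(rho[-best]) else NA_real_
    bind_cols(tibble(sample_id = s),
              as_tibble(setNames(as.list(rho), paste0("rho_", subtypes))),
              tibble(subtype = subtypes[best], margin = margin))
  })
}

#' Consensus subtype over replicate calls
#'
#' Majority label over per-replicate calls; a tie is broken by the highest
#' mean correlation among tied labels, and any residual tie by the fixed
#' subtype order with a warning.
#'
#' @param replicate_calls Tibble of calls from [classify_by_centroid()] for
#'   the replicates of one isolate.
#' @return A single subtype label.
#' @export
consensus_call <- function(replicate_calls) {
  calls <- as_tibble(replicate_calls)
  stopifnot("subtype" %in% names(calls), nrow(calls) >= 1)
  counts <- table(calls$subtype)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) > 1) {
    rho_cols <- paste0("rho_", winners)
    if (all(rho_cols %in% names(calls))) {
      mean_rho <- vapply(rho_cols, function(cc) mean(calls[[cc]]), numeric(1))
      top <- winners[mean_rho == max(mean_rho)]
      if (length(top) == 1) return(top)
      winners <- top
    }
    warn(paste0("consensus tie between ", paste(winners, collapse = ", "),
                "; resolved by fixed subtype order"))
    key <- match(winners, .subtype_levels)
    key[is.na(key)] <- Inf
    winners <- winners[order(key, winners)]
  }
  winners[1]
}

#' Hierarchical clustering of samples with newick export
#'
#' Agglomerative clustering of sample columns under either of the two
#' recipes the pipeline uses: euclidean distance with unweighted average
#' (UPGMA) linkage, or Manhattan distance with complete linkage. Any
#' metric/linkage combination from those vocabularies is allowed.
#'
#' @param x An [expr_mat].
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param linkage `"average"` or `"complete"`.
#' @param log_transform Cluster on `log2(x + 1)` instead of raw values.
#' @return A list of class `cluster_tree` with `hclust`, `phylo` (an
#'   `ape::phylo` with branch lengths from merge heights) and `newick`.
#' @export
hierarchical_cluster <- function(x, metric = c("euclidean", "manhattan"),
                                 linkage = c("average", "complete"),
                                 log_transform = FALSE) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  stopifnot(inherits(x, "expr_mat"))
  m <- t(expr_values(x))
  if (nrow(m) < 2) {
    abort("clustering needs >= 2 samples", class = "channelscreen_validation_error")
  }
  if (log_transform) m <- log2(m + 1)
  hc <- hclust(dist(m, method = metric), method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy),
                 metric = metric, linkage = linkage),
            class = "cluster_tree")
}

#' Write a cluster tree as a newick file
#' @param tree A `cluster_tree` from [hierarchical_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("# cluster_tree: ", length(x$hclust$labels), " samples, ", x$metric,
      " distance, ", x$linkage, " linkage\n", sep = "")
  invisible(x)
}
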