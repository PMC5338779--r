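#' Trimmed mean of M-values (TMM) scale factors
#'
#' Computes between-sample scale factors for count data by the TMM method:
#' for each sample, per-gene log2 expression ratios (M) against a reference
#' sample are doubly trimmed — by the M quantiles (`trim_M` each side) and
#' the average log abundance A quantiles (`trim_A` each side) — and averaged
#' with inverse binomial-variance weights; the factor is 2 to that mean.
#' Genes with a zero count in either member of a pair are excluded for that
#' comparison only. The reference is the sample whose upper-quartile to
#' library-size ratio is closest to the mean of that ratio across samples,
#' and the factors are rescaled to geometric mean 1.
#'
#' @param counts An [expr_mat] with unit `"counts"` and >= 2 samples.
#' @param trim_M Two-sided trim fraction on M values (default 0.30).
#' @param trim_A Two-sided trim fraction on A values (default 0.05).
#' @return A tibble (`sample_id`, `factor`) of class `scale_factors` with
#'   the reference sample in attribute `reference_sample_id`.
#' @examples
#' sim <- simulate_expression(screen_sim_config(n_genes = 200, seed = 7))
#' tmm_factors(sim$expr)
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  check_unit(counts, "counts", "tmm_factors")
  x <- expr_values(counts)
  if (ncol(x) < 2) {
    abort("tmm_factors() needs >= 2 samples", class = "channelscreen_validation_error")
  }
  lib <- colSums(x)
  if (any(lib == 0)) {
    abort(paste0("sample '", colnames(x)[which(lib == 0)[1]], "' has zero library size"),
          class = "channelscreen_validation_error")
  }
  # genes that are zero everywhere carry no information for any pair
  x <- x[rowSums(x > 0) > 0, , drop = FALSE]

  uq_ratio <- apply(x, 2, quantile, probs = 0.75) / lib
  ref_j <- which.min(abs(uq_ratio - mean(uq_ratio)))

  f <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair(x[, j], x[, ref_j], lib[j], lib[ref_j], trim_M, trim_A)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(tibble(sample_id = colnames(x), factor = f),
            reference_sample_id = colnames(x)[ref_j],
            class = c("scale_factors", class(tibble())))
}

# one TMM comparison: sample obs against reference ref
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0) {
    warn("TMM: no usable genes for a sample pair; factor set to 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loM <- floor(n * trim_M) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1
  hiA <- n + 1 - loA
  keep <- rank(logR) >= loM & rank(logR) <= hiM &
    rank(absE) >= loA & rank(absE) <= hiA
  if (!any(keep)) {
    warn("TMM: all genes trimmed away for a sample pair; factor set to 1")
    return(1)
  }
  2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Counts per million
#'
#' `value = count / (library_size x factor) x 1e6`. Without scale factors
#' every column sums to exactly 1e6; with TMM factors a column sums to
#' `1e6 / factor`.
#'
#' @param counts An [expr_mat] with unit `"counts"`.
#' @param factors Optional `scale_factors` from [tmm_factors()]; `NULL`
#'   means plain library-size CPM.
#' @return An [expr_mat] with unit `"CPM"`.
#' @export
cpm <- function(counts, factors = NULL) {
  check_unit(counts, "counts", "cpm")
  x <- expr_values(counts)
  lib <- colSums(x)
  if (any(lib == 0)) {
    abort(paste0("sample '", colnames(x)[which(lib == 0)[1]],
                 "' has zero library size; CPM undefined"),
          class = "channelscreen_validation_error")
  }
  f <- rep(1, ncol(x))
  if (!is.null(factors)) {
    stopifnot(inherits(factors, "scale_factors"))
    idx <- match(colnames(x), factors$sample_id)
    if (anyNA(idx)) {
      abort("scale factors missing for some samples", class = "channelscreen_validation_error")
    }
    f <- factors$factor[idx]
  }
  out <- sweep(x, 2, lib * f, "/") * 1e6
  expr_from_matrix(out, unit = "CPM")
}

#' Average replicate columns into one column per isolate
#'
#' Arithmetic mean on the abundance scale, assigning a single value per
#' isolate as the study's replicate-averaging step prescribes.
#'
#' @param x An [expr_mat] (any unit).
#' @param metadata Tibble with `sample_id` and `isolate_id` covering every
#'   sample of `x`.
#' @return An [expr_mat] with one column per isolate (same unit).
#' @export
average_replicates <- function(x, metadata) {
  stopifnot(inherits(x, "expr_mat"))
  metadata <- validate_metadata(metadata, x)
  if (!"isolate_id" %in% names(metadata)) {
    abort("metadata needs an isolate_id column", class = "channelscreen_validation_error")
  }
  m <- expr_values(x)
  isolates <- unique(metadata$isolate_id)
  out <- vapply(isolates, function(iso) {
    cols <- metadata$sample_id[metadata$isolate_id == iso]
    cols <- intersect(cols, colnames(m))
    if (length(cols) == 0) {
      abort(paste0("isolate '", iso, "' has no samples in the matrix"),
            class = "channelscreen_validation_error")
    }
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), isolates))
  expr_from_matrix(out, unit = expr_unit(x))
}

#' Per-gene mean abundance over one group's isolates
#'
#' Averages replicates into isolate columns first, then takes the per-gene
#' arithmetic mean over the isolates belonging to `group` — so the result
#' is identical whether or not `x` was isolate-averaged already.
#'
#' @param x An [expr_mat].
#' @param metadata Tibble with `sample_id`, `group` and `isolate_id`.
#' @param group `"tumor"` or `"control"`.
#' @return A tibble (`gene_id`, `mean`).
#' @export
group_means <- function(x, metadata, group) {
  metadata <- as_tibble(metadata)
  if (!group %in% unique(metadata$group)) {
    abort(paste0("unknown group label '", group, "'"),
          class = "channelscreen_validation_error")
  }
  if (!"isolate_id" %in% names(metadata)) metadata$isolate_id <- metadata$sample_id
  # tolerate x already collapsed to isolate columns
  if (all(expr_samples(x) %in% metadata$isolate_id)) {
    iso_meta <- distinct(metadata, .data$isolate_id, .data$group)
    m <- expr_values(x)
    keep <- iso_meta$isolate_id[iso_meta$group == group]
    keep <- intersect(colnames(m), keep)
  } else {
    avg <- average_replicates(x, metadata)
    m <- expr_values(avg)
    iso_meta <- distinct(metadata, .data$isolate_id, .data$group)
    keep <- intersect(colnames(m), iso_meta$isolate_id[iso_meta$group == group])
  }
  if (length(keep) == 0) {
    abort(paste0("group '", group, "' has no isolates in the matrix"),
          class = "channelscreen_validation_error")
  }
  tibble(gene_id = rownames(m), mean = rowMeans(m[, keep, drop = FALSE]))
}
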