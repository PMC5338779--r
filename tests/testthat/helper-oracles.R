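# Independent oracles, deliberately coded from first principles and kept
# separate from the implementation paths they check.

# Step-by-step TMM evaluation: explicit sort-based double trimming and
# binomial weights, one pair at a time.
oracle_tmm <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  x <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  lib <- colSums(counts)
  uq <- apply(x, 2, function(col) unname(quantile(col, 0.75))) / lib
  ref <- which.min(abs(uq - mean(uq)))
  fac <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    obs <- x[, j]; refc <- x[, ref]
    ok <- obs > 0 & refc > 0
    M <- log2((obs[ok] / lib[j]) / (refc[ok] / lib[ref]))
    A <- 0.5 * log2((obs[ok] / lib[j]) * (refc[ok] / lib[ref]))
    w <- (lib[j] - obs[ok]) / (lib[j] * obs[ok]) +
      (lib[ref] - refc[ok]) / (lib[ref] * refc[ok])
    if (max(abs(M)) < 1e-6) { fac[j] <- 1; next }
    n <- length(M)
    keepM <- rank(M) >= floor(n * trim_M) + 1 & rank(M) <= n - floor(n * trim_M)
    keepA <- rank(A) >= floor(n * trim_A) + 1 & rank(A) <= n - floor(n * trim_A)
    keep <- keepM & keepA
    fac[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  fac / exp(mean(log(fac)))
}

# Position-by-position running-sum walk with an explicit loop.
oracle_es_walk <- function(scores, hit, p = 1) {
  n <- length(scores)
  denom <- sum(abs(scores[hit])^p)
  walk <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hit[i]) cur + abs(scores[i])^p / denom else cur - 1 / (n - sum(hit))
    walk[i] <- cur
  }
  walk
}

oracle_es <- function(scores, hit, p = 1) {
  walk <- oracle_es_walk(scores, hit, p)
  walk[which.max(abs(walk))]
}

# Exact Mann-Whitney two-sided p by full enumeration of label assignments.
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(combn(n1 + n2, n1), 2, u_of)
  p_low <- mean(all_u <= u_obs)
  p_high <- mean(all_u >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_low, p_high)))
}

# Brute-force product-limit estimate at each distinct event time.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = et, survival = NA_real_)
  for (i in seq_along(et)) {
    n_risk <- sum(time >= et[i])
    d <- sum(time == et[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

# Log-rank chi-square statistic from first principles (observed - expected
# with hypergeometric variance), used for the permutation oracle.
oracle_logrank_chisq <- function(time, event, grp) {
  g1 <- unique(grp)[1]
  et <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Spearman rho with average-rank ties, via Pearson on manually computed ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Type-7 quantile by explicit sort-and-interpolate.
oracle_quantile7 <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Signal2Noise with the SD floor, evaluated independently.
oracle_s2n <- function(tumor, control, floor_frac = 0.2, abs_floor = 0.04) {
  mt <- mean(tumor); mc <- mean(control)
  st <- max(sd(tumor), floor_frac * abs(mt), abs_floor)
  sc <- max(sd(control), floor_frac * abs(mc), abs_floor)
  (mt - mc) / (st + sc)
}
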