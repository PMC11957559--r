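# Independent oracles: direct evaluations of published formulas, kept
# separate from the package's own code paths.

# TMM (trimmed mean of M-values) computed straight from the published
# recipe: reference = sample whose upper-quartile count fraction is closest
# to the mean; per-sample precision-weighted mean of gene-wise log2 count
# ratios after trimming 30% of M and 5% of A from each tail; factors
# rescaled to geometric mean 1.
tmm_oracle <- function(counts, lib_size = colSums(counts)) {
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib_size
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(k) {
    if (k == ref) return(1)
    obs <- counts[, k]; rf <- counts[, ref]
    nO <- lib_size[k]; nR <- lib_size[ref]
    keep0 <- obs > 0 & rf > 0
    obs <- obs[keep0]; rf <- rf[keep0]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
rank_sum_perm_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs_u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(us <= obs_u); p_ge <- mean(us >= obs_u)
  min(1, 2 * min(p_le, p_ge))
}

# Exact one-sided ("less") signed-rank p by enumeration of sign vectors.
signed_rank_perm_p <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs_v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  mean(vs <= obs_v)
}

expect_track_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$windows$scaffold, b$windows$scaffold)
  expect_equal(a$windows$start, b$windows$start)
  expect_equal(a$windows$end, b$windows$end)
  expect_equal(a$windows$mean_depth, b$windows$mean_depth, tolerance = tol)
}
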