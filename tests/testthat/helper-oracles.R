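# Independent oracles used across the suite. Each reimplements a statistic
# from first principles (enumeration, sorting, the textbook formula) so the
# package code is checked against something it does not share a path with.

# Percentile rank by explicit position search in the sorted nonzero values:
# n is the average position of a value among its duplicates.
oracle_percentile_rank <- function(x) {
  out <- numeric(length(x))
  nz <- x > 0
  n_expressed <- sum(nz)
  if (n_expressed == 0) return(out)
  sorted_nz <- sort(x[nz])
  out[nz] <- vapply(unname(x[nz]), function(v) {
    mean(which(sorted_nz == v)) / n_expressed * 100
  }, numeric(1))
  out
}

# Linear-interpolation quantile written out longhand: h = (n - 1) p + 1,
# interpolate between the flanking order statistics.
oracle_quantile <- function(x, p) {
  s <- sort(unname(x))
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Best contiguous two-cluster split by naive recomputation of both
# within-cluster sums of squares at every admissible split point.
oracle_best_split <- function(v) {
  s <- sort(v)
  n <- length(s)
  best_ss <- Inf
  best_k <- NA_integer_
  for (k in seq_len(n - 1)) {
    if (s[k] == s[k + 1]) next
    left <- s[1:k]
    right <- s[(k + 1):n]
    ss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best_k <- k
    }
  }
  list(cut_value = s[best_k], ss = best_ss)
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n + m, n) assignments of the pooled ranks to the first group.
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pooled_ranks <- rank(c(x, y))
  w_obs <- sum(pooled_ranks[seq_len(n)])
  combos <- utils::combn(n + m, n)
  w_all <- colSums(matrix(seq_len(n + m)[combos], nrow = n))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg by the step-up formula: sort, scale by m / i, take the
# cumulative minimum from the largest p down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# A desk-sized generator spec shared by the unit tests (the full default
# spec is exercised by the acceptance tests).
small_spec <- function(seed = 11, ...) {
  generator_spec(
    n_samples = 150, n_phenotypes = 4, n_background_genes = 150,
    n_me_pairs = 4, n_coexist_pairs = 3, n_linear_neg_pairs = 3,
    n_housekeeping = 8, n_silent = 8, seed = seed, ...
  )
}

hub_of <- function(sim) sim$truth$gene_id[sim$truth$archetype == "hub"]
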