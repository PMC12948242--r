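#' Partition samples into source-high and source-low groups
#'
#' Virtual sorting: splits the samples into two groups by the source gene's
#' percentile-rank scores using the exact two-cluster k-means solution. In
#' one dimension the optimal clusters are contiguous in value, so the global
#' optimum is found by scanning the n - 1 split points of the sorted rank
#' vector for the minimum total within-cluster sum of squares - no random
#' initialization, fully deterministic. Samples tied exactly at the boundary
#' always land on the same side (assignment is a function of the value).
#'
#' @param r Rank matrix from [rank_matrix()].
#' @param source Gene identifier whose rank scores drive the split.
#' @param min_group Minimum allowed group size (default 10); smaller groups
#'   make the rank-sum test and group ARS unstable.
#' @return An object of class `group_assignment`: a list with `source`,
#'   `samples` (tibble of `sample_id`, `rank_score`, `group`), `boundary`
#'   (midpoint rank score separating the groups), `n_high`, `n_low`.
#' @export
partition_samples <- function(r, source, min_group = 10L) {
  if (!source %in% rownames(r)) {
    rlang::abort(paste0("source gene not found in matrix: ", source))
  }
  v <- r[source, ]
  n <- length(v)
  if (diff(range(v)) == 0) {
    rlang::abort(paste0(
      "source gene ", source,
      " has zero plasticity (constant rank scores); ME analysis impossible"
    ), class = "mescreen_zero_plasticity")
  }
  s <- sort(v)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  k <- seq_len(n - 1L)
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  total <- ss_left + ss_right
  total[s[k] == s[k + 1L]] <- Inf  # a split inside a tie is not a valid partition
  k_best <- which.min(total)
  cut_value <- s[k_best]
  labels <- ifelse(v > cut_value, "high", "low")
  n_high <- sum(labels == "high")
  n_low <- n - n_high
  if (min(n_high, n_low) < min_group) {
    rlang::abort(paste0(
      "two-cluster split of ", source, " gives group sizes high=", n_high,
      ", low=", n_low, "; below min_group=", min_group
    ), class = "mescreen_small_group")
  }
  structure(
    list(
      source = source,
      samples = tibble::tibble(
        sample_id = colnames(r),
        rank_score = unname(v),
        group = unname(labels)
      ),
      boundary = (s[k_best] + s[k_best + 1L]) / 2,
      n_high = n_high,
      n_low = n_low
    ),
    class = "group_assignment"
  )
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(
    "Virtual sorting on ", x$source, ": ", x$n_high, " high / ", x$n_low,
    " low samples (rank-score boundary ", format(x$boundary, digits = 4), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Per-gene delta-ARS between the two groups
#'
#' For every gene, the difference between its average rank score in the
#' source-high group and in the source-low group. Strongly negative delta
#' marks genes whose expression collapses when the source gene is on -
#' the mutual-exclusion signature; strongly positive delta marks
#' co-existing genes.
#'
#' @param r Rank matrix.
#' @param assignment A `group_assignment` from [partition_samples()].
#' @return A tibble with `gene_id`, `ars_high`, `ars_low`, `delta`.
#' @export
delta_ars <- function(r, assignment) {
  stopifnot(inherits(assignment, "group_assignment"))
  hi <- assignment$samples$sample_id[assignment$samples$group == "high"]
  lo <- assignment$samples$sample_id[assignment$samples$group == "low"]
  ars_high <- rowMeans(r[, hi, drop = FALSE])
  ars_low <- rowMeans(r[, lo, drop = FALSE])
  tibble::tibble(
    gene_id = rownames(r),
    ars_high = unname(ars_high),
    ars_low = unname(ars_low),
    delta = unname(ars_high - ars_low)
  )
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares a gene's rank scores between the two groups. The exact null
#' distribution is used for small tie-free problems (combined n <= 25);
#' larger or tied problems use the normal approximation with tie and
#' continuity corrections. Degenerate input where every value is identical
#' returns p = 1 (no evidence either way).
#'
#' @param values_high,values_low Numeric vectors for the two groups, both
#'   non-empty.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`, default) the
#'   exact distribution.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(values_high, values_low, exact = NULL) {
  if (length(values_high) == 0L || length(values_low) == 0L) {
    rlang::abort("both groups must be non-empty")
  }
  all_values <- c(values_high, values_low)
  if (diff(range(all_values)) == 0) return(1)
  ties <- anyDuplicated(all_values) > 0L
  if (is.null(exact)) exact <- length(all_values) <= 25L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(
      values_high, values_low,
      exact = exact && !ties, correct = TRUE
    )$p.value
  )
  if (is.na(p)) 1 else min(p, 1)
}

# Vectorized Wilcoxon rank-sum over all genes of a rank matrix for one fixed
# partition: normal approximation with tie and continuity corrections,
# matching wilcox.test(exact = FALSE, correct = TRUE) per gene. Used for
# whole-matrix screens where per-gene calls would dominate runtime.
wilcox_matrix <- function(r, hi_cols, lo_cols) {
  n1 <- length(hi_cols)
  n2 <- length(lo_cols)
  n <- n1 + n2
  sub <- r[, c(hi_cols, lo_cols), drop = FALSE]
  ranks <- t(apply(sub, 1L, rank))
  w1 <- rowSums(ranks[, seq_len(n1), drop = FALSE])
  u <- w1 - n1 * (n1 + 1) / 2
  tie_term <- apply(sub, 1L, function(v) {
    t <- tabulate(match(v, unique(v)))
    sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- u - n1 * n2 / 2
  zz <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(zz))
  p <- pmin(p, 1)
  p[sigma2 == 0] <- 1  # gene constant across samples
  unname(p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction over one screen's family of raw
#' p-values (all genes tested against one source gene).
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise `>=` the raw values and `<= 1`.
#' @export
adjust_bh <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    rlang::abort("p-values must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Virtual-sorting screen for one source gene
#'
#' Runs the full differential stage: partitions the samples by the source
#' gene's rank scores ([partition_samples()]), computes every gene's
#' delta-ARS between the groups, tests each gene's rank scores with the
#' Wilcoxon rank-sum test, and applies Benjamini-Hochberg correction across
#' all genes. Rows are ordered by decreasing delta, so co-existing
#' candidates head the table and mutual-exclusion candidates close it.
#'
#' @inheritParams partition_samples
#' @return A tibble with `gene_id`, `ars_high`, `ars_low`, `delta`, `p_raw`,
#'   `p_adj`, sorted by `delta` descending; the `group_assignment` used is
#'   attached as attribute `assignment`.
#' @export
virtual_sort <- function(r, source, min_group = 10L) {
  assignment <- partition_samples(r, source, min_group = min_group)
  out <- delta_ars(r, assignment)
  hi <- assignment$samples$sample_id[assignment$samples$group == "high"]
  lo <- assignment$samples$sample_id[assignment$samples$group == "low"]
  if (ncol(r) <= 25L) {
    p_raw <- vapply(
      rownames(r),
      function(g) rank_sum_test(r[g, hi], r[g, lo]),
      numeric(1L)
    )
  } else {
    p_raw <- wilcox_matrix(r, hi, lo)
  }
  out$p_raw <- unname(p_raw)
  out$p_adj <- adjust_bh(out$p_raw)
  out <- dplyr::arrange(out, dplyr::desc(.data$delta))
  attr(out, "assignment") <- assignment
  out
}
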