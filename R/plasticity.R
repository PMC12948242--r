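#' Percentile-rank scores for one sample
#'
#' Converts one sample's TPM vector to percentile-rank scores
#' `P = n / N * 100`, where `N` is the number of genes with non-zero TPM in
#' the sample and `n` is a gene's ascending ordinal rank among those non-zero
#' genes (ties receive the average rank). A gene with zero TPM gets `P = 0`
#' by definition, so scores run from 0 (silent) to 100 (the sample's top
#' expressed gene).
#'
#' @param tpm Nonnegative finite numeric vector of TPM values over genes.
#' @return Numeric vector of rank scores in `[0, 100]`, same length and names
#'   as `tpm`. An all-zero sample yields all-zero scores with a warning
#'   (such a sample carries no ranking information).
#'
#' @examples
#' percentile_rank(c(0, 1, 2, 4))   # 0, 33.3, 66.7, 100
#' percentile_rank(c(5, 5, 10))     # ties share the average rank: 50, 50, 100
#' @export
percentile_rank <- function(tpm) {
  if (!is.numeric(tpm) || anyNA(tpm) || any(!is.finite(tpm))) {
    rlang::abort("TPM vector must be finite and numeric")
  }
  if (any(tpm < 0)) rlang::abort("TPM vector must be nonnegative")
  out <- numeric(length(tpm))
  names(out) <- names(tpm)
  nz <- tpm > 0
  n_expressed <- sum(nz)
  if (n_expressed == 0L) {
    rlang::warn("sample has no non-zero TPM values; all rank scores set to 0")
    return(out)
  }
  out[nz] <- rank(tpm[nz], ties.method = "average") / n_expressed * 100
  out
}

#' Percentile-rank matrix
#'
#' Applies [percentile_rank()] to every sample (column) of a TPM matrix.
#' Ranks are strictly within-sample, so the transform is invariant to
#' between-sample scale differences and to any strictly monotone
#' transformation of a sample's values.
#'
#' @param m Genes x samples TPM matrix (or `gene_id`-keyed data frame).
#' @return Numeric matrix of the same shape with values in `[0, 100]`.
#' @export
rank_matrix <- function(m) {
  m <- validate_expression_matrix(m)
  r <- apply(m, 2L, percentile_rank)
  dimnames(r) <- dimnames(m)
  r
}

#' Average rank score (ARS)
#'
#' The mean of a gene's percentile-rank scores over a set of samples: a
#' rank-based summary of its average expression level under the conditions
#' those samples represent.
#'
#' @param r Rank matrix from [rank_matrix()].
#' @param samples Character vector of sample identifiers to average over;
#'   defaults to all samples. Must be non-empty.
#' @return A tibble with columns `gene_id` and `ars`.
#' @export
average_rank_score <- function(r, samples = colnames(r)) {
  if (length(samples) == 0L) rlang::abort("sample subset must be non-empty")
  missing <- setdiff(samples, colnames(r))
  if (length(missing) > 0L) {
    rlang::abort(paste0("unknown sample id(s): ", paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    gene_id = rownames(r),
    ars = unname(rowMeans(r[, samples, drop = FALSE]))
  )
}

#' Gene plasticity profile (Delta 95/5)
#'
#' For each gene, takes the 5th and 95th percentiles of its rank scores
#' across samples (linear-interpolation quantiles) and scores plasticity as
#' their difference, `gp = q95 - q05`. The 5/95 window means at least 10% of
#' the samples back any claimed plasticity while extreme outliers are
#' ignored. Genes are labelled `high` plasticity when `gp` reaches
#' `gp_threshold`, by default the matrix-wide mean GP.
#'
#' @param r Rank matrix from [rank_matrix()].
#' @param gp_threshold GP cutoff separating high from low plasticity;
#'   `NULL` (default) uses the mean GP over all genes in `r`.
#' @return A tibble with columns `gene_id`, `ars`, `q05`, `q95`, `gp`,
#'   `plasticity_class`, with the threshold used stored in attribute
#'   `gp_threshold`. With fewer than 20 samples a warning is raised: the
#'   tail quantiles are then dominated by interpolation.
#' @export
gene_plasticity <- function(r, gp_threshold = NULL) {
  if (ncol(r) < 20L) {
    rlang::warn(paste0(
      "only ", ncol(r), " samples: 5th/95th percentiles are interpolation-dominated; ",
      "plasticity scores are unstable below ~20 samples"
    ))
  }
  q <- apply(r, 1L, stats::quantile, probs = c(0.05, 0.95), names = FALSE, type = 7L)
  gp <- q[2L, ] - q[1L, ]
  if (is.null(gp_threshold)) gp_threshold <- mean(gp)
  out <- tibble::tibble(
    gene_id = rownames(r),
    ars = unname(rowMeans(r)),
    q05 = unname(q[1L, ]),
    q95 = unname(q[2L, ]),
    gp = unname(gp),
    plasticity_class = unname(ifelse(gp >= gp_threshold, "high", "low"))
  )
  attr(out, "gp_threshold") <- gp_threshold
  out
}
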