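#' Cosine similarity of two expression vectors
#'
#' The normalized inner product of two genes' TPM vectors across samples,
#' `sum(x * y) / (||x|| * ||y||)`. For nonnegative expression it lies in
#' `[0, 1]`: 1 for parallel profiles, 0 when the genes are expressed in
#' disjoint sample sets (a 90-degree angle), the geometric signature of
#' mutual exclusion. Computed on raw TPM, not ranks. If either vector is
#' all-zero the similarity is undefined and `NA` is returned - a
#' never-expressed gene carries no exclusion evidence.
#'
#' @param x,y Nonnegative finite numeric vectors of equal length.
#' @return Similarity in `[0, 1]`, or `NA` if undefined.
#'
#' @examples
#' cosine_similarity(c(1, 2, 3), c(2, 4, 6))    # parallel: 1
#' cosine_similarity(c(1, 0, 2, 0), c(0, 3, 0, 4))  # disjoint support: 0
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("vectors must have equal length")
  }
  if (!is.numeric(x) || !is.numeric(y) ||
      any(!is.finite(x)) || any(!is.finite(y))) {
    rlang::abort("vectors must be finite and numeric")
  }
  if (any(x < 0) || any(y < 0)) {
    rlang::abort("expression vectors must be nonnegative")
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

#' Cosine similarity of every gene to a source gene
#'
#' @param m TPM matrix (genes x samples) or `gene_id`-keyed data frame.
#' @param source Source gene identifier, present in `m` and not all-zero.
#' @return A tibble with `gene_id` and `cosine` (`NA` for all-zero genes);
#'   the source's own similarity is exactly 1.
#' @export
cosine_to_source <- function(m, source) {
  m <- as_tpm_matrix(m)
  if (!source %in% rownames(m)) {
    rlang::abort(paste0("source gene not found in matrix: ", source))
  }
  s <- m[source, ]
  s_norm <- sqrt(sum(s^2))
  if (s_norm == 0) {
    rlang::abort(paste0("source gene ", source, " is all-zero; cosine undefined"))
  }
  norms <- sqrt(rowSums(m^2))
  cosine <- as.vector(m %*% s) / (norms * s_norm)
  cosine[norms == 0] <- NA_real_
  cosine[rownames(m) == source] <- 1
  tibble::tibble(gene_id = rownames(m), cosine = unname(cosine))
}

#' Three-way mutual-exclusion filter
#'
#' Combines the virtual-sorting statistics with the cosine filter. A gene is
#' a mutual-exclusion candidate when all three conditions hold (inclusive
#' boundaries): cosine to source `<= cos_max`, `delta <= delta_max`, and
#' `p_adj <= padj_max`. The delta and p conditions remove low-plasticity
#' noise genes whose cosine drifts toward 0 without any real exclusion; the
#' cosine condition removes linearly anti-correlated genes that are
#' co-expressed at intermediate levels. Genes with undefined (all-zero)
#' cosine fail the cosine condition, and the source gene itself is never a
#' candidate. Each gene is also labelled with its exclusion pattern from
#' [classify_exclusion_pattern()].
#'
#' @param sorting Sorting table from [virtual_sort()].
#' @param cosines Tibble from [cosine_to_source()] over the same genes.
#' @param plasticity Plasticity profile from [gene_plasticity()], used for
#'   pattern classification.
#' @param source Source gene identifier.
#' @param cos_max Cosine ceiling, default 0.05 (must lie in `[0, 1]`).
#' @param delta_max Delta ceiling, default -15 (must lie in `[-100, 100]`).
#' @param padj_max Adjusted-p ceiling, default 0.01 (must lie in `(0, 1]`).
#' @param coexist_min Delta floor for the co-existing pattern, default +15.
#' @param gp_threshold GP cutoff for the pattern classifier; `NULL` uses the
#'   threshold stored on `plasticity`.
#' @return A tibble (one row per gene) with the sorting statistics, cosine,
#'   the three pass flags, `is_candidate`, and `pattern`.
#' @export
screen_me <- function(sorting, cosines, plasticity, source,
                      cos_max = 0.05, delta_max = -15, padj_max = 0.01,
                      coexist_min = 15, gp_threshold = NULL) {
  if (cos_max < 0 || cos_max > 1) {
    rlang::abort("cos_max must lie in [0, 1]")
  }
  if (delta_max < -100 || delta_max > 100) {
    rlang::abort("delta_max must lie in [-100, 100]")
  }
  if (padj_max <= 0 || padj_max > 1) {
    rlang::abort("padj_max must lie in (0, 1]")
  }
  if (!setequal(sorting$gene_id, cosines$gene_id)) {
    rlang::abort("sorting table and cosine table cover different gene sets")
  }
  if (is.null(gp_threshold)) {
    gp_threshold <- attr(plasticity, "gp_threshold") %||% mean(plasticity$gp)
  }
  gp_source <- plasticity$gp[plasticity$gene_id == source]
  if (length(gp_source) != 1L) {
    rlang::abort(paste0("source gene not found in plasticity profile: ", source))
  }
  out <- sorting |>
    dplyr::left_join(cosines, by = "gene_id") |>
    dplyr::left_join(
      dplyr::select(plasticity, "gene_id", gp_target = "gp"),
      by = "gene_id"
    ) |>
    dplyr::mutate(
      pass_cosine = !is.na(.data$cosine) & .data$cosine <= cos_max,
      pass_delta = .data$delta <= delta_max,
      pass_padj = .data$p_adj <= padj_max,
      is_candidate = .data$pass_cosine & .data$pass_delta & .data$pass_padj &
        .data$gene_id != source,
      pattern = classify_exclusion_pattern(
        gp_source = gp_source,
        gp_target = .data$gp_target,
        delta = .data$delta,
        gp_threshold = gp_threshold,
        delta_max = delta_max,
        coexist_min = coexist_min
      )
    )
  attr(out, "thresholds") <- list(
    cos_max = cos_max, delta_max = delta_max,
    padj_max = padj_max, coexist_min = coexist_min,
    gp_threshold = gp_threshold
  )
  out
}

#' Classify the exclusion pattern of a source-target pair
#'
#' Mutual exclusion is only interpretable when both genes are plastic.
#' `bilateral_ME`: both genes highly plastic and delta at or below the ME
#' cutoff - the trustworthy case. `unilateral_source_low` /
#' `unilateral_target_low`: one side is a low-plasticity gene, so the
#' evidence is one-sided and the screen is insensitive (for example a source
#' gene that is broadly silent in a given cell type). `co_existing`: both
#' plastic with delta at or above `coexist_min`. Anything else is `none`.
#'
#' @param gp_source GP score of the source gene (scalar, `[0, 100]`).
#' @param gp_target GP score(s) of the target gene(s).
#' @param delta delta-ARS value(s) for the pair(s).
#' @param gp_threshold GP cutoff separating high from low plasticity.
#' @param delta_max Delta ceiling for mutual exclusion, default -15.
#' @param coexist_min Delta floor for co-existence, default +15.
#' @return Character vector of pattern labels.
#' @export
classify_exclusion_pattern <- function(gp_source, gp_target, delta,
                                       gp_threshold,
                                       delta_max = -15, coexist_min = 15) {
  both_high <- gp_source >= gp_threshold & gp_target >= gp_threshold
  dplyr::case_when(
    both_high & delta <= delta_max ~ "bilateral_ME",
    gp_source < gp_threshold & gp_target >= gp_threshold ~ "unilateral_source_low",
    gp_target < gp_threshold & gp_source >= gp_threshold ~ "unilateral_target_low",
    both_high & delta >= coexist_min ~ "co_existing",
    TRUE ~ "none"
  )
}

#' Reciprocal mutual-exclusion check
#'
#' Confirmatory annotation: for each candidate, reruns the virtual-sorting
#' screen with the candidate as the source gene and asks whether the
#' original source gene then satisfies the delta and adjusted-p conditions
#' in the reverse direction. True bilateral exclusion is symmetric.
#' Candidates whose own rank vector is constant (zero plasticity) or cannot
#' be split into two groups of at least `min_group` samples are not
#' evaluable - exactly the unilateral-exclusion failure mode - and get
#' `reciprocal_ok = NA`.
#'
#' @param r Rank matrix.
#' @param candidates Character vector of candidate gene identifiers.
#' @param source The original source gene.
#' @param min_group Minimum group size for the reverse split.
#' @param delta_max,padj_max Thresholds the source must meet in the reverse
#'   screen.
#' @return A tibble with `gene_id`, `reciprocal_delta`, `reciprocal_p_adj`,
#'   `reciprocal_ok` (logical, `NA` when not evaluable), `note`.
#' @export
reciprocal_check <- function(r, candidates, source, min_group = 10L,
                             delta_max = -15, padj_max = 0.01) {
  purrr::map_dfr(candidates, function(cand) {
    res <- tryCatch(
      virtual_sort(r, cand, min_group = min_group),
      mescreen_zero_plasticity = function(e) e,
      mescreen_small_group = function(e) e
    )
    if (inherits(res, "error")) {
      return(tibble::tibble(
        gene_id = cand,
        reciprocal_delta = NA_real_,
        reciprocal_p_adj = NA_real_,
        reciprocal_ok = NA,
        note = conditionMessage(res)
      ))
    }
    row <- res[res$gene_id == source, ]
    tibble::tibble(
      gene_id = cand,
      reciprocal_delta = row$delta,
      reciprocal_p_adj = row$p_adj,
      reciprocal_ok = row$delta <= delta_max && row$p_adj <= padj_max,
      note = NA_character_
    )
  })
}
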