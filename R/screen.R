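#' Run the full mutual-exclusion screen for one source gene
#'
#' End-to-end pipeline: TPM matrix -> percentile ranks -> plasticity
#' profile -> virtual sorting on the source gene -> per-gene delta-ARS,
#' Wilcoxon and BH statistics -> cosine filter -> candidate table, with an
#' optional reciprocal check on the surviving candidates. A source gene with
#' zero plasticity (constant rank scores) or whose split violates
#' `min_group` cannot be screened; rather than fail, the returned object
#' carries `status = "source_not_analyzable"` and the reason - the
#' unilateral-exclusion situation where virtual sorting has nothing to
#' sort.
#'
#' @param m TPM matrix (genes x samples), `gene_id`-keyed data frame, or a
#'   path to a TSV readable by [read_expression_matrix()].
#' @param source Source gene identifier (for example `"CD274"`).
#' @param cos_max,delta_max,padj_max Candidate thresholds; defaults 0.05,
#'   -15, 0.01.
#' @param coexist_min Delta floor for the co-existing pattern, default +15.
#' @param min_group Minimum virtual-sorting group size, default 10.
#' @param gp_threshold GP cutoff for plasticity classes and pattern labels;
#'   `NULL` uses the matrix-wide mean GP.
#' @param reciprocal If `TRUE`, annotate candidates with the reciprocal
#'   check ([reciprocal_check()]).
#' @param out_dir If non-`NULL`, write the plasticity, sorting and candidate
#'   TSVs, the Venn-count JSON and a run log into this directory.
#' @return An object of class `me_screen`; see [tidy.me_screen()],
#'   [glance.me_screen()] and [autoplot.me_screen()].
#'
#' @examples
#' sim <- simulate_expression(generator_spec(
#'   n_samples = 120, n_phenotypes = 4, n_background_genes = 100,
#'   n_me_pairs = 3, n_coexist_pairs = 2, n_linear_neg_pairs = 2,
#'   n_housekeeping = 5, n_silent = 5, seed = 7
#' ))
#' hub <- sim$truth$gene_id[sim$truth$archetype == "hub"]
#' scr <- run_me_screen(sim$matrix, source = hub)
#' scr
#' @export
run_me_screen <- function(m, source,
                          cos_max = 0.05, delta_max = -15, padj_max = 0.01,
                          coexist_min = 15, min_group = 10L,
                          gp_threshold = NULL, reciprocal = FALSE,
                          out_dir = NULL) {
  if (is.character(m) && length(m) == 1L) m <- read_expression_matrix(m)
  m <- validate_expression_matrix(m)
  if (!source %in% rownames(m)) {
    rlang::abort(paste0("source gene not found in matrix: ", source))
  }
  r <- rank_matrix(m)
  plasticity <- gene_plasticity(r, gp_threshold = gp_threshold)

  sorting <- tryCatch(
    virtual_sort(r, source, min_group = min_group),
    mescreen_zero_plasticity = function(e) e,
    mescreen_small_group = function(e) e
  )
  if (inherits(sorting, "error")) {
    res <- structure(
      list(
        source = source, status = "source_not_analyzable",
        reason = conditionMessage(sorting),
        plasticity = plasticity, sorting = NULL, candidates = NULL,
        assignment = NULL, venn = NULL, reciprocal = NULL,
        thresholds = list(cos_max = cos_max, delta_max = delta_max,
                          padj_max = padj_max, coexist_min = coexist_min),
        n_genes = nrow(m), n_samples = ncol(m)
      ),
      class = "me_screen"
    )
    if (!is.null(out_dir)) write_screen_outputs(res, out_dir)
    return(res)
  }

  cosines <- cosine_to_source(m, source)
  candidates <- screen_me(
    sorting, cosines, plasticity, source,
    cos_max = cos_max, delta_max = delta_max, padj_max = padj_max,
    coexist_min = coexist_min, gp_threshold = gp_threshold
  )
  venn <- venn_counts(candidates)
  recip <- NULL
  if (reciprocal) {
    cand_ids <- candidates$gene_id[candidates$is_candidate]
    recip <- reciprocal_check(
      r, cand_ids, source,
      min_group = min_group, delta_max = delta_max, padj_max = padj_max
    )
    candidates <- dplyr::left_join(candidates, recip, by = "gene_id")
  }

  res <- structure(
    list(
      source = source, status = "ok", reason = NULL,
      plasticity = plasticity, sorting = sorting, candidates = candidates,
      assignment = attr(sorting, "assignment"), venn = venn,
      reciprocal = recip,
      thresholds = attr(candidates, "thresholds") %||%
        list(cos_max = cos_max, delta_max = delta_max,
             padj_max = padj_max, coexist_min = coexist_min),
      n_genes = nrow(m), n_samples = ncol(m)
    ),
    class = "me_screen"
  )
  if (!is.null(out_dir)) write_screen_outputs(res, out_dir)
  res
}

# Venn-diagram counts over the three filter conditions.
venn_counts <- function(candidates) {
  with(candidates, list(
    n_genes = length(gene_id),
    cosine = sum(pass_cosine),
    delta = sum(pass_delta),
    padj = sum(pass_padj),
    cosine_delta = sum(pass_cosine & pass_delta),
    cosine_padj = sum(pass_cosine & pass_padj),
    delta_padj = sum(pass_delta & pass_padj),
    all_three = sum(is_candidate)
  ))
}

write_screen_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- res$source
  write_results_table(res$plasticity, file.path(out_dir, "plasticity.tsv"))
  log_lines <- c(
    paste0("mescreen ", as.character(utils::packageVersion("mescreen"))),
    paste0("source: ", tag),
    paste0("status: ", res$status),
    paste0("genes: ", res$n_genes, "  samples: ", res$n_samples),
    paste0("thresholds: cos_max=", res$thresholds$cos_max,
           " delta_max=", res$thresholds$delta_max,
           " padj_max=", res$thresholds$padj_max)
  )
  if (res$status == "ok") {
    write_results_table(res$sorting, file.path(out_dir, paste0("sorting_", tag, ".tsv")))
    write_results_table(res$candidates, file.path(out_dir, paste0("candidates_", tag, ".tsv")))
    jsonlite::write_json(res$venn, file.path(out_dir, paste0("venn_", tag, ".json")),
                         auto_unbox = TRUE)
    log_lines <- c(log_lines,
                   paste0("groups: high=", res$assignment$n_high,
                          " low=", res$assignment$n_low),
                   paste0("candidates: ", res$venn$all_three))
  } else {
    jsonlite::write_json(
      list(source = tag, status = res$status, reason = res$reason),
      file.path(out_dir, paste0("not_analyzable_", tag, ".json")),
      auto_unbox = TRUE
    )
    log_lines <- c(log_lines, paste0("reason: ", res$reason))
  }
  writeLines(log_lines, file.path(out_dir, paste0("screen_", tag, ".log")))
  invisible(out_dir)
}

#' Screen many source genes
#'
#' Runs [run_me_screen()] for each source gene in turn (each with its own
#' BH family) and binds the results into one long source x target table.
#' Sources that cannot be analyzed - zero plasticity, or a split below
#' `min_group` - are skipped with a message and recorded in the `skipped`
#' attribute.
#'
#' @param m TPM matrix, `gene_id`-keyed data frame, or TSV path.
#' @param sources Character vector of source genes, or `"all"` for every
#'   gene in the matrix. Must be non-empty.
#' @param ... Passed to [run_me_screen()] (thresholds, `min_group`, ...).
#' @return A tibble with columns `source`, `gene_id` (the target), the
#'   per-pair statistics and flags, one row per source x target pair;
#'   attribute `skipped` is a tibble of skipped sources and reasons.
#' @export
run_multi_source <- function(m, sources = "all", ...) {
  if (is.character(m) && length(m) == 1L) m <- read_expression_matrix(m)
  m <- validate_expression_matrix(m)
  if (length(sources) == 0L) rlang::abort("source list must be non-empty")
  if (identical(sources, "all")) sources <- rownames(m)
  missing <- setdiff(sources, rownames(m))
  if (length(missing) > 0L) {
    rlang::abort(paste0("source gene(s) not in matrix: ",
                        paste(missing, collapse = ", ")))
  }
  runs <- purrr::map(sources, function(src) run_me_screen(m, src, ...))
  skipped <- purrr::map_dfr(runs, function(x) {
    if (x$status == "ok") return(NULL)
    message("skipping source ", x$source, ": ", x$reason)
    tibble::tibble(source = x$source, reason = x$reason)
  })
  out <- purrr::map_dfr(runs, function(x) {
    if (x$status != "ok") return(NULL)
    dplyr::mutate(x$candidates, source = x$source, .before = 1L)
  })
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.me_screen <- function(x, ...) {
  cat("Mutual-exclusion screen: source ", x$source, " (", x$n_genes,
      " genes x ", x$n_samples, " samples)\n", sep = "")
  if (x$status != "ok") {
    cat("  not analyzable: ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  th <- x$thresholds
  cat("  virtual sorting: ", x$assignment$n_high, " high / ",
      x$assignment$n_low, " low samples\n", sep = "")
  cat("  filters: cosine <= ", th$cos_max, ", delta <= ", th$delta_max,
      ", p_adj <= ", th$padj_max, "\n", sep = "")
  cat("  pass counts: cosine ", x$venn$cosine, ", delta ", x$venn$delta,
      ", p_adj ", x$venn$padj, "; all three: ", x$venn$all_three,
      " candidate(s)\n", sep = "")
  if (!is.null(x$reciprocal) && nrow(x$reciprocal) > 0L) {
    cat("  reciprocal check: ", sum(x$reciprocal$reciprocal_ok %in% TRUE),
        "/", nrow(x$reciprocal), " candidates confirmed\n", sep = "")
  }
  invisible(x)
}

#' Tidy a mutual-exclusion screen
#'
#' Returns the per-gene results table: sorting statistics, cosine, pass
#' flags, candidacy and exclusion pattern (plus reciprocal columns when the
#' screen ran with `reciprocal = TRUE`).
#'
#' @param x An `me_screen` object.
#' @param candidates_only If `TRUE`, keep only the genes passing all three
#'   filters.
#' @param ... Unused.
#' @return A tibble, one row per gene (empty if the source was not
#'   analyzable).
#' @method tidy me_screen
#' @export
tidy.me_screen <- function(x, candidates_only = FALSE, ...) {
  if (x$status != "ok") return(tibble::tibble())
  out <- tibble::as_tibble(x$candidates)
  if (candidates_only) out <- dplyr::filter(out, .data$is_candidate)
  out
}

#' One-row summary of a mutual-exclusion screen
#'
#' @param x An `me_screen` object.
#' @param ... Unused.
#' @return A one-row tibble: matrix size, group sizes, source GP, mean GP,
#'   per-filter pass counts and the candidate count.
#' @method glance me_screen
#' @export
glance.me_screen <- function(x, ...) {
  base <- tibble::tibble(
    source = x$source, status = x$status,
    n_genes = x$n_genes, n_samples = x$n_samples,
    source_gp = x$plasticity$gp[x$plasticity$gene_id == x$source],
    mean_gp = mean(x$plasticity$gp)
  )
  if (x$status != "ok") return(base)
  dplyr::mutate(
    base,
    n_high = x$assignment$n_high, n_low = x$assignment$n_low,
    n_pass_cosine = x$venn$cosine, n_pass_delta = x$venn$delta,
    n_pass_padj = x$venn$padj, n_candidates = x$venn$all_three
  )
}
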