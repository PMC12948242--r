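#' Specification for the mixed-phenotype expression simulator
#'
#' Describes a pooled bulk RNA-seq design: samples drawn from several latent
#' cell phenotypes, most genes broadly expressed, and a set of planted
#' gene-pair archetypes that exercise every branch of the screen. The
#' defaults describe the pooled design the pipeline targets - 600 samples
#' from 8 phenotypes, 2000 genes, one highly plastic hub source gene active
#' in half the phenotypes, 20 bilateral mutual-exclusion pairs anchored to
#' the hub's phenotype split, 10 co-existing pairs, 10 linear
#' negative-correlation pairs (anti-correlated but co-expressed at
#' intermediate levels - the confounder cosine must reject), 50
#' constitutive housekeeping genes, and 50 near-silent genes (the
#' confounder whose spurious near-zero cosine the delta filter must
#' reject).
#'
#' Expression is lognormal on the TPM scale: active states have median
#' `mu_hi` TPM, inactive states are exactly zero with probability
#' `dropout_off` and otherwise lognormal with median `mu_lo` TPM, both with
#' log-scale standard deviation `sigma`. `p_active` is the per-phenotype
#' inclusion probability used when drawing active-phenotype subsets for
#' background and planted-pair genes; its default (0.75) reflects that most
#' protein-coding genes are detected in the majority of cell types.
#'
#' @param n_samples Number of samples (default 600).
#' @param n_phenotypes Number of latent phenotypes (default 8).
#' @param phenotype_weights Probability vector over phenotypes (default
#'   uniform); must sum to 1.
#' @param n_background_genes Background genes with independently random
#'   active-phenotype subsets (default 1819, bringing the default total to
#'   2000 genes).
#' @param n_me_pairs Bilateral ME pairs (default 20): partner A active in a
#'   non-empty subset of the hub's phenotypes, partner B in a non-empty
#'   subset of the complement, so every B gene is also a planted ME partner
#'   of the hub.
#' @param n_coexist_pairs Pairs sharing one active subset (default 10).
#' @param n_linear_neg_pairs Linearly anti-correlated, never-near-zero
#'   pairs (default 10).
#' @param n_housekeeping Constitutively high genes (default 50).
#' @param n_silent Genes zero in 95% of samples, tiny otherwise
#'   (default 50).
#' @param mu_hi,mu_lo Median TPM of active / inactive expression
#'   (defaults 100 and 1); `mu_hi` must exceed `mu_lo`.
#' @param sigma Log-scale standard deviation (default 0.8).
#' @param dropout_off Probability an inactive state is exactly zero
#'   (default 0.7).
#' @param p_active Per-phenotype inclusion probability for random active
#'   subsets (default 0.75).
#' @param seed Integer seed; the generator is bit-reproducible for a fixed
#'   spec.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_samples = 600L,
                           n_phenotypes = 8L,
                           phenotype_weights = NULL,
                           n_background_genes = 1819L,
                           n_me_pairs = 20L,
                           n_coexist_pairs = 10L,
                           n_linear_neg_pairs = 10L,
                           n_housekeeping = 50L,
                           n_silent = 50L,
                           mu_hi = 100,
                           mu_lo = 1,
                           sigma = 0.8,
                           dropout_off = 0.7,
                           p_active = 0.75,
                           seed = 1L) {
  if (n_samples < 1L || n_phenotypes < 1L) {
    rlang::abort("need at least one sample and one phenotype")
  }
  if (is.null(phenotype_weights)) {
    phenotype_weights <- rep(1 / n_phenotypes, n_phenotypes)
  }
  if (length(phenotype_weights) != n_phenotypes ||
      abs(sum(phenotype_weights) - 1) > 1e-8 || any(phenotype_weights < 0)) {
    rlang::abort("phenotype_weights must be a probability vector over the phenotypes")
  }
  counts <- c(n_background_genes, n_me_pairs, n_coexist_pairs,
              n_linear_neg_pairs, n_housekeeping, n_silent)
  if (any(counts < 0)) rlang::abort("archetype counts must be nonnegative")
  if (mu_hi <= mu_lo) rlang::abort("mu_hi must exceed mu_lo")
  if (dropout_off < 0 || dropout_off > 1) rlang::abort("dropout_off must lie in [0, 1]")
  if (sigma <= 0) rlang::abort("sigma must be positive")
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_phenotypes = as.integer(n_phenotypes),
      phenotype_weights = phenotype_weights,
      n_background_genes = as.integer(n_background_genes),
      n_me_pairs = as.integer(n_me_pairs),
      n_coexist_pairs = as.integer(n_coexist_pairs),
      n_linear_neg_pairs = as.integer(n_linear_neg_pairs),
      n_housekeeping = as.integer(n_housekeeping),
      n_silent = as.integer(n_silent),
      mu_hi = mu_hi,
      mu_lo = mu_lo,
      sigma = sigma,
      dropout_off = dropout_off,
      p_active = p_active,
      seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

#' Simulate a mixed-phenotype TPM matrix with planted archetypes
#'
#' Generates a genes x samples TPM matrix under a [generator_spec()],
#' together with per-gene ground-truth labels. Samples are assigned latent
#' phenotypes by the spec's weights; a designated hub gene is active in half
#' the phenotypes (so its plasticity is high, making it a usable virtual-
#' sorting source); each planted archetype then follows the construction
#' documented in [generator_spec()]. Generation order is fixed, so a given
#' spec always yields a bit-identical matrix.
#'
#' @param spec A `generator_spec`.
#' @return A list with elements `matrix` (TPM, genes x samples, dimnames
#'   set), `truth` (tibble: `gene_id`, `archetype` in hub / me_partner /
#'   coexist_partner / linear_neg_partner / housekeeping / silent /
#'   background, `partner`, `hub_partner` - `TRUE` for the ME genes whose
#'   active phenotypes are disjoint from the hub's, `active_phenotypes` as
#'   a comma-joined index string), and `phenotype` (integer phenotype per
#'   sample).
#' @export
simulate_expression <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  phen <- sample.int(spec$n_phenotypes, n, replace = TRUE,
                     prob = spec$phenotype_weights)
  hub_phens <- sort(sample.int(spec$n_phenotypes,
                               max(1L, floor(spec$n_phenotypes / 2))))
  off_phens <- setdiff(seq_len(spec$n_phenotypes), hub_phens)
  if (length(off_phens) == 0L) {
    rlang::abort("need at least 2 phenotypes to plant mutual exclusion")
  }

  # one lognormal draw per sample: active median mu_hi, inactive median
  # mu_lo with exact-zero dropout
  draw_active <- function(k) {
    stats::rlnorm(k, meanlog = log(spec$mu_hi), sdlog = spec$sigma)
  }
  draw_inactive <- function(k) {
    v <- stats::rlnorm(k, meanlog = log(spec$mu_lo), sdlog = spec$sigma)
    v[stats::runif(k) < spec$dropout_off] <- 0
    v
  }
  phenotype_gene <- function(active_set) {
    on <- phen %in% active_set
    v <- numeric(n)
    v[on] <- draw_active(sum(on))
    v[!on] <- draw_inactive(sum(!on))
    v
  }
  random_subset <- function(pool) {
    in_set <- pool[stats::runif(length(pool)) < spec$p_active]
    if (length(in_set) == 0L) in_set <- pool[sample.int(length(pool), 1L)]
    sort(in_set)
  }

  rows <- list()
  truth <- list()
  add_gene <- function(values, archetype, partner = NA_character_,
                       hub_partner = FALSE, active = NULL) {
    i <- length(rows) + 1L
    rows[[i]] <<- values
    truth[[i]] <<- list(
      archetype = archetype, partner = partner, hub_partner = hub_partner,
      active_phenotypes = if (is.null(active)) NA_character_ else
        paste(active, collapse = ",")
    )
  }

  n_total <- 1L + 2L * spec$n_me_pairs + 2L * spec$n_coexist_pairs +
    2L * spec$n_linear_neg_pairs + spec$n_housekeeping + spec$n_silent +
    spec$n_background_genes
  ids <- sprintf("G%05d", seq_len(n_total))

  # hub: the source-like gene, active in half the phenotypes
  add_gene(phenotype_gene(hub_phens), "hub", active = hub_phens)

  for (i in seq_len(spec$n_me_pairs)) {
    set_a <- random_subset(hub_phens)
    set_b <- random_subset(off_phens)
    id_a <- ids[length(rows) + 1L]
    id_b <- ids[length(rows) + 2L]
    add_gene(phenotype_gene(set_a), "me_partner", partner = id_b,
             hub_partner = FALSE, active = set_a)
    add_gene(phenotype_gene(set_b), "me_partner", partner = id_a,
             hub_partner = TRUE, active = set_b)
  }

  for (i in seq_len(spec$n_coexist_pairs)) {
    shared <- random_subset(seq_len(spec$n_phenotypes))
    id_a <- ids[length(rows) + 1L]
    id_b <- ids[length(rows) + 2L]
    add_gene(phenotype_gene(shared), "coexist_partner", partner = id_b,
             active = shared)
    add_gene(phenotype_gene(shared), "coexist_partner", partner = id_a,
             active = shared)
  }

  for (i in seq_len(spec$n_linear_neg_pairs)) {
    x <- stats::runif(n, 40, 160)
    y <- pmax(200 - x, 5) + stats::rlnorm(n, meanlog = 0, sdlog = spec$sigma)
    id_a <- ids[length(rows) + 1L]
    id_b <- ids[length(rows) + 2L]
    add_gene(x, "linear_neg_partner", partner = id_b)
    add_gene(y, "linear_neg_partner", partner = id_a)
  }

  for (i in seq_len(spec$n_housekeeping)) {
    add_gene(draw_active(n), "housekeeping")
  }

  for (i in seq_len(spec$n_silent)) {
    v <- numeric(n)
    on <- stats::runif(n) < 0.05
    v[on] <- stats::rlnorm(sum(on), meanlog = log(spec$mu_lo * 0.1),
                           sdlog = spec$sigma)
    add_gene(v, "silent")
  }

  for (i in seq_len(spec$n_background_genes)) {
    set_g <- random_subset(seq_len(spec$n_phenotypes))
    add_gene(phenotype_gene(set_g), "background", active = set_g)
  }

  m <- do.call(rbind, rows)
  dimnames(m) <- list(ids, sprintf("S%04d", seq_len(n)))
  truth_tbl <- tibble::tibble(
    gene_id = ids,
    archetype = purrr::map_chr(truth, "archetype"),
    partner = purrr::map_chr(truth, "partner"),
    hub_partner = purrr::map_lgl(truth, "hub_partner"),
    active_phenotypes = purrr::map_chr(truth, "active_phenotypes")
  )
  list(matrix = m, truth = truth_tbl, phenotype = phen)
}

#' @export
print.generator_spec <- function(x, ...) {
  n_total <- 1L + 2L * (x$n_me_pairs + x$n_coexist_pairs + x$n_linear_neg_pairs) +
    x$n_housekeeping + x$n_silent + x$n_background_genes
  cat("Mixed-phenotype generator spec: ", n_total, " genes x ", x$n_samples,
      " samples, ", x$n_phenotypes, " phenotypes\n",
      "  planted: ", x$n_me_pairs, " ME pairs, ", x$n_coexist_pairs,
      " co-exist pairs, ", x$n_linear_neg_pairs, " linear-negative pairs, ",
      x$n_housekeeping, " housekeeping, ", x$n_silent, " silent\n",
      "  TPM medians hi/lo ", x$mu_hi, "/", x$mu_lo, ", sdlog ", x$sigma,
      ", dropout ", x$dropout_off, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
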