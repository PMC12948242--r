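---
title: "Screening for mutually exclusive gene expression by virtual sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for mutually exclusive gene expression by virtual sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mescreen)
library(dplyr)
```

## The problem

Two genes are *mutually exclusive* (ME) in expression when at most one of them
is highly expressed in any given sample: across a heterogeneous collection of
samples, the high-expression states of the pair never co-occur. Expression-level
mutual exclusion is a useful lens for finding negative regulators of a gene of
interest — if candidate regulator B suppresses gene A, samples with B on tend to
have A off — and it is distinct from *linear negative correlation*, which is
perfectly compatible with both genes being co-expressed at intermediate levels
in every sample. A screen built on Pearson correlation therefore conflates two
different biological situations; `mescreen` implements a screen built instead on
rank plasticity, virtual sorting, and cosine geometry.

The screen presumes a *mixed-phenotype* sample collection: many samples pooled
across different cell types or states, so that a plastic gene is captured in
both its high and its low state. Within a single homogeneous cell type, a gene
that is simply never expressed there (low plasticity) can neither serve as a
usable source gene nor be detected as a target — the *unilateral exclusion*
failure modes that the exclusion-pattern classifier makes explicit.

## The statistics

**Percentile-rank scores.** Within each sample, TPM values are converted to
percentile ranks: for the `N` genes with non-zero TPM, `P = n / N * 100`,
where `n` is the gene's ascending ordinal rank among those non-zero genes
(ties get the average rank); a zero-TPM gene gets `P = 0` by definition. Ranks
make samples comparable regardless of their expression scale: `P` is invariant
under any strictly monotone transformation of one sample's TPM values.

**ARS and gene plasticity.** A gene's average rank score (ARS) is the mean of
its rank scores over a set of samples. Its gene-plasticity (GP) score is the
spread of its rank distribution: the difference between the 95th and 5th
percentiles of its rank scores across samples (`Delta 95/5`), so GP lies in
[0, 100]. The 5/95 window means at least 10% of the samples support any claimed
plasticity while single outlier samples cannot fake it. Genes split into
high- and low-plasticity classes at a configurable GP cutoff, defaulting to
the matrix-wide mean GP.

**Virtual sorting.** Samples are partitioned into source-high and source-low
groups by two-cluster k-means on the source gene's rank scores. Because the
data are one-dimensional, we do not run iterative k-means: the optimal
two-cluster solution is contiguous in value, so `partition_samples()` scans
the n − 1 split points of the sorted rank vector and takes the global minimum
of the within-cluster sum of squares. This is exact, deterministic, and
seed-free, where generic k-means is initialization-dependent. Samples tied at
the boundary always land on the same side, so group membership is a function
of the rank value alone.

**The delta-ARS statistic.** For every gene, `delta = ARS(high group) −
ARS(low group)`. A strongly negative delta says the gene's expression rank
collapses precisely when the source gene is on — the ME signature; a strongly
positive delta marks co-existing genes. Significance is assessed with a
two-sided Wilcoxon rank-sum test on the rank scores (exact for small tie-free
problems, normal approximation with tie and continuity corrections otherwise),
corrected across all genes of one source's screen by Benjamini–Hochberg.
We test rank scores rather than raw TPM because the whole screen — ARS, delta,
plasticity — is defined on the rank scale; this also makes the test invariant
to each sample's expression scale.

**Cosine similarity.** The third filter is the normalized inner product of the
two genes' raw TPM vectors across samples. For nonnegative data it lies in
[0, 1] and approaches 0 only when the genes' expression mass lives on disjoint
sample sets (a 90° angle) — which is exactly mutual exclusion, and exactly what
linear negative correlation is not: two anti-correlated genes co-expressed at
mid levels keep a large inner product. Cosine operates on raw TPM (a `log1p`
variant exists as an option but is off by default) because the angle between
raw expression vectors is what separates the L-shaped ME cloud from the
descending band of a linear relationship.

**The three-way filter.** A gene is an ME candidate when all three hold
(boundaries inclusive): cosine ≤ 0.05, delta ≤ −15, adjusted p ≤ 0.01. Each
condition kills a specific confounder: the delta and p conditions remove
near-silent noise genes whose cosine drifts toward 0 without any exclusion
evidence; the cosine condition removes linearly anti-correlated genes. The
filter is a pure conjunction, so the order of application is immaterial. The
source gene itself is never a candidate.

**Reciprocity and exclusion patterns.** True bilateral exclusion is symmetric,
so `reciprocal_check()` reruns the screen with each candidate as the source and
asks whether the original source gene passes the delta and p conditions in
reverse. It is reported as an annotation, not an extra hard filter — a
candidate whose own plasticity is too low to seed a reverse screen is flagged
not-evaluable rather than discarded, because that is precisely the unilateral
case the method warns about. `classify_exclusion_pattern()` labels each pair
bilateral_ME, unilateral_source_low, unilateral_target_low, co_existing, or
none, from the two GP scores and delta.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cos_max` | 0.05 | cosine ceiling (unitless, [0, 1]) for candidacy |
| `delta_max` | −15 | delta-ARS ceiling (rank-score points) for ME |
| `coexist_min` | +15 | delta-ARS floor for the co-existing label |
| `padj_max` | 0.01 | BH-adjusted p ceiling |
| `min_group` | 10 | smallest allowed virtual-sorting group; below ~10 samples the rank-sum test and group ARS are unstable |
| `gp_threshold` | mean GP | high/low plasticity cutoff (rank-score points); no canonical value exists, so the matrix-wide mean is used and it is a config knob |

The delta and p defaults are deliberately strict screening values; relaxing
`delta_max` toward 0 admits weaker, possibly indirect exclusions.

## The synthetic-data generator

`simulate_expression()` emulates the pooled mixed-phenotype design the screen
targets, with ground-truth labels so every stage is testable without any
external download. Samples draw a latent phenotype (default: 8 phenotypes,
equal weights, 600 samples). Expression is lognormal on the TPM scale —
active states with median 100 TPM, inactive states exactly zero with
probability 0.7 (dropout) and otherwise median 1 TPM, both with sdlog 0.8 —
the simplest model that reproduces the structures the method relies on:
phenotype-restricted plastic expression, exact zeros for the `P = 0` rule,
and a heavy right tail.

Planted archetypes (defaults bring the matrix to 2000 genes):

- **hub** — one source-like gene active in half the phenotypes, so its GP is
  high and virtual sorting has a clean two-cluster structure;
- **20 ME pairs** — partner A active in a non-empty subset of the hub's
  phenotypes, partner B in a non-empty subset of the complement; each pair is
  bilaterally exclusive and every B gene is also a planted ME partner of the
  hub;
- **10 co-existing pairs** — both partners share one active subset;
- **10 linear-negative pairs** — per sample, `x ~ U(40, 160)` and
  `y = max(200 − x, 5)` plus lognormal noise: strongly anti-correlated, never
  near zero, and therefore a cosine far above 0.05 — the confounder the cosine
  filter must reject;
- **50 housekeeping genes** — constitutively high, zero plasticity;
- **50 silent genes** — zero in 95% of samples, tiny (median 0.1 TPM)
  otherwise: the confounder producing spurious near-zero cosines that the
  delta/p conditions must reject;
- **background** (remainder, 1819) — active in an independently random
  phenotype subset, each phenotype included with probability 0.75, reflecting
  that most protein-coding genes are detected in the majority of cell types.

Active-subset draws for planted pairs use the same 0.75 inclusion probability
within their respective phenotype compartments. Generation order is fixed and
all draws come from one seeded stream, so a given spec is bit-reproducible.

What the generator does *not* emulate: library-size or batch effects,
correlated gene programs beyond the planted pairs, single-cell sparsity
beyond the dropout parameter, and realistic GP distributions — because the
archetypes are all phenotype-restricted, the matrix-wide mean GP (~89) is far
above the ~40 typical of real pooled bulk collections. Passing tests on this
generator therefore demonstrate that the statistics and filters behave as
specified under planted truth, not that thresholds tuned here transfer
unchanged to any real data set.

## Numerical and degenerate-input choices

- Within-sample rank ties get the average ordinal rank, making ranks
  independent of input row order; whether non-zero genes are ranked among all
  genes or among non-zero genes only is genuinely ambiguous in the field's
  usage — we rank among the `N` non-zero genes only, so an expressed gene's
  score lies in (0, 100] and the top gene of every sample scores exactly 100,
  consistent with the separate zero rule.
- Quantiles use linear interpolation between order statistics (R's type 7),
  the common default; with fewer than 20 samples a warning flags that q05/q95
  are interpolation-dominated.
- An all-zero sample yields all-zero ranks plus a warning; an all-zero gene
  has ARS = GP = 0, class low, undefined cosine, and is retained (it matters
  for unilateral-exclusion diagnostics) but can never pass the cosine filter —
  a never-expressed gene carries no exclusion evidence.
- A constant-rank source gene is a structured `source_not_analyzable` result,
  not a crash; in multi-source mode such sources are skipped with a logged
  reason.
- Genes whose rank vector is constant across samples get Wilcoxon p = 1
  (no evidence) rather than NaN.
- BH families are per source gene: when many sources are screened, each
  source's gene-wise p-values are corrected independently.
- Whole-matrix screens (> 25 samples) use a vectorized normal-approximation
  Wilcoxon path; it is tested for per-gene agreement with `wilcox.test()` and,
  for small tie-free problems, against full enumeration of the rank-sum null.

## Problem sizes used in validation

The packaged tests validate the formula-level statistics against independent
oracles (sort-based ranks, longhand quantiles, brute-force split enumeration,
exhaustive Wilcoxon null enumeration for group sizes up to 8, the BH step-up
formula) and run the full screen on the default 600 x 2000 simulation, where
they require at least 18 of the 20 planted hub partners recovered, every
linear-negative gene rejected by the cosine condition, every silent gene
rejected by delta or adjusted p, at most 1% of background genes flagged, and
full reverse-direction confirmation of recovered partners. Unit tests use
smaller simulations (about 150 samples, a few hundred genes) of the same
design.

## A worked run

```{r example}
sim <- simulate_expression(generator_spec(
  n_samples = 150, n_phenotypes = 4, n_background_genes = 150,
  n_me_pairs = 4, n_coexist_pairs = 3, n_linear_neg_pairs = 3,
  n_housekeeping = 8, n_silent = 8, seed = 11
))
hub <- sim$truth$gene_id[sim$truth$archetype == "hub"]

screen <- run_me_screen(sim$matrix, hub, reciprocal = TRUE)
screen

glance(screen)

tidy(screen, candidates_only = TRUE) |>
  select(gene_id, delta, p_adj, cosine, pattern, reciprocal_ok)
```

```{r volcano, fig.width = 6, fig.height = 4}
autoplot(screen)
```

The delta volcano is the screen's summary view: mutual-exclusion candidates
sit in the lower-left (delta ≤ −15, small adjusted p) and must additionally
pass the cosine condition to be flagged.

## Known limitations

- Sensitivity is bounded by plasticity: a target silent in the pooled
  collection, or a source with no high/low structure, cannot be screened
  (the unilateral patterns). Pooling more diverse phenotypes is the remedy,
  not a different statistic.
- The screen is correlational; candidates are starting points for regulator
  validation, not verified regulators.
- Cosine on raw TPM is dominated by the largest values; near-silent genes
  reach small cosines spuriously, which is why the conjunction with delta and
  adjusted p is mandatory rather than optional.
- Somatic-mutation mutual-exclusivity statistics are a different problem and
  out of scope.
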