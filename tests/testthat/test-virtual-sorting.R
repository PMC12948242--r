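rank_row <- function(v, ids = sprintf("s%03d", seq_along(v))) {
  matrix(v, 1, length(v), dimnames = list("src", ids))
}

test_that("the two-cluster split separates clean groups and honors ties", {
  g <- partition_samples(rank_row(c(0, 0, 0, 100, 100)), "src", min_group = 1)
  expect_equal(g$n_low, 3L)
  expect_equal(g$n_high, 2L)
  expect_setequal(g$samples$sample_id[g$samples$group == "high"], c("s004", "s005"))

  # within-cluster SS decides: {10,12} vs {90} beats {10} vs {12,90}
  g2 <- partition_samples(rank_row(c(10, 12, 90)), "src", min_group = 1)
  expect_setequal(g2$samples$sample_id[g2$samples$group == "low"], c("s001", "s002"))

  # boundary ties are assigned by value, never split across groups
  g3 <- partition_samples(rank_row(c(0, 50, 50, 50, 100, 100)), "src", min_group = 1)
  tied <- g3$samples$group[g3$samples$rank_score == 50]
  expect_length(unique(tied), 1L)

  # the high group always holds the larger values
  expect_gt(
    min(g3$samples$rank_score[g3$samples$group == "high"]),
    max(g3$samples$rank_score[g3$samples$group == "low"])
  )
})

test_that("degenerate sources and undersized groups are hard errors", {
  expect_error(partition_samples(rank_row(rep(50, 4)), "src", min_group = 1),
               "zero plasticity")
  expect_error(partition_samples(rank_row(c(0, 0, 100, 100)), "src"),
               "high=2, low=2.*min_group=10")
  expect_error(partition_samples(rank_row(1:30), "absent"), "not found")
})

test_that("the exhaustive split matches multi-start k-means on random vectors", {
  set.seed(101)
  for (i in 1:30) {
    v <- runif(sample(10:80, 1), 0, 100)
    g <- partition_samples(rank_row(v), "src", min_group = 1)
    labels <- g$samples$group
    my_ss <- sum(tapply(v, labels, function(x) sum((x - mean(x))^2)))
    km <- kmeans(v, centers = 2, nstart = 25)
    expect_lte(my_ss, km$tot.withinss + 1e-8)
  }
})

test_that("delta-ARS is the difference of group means and is antisymmetric", {
  r <- rbind(
    src = c(0, 0, 90, 95),
    me = c(100, 80, 0, 0),
    flat = c(7, 7, 7, 7)
  )
  colnames(r) <- sprintf("s%03d", 1:4)
  g <- partition_samples(r, "src", min_group = 1)
  d <- delta_ars(r, g)
  expect_equal(d$delta[d$gene_id == "me"], mean(c(0, 0)) - mean(c(100, 80)))
  expect_equal(d$delta[d$gene_id == "flat"], 0)

  swapped <- g
  swapped$samples$group <- ifelse(g$samples$group == "high", "low", "high")
  expect_equal(delta_ars(r, swapped)$delta, -d$delta)

  set.seed(3)
  r2 <- matrix(runif(5 * 40, 0, 100), 5, 40,
               dimnames = list(c("src", letters[1:4]), sprintf("s%03d", 1:40)))
  g2 <- partition_samples(r2, "src", min_group = 1)
  hi <- g2$samples$sample_id[g2$samples$group == "high"]
  lo <- g2$samples$sample_id[g2$samples$group == "low"]
  d2 <- delta_ars(r2, g2)
  for (gene in rownames(r2)) {
    expect_equal(d2$delta[d2$gene_id == gene],
                 mean(r2[gene, hi]) - mean(r2[gene, lo]))
  }
})

test_that("the rank-sum test gives textbook p-values and handles degeneracy", {
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3)), 0.1)
  expect_equal(rank_sum_test(c(1, 2), c(1, 2)), 1)
  expect_equal(rank_sum_test(rep(5, 4), rep(5, 3)), 1)
  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")
})

test_that("the vectorized normal-approximation path agrees with wilcox.test per gene", {
  set.seed(77)
  r <- matrix(runif(30 * 60, 0, 100), 30, 60,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:60)))
  r[sample(length(r), 250)] <- 0  # heavy ties
  hi <- colnames(r)[1:25]
  lo <- colnames(r)[26:60]
  p_fast <- mescreen:::wilcox_matrix(r, hi, lo)
  for (i in seq_len(nrow(r))) {
    p_ref <- suppressWarnings(
      wilcox.test(r[i, hi], r[i, lo], exact = FALSE, correct = TRUE)$p.value
    )
    expect_equal(p_fast[i], p_ref, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up oracle and its guarantees", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("virtual_sort composes the stages, sorts by delta, and keeps the source row", {
  sim <- simulate_expression(small_spec())
  r <- rank_matrix(sim$matrix)
  hub <- hub_of(sim)
  st <- virtual_sort(r, hub)
  expect_identical(sort(st$gene_id), sort(rownames(r)))
  expect_true(all(diff(st$delta) <= 1e-12))
  src_row <- st[st$gene_id == hub, ]
  expect_gt(src_row$delta, 0)
  expect_lte(src_row$p_adj, 0.01)
  expect_true(all(st$p_adj >= st$p_raw - 1e-15))
  expect_equal(st$delta, st$ars_high - st$ars_low)
})

test_that("the sorting table is invariant under sample permutation", {
  sim <- simulate_expression(small_spec(seed = 23))
  r <- rank_matrix(sim$matrix)
  hub <- hub_of(sim)
  st1 <- virtual_sort(r, hub)
  set.seed(1)
  st2 <- virtual_sort(r[, sample(ncol(r))], hub)
  expect_equal(st1$gene_id, st2$gene_id)
  expect_equal(st1$delta, st2$delta)
  expect_equal(st1$p_adj, st2$p_adj)
})
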