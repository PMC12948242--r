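test_that("cosine similarity has its closed-form values and error modes", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(cosine_similarity(c(1, 0, 2, 0), c(0, 3, 0, 4)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2), tolerance = 1e-12)
  expect_true(is.na(cosine_similarity(c(0, 0), c(1, 2))))
  expect_error(cosine_similarity(1:3, 1:4), "equal length")
  expect_error(cosine_similarity(c(1, -1), c(1, 1)), "nonnegative")
})

test_that("cosine similarity is symmetric, scale-invariant, and bounded", {
  set.seed(19)
  for (i in 1:25) {
    x <- rlnorm(40); y <- rlnorm(40)
    x[runif(40) < 0.3] <- 0; y[runif(40) < 0.3] <- 0
    cs <- cosine_similarity(x, y)
    expect_equal(cs, cosine_similarity(y, x))
    expect_equal(cs, cosine_similarity(runif(1, 0.1, 10) * x,
                                       runif(1, 0.1, 10) * y))
    expect_gte(cs, 0)
    expect_lte(cs, 1 + 1e-12)
  }
})

test_that("per-gene cosines to the source handle self and all-zero genes", {
  m <- rbind(
    src = c(10, 0, 5, 0),
    same = c(20, 0, 10, 0),
    anti = c(0, 3, 0, 7),
    dead = c(0, 0, 0, 0)
  )
  colnames(m) <- sprintf("s%d", 1:4)
  cs <- cosine_to_source(m, "src")
  expect_equal(cs$cosine[cs$gene_id == "src"], 1)
  expect_equal(cs$cosine[cs$gene_id == "same"], 1)
  expect_equal(cs$cosine[cs$gene_id == "anti"], 0)
  expect_true(is.na(cs$cosine[cs$gene_id == "dead"]))
  expect_error(cosine_to_source(m, "nope"), "not found")
  expect_error(cosine_to_source(m[c("dead", "src"), ], "dead"), "all-zero")
})

test_that("the three-way filter is a pure conjunction with inclusive boundaries", {
  sorting <- tibble::tibble(
    gene_id = c("src", "all_pass", "delta_fail", "cos_fail", "p_fail",
                "boundary", "dead"),
    ars_high = 0, ars_low = 0,
    delta = c(40, -40, -10, -40, -40, -15, -40),
    p_raw = 1e-8,
    p_adj = c(1e-8, 1e-6, 1e-6, 1e-6, 0.5, 0.01, 1e-6)
  )
  cosines <- tibble::tibble(
    gene_id = sorting$gene_id,
    cosine = c(1, 0.01, 0.01, 0.8, 0.01, 0.05, NA)
  )
  plasticity <- tibble::tibble(gene_id = sorting$gene_id, gp = 80)
  out <- screen_me(sorting, cosines, plasticity, "src", gp_threshold = 40)

  expect_identical(out$is_candidate[out$gene_id == "all_pass"], TRUE)
  expect_identical(out$is_candidate[out$gene_id == "delta_fail"], FALSE)
  expect_identical(out$is_candidate[out$gene_id == "cos_fail"], FALSE)
  expect_identical(out$is_candidate[out$gene_id == "p_fail"], FALSE)
  expect_identical(out$is_candidate[out$gene_id == "boundary"], TRUE)  # <= is inclusive
  expect_identical(out$pass_cosine[out$gene_id == "dead"], FALSE)     # undefined fails
  expect_identical(out$is_candidate[out$gene_id == "src"], FALSE)     # source excluded
  expect_equal(out$is_candidate, out$pass_cosine & out$pass_delta &
                 out$pass_padj & out$gene_id != "src")

  expect_error(screen_me(sorting, cosines, plasticity, "src", cos_max = 1.5),
               "cos_max")
  expect_error(screen_me(sorting, cosines, plasticity, "src", delta_max = -150),
               "delta_max")
  expect_error(screen_me(sorting, cosines, plasticity, "src", padj_max = 0),
               "padj_max")
})

test_that("exclusion patterns follow the bilateral/unilateral taxonomy", {
  expect_identical(
    classify_exclusion_pattern(65, 70, -40, gp_threshold = 40), "bilateral_ME"
  )
  # plastic source, broadly silent target: the one-sided case the screen misses
  expect_identical(
    classify_exclusion_pattern(65, 5, -40, gp_threshold = 40),
    "unilateral_target_low"
  )
  # silent source, plastic target: virtual sorting has nothing to sort
  expect_identical(
    classify_exclusion_pattern(5, 65, -40, gp_threshold = 40),
    "unilateral_source_low"
  )
  expect_identical(
    classify_exclusion_pattern(65, 70, 40, gp_threshold = 40), "co_existing"
  )
  expect_identical(
    classify_exclusion_pattern(65, 70, 0, gp_threshold = 40), "none"
  )
  expect_identical(
    classify_exclusion_pattern(65, c(70, 5, 70), c(-40, -40, 3), gp_threshold = 40),
    c("bilateral_ME", "unilateral_target_low", "none")
  )
})

test_that("planted linear-negative pairs are anti-correlated yet far from orthogonal", {
  sim <- simulate_expression(small_spec(seed = 31))
  pairs <- sim$truth[sim$truth$archetype == "linear_neg_partner", ]
  a_ids <- pairs$gene_id[seq(1, nrow(pairs), by = 2)]
  for (a in a_ids) {
    b <- pairs$partner[pairs$gene_id == a]
    x <- sim$matrix[a, ]; y <- sim$matrix[b, ]
    expect_lt(cor(x, y), -0.5)                  # linear model sees strong negativity
    expect_gt(cosine_similarity(x, y), 0.5)     # cosine sees co-expression
    expect_gt(min(c(x, y)), 0)                  # never near zero by construction
  }
})

test_that("the reciprocal check confirms planted pairs and flags the non-evaluable", {
  sim <- simulate_expression(small_spec(seed = 47))
  r <- rank_matrix(sim$matrix)
  tr <- sim$truth
  hub <- hub_of(sim)
  partners <- tr$gene_id[tr$hub_partner]

  rc <- reciprocal_check(r, partners, hub, min_group = 10)
  expect_true(all(rc$reciprocal_ok))
  expect_true(all(rc$reciprocal_delta <= -15))

  # a gene with constant (all-zero) ranks cannot seed a reverse screen
  r0 <- rbind(r, dead = 0)
  rc0 <- reciprocal_check(r0, "dead", hub)
  expect_true(is.na(rc0$reciprocal_ok))
  expect_match(rc0$note, "zero plasticity")

  # a co-existing pair points the wrong way: strong positive delta in reverse
  co <- tr$gene_id[tr$archetype == "coexist_partner"][1]
  co_partner <- tr$partner[tr$gene_id == co]
  rc_co <- reciprocal_check(r, co_partner, co, min_group = 10)
  expect_false(isTRUE(rc_co$reciprocal_ok))
  expect_gte(rc_co$reciprocal_delta, 15)
})
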