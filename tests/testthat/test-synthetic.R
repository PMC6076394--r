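test_that("planted matrices are deterministic, nonnegative and exact at zero noise", {
  p1 <- generate_planted_matrix(60, 6, 2, 5, noise_scale = 0, seed = 3)
  p2 <- generate_planted_matrix(60, 6, 2, 5, noise_scale = 0, seed = 3)
  expect_identical(p1$X$values, p2$X$values)
  expect_identical(p1$marker_sets, p2$marker_sets)
  # noiseless identity: X == W %*% H, so the planted factors have zero divergence
  expect_equal(p1$X$values, unname(p1$W_true %*% p1$H_true),
               ignore_attr = TRUE)
  expect_equal(kl_divergence(p1$X$values, p1$W_true, p1$H_true), 0,
               tolerance = 1e-9)
  # rank-1 structure: all columns proportional
  r1 <- generate_planted_matrix(40, 5, 1, 5, noise_scale = 0, seed = 7)
  X <- r1$X$values
  ratios <- X[, -1, drop = FALSE] / X[, 1]
  expect_lt(max(apply(ratios, 2, stats::sd), na.rm = TRUE), 1e-12)
})

test_that("generated matrices are nonnegative over many parameterizations", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    m <- sample(4:12, 1)
    r <- sample(1:4, 1)
    nm <- sample(c("poisson", "truncated-gaussian"), 1)
    p <- generate_planted_matrix(n, m, r, sample(2:5, 1),
                                 signal = stats::runif(1, 1, 50),
                                 baseline = stats::runif(1, 0.01, 5),
                                 noise_model = nm,
                                 noise_scale = stats::runif(1, 0, 3),
                                 seed = i)
    expect_true(all(p$X$values >= 0))
    expect_true(all(p$W_true >= 0) && all(p$H_true >= 0))
  }
})

test_that("factor-1 markers are elevated where factor 1 dominates", {
  p <- generate_planted_matrix(100, 8, 2, 10, signal = 10, baseline = 0.1,
                               noise_model = "poisson", seed = 21)
  dom1 <- which(apply(p$H_true, 2, which.max) == 1)
  m1 <- match(p$marker_sets[[1]], gene_ids(p$X))
  bg <- setdiff(seq_len(100), match(unlist(p$marker_sets), gene_ids(p$X)))
  marker_mean <- mean(p$X$values[m1, dom1])
  background_mean <- mean(p$X$values[bg, dom1])
  expect_gt(marker_mean, background_mean)
})

test_that("planted factors are recoverable in the noiseless limit", {
  p <- generate_planted_matrix(100, 8, 2, 10, noise_scale = 0, seed = 13)
  m <- fit_nmf(p$X, 2, n_runs = 5, max_iter = 1500, tol = 1e-9, seed = 4)
  expect_lt(m$divergence, 1e-6 * sum(p$X$values))
})

test_that("two-condition study honors shared-fraction boundaries and invariants", {
  st1 <- generate_two_condition_study(n_genes = 400, markers_per_factor = 10,
                                      shared_fraction = 1, seed = 2)
  expect_length(st1$specific_markers_b, 0)
  st0 <- generate_two_condition_study(n_genes = 400, markers_per_factor = 10,
                                      shared_fraction = 0, seed = 2)
  expect_length(st0$shared_markers, 0)

  st <- generate_two_condition_study(seed = 8)
  # default shared ratio ~ 0.1 by set counting
  expect_equal(length(st$shared_markers) / length(st$marker_sets_b[[1]]), 0.1,
               tolerance = 0.02)
  # marker sets within one condition are pairwise disjoint
  for (sets in list(st$marker_sets_a, st$marker_sets_b)) {
    all_ids <- unlist(sets)
    expect_false(anyDuplicated(all_ids) > 0)
  }
  expect_true(all(st$shared_markers %in% st$marker_sets_a[[1]]))
  expect_true(all(st$shared_markers %in% st$marker_sets_b[[1]]))
  expect_length(intersect(st$specific_markers_b, unlist(st$marker_sets_a)), 0)
  expect_identical(gene_ids(st$X_a), gene_ids(st$X_b))
  expect_true(all(st$X_a$values >= 0) && all(st$X_b$values >= 0))
  # determinism
  st2 <- generate_two_condition_study(seed = 8)
  expect_identical(st$X_b$values, st2$X_b$values)
})

test_that("annotation categories follow the rounded fractions", {
  ids10 <- sprintf("p%02d", 1:10)
  a <- generate_annotation(ids10, frac_cdna = 0.2, seed = 1)
  expect_equal(sum(a$category == "cdna"), 2L)

  ids <- sprintf("p%03d", 1:100)
  b <- generate_annotation(ids, frac_cdna = 0.3, frac_hypothetical = 0.1,
                           frac_non_human = 0.05, frac_obsolete = 0.05,
                           n_duplicate_symbols = 5, seed = 9)
  counts <- table(b$category)
  expect_equal(as.integer(counts[c("symbol", "cdna", "hypothetical",
                                   "non_human", "obsolete")]),
               c(50L, 30L, 10L, 5L, 5L))
  # category counts partition the probes
  expect_equal(sum(counts), 100L)
  # exactly 5 symbol probes share their symbol with another probe
  sym <- b$symbol[b$category == "symbol"]
  expect_equal(sum(sym %in% sym[duplicated(sym)]), 5L)
  # symbol string present iff category == symbol
  expect_true(all(is.na(b$symbol) == (b$category != "symbol")))
  expect_identical(b, generate_annotation(ids, 0.3, 0.1, 0.05, 0.05, 5, seed = 9))
})

test_that("annotation with zero fractions gives unique symbols for all probes", {
  a <- generate_annotation(sprintf("p%d", 1:25), seed = 3)
  expect_true(all(a$category == "symbol"))
  expect_false(anyDuplicated(a$symbol) > 0)
})

test_that("generator rejects invalid arguments", {
  expect_error(generate_planted_matrix(0, 5, 2, 2), "n_genes")
  expect_error(generate_planted_matrix(10, 5, 3, 5), "exceeds n_genes")
  expect_error(generate_annotation(c("a", "b"), frac_cdna = 0.8,
                                   frac_hypothetical = 0.5), "sum above 1")
  expect_error(generate_annotation(letters, n_duplicate_symbols = 1),
               "single probe")
})
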