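test_that("volcano statistics match closed-form hand computation", {
  # 2 + 2 toy, pooled variance
  x <- rbind(g1 = c(1, 2, 4, 7), g2 = c(1, 2, 1, 2), g3 = c(5, 5, 5, 5))
  labels <- c("A", "A", "B", "B")
  suppressMessages(v <- volcano_stats(x, labels))
  ma <- mean(c(1, 2)); mb <- mean(c(4, 7))
  sp2 <- (stats::var(c(1, 2)) + stats::var(c(4, 7))) / 2
  t_hand <- (mb - ma) / sqrt(sp2 * (1 / 2 + 1 / 2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 2)
  expect_equal(v$mean_diff[1], mb - ma)
  expect_equal(v$t_stat[1], t_hand, tolerance = 1e-12)
  expect_equal(v$p_value[1], p_hand, tolerance = 1e-12)
  # identical samples per group: t = 0, p = 1
  expect_equal(v$t_stat[2], 0)
  expect_equal(v$p_value[2], 1)
  # zero variance in both groups: p = 1 by convention (message logged)
  expect_equal(v$p_value[3], 1)
  expect_equal(v$neg_log10_p, -log10(v$p_value))
})

test_that("volcano statistics are symmetric under label swap", {
  set.seed(18)
  x <- rand_nonneg(30, 9, zero_frac = 0)
  labels <- rep(c("A", "B"), c(4, 5))
  v1 <- volcano_stats(x, labels)
  v2 <- volcano_stats(x, ifelse(labels == "A", "Z", "A")) # swap group order
  expect_equal(v2$mean_diff, -v1$mean_diff, tolerance = 1e-12)
  expect_equal(v2$p_value, v1$p_value, tolerance = 1e-12)
})

test_that("a strongly shifted gene falls below the 0.05 line", {
  set.seed(20)
  x <- matrix(stats::rnorm(40 * 18, mean = 50, sd = 1), 40, 18)
  x[7, 9:18] <- x[7, 9:18] + 10 # 10 pooled SDs between groups of 8 and 10
  labels <- rep(c("MGUS", "MM"), c(8, 10))
  v <- volcano_stats(abs(x), labels)
  expect_lt(v$p_value[7], 0.05)
})

test_that("volcano input validation", {
  x <- rand_nonneg(5, 4)
  expect_error(volcano_stats(x, c("A", "A", "A", "B")), "at least 2")
  expect_error(volcano_stats(x, c("A", "B", "C", "A")), "two groups")
})

test_that("PC1 matches a covariance-eigenvector oracle and its edge cases", {
  # exact rank-1 centered matrix -> variance fraction 1
  u <- stats::runif(15); s <- c(1, 2, 3, 4)
  x <- outer(u, s) + 5
  pc <- pca_first_component(x)
  expect_equal(pc$variance_fraction, 1, tolerance = 1e-12)

  set.seed(22)
  y <- rand_nonneg(20, 6, zero_frac = 0)
  pcy <- pca_first_component(y)
  yc <- y - rowMeans(y)
  eig <- eigen(yc %*% t(yc), symmetric = TRUE)
  ev <- eig$vectors[, 1]
  if (ev[which.max(abs(ev))] < 0) ev <- -ev
  expect_equal(unname(pcy$loading), ev, tolerance = 1e-8)
  expect_equal(pcy$variance_fraction, eig$values[1] / sum(eig$values),
               tolerance = 1e-10)
  # variance fractions over all components sum to 1
  sv <- svd(yc)
  expect_equal(sum(sv$d^2 / sum(sv$d^2)), 1)
  # largest-magnitude loading entry is positive
  expect_gt(pcy$loading[which.max(abs(pcy$loading))], 0)
  expect_error(pca_first_component(matrix(3, 4, 5)), "PC1 undefined")
})

test_that("concatenation preserves genes, labels and rejects mismatches", {
  st <- small_study(seed = 6)
  xc <- concatenate_conditions(st$X_a, st$X_b)
  expect_equal(dim(xc), c(400L, 18L))
  expect_identical(gene_ids(xc), gene_ids(st$X_a))
  expect_identical(xc$condition, c(st$X_a$condition, st$X_b$condition))
  expect_equal(xc$values[, 1:8], st$X_a$values, ignore_attr = TRUE)

  shuffled <- expression_matrix(st$X_b$values[c(2, 1, 3:400), ],
                                gene_ids = gene_ids(st$X_b)[c(2, 1, 3:400)])
  expect_error(concatenate_conditions(st$X_a, shuffled),
               "first discrepancy at row 1")
})

test_that("rank bound check reflects subadditivity", {
  expect_true(rank_bound_check(5, 5, 8))
  expect_false(rank_bound_check(13, 5, 8))
  expect_true(rank_bound_check(1, 1, 1))
})

test_that("metagene sample weights normalize per column", {
  H <- rbind(c(1, 2, 0.5), c(3, 2, 4.5))
  expect_equal(unname(metagene_sample_weights(H, 2)[1]), 0.75)
  expect_equal(unname(metagene_sample_weights(H, 1) +
                        metagene_sample_weights(H, 2)), rep(1, 3))
  expect_equal(unname(metagene_sample_weights(matrix(2, 1, 4), 1)), rep(1, 4))
  Hz <- H; Hz[, 2] <- 0
  colnames(Hz) <- c("s1", "s2", "s3")
  expect_error(metagene_sample_weights(Hz, 1), "s2")
})

test_that("group weight summaries reproduce the exact rank-sum null", {
  # equal weights everywhere: equal means, p = 1
  eq <- suppressWarnings(group_weight_summary(rep(0.2, 6),
                                              rep(c("A", "B"), each = 3)))
  expect_equal(unname(eq$mean_weight), c(0.2, 0.2))
  expect_equal(eq$p_value, 1)
  # enumerable toy: (1,2,3) vs (4,5,6) -> two-sided exact p = 0.1
  toy <- group_weight_summary(c(1, 2, 3, 4, 5, 6),
                              rep(c("A", "B"), each = 3))
  expect_equal(toy$p_value, 0.1, tolerance = 1e-12)
  expect_equal(toy$higher_in, "B")
  expect_error(group_weight_summary(1:4, rep("A", 4)), "two conditions")
})

test_that("a planted B-only metagene concentrates top counts in condition B", {
  H <- matrix(0.05, 3, 8)
  H[1, 1:4] <- 1    # metagene 1 dominates condition A samples
  H[2, 5:8] <- 1.5  # metagene 2 dominates condition B samples
  labels <- rep(c("A", "B"), each = 4)
  w <- metagene_sample_weights(H, 2)
  Hn <- sweep(H, 2, colSums(H), "/")
  top <- apply(Hn, 2, which.max) == 2
  ws <- group_weight_summary(w, labels, top_selected = top)
  expect_equal(unname(ws$top_counts), c(0L, 4L))
  expect_equal(ws$higher_in, "B")
  expect_lt(ws$p_value, 0.05)
})

test_that("containment is the recovered fraction of the reference set", {
  expect_equal(containment(c("a", "b", "c"), c("a", "b")), 1)
  expect_equal(containment(c("x"), c("a", "b")), 0)
  expect_equal(containment(c("a", "b", "c"), c("a", "b", "c", "d")), 0.75)
  expect_error(containment("a", character(0)), "non-empty")
})

test_that("the metagene loading is sparser than the PC1 loading on planted data", {
  gini <- function(v) {
    v <- sort(abs(v)); n <- length(v)
    if (sum(v) == 0) return(0)
    sum((2 * seq_len(n) - n - 1) * v) / (n * sum(v))
  }
  st <- small_study(seed = 9)
  xc <- concatenate_conditions(st$X_a, st$X_b)
  pc <- pca_first_component(xc)
  m <- fit_nmf(xc, 5, n_runs = 4, max_iter = 600, seed = 12)
  sets <- extract_genes(m)$sets
  loading <- m$W[, sets$most_informative]
  expect_gt(gini(loading), gini(pc$loading))
})
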