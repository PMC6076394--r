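test_that("kl_divergence matches hand-evaluated cases and the identity", {
  W <- matrix(c(1, 2, 0.5, 1), 2, 2)
  H <- matrix(c(1, 0.3, 2, 1), 2, 2)
  expect_equal(kl_divergence(W %*% H, W, H), 0, tolerance = 1e-12)
  expect_equal(kl_divergence(matrix(2, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1)),
               2 * log(2) - 1, tolerance = 1e-12)
  expect_equal(kl_divergence(matrix(1, 1, 1), matrix(1, 1, 1), matrix(2, 1, 1)),
               log(1 / 2) + 1, tolerance = 1e-12)
  expect_error(kl_divergence(matrix(1, 2, 2), matrix(1, 3, 1), matrix(1, 1, 2)),
               "shape|conformable")
  expect_error(kl_divergence(matrix(-1, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1)),
               "negative")
})

test_that("multiplicative updates are monotone and keep factors nonnegative", {
  set.seed(42)
  X <- rand_nonneg(6, 4)
  W <- matrix(stats::runif(12), 6, 2)
  H <- matrix(stats::runif(8), 2, 4)
  d <- kl_divergence(X, W, H)
  for (i in 1:200) {
    up <- multiplicative_update(X, W, H)
    W <- up$W
    H <- up$H
    d2 <- kl_divergence(X, W, H)
    expect_lte(d2, d + 1e-9 * (1 + d))
    d <- d2
  }
  expect_true(all(W >= 0) && all(H >= 0))
})

test_that("an exact factorization is a fixed point up to numerical slack", {
  set.seed(1)
  W <- matrix(stats::runif(8, 0.5, 2), 4, 2)
  H <- matrix(stats::runif(6, 0.5, 2), 2, 3)
  X <- W %*% H
  up <- multiplicative_update(X, W, H)
  d <- kl_divergence(X, up$W, up$H)
  expect_lt(d, 1e-9 * (1 + kl_divergence(X, W, H)))
})

test_that("an all-zero row of X drives the matching W row to zero", {
  set.seed(2)
  X <- rand_nonneg(8, 5, zero_frac = 0)
  X[3, ] <- 0
  W <- matrix(stats::runif(16), 8, 2)
  H <- matrix(stats::runif(10), 2, 5)
  for (i in 1:200) {
    up <- multiplicative_update(X, W, H)
    W <- up$W
    H <- up$H
  }
  expect_lt(sum(W[3, ]), 1e-6)
})

test_that("divergence and updates scale linearly with the data", {
  set.seed(3)
  X <- rand_nonneg(5, 4, zero_frac = 0)
  W <- matrix(stats::runif(10, 0.2, 1), 5, 2)
  H <- matrix(stats::runif(8, 0.2, 1), 2, 4)
  cc <- 3.7
  expect_equal(kl_divergence(cc * X, cc * W, H), cc * kl_divergence(X, W, H),
               tolerance = 1e-9)
  u1 <- multiplicative_update(X, W, H)
  u2 <- multiplicative_update(cc * X, cc * W, H)
  expect_equal(u2$W, cc * u1$W, tolerance = 1e-9)
  expect_equal(u2$H, u1$H, tolerance = 1e-9)
})

test_that("fit_nmf is reproducible, recovers planted structure, and warns on large rank", {
  p <- generate_planted_matrix(100, 8, 2, 10, noise_scale = 0, seed = 3)
  m1 <- fit_nmf(p$X, 2, n_runs = 5, seed = 7)
  m2 <- fit_nmf(p$X, 2, n_runs = 5, seed = 7)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$H, m2$H)
  expect_lt(m1$divergence, 1e-6 * sum(p$X$values))
  # divergence trace is non-increasing within tolerance
  tr <- m1$divergence_trace
  expect_true(all(diff(tr) <= 1e-9 * (1 + tr[-length(tr)])))
  expect_equal(m1$divergence, tr[length(tr)])
  # H rows are normalized to unit sum (scale convention)
  expect_equal(unname(rowSums(m1$H)[rowSums(m1$H) > 0]),
               rep(1, sum(rowSums(m1$H) > 0)), tolerance = 1e-12)
  expect_warning(fit_nmf(matrix(1:6 + 0, 3, 2), rank = 5, n_runs = 1,
                         max_iter = 5, seed = 1), "exceeds")
  expect_error(fit_nmf(matrix(numeric(0), 0, 0), 2), "empty")
})

test_that("richer models fit no worse than nested ones on the same data", {
  set.seed(11)
  X <- rand_nonneg(20, 6, zero_frac = 0)
  d2 <- fit_nmf(X, 2, n_runs = 8, max_iter = 800, seed = 5)$divergence
  d3 <- fit_nmf(X, 3, n_runs = 8, max_iter = 800, seed = 5)$divergence
  expect_lte(d3, d2 * (1 + 1e-6))
})

test_that("rank-1 fits match the closed-form KL optimum", {
  set.seed(19)
  for (i in 1:5) {
    X <- rand_nonneg(sample(3:6, 1), sample(2:4, 1), zero_frac = 0)
    m <- fit_nmf(X, 1, n_runs = 3, max_iter = 1000, tol = 1e-10, seed = i)
    expect_lte(m$divergence, oracle_rank1_kl(X) * 1.01 + 1e-9)
  }
})

test_that("consensus matrices are valid and block-structured on separable data", {
  p <- generate_planted_matrix(80, 8, 2, 10, noise_scale = 0, seed = 31)
  C <- consensus_matrix(p$X, 2, n_runs = 10, seed = 17)
  expect_equal(diag(C), rep(1, 8), ignore_attr = TRUE)
  expect_equal(C, t(C))
  expect_true(all(C >= 0 & C <= 1))
  # perfectly separable planted clusters: consensus is a 0/1 matrix and
  # within-cluster consensus exceeds between-cluster consensus
  expect_true(all(C %in% c(0, 1)))
  cl <- apply(p$H_true, 2, which.max)
  same <- outer(cl, cl, `==`)
  expect_gt(mean(C[same & upper.tri(C)]), mean(C[!same & upper.tri(C)]))
})

test_that("cophenetic coefficient handles perfect, degenerate and generic cases", {
  block <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
                 cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
  expect_equal(cophenetic_coefficient(block), 1)
  expect_equal(cophenetic_coefficient(matrix(c(1, 0.4, 0.4, 1), 2, 2)), 1)
  set.seed(23)
  for (i in 1:5) {
    C <- block[1:6, 1:6] * 0.8 + matrix(stats::runif(36, 0, 0.2), 6, 6)
    C <- (C + t(C)) / 2
    diag(C) <- 1
    expect_equal(cophenetic_coefficient(C), oracle_cophenetic_corr(1 - C),
                 tolerance = 1e-10)
    expect_lt(cophenetic_coefficient(C), 1)
  }
})

test_that("survey_ranks selects the planted rank and is deterministic", {
  p <- generate_planted_matrix(120, 12, 3, 12, noise_scale = 0, seed = 41)
  sv <- survey_ranks(p$X, 2:5, seed = 6)
  expect_equal(sv$selected_rank, 3L)
  sv2 <- survey_ranks(p$X, 2:5, seed = 6)
  expect_identical(sv$cophenetic, sv2$cophenetic)
  expect_identical(sv$consensus, sv2$consensus)
  # singleton candidate list
  sv1 <- survey_ranks(p$X, 3, n_runs = 5, max_iter = 200, seed = 2)
  expect_equal(sv1$selected_rank, 3L)
  expect_error(survey_ranks(p$X, c(1, 2)), "ranks")
})
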