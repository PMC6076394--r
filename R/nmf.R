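#' Generalized Kullback-Leibler divergence between a matrix and its factorization
#'
#' Computes `D(X || WH) = sum_ij [ X_ij * ln(X_ij / (WH)_ij) - X_ij + (WH)_ij ]`
#' with the conventions `0 * ln 0 = 0` and an epsilon guard on the
#' reconstruction in the denominator. This is the objective minimized by the
#' multiplicative updates in [fit_nmf()]. Natural logarithm; the log base only
#' changes the objective by a global scale.
#'
#' @param X nonnegative numeric matrix (genes x samples).
#' @param W nonnegative basis matrix (genes x rank).
#' @param H nonnegative coefficient matrix (rank x samples).
#' @param eps guard added implicitly to the reconstruction to avoid division
#'   by zero; entries of `WH` below `eps` are floored at `eps` inside the log.
#' @return A single nonnegative number; 0 iff `X == WH` entrywise (within
#'   numerical tolerance).
#' @examples
#' X <- matrix(2, 1, 1)
#' kl_divergence(X, matrix(1, 1, 1), matrix(1, 1, 1)) # 2*log(2) - 1
#' @export
kl_divergence <- function(X, W, H, eps = 1e-12) {
  .check_matrix_nonneg(X, "X")
  .check_matrix_nonneg(W, "W")
  .check_matrix_nonneg(H, "H")
  .assert(ncol(W) == nrow(H), "`W` and `H` are not conformable")
  .assert(nrow(W) == nrow(X) && ncol(H) == ncol(X),
          "`W %*% H` does not match the shape of `X`")
  WH <- W %*% H
  pos <- X > 0
  d <- sum(WH) - sum(X) +
    sum(X[pos] * log(X[pos] / pmax(WH[pos], eps)))
  # mathematically >= 0; clamp roundoff
  max(d, 0)
}

#' One sweep of the multiplicative update rules for KL-NMF
#'
#' Applies the standard multiplicative rules for the generalized KL objective:
#' first `H <- H * (W' (X / WH)) / colSums(W)`, then, with the refreshed
#' reconstruction, `W <- W * ((X / WH) H') / rowSums(H)`. Divisions are
#' epsilon-guarded. Each sweep is non-increasing in [kl_divergence()] up to
#' numerical slack and preserves nonnegativity.
#'
#' @inheritParams kl_divergence
#' @return A list with updated `W` and `H`.
#' @export
multiplicative_update <- function(X, W, H, eps = 1e-12) {
  .check_matrix_nonneg(X, "X")
  .check_matrix_nonneg(W, "W")
  .check_matrix_nonneg(H, "H")
  .assert(ncol(W) == nrow(H) && nrow(W) == nrow(X) && ncol(H) == ncol(X),
          "shape mismatch between X, W and H")
  R <- X / pmax(W %*% H, eps)
  H <- H * (crossprod(W, R) / pmax(colSums(W), eps))
  R <- X / pmax(W %*% H, eps)
  W <- W * (tcrossprod(R, H) / rep(pmax(rowSums(H), eps), each = nrow(W)))
  list(W = W, H = H)
}

.init_factors <- function(X, rank, seed) {
  set.seed(seed)
  n <- nrow(X)
  m <- ncol(X)
  s <- sqrt(mean(X) / rank)
  if (s == 0) s <- 1e-6 # all-zero X: any tiny positive init works
  list(W = matrix(stats::runif(n * rank), n, rank) * s,
       H = matrix(stats::runif(rank * m), rank, m) * s)
}

.fit_single <- function(X, rank, max_iter, tol, seed, eps = 1e-12) {
  f <- .init_factors(X, rank, seed)
  W <- f$W
  H <- f$H
  trace <- numeric(max_iter + 1L)
  d_prev <- kl_divergence(X, W, H, eps)
  trace[1L] <- d_prev
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    up <- multiplicative_update(X, W, H, eps)
    W <- up$W
    H <- up$H
    d <- kl_divergence(X, W, H, eps)
    trace[it + 1L] <- d
    if ((d_prev - d) <= tol * max(d_prev, .Machine$double.eps)) {
      converged <- TRUE
      d_prev <- d
      break
    }
    d_prev <- d
  }
  list(W = W, H = H, divergence = d_prev, n_iter = it,
       converged = converged, seed = seed,
       divergence_trace = trace[seq_len(it + 1L)])
}

#' Fit a KL-NMF model with random multi-start
#'
#' Runs `n_runs` independent fits from i.i.d. uniform random initializations
#' (entries scaled by `sqrt(mean(X)/rank)`) and returns the run achieving the
#' lowest final divergence. Each run `k` uses a seed derived deterministically
#' from `seed`, so results are exactly reproducible. A run stops when the
#' relative divergence decrease falls below `tol` or after `max_iter` sweeps.
#'
#' @param X nonnegative numeric matrix (genes x samples) or an
#'   [expression_matrix()].
#' @param rank number of metagenes `r`. Values above `min(dim(X))` trigger a
#'   warning, not an error.
#' @param n_runs number of random restarts.
#' @param max_iter maximum multiplicative-update sweeps per run.
#' @param tol relative divergence-decrease stopping tolerance.
#' @param seed integer master seed.
#' @return An object of class `nmf_model`: list with `W`, `H`, `divergence`,
#'   `n_iter`, `converged`, `seed`, `divergence_trace`, `rank`, and
#'   `best_run`. Row/column names of `X` are carried onto `W` and `H`.
#' @seealso [consensus_matrix()], [survey_ranks()], [gene_scores()]
#' @export
fit_nmf <- function(X, rank, n_runs = 10L, max_iter = 2000L, tol = 1e-6,
                    seed = 1L) {
  X <- .values_of(X)
  .check_matrix_nonneg(X, "X")
  .assert(length(X) > 0, "empty matrix")
  rank <- .check_count(rank, "rank")
  n_runs <- .check_count(n_runs, "n_runs")
  max_iter <- .check_count(max_iter, "max_iter")
  tol <- .check_scalar(tol, "tol", min = 0)
  if (rank > min(dim(X))) {
    warning(sprintf("rank %d exceeds min(dim(X)) = %d; fit proceeds anyway",
                    rank, min(dim(X))))
  }
  best <- NULL
  for (k in seq_len(n_runs)) {
    run <- .fit_single(X, rank, max_iter, tol, .derive_seed(seed, k))
    if (is.null(best) || run$divergence < best$divergence) {
      best <- run
      best$best_run <- k
    }
  }
  # Deterministic output scale: H rows sum to 1 (each metagene's distribution
  # across samples) and W carries the magnitude, so W[i, k] reads as the
  # expression of gene i attributed to metagene k in intensity units. WH and
  # the divergence are unchanged; without a convention the per-factor scale
  # split between W and H is an arbitrary by-product of the run.
  rs <- rowSums(best$H)
  pos <- rs > 0
  best$H[pos, ] <- best$H[pos, , drop = FALSE] / rs[pos]
  best$W[, pos] <- sweep(best$W[, pos, drop = FALSE], 2L, rs[pos], "*")
  rownames(best$W) <- rownames(X)
  colnames(best$W) <- paste0("metagene", seq_len(rank))
  rownames(best$H) <- paste0("metagene", seq_len(rank))
  colnames(best$H) <- colnames(X)
  best$rank <- rank
  best$master_seed <- seed
  class(best) <- "nmf_model"
  best
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("KL-NMF model: %d genes x %d samples, rank %d\n",
              nrow(x$W), ncol(x$H), x$rank))
  cat(sprintf("  divergence %.6g after %d iterations (%s), best of run %d\n",
              x$divergence, x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$best_run))
  invisible(x)
}

#' Consensus matrix over NMF restarts
#'
#' For each of `n_runs` single random-start fits at the given rank, every
#' sample `j` is assigned to the metagene `k` maximizing `H[k, j]`; the
#' consensus entry `(j, j')` is the fraction of runs assigning `j` and `j'`
#' to the same metagene. The result is symmetric with unit diagonal.
#'
#' @inheritParams fit_nmf
#' @param n_runs number of restarts entering the consensus (>= 2).
#' @param max_iter,tol per-run stopping controls. Consensus runs default to
#'   many short runs (30 x 100 sweeps) rather than a few exhaustive ones:
#'   stability is measured across stochastic restarts, and fully converged
#'   fits on clean data collapse to one solution, making every rank look
#'   spuriously stable.
#' @return An `m x m` numeric matrix with entries in `[0, 1]`.
#' @export
consensus_matrix <- function(X, rank, n_runs = 30L, max_iter = 100L,
                             tol = 1e-5, seed = 1L) {
  X <- .values_of(X)
  .check_matrix_nonneg(X, "X")
  .assert(ncol(X) >= 2L, "consensus requires at least 2 samples")
  rank <- .check_count(rank, "rank")
  n_runs <- .check_count(n_runs, "n_runs", min = 2L)
  m <- ncol(X)
  C <- matrix(0, m, m)
  for (k in seq_len(n_runs)) {
    run <- .fit_single(X, rank, max_iter, tol, .derive_seed(seed, 1000L + k))
    assign <- apply(run$H, 2L, which.max)
    C <- C + outer(assign, assign, `==`)
  }
  C <- C / n_runs
  dimnames(C) <- list(colnames(X), colnames(X))
  C
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Measures how faithfully the average-linkage hierarchical clustering of the
#' consensus-based distances `1 - C` reproduces those distances: the Pearson
#' correlation between the original distances and the cophenetic (merge
#' height) distances of the dendrogram. Equals 1 for a perfect block
#' `{0, 1}` consensus. A constant distance matrix (including the 2-sample
#' case with a single pair) returns 1 by convention, since the hierarchy
#' reproduces it exactly.
#'
#' @param consensus symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @return A scalar in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(consensus) {
  .assert(is.matrix(consensus) && nrow(consensus) == ncol(consensus),
          "`consensus` must be a square matrix")
  .assert(max(abs(consensus - t(consensus))) < 1e-8,
          "`consensus` must be symmetric")
  d <- stats::as.dist(1 - consensus)
  if (length(d) < 2L || stats::sd(d) == 0) {
    return(1)
  }
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  cc <- suppressWarnings(stats::cor(as.vector(d), as.vector(cd)))
  if (is.na(cc)) 1 else cc
}

#' Survey candidate factorization ranks by consensus stability
#'
#' Computes the consensus matrix and its cophenetic coefficient for each
#' candidate rank and selects the rank empirically: the largest rank before
#' the first drop of the cophenetic coefficient below `theta` (default 0.95),
#' falling back to the argmax of the coefficient (ties to the smallest rank)
#' when no rank qualifies — i.e. when the very first candidate is already
#' unstable, or when no drop occurs at all.
#'
#' @inheritParams consensus_matrix
#' @param ranks integer vector of candidate ranks, each >= 2; surveyed in
#'   increasing order.
#' @param theta cophenetic stability threshold.
#' @return An object of class `rank_survey`: list with `ranks`, `consensus`
#'   (list of matrices), `cophenetic` (numeric vector), `selected_rank`,
#'   `theta`, `seed`.
#' @export
survey_ranks <- function(X, ranks, n_runs = 30L, max_iter = 100L, tol = 1e-5,
                         seed = 1L, theta = 0.95) {
  .assert(length(ranks) >= 1L && all(ranks == round(ranks)) && all(ranks >= 2L),
          "`ranks` must be a non-empty vector of integers >= 2")
  ranks <- sort(unique(as.integer(ranks)))
  theta <- .check_proportion(theta, "theta")
  cons <- vector("list", length(ranks))
  coph <- numeric(length(ranks))
  for (i in seq_along(ranks)) {
    cons[[i]] <- consensus_matrix(X, ranks[i], n_runs = n_runs,
                                  max_iter = max_iter, tol = tol,
                                  seed = .derive_seed(seed, 5000L + ranks[i]))
    coph[i] <- cophenetic_coefficient(cons[[i]])
  }
  drop_idx <- which(coph < theta)
  selected <- if (length(drop_idx) == 0L || drop_idx[1L] == 1L) {
    ranks[which.max(coph)]
  } else {
    ranks[drop_idx[1L] - 1L]
  }
  structure(list(ranks = ranks, consensus = cons, cophenetic = coph,
                 selected_rank = selected, theta = theta, seed = seed),
            class = "rank_survey")
}

#' @export
print.rank_survey <- function(x, ...) {
  cat("Rank survey (consensus / cophenetic):\n")
  for (i in seq_along(x$ranks)) {
    cat(sprintf("  rank %d: cophenetic %.4f%s\n", x$ranks[i], x$cophenetic[i],
                if (x$ranks[i] == x$selected_rank) "  <- selected" else ""))
  }
  invisible(x)
}
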