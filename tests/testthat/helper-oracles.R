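# Independent oracles and small fixture builders used across the suite.

# Random nonnegative matrix with a sprinkling of exact zeros.
rand_nonneg <- function(n, m, zero_frac = 0.1) {
  X <- matrix(stats::runif(n * m, 0, 5), n, m)
  X[stats::runif(n * m) < zero_frac] <- 0
  X
}

# Entropy-based gene score computed directly from the definition, one gene
# at a time (independent of the vectorized implementation).
oracle_gene_score <- function(w) {
  r <- length(w)
  s <- sum(w)
  if (s == 0) return(0)
  if (r == 1) return(1)
  p <- w / s
  acc <- 0
  for (k in seq_len(r)) {
    if (p[k] > 0) acc <- acc + p[k] * log2(p[k])
  }
  1 + acc / log2(r)
}

# Brute-force average-linkage (UPGMA) cophenetic correlation: merge heights
# computed as means of the *original* distances between cluster members,
# assembled pair by pair.
oracle_cophenetic_corr <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  CD <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- 0L
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
        if (d < best) {
          best <- d
          bi <- i
          bj <- j
        }
      }
    }
    CD[clusters[[bi]], clusters[[bj]]] <- best
    CD[clusters[[bj]], clusters[[bi]]] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  lt <- lower.tri(D)
  if (stats::sd(D[lt]) == 0 || stats::sd(CD[lt]) == 0) return(1)
  stats::cor(D[lt], CD[lt])
}

# Closed-form optimal rank-1 KL approximation: the independence model
# outer(rowSums, colSums) / sum.
oracle_rank1_kl <- function(X) {
  fit <- outer(rowSums(X), colSums(X)) / sum(X)
  pos <- X > 0
  sum(fit) - sum(X) + sum(X[pos] * log(X[pos] / fit[pos]))
}

# Small planted study used where the full default study would be wasteful.
small_study <- function(seed = 5L) {
  generate_two_condition_study(n_genes = 400L, markers_per_factor = 15L,
                               seed = seed)
}
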