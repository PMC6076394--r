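# Internal argument checking and seed derivation shared across modules.

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

.check_count <- function(x, name, min = 1L) {
  .assert(length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min,
          sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

.check_scalar <- function(x, name, min = -Inf, strict_min = FALSE) {
  .assert(length(x) == 1L && is.numeric(x) && is.finite(x),
          sprintf("`%s` must be a single finite number", name))
  if (strict_min) {
    .assert(x > min, sprintf("`%s` must be > %g", name, min))
  } else {
    .assert(x >= min, sprintf("`%s` must be >= %g", name, min))
  }
  as.numeric(x)
}

.check_proportion <- function(x, name) {
  .assert(length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1,
          sprintf("`%s` must be a proportion in [0, 1]", name))
  as.numeric(x)
}

# Numeric matrix, finite, entrywise >= 0.
.check_matrix_nonneg <- function(X, name) {
  .assert(is.matrix(X) && is.numeric(X),
          sprintf("`%s` must be a numeric matrix", name))
  .assert(all(is.finite(X)), sprintf("`%s` contains non-finite entries", name))
  if (any(X < 0)) {
    stop(sprintf("`%s` contains negative entries; all inputs must be nonnegative",
                 name), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic per-task seed derived from a user seed; kept below 2^31 - 1
# so set.seed() always accepts it.
.derive_seed <- function(seed, k) {
  seed <- .check_count(seed, "seed", min = 0L)
  k <- .check_count(k, "k", min = 0L)
  as.integer(((as.numeric(seed) %% 59999) * 31013 + 7 * as.numeric(k)) %% 2147483647)
}

# Coerce an expression_matrix or plain matrix to a values matrix.
.values_of <- function(x) {
  if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
}
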