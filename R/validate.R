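# QC statistics (volcano, PCA-vs-metagene) and the concatenated-matrix
# validation of the metagene-condition association.

#' Per-gene volcano statistics for a two-group design
#'
#' Row-wise two-sample t-test between the two condition groups: `mean_diff`
#' is group-B mean minus group-A mean (second factor level minus first),
#' `t_stat` the pooled-variance t statistic (`welch = TRUE` switches to
#' Welch), `p_value` the two-sided p. Genes with zero pooled variance get
#' `p = 1` by convention and are reported via a message.
#'
#' @param x [expression_matrix()] or numeric matrix.
#' @param labels per-sample group labels (exactly two groups, each with at
#'   least 2 samples); defaults to the condition labels of `x`.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return data.frame with `gene_id`, `mean_diff`, `t_stat`, `p_value`,
#'   `neg_log10_p`.
#' @export
volcano_stats <- function(x, labels = NULL, welch = FALSE) {
  v <- .values_of(x)
  if (is.null(labels) && inherits(x, "expression_matrix")) {
    labels <- x$condition
  }
  .assert(!is.null(labels) && length(labels) == ncol(v),
          "`labels` must have one entry per sample")
  f <- factor(labels)
  .assert(nlevels(f) == 2L, "exactly two groups are required")
  na <- sum(f == levels(f)[1L])
  nb <- sum(f == levels(f)[2L])
  .assert(na >= 2L && nb >= 2L, "each group needs at least 2 samples")
  A <- v[, f == levels(f)[1L], drop = FALSE]
  B <- v[, f == levels(f)[2L], drop = FALSE]
  ma <- rowMeans(A)
  mb <- rowMeans(B)
  va <- apply(A, 1L, stats::var)
  vb <- apply(B, 1L, stats::var)
  diff <- mb - ma
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  }
  zero_var <- se == 0 | !is.finite(se)
  t_stat <- ifelse(zero_var, 0, diff / se)
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(t_stat), df))
  if (any(zero_var)) {
    message(sprintf("%d gene(s) with zero within-group variance: p set to 1",
                    sum(zero_var)))
  }
  ids <- rownames(v)
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_len(nrow(v)))
  data.frame(gene_id = ids, mean_diff = diff, t_stat = t_stat, p_value = p,
             neg_log10_p = -log10(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' First principal component of an expression matrix
#'
#' Centers each gene row across samples, takes the first left singular
#' vector as the gene loading (sign fixed so the largest-magnitude entry is
#' positive) and reports the fraction of total variance it captures. Used to
#' contrast the dense PC1 loading with the sparse metagene loading.
#'
#' @param x [expression_matrix()] or numeric matrix (genes x samples,
#'   `>= 2` samples).
#' @param center center gene rows before the SVD (default; overridable).
#' @return List with `loading` (numeric vector over genes) and
#'   `variance_fraction`.
#' @export
pca_first_component <- function(x, center = TRUE) {
  v <- .values_of(x)
  .assert(ncol(v) >= 2L, "PCA requires at least 2 samples")
  vc <- if (center) v - rowMeans(v) else v
  if (all(vc == 0)) {
    stop("matrix is constant per gene after centering; PC1 undefined",
         call. = FALSE)
  }
  sv <- svd(vc)
  loading <- sv$u[, 1L]
  i <- which.max(abs(loading))
  if (loading[i] < 0) loading <- -loading
  names(loading) <- rownames(v)
  list(loading = loading,
       variance_fraction = sv$d[1L]^2 / sum(sv$d^2))
}

#' Rank bound for a column-concatenated matrix
#'
#' `TRUE` iff `r_concat < r_a + r_b`, the subadditivity bound
#' `rank([A1, A2]) <= rank(A1) + rank(A2)` justifying a concatenated-fit
#' rank below the sum of the per-condition ranks.
#'
#' @param r_concat,r_a,r_b positive integers.
#' @return Logical flag.
#' @export
rank_bound_check <- function(r_concat, r_a, r_b) {
  r_concat <- .check_count(r_concat, "r_concat")
  r_a <- .check_count(r_a, "r_a")
  r_b <- .check_count(r_b, "r_b")
  r_concat < r_a + r_b
}

#' Column-normalized weights of one metagene across samples
#'
#' Normalizes each coefficient column to unit sum and returns row `k`:
#' `weight(j) = H[k, j] / sum_i H[i, j]`, the relative influence of
#' metagene `k` on sample `j`. Weights over all metagenes sum to 1 per
#' sample.
#'
#' @param H nonnegative coefficient matrix (metagenes x samples) with no
#'   all-zero column.
#' @param k metagene index.
#' @return Numeric vector of weights in `[0, 1]`, named by sample.
#' @export
metagene_sample_weights <- function(H, k) {
  .check_matrix_nonneg(H, "H")
  k <- .check_count(k, "k")
  .assert(k <= nrow(H), "`k` exceeds the number of metagenes")
  cs <- colSums(H)
  if (any(cs == 0)) {
    bad <- which(cs == 0)[1L]
    nm <- colnames(H)[bad]
    stop(sprintf("all-zero coefficient column for sample %s: weight undefined",
                 if (is.null(nm)) bad else nm), call. = FALSE)
  }
  w <- H[k, ] / cs
  names(w) <- colnames(H)
  w
}

#' Condition-wise summary of the selected metagene's weights
#'
#' Quantifies whether the selected metagene loads preferentially on one
#' condition: per-condition mean weight, the count of samples per condition
#' whose top-weight metagene is the selected one, and a two-sided Wilcoxon
#' rank-sum test of the weights between conditions (exact null distribution
#' for small samples without ties).
#'
#' @param weights per-sample weights of the selected metagene (from
#'   [metagene_sample_weights()]).
#' @param labels per-sample condition labels (exactly two groups).
#' @param top_selected optional logical vector: is the selected metagene the
#'   sample's top-weight metagene? Computed upstream from the full `H`.
#' @return An object of class `weight_summary`: list with `mean_weight`
#'   (named by condition), `top_counts`, `rank_sum_stat`, `p_value`,
#'   `higher_in` (condition with the larger mean weight).
#' @export
group_weight_summary <- function(weights, labels, top_selected = NULL) {
  .assert(length(weights) == length(labels),
          "`weights` and `labels` must align")
  f <- factor(labels)
  .assert(nlevels(f) == 2L, "exactly two conditions are required")
  wa <- weights[f == levels(f)[1L]]
  wb <- weights[f == levels(f)[2L]]
  mean_weight <- c(mean(wa), mean(wb))
  names(mean_weight) <- levels(f)
  wt <- suppressWarnings(stats::wilcox.test(wb, wa, exact = TRUE,
                                            correct = FALSE))
  # fully tied weights leave the normal-approximation statistic undefined
  if (is.na(wt$p.value)) wt$p.value <- 1
  top_counts <- if (is.null(top_selected)) {
    NULL
  } else {
    tc <- vapply(levels(f), function(l) sum(top_selected[f == l]), integer(1))
    tc
  }
  structure(list(mean_weight = mean_weight,
                 top_counts = top_counts,
                 rank_sum_stat = unname(wt$statistic),
                 p_value = wt$p.value,
                 higher_in = names(which.max(mean_weight))),
            class = "weight_summary")
}

#' @export
print.weight_summary <- function(x, ...) {
  cat("selected-metagene weight summary\n")
  cat(sprintf("  mean weight: %s\n",
              paste(sprintf("%s %.4f", names(x$mean_weight), x$mean_weight),
                    collapse = ", ")))
  if (!is.null(x$top_counts)) {
    cat(sprintf("  samples with this metagene on top: %s\n",
                paste(sprintf("%s %d", names(x$top_counts), x$top_counts),
                      collapse = ", ")))
  }
  cat(sprintf("  rank-sum W = %g, two-sided p = %.4g (higher in %s)\n",
              x$rank_sum_stat, x$p_value, x$higher_in))
  invisible(x)
}

#' Containment of a reference gene set in an extracted set
#'
#' `|common_set intersect extracted| / |common_set|`; the fraction of
#' previously extracted common genes recovered by the concatenated-matrix
#' extraction.
#'
#' @param extracted gene ids extracted from the concatenated matrix.
#' @param common_set non-empty reference gene-id set.
#' @return Proportion in `[0, 1]`.
#' @export
containment <- function(extracted, common_set) {
  common_set <- unique(as.character(common_set))
  .assert(length(common_set) > 0, "`common_set` must be non-empty")
  length(intersect(unique(as.character(extracted)), common_set)) /
    length(common_set)
}
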