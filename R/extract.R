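#' Entropy-based gene scores on the basis matrix
#'
#' For each gene (row) of `W`, with `p(i,k) = W[i,k] / sum_k W[i,k]`, the
#' score is `1 + (1/log2(r)) * sum_k p(i,k) * log2 p(i,k)` (with
#' `0 * log 0 = 0`): 1 for a row loading on a single metagene (one-hot),
#' 0 for a uniform row. Scores are invariant to row scaling. All-zero rows
#' score 0 by convention (their loading profile is undefined); for `r = 1`
#' nonzero rows score 1 by convention.
#'
#' @param W nonnegative basis matrix (genes x metagenes).
#' @return Numeric vector of scores in `[0, 1]`, named by `rownames(W)`.
#' @export
gene_scores <- function(W) {
  .check_matrix_nonneg(W, "W")
  r <- ncol(W)
  rs <- rowSums(W)
  if (r == 1L) {
    s <- as.numeric(rs > 0)
    names(s) <- rownames(W)
    return(s)
  }
  P <- W / ifelse(rs > 0, rs, 1)
  plogp <- P * log2(P)
  plogp[P == 0] <- 0
  s <- 1 + rowSums(plogp) / log2(r)
  s[rs == 0] <- 0
  s <- pmin(pmax(s, 0), 1) # clamp roundoff at the endpoints
  names(s) <- rownames(W)
  s
}

#' Robust selection threshold: median + 3 * MAD of the scores
#'
#' The MAD is unscaled — `median(|score - median(score)|)` with no
#' normal-consistency factor.
#'
#' @param scores numeric vector of gene scores.
#' @return A single numeric threshold.
#' @export
selection_threshold <- function(scores) {
  .assert(length(scores) > 0 && is.numeric(scores),
          "`scores` must be a non-empty numeric vector")
  med <- stats::median(scores)
  med + 3 * stats::median(abs(scores - med))
}

#' Apply the two-gate gene selection rule to a basis matrix
#'
#' A gene is selected iff (i) its score is strictly greater than
#' `median + 3 * MAD` of all scores, and (ii) the maximum of its row of `W`
#' is strictly greater than the median of all entries of `W`. Both gate
#' values are reported for audit. Each gene is assigned to its
#' argmax metagene (ties to the lowest index).
#'
#' @param W nonnegative basis matrix.
#' @param scores optional precomputed [gene_scores()]; recomputed when
#'   missing. Must align with the rows of `W`.
#' @return An object of classes `gene_score_table` and `data.frame` with
#'   columns `gene_id`, `score`, `row_max`, `metagene`, `selected`, and
#'   attributes `threshold` and `w_median`.
#' @export
select_genes <- function(W, scores = NULL) {
  .check_matrix_nonneg(W, "W")
  if (is.null(scores)) scores <- gene_scores(W)
  .assert(length(scores) == nrow(W), "`scores` must align with the rows of W")
  thr <- selection_threshold(scores)
  w_med <- stats::median(W)
  row_max <- apply(W, 1L, max)
  metagene <- max.col(W, ties.method = "first")
  ids <- rownames(W)
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_len(nrow(W)))
  selected <- scores > thr & row_max > w_med
  out <- data.frame(gene_id = ids, score = as.numeric(scores),
                    row_max = row_max, metagene = metagene,
                    selected = selected, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "threshold") <- thr
  attr(out, "w_median") <- w_med
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Group selected genes by metagene and pick the most informative one
#'
#' Each selected gene belongs to its argmax metagene; the most informative
#' metagene is the one possessing the largest number of selected genes (ties
#' to the lowest index). Its gene list is the extracted set. Gene lists are
#' ordered by descending score, ties broken lexicographically by id.
#'
#' @param table a [select_genes()] result.
#' @param rank number of metagenes; defaults to the largest index present.
#' @return An object of class `metagene_sets`: list with `per_metagene`
#'   (list of gene-id vectors), `counts`, `most_informative`,
#'   `extracted_set`.
#' @export
assign_and_pick <- function(table, rank = NULL) {
  .assert(inherits(table, "gene_score_table"),
          "`table` must come from select_genes()")
  if (is.null(rank)) rank <- max(table$metagene, 1L)
  rank <- .check_count(rank, "rank")
  sel <- table[table$selected, , drop = FALSE]
  ord <- order(-sel$score, sel$gene_id)
  sel <- sel[ord, , drop = FALSE]
  per <- lapply(seq_len(rank),
                function(k) sel$gene_id[sel$metagene == k])
  names(per) <- paste0("metagene", seq_len(rank))
  counts <- vapply(per, length, integer(1))
  most <- which.max(counts) # ties -> lowest index
  structure(list(per_metagene = per, counts = counts,
                 most_informative = as.integer(most),
                 extracted_set = per[[most]]),
            class = "metagene_sets")
}

#' @export
print.metagene_sets <- function(x, ...) {
  cat(sprintf("metagene_sets: %d metagenes, %d selected genes\n",
              length(x$per_metagene), sum(x$counts)))
  cat(sprintf("  most informative: metagene %d (%d genes)\n",
              x$most_informative, length(x$extracted_set)))
  invisible(x)
}

#' Score, select and extract genes from a fitted NMF model
#'
#' Convenience wrapper running [gene_scores()], [select_genes()] and
#' [assign_and_pick()] on the raw fitted basis matrix. The score gate is
#' invariant to row normalization but the magnitude gate is not;
#' `row_normalize = TRUE` applies the gates to the row-normalized basis
#' instead.
#'
#' @param model an `nmf_model` from [fit_nmf()].
#' @param row_normalize apply the gates to `W` with rows scaled to unit sum.
#' @return A list with `score_table` and `sets`.
#' @export
extract_genes <- function(model, row_normalize = FALSE) {
  .assert(inherits(model, "nmf_model"), "`model` must be an nmf_model")
  W <- model$W
  if (row_normalize) {
    rs <- rowSums(W)
    W <- W / ifelse(rs > 0, rs, 1)
  }
  tab <- select_genes(W)
  list(score_table = tab, sets = assign_and_pick(tab, rank = ncol(W)))
}
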