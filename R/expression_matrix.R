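#' Nonnegative expression matrix with sample metadata
#'
#' Lightweight container for a genes x samples intensity matrix with unique
#' gene and sample identifiers, per-sample condition labels, and a scale tag.
#' All pipeline stages operate on linear-scale nonnegative values; log2 is a
#' display transform only (see [log2_display_transform()]).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids unique identifier vectors; default to the
#'   dimnames of `values`.
#' @param condition optional per-sample condition label (length `ncol`).
#' @param scale `"linear"` (default) or `"log2-display-only"`.
#' @return An object of class `expression_matrix`: list with `values`
#'   (dimnames set from the ids), `condition`, `scale`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              condition = NULL, scale = "linear") {
  values <- as.matrix(values)
  .assert(is.numeric(values), "`values` must be numeric")
  .assert(all(is.finite(values)), "`values` contains non-finite entries")
  .check_matrix_nonneg(values, "values")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%02d", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  .assert(length(gene_ids) == nrow(values), "gene_ids length != nrow(values)")
  .assert(length(sample_ids) == ncol(values), "sample_ids length != ncol(values)")
  .assert(!anyDuplicated(gene_ids), "duplicate gene ids")
  .assert(!anyDuplicated(sample_ids), "duplicate sample ids")
  if (is.null(condition)) condition <- rep(NA_character_, ncol(values))
  condition <- as.character(condition)
  .assert(length(condition) == ncol(values),
          "condition labels must have one entry per sample")
  .assert(scale %in% c("linear", "log2-display-only"), "unknown scale tag")
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  structure(list(values = values, condition = condition, scale = scale),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!all(is.na(x$condition))) {
    tab <- table(x$condition, useNA = "no")
    cat("  conditions:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(.values_of(x))

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(.values_of(x))

#' Concatenate two conditions column-wise
#'
#' Binds the samples of two expression matrices over an identical, identically
#' ordered gene universe; condition labels are carried through. This is the
#' input of the concatenated-matrix validation stage.
#'
#' @param x_a,x_b `expression_matrix` objects with identical gene-id order.
#' @return An `expression_matrix` with the columns of `x_a` then `x_b`.
#' @export
concatenate_conditions <- function(x_a, x_b) {
  .assert(inherits(x_a, "expression_matrix") && inherits(x_b, "expression_matrix"),
          "inputs must be expression_matrix objects")
  ga <- gene_ids(x_a)
  gb <- gene_ids(x_b)
  if (!identical(ga, gb)) {
    if (length(ga) != length(gb)) {
      stop(sprintf("gene universes differ in size (%d vs %d genes)",
                   length(ga), length(gb)), call. = FALSE)
    }
    bad <- which(ga != gb)[1L]
    stop(sprintf(
      "gene ids differ between the two matrices (first discrepancy at row %d: '%s' vs '%s')",
      bad, ga[bad], gb[bad]), call. = FALSE)
  }
  expression_matrix(cbind(x_a$values, x_b$values),
                    condition = c(x_a$condition, x_b$condition),
                    scale = x_a$scale)
}

#' Log2 transform for display and export
#'
#' Returns `log2(value + pseudocount)`. Intended for heatmap-style exports
#' only: the NMF stages always consume linear-scale nonnegative intensities.
#'
#' @param x `expression_matrix` or numeric matrix on linear scale.
#' @param pseudocount positive offset avoiding `log2(0)`.
#' @return A numeric matrix of the same shape.
#' @export
log2_display_transform <- function(x, pseudocount = 1) {
  pseudocount <- .check_scalar(pseudocount, "pseudocount", min = 0,
                               strict_min = TRUE)
  if (inherits(x, "expression_matrix")) {
    .assert(x$scale == "linear", "input must be linear-scale")
  }
  v <- .values_of(x)
  .check_matrix_nonneg(v, "x")
  log2(v + pseudocount)
}
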