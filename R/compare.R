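# Post-processing of the two extracted gene sets: common/uncommon split,
# symbol mapping with annotation-category filtering, deduplication, and
# per-condition expression medians.

#' Common and uncommon genes between two extracted sets
#'
#' Exact set algebra over a shared gene universe, with deterministic
#' (lexicographic) output ordering.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return List with `common`, `only_a`, `only_b`, each sorted.
#' @export
compare_gene_sets <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  list(common = sort(intersect(set_a, set_b)),
       only_a = sort(setdiff(set_a, set_b)),
       only_b = sort(setdiff(set_b, set_a)))
}

#' Map a gene set to symbols and count annotation categories
#'
#' Looks each gene up in the annotation, tallies the full five-category
#' histogram (`symbol`, `cdna`, `hypothetical`, `non_human`, `obsolete`),
#' and returns the deduplicated symbol list of the symbol-bearing genes.
#' Genes missing from the annotation are treated as `obsolete` and reported
#' via a message. Deduplication keeps the first occurrence in the order the
#' genes are supplied (callers pass score-descending order; ids arriving
#' unordered are processed as given).
#'
#' @param gene_set character vector of gene/probe ids.
#' @param annotation data.frame with `probe_id`, `symbol`, `category`
#'   (see [generate_annotation()] / [read_annotation()]).
#' @return List with `symbols` (deduplicated character vector) and `counts`
#'   (named integer vector over the five categories, summing to
#'   `length(unique(gene_set))`).
#' @export
annotate_and_filter <- function(gene_set, annotation) {
  gene_set <- unique(as.character(gene_set))
  .assert(is.data.frame(annotation) &&
            all(c("probe_id", "symbol", "category") %in% colnames(annotation)),
          "`annotation` must have columns probe_id, symbol, category")
  idx <- match(gene_set, annotation$probe_id)
  missing <- is.na(idx)
  if (any(missing)) {
    message(sprintf("%d gene(s) missing from the annotation, treated as obsolete: %s",
                    sum(missing),
                    paste(utils::head(gene_set[missing], 5L), collapse = ", ")))
  }
  category <- as.character(ifelse(missing, "obsolete",
                                  annotation$category[idx]))
  symbol <- as.character(ifelse(missing, NA_character_,
                                annotation$symbol[idx]))
  counts <- vapply(.annotation_categories,
                   function(cc) sum(category == cc), integer(1))
  symbols <- symbol[category == "symbol" & !is.na(symbol)]
  list(symbols = symbols[!duplicated(symbols)], counts = counts)
}

#' Per-condition expression medians for a gene list
#'
#' Sample medians within each condition; even sample counts use the midpoint
#' of the two central order statistics (the standard median).
#'
#' @param x_a,x_b [expression_matrix()] objects (or matrices with gene-id
#'   rownames) for the two conditions.
#' @param genes gene ids; each must be present in both matrices.
#' @return data.frame with `gene_id`, `median_a`, `median_b`.
#' @export
condition_medians <- function(x_a, x_b, genes) {
  va <- .values_of(x_a)
  vb <- .values_of(x_b)
  genes <- as.character(genes)
  for (nm in c("a", "b")) {
    v <- if (nm == "a") va else vb
    miss <- setdiff(genes, rownames(v))
    if (length(miss) > 0) {
      stop(sprintf("gene id '%s' not found in condition %s matrix",
                   miss[1L], toupper(nm)), call. = FALSE)
    }
  }
  data.frame(gene_id = genes,
             median_a = apply(va[genes, , drop = FALSE], 1L, stats::median),
             median_b = apply(vb[genes, , drop = FALSE], 1L, stats::median),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full comparison report between the two extracted gene sets
#'
#' Runs [compare_gene_sets()], annotates each of the three sets with
#' [annotate_and_filter()], and attaches per-condition medians — the tabular
#' output of the post-processing workflow. When score tables are supplied,
#' set members are ordered by descending score (ties lexicographic) before
#' symbol deduplication, so the kept duplicate is the highest-scoring one.
#'
#' @param set_a,set_b extracted gene-id sets of conditions A and B.
#' @param annotation probe annotation data.frame.
#' @param x_a,x_b per-condition [expression_matrix()] objects.
#' @param scores_a,scores_b optional named score vectors (or
#'   `gene_score_table`s) used for ordering.
#' @return An object of class `comparison_report`: list with `common`,
#'   `only_a`, `only_b`, `counts` (per-set category histograms), `symbols`
#'   (per-set deduplicated lists), `medians` (data.frame over the union),
#'   `provenance`.
#' @export
compare_conditions <- function(set_a, set_b, annotation, x_a, x_b,
                               scores_a = NULL, scores_b = NULL) {
  sets <- compare_gene_sets(set_a, set_b)
  score_of <- function(scores) {
    if (inherits(scores, "gene_score_table")) {
      stats::setNames(scores$score, scores$gene_id)
    } else {
      scores
    }
  }
  sa <- score_of(scores_a)
  sb <- score_of(scores_b)
  order_set <- function(ids, scores) {
    if (is.null(scores)) return(ids) # already lexicographic
    s <- scores[ids]
    s[is.na(s)] <- -Inf
    ids[order(-s, ids)]
  }
  ordered <- list(common = order_set(sets$common, if (is.null(sb)) sa else sb),
                  only_a = order_set(sets$only_a, sa),
                  only_b = order_set(sets$only_b, sb))
  ann <- lapply(ordered, annotate_and_filter, annotation = annotation)
  union_genes <- sort(unique(c(sets$common, sets$only_a, sets$only_b)))
  med <- if (length(union_genes) > 0) {
    condition_medians(x_a, x_b, union_genes)
  } else {
    data.frame(gene_id = character(0), median_a = numeric(0),
               median_b = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(common = sets$common, only_a = sets$only_a,
                 only_b = sets$only_b,
                 counts = lapply(ann, `[[`, "counts"),
                 symbols = lapply(ann, `[[`, "symbols"),
                 medians = med,
                 provenance = list(schema = "comparison_report/1",
                                   size_a = length(unique(set_a)),
                                   size_b = length(unique(set_b)))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: |A| = %d, |B| = %d\n",
              x$provenance$size_a, x$provenance$size_b))
  cat(sprintf("  common %d, only A %d, only B %d\n",
              length(x$common), length(x$only_a), length(x$only_b)))
  for (nm in names(x$counts)) {
    cc <- x$counts[[nm]]
    cat(sprintf("  %s: %s; %d symbols after dedup\n", nm,
                paste(sprintf("%s %d", names(cc), cc), collapse = ", "),
                length(x$symbols[[nm]])))
  }
  invisible(x)
}
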