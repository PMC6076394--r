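# Schema-versioned report serialization. JSON is lossless and round-trips
# via read_report(); CSV is the flat tabular export (one row per gene).

.report_schema <- function(x) {
  if (inherits(x, "gene_score_table")) return("gene_score_table/1")
  if (inherits(x, "rank_survey")) return("rank_survey/1")
  if (inherits(x, "comparison_report")) return("comparison_report/1")
  stop("unsupported report object", call. = FALSE)
}

#' Write a pipeline report to CSV or JSON
#'
#' Supports [select_genes()] tables, [survey_ranks()] results and
#' [compare_conditions()] reports. JSON serializations are schema-versioned
#' and lossless (see [read_report()]); CSV is a flat per-gene (or per-rank)
#' table. Gene rows are ordered by descending score, ties broken
#' lexicographically by id.
#'
#' @param x report object.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  schema <- .report_schema(x)
  if (format == "json") {
    payload <- if (inherits(x, "gene_score_table")) {
      ord <- order(-x$score, x$gene_id)
      list(schema = schema, threshold = attr(x, "threshold"),
           w_median = attr(x, "w_median"),
           genes = x[ord, , drop = FALSE])
    } else if (inherits(x, "rank_survey")) {
      list(schema = schema, ranks = x$ranks, cophenetic = x$cophenetic,
           selected_rank = x$selected_rank, theta = x$theta, seed = x$seed,
           consensus = lapply(x$consensus, function(m) unname(as.matrix(m))))
    } else {
      list(schema = schema, common = x$common, only_a = x$only_a,
           only_b = x$only_b, counts = x$counts, symbols = x$symbols,
           medians = x$medians, provenance = x$provenance)
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(path))
  }
  if (inherits(x, "gene_score_table")) {
    ord <- order(-x$score, x$gene_id)
    utils::write.csv(x[ord, , drop = FALSE], path, row.names = FALSE)
  } else if (inherits(x, "rank_survey")) {
    utils::write.csv(data.frame(rank = x$ranks, cophenetic = x$cophenetic,
                                selected = x$ranks == x$selected_rank),
                     path, row.names = FALSE)
  } else {
    rows <- do.call(rbind, lapply(c("common", "only_a", "only_b"),
                                  function(nm) {
      ids <- x[[nm]]
      if (length(ids) == 0L) return(NULL)
      data.frame(gene_id = ids, set = nm, stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) {
      rows <- data.frame(gene_id = character(0), set = character(0),
                         stringsAsFactors = FALSE)
    }
    rows <- merge(rows, x$medians, by = "gene_id", all.x = TRUE, sort = TRUE)
    utils::write.csv(rows[order(rows$set, rows$gene_id), , drop = FALSE],
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' Dispatches on the embedded schema tag and reconstructs the original
#' object (class, attributes and field types included).
#'
#' @param path JSON file path.
#' @return The reconstructed report object.
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  .assert(!is.null(p$schema), "not a schema-versioned report")
  chr <- function(v) if (length(v) == 0L) character(0) else as.character(v)
  if (p$schema == "gene_score_table/1") {
    out <- as.data.frame(p$genes, stringsAsFactors = FALSE)
    attr(out, "threshold") <- p$threshold
    attr(out, "w_median") <- p$w_median
    class(out) <- c("gene_score_table", "data.frame")
    return(out)
  }
  if (p$schema == "rank_survey/1") {
    cons <- p$consensus
    if (is.array(cons) && length(dim(cons)) == 3L) {
      # jsonlite collapses a list of same-shaped matrices into a 3-d array
      cons <- lapply(seq_len(dim(cons)[1L]), function(i) cons[i, , ])
    }
    return(structure(list(ranks = as.integer(p$ranks),
                          consensus = lapply(cons, as.matrix),
                          cophenetic = as.numeric(p$cophenetic),
                          selected_rank = as.integer(p$selected_rank),
                          theta = p$theta, seed = p$seed),
                     class = "rank_survey"))
  }
  if (p$schema == "comparison_report/1") {
    med <- as.data.frame(p$medians, stringsAsFactors = FALSE)
    if (nrow(med) == 0L) {
      med <- data.frame(gene_id = character(0), median_a = numeric(0),
                        median_b = numeric(0), stringsAsFactors = FALSE)
    } else {
      med$gene_id <- as.character(med$gene_id)
    }
    counts <- lapply(p$counts, function(cc) {
      v <- as.integer(unlist(cc))
      names(v) <- .annotation_categories
      v
    })
    return(structure(list(common = chr(p$common), only_a = chr(p$only_a),
                          only_b = chr(p$only_b), counts = counts,
                          symbols = lapply(p$symbols, chr),
                          medians = med,
                          provenance = p$provenance),
                     class = "comparison_report"))
  }
  stop(sprintf("unknown report schema '%s'", p$schema), call. = FALSE)
}
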