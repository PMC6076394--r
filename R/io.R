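# Text readers/writers for matrices, annotation tables and fitted models.
# Everything round-trips through plain TSV/CSV/JSON so runs are portable
# and diffable.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (tab- or comma-delimited, auto-detected). Negative intensities — possible
#' after background subtraction upstream — are clamped to zero by default
#' with a message reporting how many cells were affected; with
#' `clamp_negatives = FALSE` they are an error, since NMF requires
#' nonnegative input.
#'
#' @param path file path.
#' @param clamp_negatives clamp negative cells to 0 (default) instead of
#'   erroring.
#' @param condition optional per-sample condition labels.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, clamp_negatives = TRUE, condition = NULL) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  .assert(ncol(df) >= 2L, "expected a gene-id column plus at least one sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene id '%s' in %s",
                 ids[duplicated(ids)][1L], path), call. = FALSE)
  }
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      parsed <- suppressWarnings(as.numeric(body[[j]]))
      bad <- which(is.na(parsed) & !is.na(body[[j]]) &
                     toupper(trimws(body[[j]])) != "NA")[1L]
      if (!is.na(bad)) {
        stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                     body[[j]][bad], bad, colnames(body)[j]), call. = FALSE)
      }
      body[[j]] <- parsed
    }
  }
  M <- as.matrix(body)
  .assert(all(is.finite(M)), "matrix contains missing or non-finite cells")
  n_neg <- sum(M < 0)
  if (n_neg > 0) {
    if (!clamp_negatives) {
      stop(sprintf("%d negative entries found and clamping is disabled", n_neg),
           call. = FALSE)
    }
    M[M < 0] <- 0
    message(sprintf("clamped %d negative cell(s) to 0", n_neg))
  }
  expression_matrix(M, gene_ids = ids, sample_ids = colnames(body),
                    condition = condition)
}

#' Write an expression matrix as tab-separated text
#'
#' First column `gene_id`, then one column per sample. Inverse of
#' [read_expression()].
#'
#' @param x an [expression_matrix()] or numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  v <- .values_of(x)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a probe annotation table
#'
#' Tab-separated with columns `probe_id`, `symbol`, `category`; `symbol` is
#' empty for probes without a gene-symbol identification. Categories are
#' `symbol`, `cdna`, `hypothetical`, `non_human`, `obsolete`.
#'
#' @param path file path.
#' @return A data.frame with the three columns (symbol `NA` where absent).
#' @export
read_annotation <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "\"",
                          na.strings = c("NA", ""), comment.char = "")
  .assert(all(c("probe_id", "symbol", "category") %in% colnames(df)),
          "annotation must have columns probe_id, symbol, category")
  .assert(!anyDuplicated(df$probe_id), "duplicate probe ids in annotation")
  .assert(all(df$category %in% .annotation_categories),
          "unknown annotation category")
  df[, c("probe_id", "symbol", "category")]
}

#' @rdname read_annotation
#' @param annotation data.frame as produced by [generate_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a fitted NMF model to text files
#'
#' Writes `<prefix>_W.tsv`, `<prefix>_H.tsv` and `<prefix>_meta.json`
#' (divergence, iterations, seeds, trace). [read_nmf_model()] restores the
#' model.
#'
#' @param model an `nmf_model` from [fit_nmf()].
#' @param prefix path prefix for the three files.
#' @return `prefix`, invisibly.
#' @export
write_nmf_model <- function(model, prefix) {
  .assert(inherits(model, "nmf_model"), "`model` must be an nmf_model")
  write_expression(model$W, paste0(prefix, "_W.tsv"))
  hdf <- data.frame(metagene = rownames(model$H), model$H,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(hdf, paste0(prefix, "_H.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(schema = "nmf_model/1", rank = model$rank,
               divergence = model$divergence, n_iter = model$n_iter,
               converged = model$converged, seed = model$seed,
               master_seed = model$master_seed, best_run = model$best_run,
               divergence_trace = model$divergence_trace)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_nmf_model
#' @export
read_nmf_model <- function(prefix) {
  Wdf <- utils::read.table(paste0(prefix, "_W.tsv"), header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  W <- as.matrix(Wdf[, -1L, drop = FALSE])
  rownames(W) <- Wdf[[1L]]
  Hdf <- utils::read.table(paste0(prefix, "_H.tsv"), header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  H <- as.matrix(Hdf[, -1L, drop = FALSE])
  rownames(H) <- Hdf[[1L]]
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  structure(list(W = W, H = H, divergence = meta$divergence,
                 n_iter = meta$n_iter, converged = meta$converged,
                 seed = meta$seed, master_seed = meta$master_seed,
                 best_run = meta$best_run,
                 divergence_trace = meta$divergence_trace,
                 rank = meta$rank),
            class = "nmf_model")
}

#' Read a GEO series-matrix file (convenience)
#'
#' Minimal parser for the plain-text `*_series_matrix.txt` format: extracts
#' the block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` as an expression matrix. Provided for
#' integrating public two-condition series; no pipeline stage depends on it.
#'
#' @inheritParams read_expression
#' @export
read_geo_series_matrix <- function(path, clamp_negatives = TRUE,
                                   condition = NULL) {
  lines <- readLines(path)
  from <- grep("^!series_matrix_table_begin", lines)
  to <- grep("^!series_matrix_table_end", lines)
  .assert(length(from) == 1L && length(to) == 1L && to > from + 1L,
          "no series-matrix table block found")
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(gsub('"', "", lines[(from + 1L):(to - 1L)], fixed = TRUE), tmp)
  read_expression(tmp, clamp_negatives = clamp_negatives,
                  condition = condition)
}
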