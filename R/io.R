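# Readers and writers for the package's plain-text interchange formats.

# Internal: open a (possibly gzipped) text connection for reading.
open_text <- function(path) {
  if (!file.exists(path))
    stop("IO_NO_FILE: file not found: ", path, call. = FALSE)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# Internal: field separator from extension (.csv -> comma, else tab).
sep_for <- function(path) {
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' tab-separated by default, comma-separated for `.csv`, transparently
#' gunzipped for `.gz`. All expression cells must parse as finite numbers.
#' If `log2_transform` is `TRUE` the values are taken as raw intensities and
#' `log2(x + pseudocount)` is applied.
#'
#' @param path file path (TSV/CSV, optionally .gz).
#' @param log2_transform apply `log2(x + pseudocount)` after loading.
#' @param pseudocount added before the log transform (default 1).
#' @return numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path, log2_transform = FALSE, pseudocount = 1) {
  con <- open_text(path)
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, header = TRUE, sep = sep_for(path),
                      row.names = NULL, check.names = FALSE,
                      colClasses = "character", quote = "\"",
                      comment.char = ""),
    error = function(e)
      stop("IO_PARSE: cannot parse ", path, ": ", conditionMessage(e),
           call. = FALSE))
  if (ncol(df) < 2L)
    stop("IO_PARSE: ", path, " has no sample columns", call. = FALSE)
  gene_ids <- df[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("IO_DUP_GENE: duplicate gene id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  X <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(X) | !is.finite(X), arr.ind = TRUE)
  if (nrow(bad))
    stop("IO_BAD_CELL: non-numeric or missing value at line ",
         bad[1L, 1L] + 1L, ", column '", colnames(vals)[bad[1L, 2L]], "'",
         call. = FALSE)
  dimnames(X) <- list(gene_ids, colnames(vals))
  if (log2_transform) X <- log2(X + pseudocount)
  validate_expression(X)
  X
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: header of sample ids, first column
#' `gene_id`. Appending `.gz` to the path gzips the output.
#'
#' @param X expression matrix.
#' @param path output path.
#' @export
write_expression <- function(X, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  # %.17g guarantees doubles survive the text round trip bit-exactly
  vals <- matrix(formatC(X, digits = 17, format = "g"), nrow(X), ncol(X))
  df <- data.frame(gene_id = rownames(X), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(X))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read two-group sample labels
#'
#' Two-column headerless or headered TSV: sample id, group (1 or 2). A
#' header line is detected by a non-numeric second field on line 1.
#'
#' @param path file path.
#' @return named integer vector of group codes.
#' @export
read_labels <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = FALSE, sep = sep_for(path),
                          colClasses = "character", quote = "\"")
  if (ncol(df) != 2L)
    stop("IO_LABELS: expected 2 columns (sample_id, group) in ", path,
         call. = FALSE)
  if (is.na(suppressWarnings(as.integer(df[1L, 2L]))))
    df <- df[-1L, , drop = FALSE]   # header line
  g <- suppressWarnings(as.integer(df[[2L]]))
  if (anyNA(g) || !all(g %in% c(1L, 2L)))
    stop("LABELS_BAD_GROUP: groups must be coded 1 or 2", call. = FALSE)
  stats::setNames(g, df[[1L]])
}

#' Write group labels as TSV
#' @param labels named integer vector of group codes.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), group = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the top of a reranked gene list as TSV
#'
#' Columns: `rank` (1 = largest |tau|), `gene_id`, `tau`, `raw_t`, and
#' `raw_rank` (the gene's rank among all G genes by decreasing |raw t|).
#'
#' @param result a `corrank_rerank` from [decorrelate()] or `rerank()$result`.
#' @param G_star number of genes to report.
#' @param path output path.
#' @export
write_ranking <- function(result, G_star, path) {
  stopifnot(inherits(result, "corrank_rerank"))
  if (G_star > length(result$ranking))
    stop("IO_GSTAR: G_star = ", G_star, " exceeds candidate list size ",
         length(result$ranking), call. = FALSE)
  top <- result$ranking[seq_len(G_star)]
  df <- data.frame(rank = seq_len(G_star), gene_id = top,
                   tau = unname(result$tau[top]),
                   raw_t = unname(result$raw_t[top]),
                   raw_rank = unname(result$raw_rank[top]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a benchmark trial to disk
#'
#' Writes `<prefix>_X.tsv`, `<prefix>_labels.tsv`, `<prefix>_truth.tsv`.
#'
#' @param td a `corrank_trial`.
#' @param out_prefix path prefix.
#' @return character vector of the three paths written.
#' @export
write_trial <- function(td, out_prefix) {
  stopifnot(inherits(td, "corrank_trial"))
  paths <- paste0(out_prefix, c("_X.tsv", "_labels.tsv", "_truth.tsv"))
  write_expression(td$X, paths[1L])
  write_labels(td$labels, paths[2L])
  utils::write.table(td$truth, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
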