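# Delimited-text I/O. Matrices are written with a header row of gene ids and
# a first column of cell ids; the field separator (tab or comma) is
# auto-detected on read. Missing Cq values are empty fields or "NA".

detect_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Read a cells-by-genes matrix from delimited text
#'
#' @param path file with a header row of gene ids and first column of cell
#'   ids; tab or comma separated (auto-detected).
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "#")
  as.matrix(df)
}

#' Write a cells-by-genes matrix as delimited text
#'
#' @param m matrix with cell rownames and gene colnames.
#' @param path output file.
#' @param sep field separator (default tab).
#' @param comment optional `#`-prefixed header line (e.g. a config hash).
#' @export
write_matrix <- function(m, path, sep = "\t", comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("cell_id", colnames(m)), collapse = sep), con)
  utils::write.table(m, con, sep = sep, quote = FALSE, col.names = FALSE,
                     row.names = TRUE)
  invisible(path)
}

#' Read a Cq table (with optional QC flag file)
#'
#' @param path delimited Cq matrix; empty fields or `NA` mark no detection.
#' @param qc_path optional delimited logical matrix of QC-pass flags.
#' @return a [cq_table()].
#' @export
read_cq_table <- function(path, qc_path = NULL) {
  cq <- read_matrix(path)
  qc <- if (!is.null(qc_path)) read_matrix(qc_path) > 0 else NULL
  cq_table(cq, qc)
}

#' Read a cell annotation table
#'
#' @param path delimited table with columns `cell_id`, `line`, `phase`,
#'   `size` and optionally `treatment`.
#' @return data.frame.
#' @export
read_annotation <- function(path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "phase", "size")
  if (!all(need %in% names(ann))) {
    abort("annotation must contain columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ann$cell_id)) abort("duplicated cell ids in annotation")
  bad <- setdiff(unique(ann$phase), c("G1", "S", "G2M"))
  if (length(bad) > 0) abort("unknown phase label: ", bad[1])
  bad <- setdiff(unique(ann$size), c("small", "large"))
  if (length(bad) > 0) abort("unknown size label: ", bad[1])
  ann
}
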