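#' Construct a Cq table
#'
#' Raw quantification-cycle values for cells (rows) by genes (columns), with
#' optional per-well QC flags. Missing amplification is encoded as `NA`.
#' Wells with aberrant melting curves should be flagged `FALSE` in `qc`; they
#' are treated as missing downstream.
#'
#' @param cq numeric matrix of Cq values with cell rownames and gene
#'   colnames; `NA` marks no detection.
#' @param qc logical matrix of the same shape, `TRUE` = pass; defaults to all
#'   pass.
#' @return an object of class `cq_table`.
#' @export
cq_table <- function(cq, qc = NULL) {
  cq <- as.matrix(cq)
  if (is.null(rownames(cq))) rownames(cq) <- sprintf("cell%03d", seq_len(nrow(cq)))
  if (is.null(colnames(cq))) colnames(cq) <- sprintf("g%03d", seq_len(ncol(cq)))
  if (is.null(qc)) {
    qc <- matrix(TRUE, nrow(cq), ncol(cq), dimnames = dimnames(cq))
  } else {
    qc <- as.matrix(qc)
    stopifnot(identical(dim(qc), dim(cq)))
    dimnames(qc) <- dimnames(cq)
  }
  structure(list(cq = cq, qc = qc), class = "cq_table")
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("<cq_table> %d cells x %d genes; %.1f%% detected, %d QC-failed wells\n",
              nrow(x$cq), ncol(x$cq), 100 * mean(!is.na(x$cq)),
              sum(!x$qc)))
  invisible(x)
}

#' Convert Cq values to molecules per cell
#'
#' Applies the absolute-scale transformation used for single-cell RT-qPCR:
#' Cq values above `cap` are truncated to `cap`, molecules are computed as
#' `(1 + efficiency)^(anchor - Cq)` so that `Cq == anchor` corresponds to one
#' molecule (exactly one at 100% efficiency), and missing or QC-failed wells
#' are imputed at a sub-detection constant (default 0.5 molecules). No
#' between-cell normalization is applied: values are molecules per cell.
#'
#' @param cq a [cq_table()] or a numeric matrix (then all wells pass QC).
#' @param anchor Cq value equal to one molecule (default 25).
#' @param cap maximal Cq; larger values are replaced by `cap` (default 25).
#' @param efficiency PCR efficiency in (0, 1]; default 1 (perfect doubling).
#' @param impute molecule value assigned to missing wells (default 0.5).
#' @return an `expression_matrix`: list with `molecules` (cells x genes),
#'   `detected` (logical, `FALSE` where imputed), and the transformation
#'   constants.
#' @export
cq_to_molecules <- function(cq, anchor = 25, cap = 25, efficiency = 1.0,
                            impute = 0.5) {
  if (!inherits(cq, "cq_table")) cq <- cq_table(cq)
  if (efficiency <= 0 || efficiency > 1) abort("efficiency must be in (0, 1]")
  vals <- cq$cq
  bad <- which(!is.na(vals) & !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-finite Cq at cell '%s', gene '%s'",
                  rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  vals[!cq$qc] <- NA_real_  # aberrant melting curves treated as missing
  detected <- !is.na(vals)
  molecules <- (1 + efficiency)^(anchor - pmin(vals, cap))
  molecules[!detected] <- impute
  structure(list(molecules = molecules, detected = detected,
                 anchor = anchor, cap = cap, efficiency = efficiency,
                 impute = impute),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes (molecules per cell); %.1f%% measured, %.1f%% imputed at %.2g\n",
              nrow(x$molecules), ncol(x$molecules), 100 * mean(x$detected),
              100 * mean(!x$detected), x$impute))
  invisible(x)
}

resolve_classes <- function(ann, classes) {
  if (is.character(classes) && length(classes) == 1 && classes %in% names(ann)) {
    split(ann$cell_id, ann[[classes]])
  } else if (is.list(classes)) {
    classes
  } else {
    abort("classes must be an annotation column name or a list of cell-id vectors")
  }
}

#' Filter genes by detection rate within classes
#'
#' Keeps a gene if it is measured (detected, QC-pass) in at least
#' `min_fraction` of the cells of at least one class. Imputed entries never
#' count toward detection. The default 50% rule is the standard inclusion
#' criterion before classification.
#'
#' @param expr an `expression_matrix` from [cq_to_molecules()].
#' @param ann cell annotation data.frame with `cell_id`.
#' @param classes either the name of an annotation column (cells are split by
#'   its values) or a named list of cell-id vectors.
#' @param min_fraction minimal within-class detection fraction (default 0.5).
#' @return character vector of retained gene ids, in input column order.
#' @export
filter_genes_by_detection <- function(expr, ann, classes,
                                      min_fraction = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  groups <- resolve_classes(ann, classes)
  if (length(groups) < 1) abort("no classes given")
  frac <- sapply(groups, function(cells) {
    if (length(cells) == 0) abort("empty class in detection filter")
    missing <- setdiff(cells, rownames(expr$detected))
    if (length(missing) > 0) abort("unknown cell id: ", missing[1])
    colMeans(expr$detected[cells, , drop = FALSE])
  })
  keep <- apply(as.matrix(frac), 1, max) >= min_fraction
  colnames(expr$molecules)[keep]
}

#' Log2 expression matrix
#'
#' Elementwise log2 of molecules per cell; with the default 0.5-molecule
#' imputation, imputed entries map to -1.
#'
#' @param expr an `expression_matrix` or a positive numeric matrix.
#' @return cells x genes matrix of log2 molecules.
#' @export
log2_matrix <- function(expr) {
  m <- if (inherits(expr, "expression_matrix")) expr$molecules else as.matrix(expr)
  if (any(m <= 0)) abort("molecule counts must be positive for log2")
  log2(m)
}

#' Autoscale a matrix per gene
#'
#' Standardizes every gene column to mean 0 and unit sample (n-1) standard
#' deviation across cells, the scaling conventionally applied before PCA,
#' hierarchical clustering and self-organizing maps. Zero-variance columns
#' cannot be scaled and are dropped with a warning.
#'
#' @param x cells x genes numeric matrix (typically log2 molecules).
#' @return the standardized matrix, possibly with fewer columns.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("autoscaling needs at least 2 cells")
  sds <- apply(x, 2, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance gene(s): %s", sum(drop),
                    paste(colnames(x)[drop], collapse = ", ")))
    x <- x[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}
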