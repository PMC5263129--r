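# Per-cell cell-cycle index and the piecewise-linear crossover estimate.

#' Cell-cycle index
#'
#' A per-cell scalar summarizing cell-cycle progression from a directed gene
#' signature: the sum of log2 expression over genes upregulated from G1
#' toward S/G2M minus the sum over downregulated genes, divided by the total
#' number of signature genes. Imputed sub-detection values (log2 = -1 under
#' defaults) enter the sums like any other value.
#'
#' @param x cells x genes log2 matrix.
#' @param up_genes gene ids entering with a plus sign.
#' @param down_genes gene ids entering with a minus sign.
#' @return data.frame with `cell_id` and `index`.
#' @export
cell_cycle_index <- function(x, up_genes, down_genes = character(0)) {
  x <- as.matrix(x)
  if (length(intersect(up_genes, down_genes)) > 0) {
    abort("up and down gene sets overlap")
  }
  genes <- c(up_genes, down_genes)
  if (length(genes) == 0) abort("signature is empty")
  if (!all(genes %in% colnames(x))) {
    abort("signature genes missing from matrix: ",
          paste(setdiff(genes, colnames(x)), collapse = ", "))
  }
  up <- rowSums(x[, up_genes, drop = FALSE])
  down <- if (length(down_genes) > 0) {
    rowSums(x[, down_genes, drop = FALSE])
  } else 0
  data.frame(cell_id = rownames(x),
             index = unname((up - down) / length(genes)))
}

#' Index of a directed signature
#'
#' Convenience wrapper applying [cell_cycle_index()] to a `gene_signature`
#' that carries directions (see [signature_directions()]).
#'
#' @param x cells x genes log2 matrix.
#' @param signature a `gene_signature` with a `directions` element.
#' @return data.frame with `cell_id` and `index`.
#' @export
signature_index <- function(x, signature) {
  stopifnot(inherits(signature, "gene_signature"))
  if (is.null(signature$directions)) {
    abort("signature has no directions; run signature_directions() first")
  }
  d <- signature$directions
  cell_cycle_index(x, names(d)[d > 0], names(d)[d < 0])
}

#' Crossover point of the cell-cycle index
#'
#' Cells are ordered by increasing index and a continuous two-segment
#' piecewise-linear model (a rising segment followed by a plateau) is fit by
#' least squares over all candidate breakpoints with at least `min_segment`
#' cells per segment. The returned crossover is the fitted index value at
#' the knot - the level at which the index enters its plateau. When the two
#' fitted slopes are similar (plateau slope above half the rising slope, or
#' no rising trend) the fit is flagged as having no distinct crossover.
#'
#' @param index numeric index values (or the data.frame from
#'   [cell_cycle_index()]).
#' @param phases optional per-cell phase labels; when given, at least two
#'   distinct phases are required.
#' @param min_segment minimal cells per segment (default 4).
#' @return list of class `crossover_fit`: `crossover` (index value at the
#'   knot; `NA` when undefined), `knot_rank`, `slope_rise`, `slope_plateau`,
#'   `sse`, `distinct` (logical flag).
#' @export
crossover_point <- function(index, phases = NULL, min_segment = 4) {
  v <- if (is.data.frame(index)) index$index else as.numeric(index)
  n <- length(v)
  if (n < 10) abort("need at least 10 cells")
  if (!is.null(phases) && length(unique(phases)) < 2) {
    abort("cells must span at least 2 phases")
  }
  y <- sort(v)
  x <- seq_len(n)
  if (max(y) == min(y)) {
    warning("constant index: crossover undefined")
    return(structure(list(crossover = NA_real_, knot_rank = NA_integer_,
                          slope_rise = 0, slope_plateau = 0, sse = 0,
                          distinct = FALSE), class = "crossover_fit"))
  }
  candidates <- seq(min_segment, n - min_segment)
  if (length(candidates) == 0) {
    warning("too few cells per segment: no crossover estimate")
    return(structure(list(crossover = NA_real_, knot_rank = NA_integer_,
                          slope_rise = NA_real_, slope_plateau = NA_real_,
                          sse = NA_real_, distinct = FALSE),
                     class = "crossover_fit"))
  }
  best <- NULL
  for (k in candidates) {
    fit <- stats::lm.fit(cbind(1, x, pmax(x - k, 0)), y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse) {
      b <- fit$coefficients
      best <- list(k = k, sse = sse, b0 = b[1], b1 = b[2], b2 = b[3])
    }
  }
  crossover <- unname(best$b0 + best$b1 * best$k)
  rise <- unname(best$b1)
  plateau <- unname(best$b1 + best$b2)
  distinct <- is.finite(rise) && rise > 0 && abs(plateau) < 0.5 * rise
  structure(list(crossover = crossover, knot_rank = best$k,
                 slope_rise = rise, slope_plateau = plateau, sse = best$sse,
                 distinct = distinct), class = "crossover_fit")
}

#' @export
print.crossover_fit <- function(x, ...) {
  if (is.na(x$crossover)) {
    cat("<crossover_fit> undefined\n")
  } else {
    cat(sprintf("<crossover_fit> index %.3f at rank %d (slopes %.3g -> %.3g)%s\n",
                x$crossover, x$knot_rank, x$slope_rise, x$slope_plateau,
                if (x$distinct) "" else " [no distinct crossover]"))
  }
  invisible(x)
}
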