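# Recursive feature elimination over forest ensembles: repeatedly train an
# ensemble, drop the gene with the lowest mean Gini importance, and record
# classification performance at every panel size, down to a single gene.

#' Run recursive feature elimination
#'
#' Cycle 1 trains a forest ensemble on all N genes; the least important gene
#' (lowest ensemble-mean Gini importance; ties broken toward the gene with
#' the larger importance SD, then lexicographically) is removed, and the
#' procedure iterates until one gene remains. The predictor-subset size is
#' re-scanned every `rescan_stride` cycles (default every cycle) and capped
#' at the current panel size in between.
#'
#' @inheritParams train_forest_ensemble
#' @param rescan_stride re-run the mtry scan every this many cycles; between
#'   scans the previous mtry (capped at the panel size) is reused.
#' @return object of class `rfe_trace`: data.frame `metrics` (one row per
#'   cycle: `cycle`, `n_genes`, `eliminated`, `mtry`, `oob_mean`, `oob_sd`,
#'   `balacc_mean`, `balacc_sd`, `fisher_p`), plus per-cycle gene sets and
#'   importances.
#' @export
run_rfe <- function(X, y, n_forests = 100, n_trees = 1000, mtry_grid = NULL,
                    pilot_forests = 10, rescan_stride = 1, seed = 1L,
                    task_id = 0L) {
  X <- as.matrix(X)
  if (ncol(X) < 2) abort("RFE needs at least 2 genes")
  genes <- colnames(X) %||% sprintf("g%03d", seq_len(ncol(X)))
  colnames(X) <- genes

  cycles <- list()
  current <- genes
  mtry_prev <- NULL
  k <- 0L
  while (length(current) >= 1) {
    k <- k + 1L
    p <- length(current)
    grid <- if (is.null(mtry_prev) || (k - 1L) %% rescan_stride == 0L) {
      g <- mtry_grid %||% seq_len(p)
      g[g <= p]
    } else {
      min(mtry_prev, p)
    }
    res <- train_forest_ensemble(X[, current, drop = FALSE], y,
                                 n_forests = n_forests, n_trees = n_trees,
                                 mtry_grid = grid,
                                 pilot_forests = pilot_forests,
                                 seed = derive_seed(seed, 7L, k),
                                 task_id = task_id)
    mtry_prev <- res$mtry
    eliminated <- if (p > 1) {
      least_important(res$importance_mean, res$importance_sd)
    } else NA_character_
    cycles[[k]] <- list(genes = current, result = res, eliminated = eliminated)
    if (p == 1) break
    current <- setdiff(current, eliminated)
  }

  metrics <- do.call(rbind, lapply(seq_along(cycles), function(i) {
    r <- cycles[[i]]$result
    data.frame(
      cycle = i, n_genes = length(cycles[[i]]$genes),
      eliminated = cycles[[i]]$eliminated, mtry = r$mtry,
      oob_mean = unname(r$oob_error["mean"]),
      oob_sd = unname(r$oob_error["sd"]),
      balacc_mean = unname(r$balanced_accuracy["mean"]),
      balacc_sd = unname(r$balanced_accuracy["sd"]),
      fisher_p = r$fisher_p
    )
  }))
  structure(list(metrics = metrics,
                 gene_sets = lapply(cycles, `[[`, "genes"),
                 importances = lapply(cycles,
                                      function(c) c$result$importance_mean),
                 classes = cycles[[1]]$result$classes,
                 seed = seed),
            class = "rfe_trace")
}

# lowest mean importance; ties -> larger SD (least stable), then first id
least_important <- function(imp_mean, imp_sd) {
  ord <- order(imp_mean, -imp_sd, names(imp_mean))
  names(imp_mean)[ord[1]]
}

#' @export
print.rfe_trace <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<rfe_trace> %s vs %s: %d cycles (%d -> 1 genes)\n",
              x$classes[1], x$classes[2], nrow(m), max(m$n_genes)))
  cat(sprintf("  best OOB error %.3f at %d genes\n",
              min(m$oob_mean), m$n_genes[which.min(m$oob_mean)]))
  invisible(x)
}

#' Select the optimal gene signature from an RFE trace
#'
#' The default parsimony rule picks the smallest panel whose mean OOB error
#' is within one ensemble SD of the global minimum; the classification
#' performance of the selected panel is then essentially indistinguishable
#' from the best cycle. Alternatives select the strict OOB-error or Fisher-p
#' minimizer. A consistency flag reports whether the three metrics (OOB
#' error minimized, balanced accuracy maximized, Fisher p minimized) agree
#' on the chosen cycle within one ensemble SD / one order of magnitude.
#'
#' @param trace an `rfe_trace`.
#' @param rule `"one_sd"` (default), `"min_oob"`, or `"min_fisher"`.
#' @return object of class `gene_signature`: `genes` (ordered, most
#'   predictive first by ensemble importance at the chosen cycle),
#'   `n_genes`, `cycle`, `metrics` (the chosen cycle's row), `consistent`,
#'   `classes`. Directions are added by [signature_directions()].
#' @export
optimal_signature <- function(trace,
                              rule = c("one_sd", "min_oob", "min_fisher")) {
  stopifnot(inherits(trace, "rfe_trace"))
  rule <- match.arg(rule)
  m <- trace$metrics
  i_oob <- which.min(m$oob_mean)
  chosen <- switch(rule,
    one_sd = {
      thr <- m$oob_mean[i_oob] + m$oob_sd[i_oob]
      cand <- which(m$oob_mean <= thr)
      cand[which.min(m$n_genes[cand])]
    },
    min_oob = i_oob,
    min_fisher = which.min(m$fisher_p)
  )
  i_bal <- which.max(m$balacc_mean)
  consistent <-
    m$balacc_mean[chosen] >= m$balacc_mean[i_bal] - m$balacc_sd[i_bal] &&
    m$fisher_p[chosen] <= max(min(m$fisher_p) * 10, .Machine$double.xmin) &&
    m$oob_mean[chosen] <= m$oob_mean[i_oob] + m$oob_sd[i_oob]
  imp <- trace$importances[[chosen]]
  genes <- names(imp)[order(-imp, names(imp))]
  structure(list(genes = genes, n_genes = length(genes), cycle = chosen,
                 metrics = m[chosen, ], consistent = consistent,
                 classes = trace$classes, rule = rule),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s vs %s (%d genes, rule %s): %s\n",
              x$classes[1], x$classes[2], x$n_genes, x$rule,
              paste(x$genes, collapse = ", ")))
  if (!is.null(x$directions)) {
    cat("  directions:", paste(sprintf("%s%s", ifelse(x$directions > 0, "+", "-"),
                                       names(x$directions)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Assign up/down directions to signature genes
#'
#' Direction +1 marks genes upregulated toward the later class (the second
#' factor level, e.g. G2M when classifying G1 vs G2M), -1 downregulated.
#' The sign of the difference of class medians of log2 expression is used
#' (robust to the skewed per-cell distributions); a zero median difference
#' falls back to the mean difference, then to +1.
#'
#' @param X cells x genes log2 matrix.
#' @param y two-class factor (second level = later state).
#' @param signature a `gene_signature` or character vector of gene ids.
#' @return the signature with a named `directions` element (values +1/-1);
#'   if `signature` was a character vector, the named direction vector.
#' @export
signature_directions <- function(X, y, signature) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  X <- as.matrix(X)
  if (!all(genes %in% colnames(X))) abort("signature genes missing from X")
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2)
  later <- levels(y)[2]
  dirs <- vapply(genes, function(g) {
    d <- stats::median(X[y == later, g]) - stats::median(X[y != later, g])
    if (d == 0) d <- mean(X[y == later, g]) - mean(X[y != later, g])
    if (d == 0) 1 else sign(d)
  }, numeric(1))
  if (inherits(signature, "gene_signature")) {
    signature$directions <- dirs
    signature
  } else {
    dirs
  }
}
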