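# Pairwise two-class random-forest classification. Forests are grown by the
# compiled backend (Gini splitting, fully grown trees, bootstrap, OOB
# voting); this file adds the ensemble protocol: an mtry scan selecting the
# smallest predictor-subset size that minimizes out-of-bag error, a
# 100-forest ensemble at the chosen mtry, and the reported statistics
# (confusion matrix mean +/- SD, OOB error, balanced accuracy, Fisher's
# exact p, Gini importance).

#' Grow one random forest
#'
#' Fully grown classification trees on bootstrap samples with Gini
#' splitting; `mtry` candidate genes are drawn at each node. Out-of-bag
#' predictions (majority vote over trees for which the cell was out of bag;
#' ties go to the first class) provide the confusion matrix and error.
#'
#' @param X cells x genes numeric matrix (log2 molecules).
#' @param y two-class factor; the level order defines the class order in the
#'   confusion matrix (earlier state first).
#' @param n_trees trees per forest (default 1000).
#' @param mtry predictors considered per split.
#' @param seed integer seed.
#' @return list of class `rf_forest`: `confusion` (rows = true class),
#'   `oob_error`, `balanced_accuracy`, `importance` (named, mean decrease in
#'   Gini), `oob_pred`.
#' @export
grow_forest <- function(X, y, n_trees = 1000, mtry = max(1, floor(sqrt(ncol(X)))),
                        seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) abort("y must have exactly two classes")
  if (!all(is.finite(X))) abort("X must be finite")
  y01 <- as.integer(y) - 1L
  fit <- .rf_fit_cpp(X, y01, as.integer(n_trees), as.integer(mtry),
                     as.integer(seed))
  votes <- fit$votes
  pred <- ifelse(votes[, 1] >= votes[, 2], 0L, 1L)
  never_oob <- rowSums(votes) == 0
  if (any(never_oob)) pred[never_oob] <- as.integer(names(which.max(table(y01))))
  conf <- table(factor(y01, levels = 0:1), factor(pred, levels = 0:1))
  conf <- matrix(as.numeric(conf), 2, 2,
                 dimnames = list(true = levels(y), predicted = levels(y)))
  imp <- stats::setNames(fit$importance, colnames(X))
  structure(list(
    confusion = conf,
    oob_error = mean(pred != y01),
    balanced_accuracy = balanced_accuracy(conf),
    importance = imp,
    oob_pred = stats::setNames(levels(y)[pred + 1L], rownames(X)),
    classes = levels(y), n_trees = n_trees, mtry = mtry, seed = seed
  ), class = "rf_forest")
}

#' Balanced accuracy of a 2x2 confusion matrix
#'
#' Mean of the per-class recalls (rows = true classes), the accuracy
#' averaged over classes so that imbalanced groups cannot inflate it.
#'
#' @param confusion 2x2 matrix of counts, rows = true class.
#' @return scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(identical(dim(confusion), c(2L, 2L)))
  rs <- rowSums(confusion)
  if (any(rs == 0)) abort("a true class has zero cells")
  mean(diag(confusion) / rs)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (standard
#' two-sided convention, with a 1e-7 relative tolerance on the comparison).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be non-negative integers (round ensemble means first)")
  }
  m <- sum(tab[1, ])          # row 1 margin
  n <- sum(tab[2, ])          # row 2 margin
  k <- sum(tab[, 1])          # column 1 margin
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(d[d <= d_obs * (1 + 1e-7)])
}

# seed for forest f of task `task` at predictor-subset size `mtry`
forest_seed <- function(master, task, mtry, f) {
  derive_seed(master, 101L, task, mtry, f)
}

#' Train a random-forest ensemble for one two-class task
#'
#' Implements the full forest protocol: the predictor-subset size (mtry) is
#' scanned over `mtry_grid` using a pilot sub-ensemble of `pilot_forests`
#' forests per candidate, and the smallest mtry attaining the minimal mean
#' OOB error is selected; a full ensemble of `n_forests` forests is then
#' grown at that mtry. Reported statistics are means and standard deviations
#' over the ensemble. The single Fisher p is computed on the ensemble-mean
#' confusion matrix rounded to integers (per-forest p-values are aggregated
#' by the median behind `fisher_method = "per_forest_median"`).
#'
#' @param X cells x genes matrix of log2 molecules.
#' @param y two-class factor (level order = class order; the second level is
#'   the "later" state).
#' @param n_forests forests in the ensemble (default 100).
#' @param n_trees trees per forest (default 1000).
#' @param mtry_grid candidate predictor-subset sizes; default the full range
#'   `1:ncol(X)`.
#' @param pilot_forests forests per mtry candidate during the scan
#'   (default 10).
#' @param fisher_method how the single Fisher p is formed.
#' @param seed master seed; forest f at a given mtry uses a seed derived
#'   from `(seed, task_id, mtry, f)`.
#' @param task_id integer tag making seeds unique across tasks.
#' @return object of class `forest_ensemble` with elements `mtry`,
#'   `confusion_mean`, `confusion_sd`, `oob_error` (mean, sd),
#'   `balanced_accuracy` (mean, sd), `fisher_p`, `importance_mean`,
#'   `importance_sd`, `mtry_scan`, `classes`, `n_forests`, `n_trees`.
#' @export
train_forest_ensemble <- function(X, y, n_forests = 100, n_trees = 1000,
                                  mtry_grid = NULL, pilot_forests = 10,
                                  fisher_method = c("rounded_mean",
                                                    "per_forest_median"),
                                  seed = 1L, task_id = 0L) {
  fisher_method <- match.arg(fisher_method)
  X <- as.matrix(X)
  if (ncol(X) < 1) abort("no genes left after filtering")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) abort("y must have exactly two classes")
  if (min(table(y)) < 5) {
    abort("each class needs >= 5 cells for a stable out-of-bag estimate")
  }
  p <- ncol(X)
  mtry_grid <- sort(unique(as.integer(mtry_grid %||% seq_len(p))))
  if (any(mtry_grid < 1 | mtry_grid > p)) abort("mtry_grid out of range")

  scan <- vapply(mtry_grid, function(m) {
    mean(vapply(seq_len(pilot_forests), function(f) {
      grow_forest(X, y, n_trees, m, forest_seed(seed, task_id, m, f))$oob_error
    }, numeric(1)))
  }, numeric(1))
  best <- mtry_grid[which(scan <= min(scan) + 1e-12)[1]]  # smallest minimizer

  # ensemble forests use seeds disjoint from the pilot sub-ensemble so the
  # mtry selection cannot leak into the reported statistics
  forests <- lapply(seq_len(n_forests), function(f) {
    grow_forest(X, y, n_trees, best,
                forest_seed(seed, task_id, best, pilot_forests + f))
  })

  confs <- simplify2array(lapply(forests, `[[`, "confusion"))
  imps <- do.call(rbind, lapply(forests, `[[`, "importance"))
  oob <- vapply(forests, `[[`, numeric(1), "oob_error")
  bal <- vapply(forests, `[[`, numeric(1), "balanced_accuracy")
  conf_mean <- apply(confs, 1:2, mean)
  conf_sd <- apply(confs, 1:2, stats::sd)
  fisher_p <- if (fisher_method == "rounded_mean") {
    fisher_exact_2x2(round(conf_mean))
  } else {
    stats::median(vapply(forests, function(f) fisher_exact_2x2(f$confusion),
                         numeric(1)))
  }
  structure(list(
    mtry = best,
    mtry_scan = data.frame(mtry = mtry_grid, oob_error = scan),
    confusion_mean = conf_mean, confusion_sd = conf_sd,
    oob_error = c(mean = mean(oob), sd = stats::sd(oob)),
    balanced_accuracy = c(mean = mean(bal), sd = stats::sd(bal)),
    fisher_p = fisher_p,
    importance_mean = colMeans(imps),
    importance_sd = apply(imps, 2, stats::sd),
    classes = levels(y), n_forests = n_forests, n_trees = n_trees,
    seed = seed, task_id = task_id
  ), class = "forest_ensemble")
}

#' @export
print.forest_ensemble <- function(x, ...) {
  cat(sprintf("<forest_ensemble> %s vs %s: %d forests x %d trees, mtry = %d\n",
              x$classes[1], x$classes[2], x$n_forests, x$n_trees, x$mtry))
  cat(sprintf("  OOB error %.3f +/- %.3f | balanced accuracy %.3f +/- %.3f | Fisher p %.3g\n",
              x$oob_error["mean"], x$oob_error["sd"],
              x$balanced_accuracy["mean"], x$balanced_accuracy["sd"],
              x$fisher_p))
  invisible(x)
}

#' Rank genes by ensemble importance
#'
#' Orders genes by descending mean decrease in Gini impurity over the
#' ensemble; ties are broken lexicographically by gene id so the ordering is
#' stable.
#'
#' @param result a `forest_ensemble`.
#' @return character vector of gene ids, most important first.
#' @export
rank_importances <- function(result) {
  stopifnot(inherits(result, "forest_ensemble"))
  imp <- result$importance_mean
  names(imp)[order(-imp, names(imp))]
}
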