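# Subpopulation discovery: PCA restricted to signature genes with a k-means
# gate, Ward hierarchical clustering, a 1-D Kohonen self-organizing map, a
# 2-of-3 consensus replacing the manual PCA gate, and the volcano /
# total-transcript characterization of the discovered group.

#' PCA embedding of an autoscaled matrix
#'
#' Principal axes of the (already autoscaled) cells x genes matrix. Each
#' component is oriented so that its largest-magnitude gene loading is
#' positive, which makes scores deterministic.
#'
#' @param x autoscaled cells x genes matrix (see [autoscale()]).
#' @param n_components number of components to return.
#' @return list of class `pca_embedding`: `scores` (cells x components),
#'   `loadings`, `explained_variance` (fraction per component, all
#'   components).
#' @export
pca_embed <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 3) abort("need at least 3 cells")
  if (ncol(x) < n_components) abort("fewer genes than components")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    l <- pr$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  pr$rotation <- sweep(pr$rotation, 2, flip, `*`)
  pr$x <- sweep(pr$x, 2, flip, `*`)
  keep <- seq_len(min(n_components, ncol(pr$x)))
  structure(list(scores = pr$x[, keep, drop = FALSE],
                 loadings = pr$rotation[, keep, drop = FALSE],
                 explained_variance = pr$sdev^2 / sum(pr$sdev^2)),
            class = "pca_embedding")
}

clustering_result <- function(method, labels, params = list()) {
  structure(list(method = method, labels = labels,
                 k = length(unique(labels)), params = params),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s: %d cells in %d clusters (%s)\n",
              x$method, length(x$labels), x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Gate cells in PCA space
#'
#' Operationalizes the manual encircling of a subpopulation in a PCA score
#' plot: cells are clustered in the space of the first `n_components`
#' principal components (k-means refined from a deterministic Ward
#' initialization, so the result needs no random seed).
#'
#' @param x autoscaled cells x genes matrix.
#' @param k number of clusters.
#' @param n_components PCA components used (default 2).
#' @return a `clustering_result` with method `"pca_gate"`.
#' @export
pca_gate_clusters <- function(x, k = 2, n_components = 2) {
  emb <- pca_embed(x, n_components)
  s <- emb$scores
  init <- stats::cutree(stats::hclust(stats::dist(s), method = "ward.D2"), k)
  centers <- do.call(rbind, lapply(split(seq_len(nrow(s)), init),
                                   function(i) colMeans(s[i, , drop = FALSE])))
  km <- stats::kmeans(s, centers = centers)
  clustering_result("pca_gate", stats::setNames(km$cluster, rownames(s)),
                    list(k = k, n_components = n_components))
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (`hclust` method `ward.D2`), cut at `k` clusters.
#'
#' @param x autoscaled cells x genes matrix.
#' @param k number of clusters.
#' @return a `clustering_result` with method `"ward"`.
#' @export
ward_clusters <- function(x, k) {
  x <- as.matrix(x)
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(x)) abort("k exceeds the number of cells")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  clustering_result("ward", stats::cutree(hc, k), list(k = k))
}

#' 1-D Kohonen self-organizing map clustering
#'
#' A one-dimensional map of `map_length` nodes trained by sequential
#' best-matching-unit updates: every epoch presents all cells in random
#' order; each presented cell pulls the weights of its best-matching node
#' and of nodes within the current neighborhood radius toward itself. The
#' learning rate decays linearly from `learning_rate` to 0 and the radius
#' from `neighbors` to 0 over the epochs. Node weights are initialized
#' evenly spaced along the first principal component. Cells are labeled by
#' their final best-matching node.
#'
#' @param x autoscaled cells x genes matrix.
#' @param map_length nodes in the map (3-4 is the conventional choice).
#' @param neighbors initial neighborhood radius.
#' @param learning_rate initial learning rate.
#' @param iterations training epochs.
#' @param seed integer seed for the presentation order.
#' @return a `clustering_result` with method `"som"`.
#' @export
som_clusters <- function(x, map_length = 3, neighbors = 2,
                         learning_rate = 0.4, iterations = 150, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < map_length) abort("fewer cells than map nodes")
  if (map_length < 1) abort("map_length must be >= 1")

  # init: evenly spaced along PC1
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = 1)
  pc1 <- drop(xc %*% sv$v[, 1])
  if (max(pc1) == min(pc1)) {
    warning("degenerate (constant) data: all cells mapped to one node")
    return(clustering_result("som",
                             stats::setNames(rep(1L, n), rownames(x)),
                             list(map_length = map_length)))
  }
  pos <- seq(min(pc1), max(pc1), length.out = map_length)
  w <- outer(pos, drop(sv$v[, 1])) + matrix(ctr, map_length, ncol(x),
                                            byrow = TRUE)

  bmu <- function(cell) which.min(rowSums(sweep(w, 2, cell)^2))
  set.seed(seed)
  if (iterations > 0) {
    for (e in seq_len(iterations)) {
      frac <- 1 - (e - 1) / iterations
      lr <- learning_rate * frac
      radius <- neighbors * frac
      for (i in sample.int(n)) {
        b <- bmu(x[i, ])
        upd <- which(abs(seq_len(map_length) - b) <= radius)
        w[upd, ] <- w[upd, ] + lr * (matrix(x[i, ], length(upd), ncol(x),
                                            byrow = TRUE) - w[upd, ])
      }
    }
  }
  labels <- vapply(seq_len(n), function(i) bmu(x[i, ]), integer(1))
  clustering_result("som", stats::setNames(labels, rownames(x)),
                    list(map_length = map_length, neighbors = neighbors,
                         learning_rate = learning_rate,
                         iterations = iterations, seed = seed))
}

#' Consensus subpopulation across clustering methods
#'
#' Replaces the manual PCA gate with an objective rule: within each
#' clustering, the cluster with the lowest mean per-cell score (typically
#' the total transcript level) is designated the candidate low-transcription
#' subpopulation; cells assigned to that cluster by at least `min_methods`
#' of the clusterings form the consensus. Per-method agreement with the
#' consensus is reported as Jaccard indices.
#'
#' @param results list of >= 2 `clustering_result` objects over the same
#'   cells.
#' @param score named numeric vector (one value per cell, e.g. totals from
#'   [total_transcripts()]) used to pick the low cluster in each method.
#' @param min_methods votes needed for consensus membership (default 2).
#' @return list: `members` (cell ids), `per_method` (list of candidate
#'   sets), `jaccard` (per method vs consensus), `votes`.
#' @export
consensus_subpopulation <- function(results, score, min_methods = 2) {
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, logical(1), "clustering_result")))
  cells <- names(results[[1]]$labels)
  for (r in results) {
    if (!setequal(names(r$labels), cells)) {
      abort("clusterings do not share the same cell universe")
    }
  }
  if (is.null(names(score))) abort("score must be named by cell id")
  per_method <- lapply(results, function(r) {
    means <- tapply(score[names(r$labels)], r$labels, mean)
    target <- names(means)[which.min(means)]
    names(r$labels)[r$labels == target]
  })
  names(per_method) <- vapply(results, `[[`, character(1), "method")
  votes <- table(unlist(per_method))
  members <- sort(names(votes)[votes >= min_methods])
  if (length(members) == 0) {
    warning("no consensus subpopulation: methods disagree")
  }
  jaccard <- vapply(per_method, function(s) {
    u <- union(s, members)
    if (length(u) == 0) return(NA_real_)
    length(intersect(s, members)) / length(u)
  }, numeric(1))
  list(members = members, per_method = per_method, jaccard = jaccard,
       votes = votes)
}

#' Volcano comparison of a subpopulation against the remainder
#'
#' Per gene: log2 fold change (difference of group means of log2 molecules,
#' so a planted uniform shift is recovered exactly) and a two-sided
#' Mann-Whitney p-value. Genes regulated at least two-fold
#' (`|log2 FC| >= 1`) are categorized by significance: `green` below the
#' Bonferroni-corrected threshold `alpha / n_tests`, `yellow` between the
#' corrected threshold and `alpha`, `red` above `alpha`; all other genes are
#' `not-regulated`.
#'
#' @param x cells x genes log2 matrix.
#' @param members cell ids of the subpopulation.
#' @param remainder cell ids of the comparison group.
#' @param n_tests Bonferroni denominator (default the number of genes in
#'   `x`).
#' @param alpha uncorrected significance level (default 0.05).
#' @param fc_stat `"mean"` (default) or `"median"` difference for the fold
#'   change.
#' @return data.frame (`gene`, `log2_fc`, `p_value`, `category`) with the
#'   corrected threshold in attribute `"threshold"`.
#' @export
volcano <- function(x, members, remainder, n_tests = NULL, alpha = 0.05,
                    fc_stat = c("mean", "median")) {
  fc_stat <- match.arg(fc_stat)
  x <- as.matrix(x)
  if (length(members) < 3 || length(remainder) < 3) {
    abort("both groups need at least 3 cells")
  }
  if (length(intersect(members, remainder)) > 0) abort("groups overlap")
  n_tests <- n_tests %||% ncol(x)
  threshold <- alpha / n_tests
  stat <- if (fc_stat == "mean") colMeans else
    function(m) apply(m, 2, stats::median)
  fc <- stat(x[members, , drop = FALSE]) - stat(x[remainder, , drop = FALSE])
  p <- vapply(seq_len(ncol(x)), function(j) {
    mann_whitney_test(x[members, j], x[remainder, j])$p_value
  }, numeric(1))
  category <- ifelse(abs(fc) < 1, "not-regulated",
              ifelse(p >= alpha, "red",
              ifelse(p >= threshold, "yellow", "green")))
  out <- data.frame(gene = colnames(x), log2_fc = unname(fc),
                    p_value = p, category = category)
  attr(out, "threshold") <- threshold
  out
}

#' Total-transcript contrast of a subpopulation
#'
#' Percent reduction of the mean total transcript level in the
#' subpopulation relative to the remainder, with a two-sided Mann-Whitney
#' p-value.
#'
#' @param totals data.frame from [total_transcripts()].
#' @param members,remainder cell-id vectors.
#' @return list with `percent_lower` (positive when the subpopulation is
#'   lower) and `p_value`.
#' @export
subpop_transcript_contrast <- function(totals, members, remainder) {
  if (length(members) == 0 || length(remainder) == 0) {
    abort("both groups must be non-empty")
  }
  tm <- totals$total[match(members, totals$cell_id)]
  tr <- totals$total[match(remainder, totals$cell_id)]
  if (anyNA(tm) || anyNA(tr)) abort("unknown cell ids in contrast")
  list(percent_lower = 100 * (1 - mean(tm) / mean(tr)),
       p_value = mann_whitney_test(tm, tr)$p_value)
}
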