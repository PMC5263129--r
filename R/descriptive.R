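# Descriptive statistics on per-cell totals: the analyses behind the total
# transcript level comparisons, the Spearman correlations against cell
# proliferation parameters, and the pairwise gene-gene correlation census.

#' Total transcript level per cell
#'
#' Sums molecules over all panel genes for every cell. Because single-cell
#' RT-qPCR reports absolute molecules per cell (no between-cell
#' normalization), this total is a meaningful per-cell quantity; imputed
#' sub-detection values are included in the sum.
#'
#' @param expr an `expression_matrix` or a numeric cells x genes matrix.
#' @return data.frame with `cell_id` and `total`.
#' @export
total_transcripts <- function(expr) {
  m <- if (inherits(expr, "expression_matrix")) expr$molecules else as.matrix(expr)
  data.frame(cell_id = rownames(m), total = unname(rowSums(m)))
}

phase_size_encoding <- function(ann, encoding,
                                combined_order = default_combined_order()) {
  switch(encoding,
    phase = phase_step(ann$phase) + 1,
    size = ifelse(ann$size == "small", 1, 2),
    phase_x_size = {
      key <- paste(ann$size, ann$phase, sep = "-")
      idx <- match(key, combined_order)
      if (anyNA(idx)) abort("combined encoding undefined for: ",
                            key[which(is.na(idx))[1]])
      idx
    },
    abort("unknown encoding: ", encoding)
  )
}

#' Default ordering of the combined phase-by-size encoding
#'
#' Small before large within each phase, phases in cycle order, giving ranks
#' 1..6. The ordering is a convention (exposed so sensitivity to it can be
#' checked).
#' @return character vector of six `size-phase` keys.
#' @export
default_combined_order <- function() {
  c("small-G1", "large-G1", "small-S", "large-S", "small-G2M", "large-G2M")
}

#' Spearman correlation between totals and a proliferation encoding
#'
#' Rank correlation (midranks for ties) between per-cell total transcript
#' level and an ordinal encoding of cell cycle phase (G1=1, S=2, G2M=3), cell
#' size (small=1, large=2), or the combined phase-by-size factor.
#'
#' @param totals data.frame from [total_transcripts()].
#' @param ann cell annotation; matched to `totals` by `cell_id`.
#' @param encoding one of `"phase"`, `"size"`, `"phase_x_size"`.
#' @param combined_order ordering used for `"phase_x_size"`.
#' @return data.frame with `encoding`, `rho`, `p_value`, `n`.
#' @export
spearman_vs_factor <- function(totals, ann,
                               encoding = c("phase", "size", "phase_x_size"),
                               combined_order = default_combined_order()) {
  encoding <- match.arg(encoding)
  idx <- match(totals$cell_id, ann$cell_id)
  if (anyNA(idx)) abort("cells in totals missing from annotation")
  if (nrow(totals) < 3) abort("need at least 3 cells")
  enc <- phase_size_encoding(ann[idx, ], encoding, combined_order)
  if (length(unique(enc)) < 2) abort("encoding is constant across cells")
  ct <- suppressWarnings(
    stats::cor.test(totals$total, enc, method = "spearman", exact = FALSE)
  )
  data.frame(encoding = encoding, rho = unname(ct$estimate),
             p_value = ct$p.value, n = nrow(totals))
}

#' Census of pairwise gene-gene Spearman correlations
#'
#' Computes the rank correlation for every unordered gene pair and reports
#' the fraction of positive correlations. When most cells share a global
#' scaling of their transcriptome (transcriptional bursting), most pairs
#' correlate positively. Zero-variance genes have undefined correlations;
#' their pairs are excluded from both numerator and denominator and counted
#' separately.
#'
#' @param x cells x genes matrix of log2 molecules.
#' @return list with `pairs` (data.frame `gene_a`, `gene_b`, `rho`),
#'   `n_pairs` (defined pairs), `fraction_positive`, and `n_excluded`.
#' @export
pairwise_gene_correlations <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) abort("need at least 3 cells")
  if (ncol(x) < 2) abort("need at least 2 genes")
  if (is.null(colnames(x))) colnames(x) <- sprintf("g%03d", seq_len(ncol(x)))
  ranks <- apply(x, 2, rank)
  sds <- apply(ranks, 2, stats::sd)
  cmat <- suppressWarnings(stats::cor(ranks))
  cmat[sds == 0, ] <- NA
  cmat[, sds == 0] <- NA
  ut <- which(upper.tri(cmat), arr.ind = TRUE)
  rho <- cmat[ut]
  ok <- !is.na(rho)
  list(
    pairs = data.frame(gene_a = colnames(x)[ut[ok, 1]],
                       gene_b = colnames(x)[ut[ok, 2]],
                       rho = rho[ok]),
    n_pairs = sum(ok),
    fraction_positive = if (any(ok)) mean(rho[ok] > 0) else NA_real_,
    n_excluded = sum(!ok)
  )
}

#' Two-sample Mann-Whitney U test
#'
#' Two-sided Wilcoxon rank-sum test; exact when there are no ties and the
#' combined sample size is at most 25, otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` and `p_value`.
#' @export
mann_whitney_test <- function(x, y) {
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && (length(x) + length(y)) <= 25
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # complete ties: zero-variance rank statistic
  list(U = unname(wt$statistic), p_value = p)
}

#' Compare totals between groups with Holm-Bonferroni control
#'
#' Runs a two-sided Mann-Whitney U test for each declared pair of groups and
#' applies Holm's step-down adjustment across the family.
#'
#' @param totals data.frame from [total_transcripts()].
#' @param grouping named list of cell-id vectors.
#' @param comparisons list of length-2 character vectors naming group pairs.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per comparison: `group_a`, `group_b`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
group_compare_mannwhitney <- function(totals, grouping, comparisons,
                                      alpha = 0.05) {
  stopifnot(is.list(grouping), is.list(comparisons))
  get_vals <- function(g) {
    cells <- grouping[[g]]
    if (is.null(cells)) abort("unknown group: ", g)
    if (length(cells) < 2) abort("group '", g, "' has fewer than 2 cells")
    totals$total[match(cells, totals$cell_id)]
  }
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2)
    if (length(intersect(grouping[[cmp[1]]], grouping[[cmp[2]]])) > 0) {
      abort("groups overlap within one comparison: ", cmp[1], " vs ", cmp[2])
    }
    mw <- mann_whitney_test(get_vals(cmp[1]), get_vals(cmp[2]))
    data.frame(group_a = cmp[1], group_b = cmp[2], p_value = mw$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Max/min ratio of totals
#'
#' The fold difference between the cell with the highest and the lowest
#' total transcript level; a simple summary of how skewed the per-cell
#' totals are.
#'
#' @param totals data.frame from [total_transcripts()] or a numeric vector.
#' @return scalar ratio.
#' @export
range_ratio <- function(totals) {
  v <- if (is.data.frame(totals)) totals$total else totals
  if (any(v <= 0)) abort("totals must be positive")
  max(v) / min(v)
}
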