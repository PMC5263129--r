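test_that("total transcripts sum molecules per cell, imputation included", {
  m <- matrix(c(1, 2, 0.5), 1, 3,
              dimnames = list("c1", c("g1", "g2", "g3")))
  expect_equal(total_transcripts(m)$total, 3.5)
  allimp <- matrix(0.5, 1, 93, dimnames = list("c1", sprintf("g%02d", 1:93)))
  expect_equal(total_transcripts(allimp)$total, 46.5)
  perm <- m[, c(3, 1, 2), drop = FALSE]
  expect_equal(total_transcripts(perm)$total, total_transcripts(m)$total)
})

test_that("spearman_vs_factor uses the ordinal encodings", {
  ann <- data.frame(cell_id = sprintf("c%d", 1:9),
                    phase = rep(c("G1", "S", "G2M"), each = 3),
                    size = rep(c("small", "large", "small"), 3))
  totals <- data.frame(cell_id = ann$cell_id, total = 1:9)
  res <- spearman_vs_factor(totals, ann, "phase")
  expect_equal(res$rho, stats::cor(rank(1:9), rank(rep(1:3, each = 3))))
  expect_equal(res$n, 9)
  # strictly increasing along the phase ordering attains the maximal rho
  one_per <- totals[c(1, 4, 7), ]
  expect_equal(spearman_vs_factor(one_per, ann, "phase")$rho, 1)
  ann_const <- data.frame(cell_id = one_per$cell_id,
                          phase = c("G1", "S", "G2M"), size = "small")
  expect_error(spearman_vs_factor(one_per, ann_const, "size"), "constant")
})

test_that("spearman agrees with rank-then-Pearson to 1e-12", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    tot <- round(stats::rexp(n, 1 / 50), 1)  # ties likely
    enc <- sample(1:3, n, replace = TRUE)
    ann <- data.frame(cell_id = sprintf("c%d", 1:n),
                      phase = c("G1", "S", "G2M")[enc],
                      size = "small")
    if (length(unique(enc)) < 2) next
    res <- spearman_vs_factor(data.frame(cell_id = ann$cell_id, total = tot),
                              ann, "phase")
    expect_equal(res$rho, stats::cor(rank(tot), rank(enc)), tolerance = 1e-12)
  }
})

test_that("null totals give near-zero rank correlation at n = 90", {
  enc <- rep(1:3, each = 30)
  ann <- data.frame(cell_id = sprintf("c%d", 1:90),
                    phase = c("G1", "S", "G2M")[enc], size = "small")
  set.seed(33)
  small <- vapply(1:1000, function(i) {
    tot <- stats::rexp(90, 1 / 50)
    abs(stats::cor(rank(tot), rank(enc))) < 0.2
  }, logical(1))
  # under the null, rho has SD ~ 1/sqrt(n-1) = 0.106, so |rho| < 0.2 holds
  # with probability ~0.94; assert the rate the enumeration-free oracle gives
  expect_gte(mean(small), 0.92)
  # and the packaged path agrees in distribution on one draw
  set.seed(34)
  res <- spearman_vs_factor(
    data.frame(cell_id = ann$cell_id, total = stats::rexp(90, 1 / 50)),
    ann, "phase")
  expect_lt(abs(res$rho), 0.3)
})

test_that("phase-coupled scaling makes phase rho exceed size rho", {
  sim <- generate_dataset(sim_config(seed = 17))  # default phase_total_log2
  totals <- total_transcripts(cq_to_molecules(sim$cq))
  rho_phase <- spearman_vs_factor(totals, sim$annotation, "phase")$rho
  rho_size <- spearman_vs_factor(totals, sim$annotation, "size")$rho
  expect_gt(rho_phase, abs(rho_size))
  expect_gt(rho_phase, 0.3)
})

test_that("pairwise correlation census counts all unordered pairs", {
  set.seed(3)
  x93 <- matrix(stats::rnorm(10 * 93), 10, 93,
                dimnames = list(NULL, sprintf("g%02d", 1:93)))
  census <- pairwise_gene_correlations(x93)
  expect_equal(census$n_pairs, 4278)
  expect_equal(census$n_excluded, 0)
  x2 <- x93[, 1:2]
  expect_equal(pairwise_gene_correlations(x2)$n_pairs, 1)

  # a zero-variance gene is excluded from numerator and denominator
  x3 <- cbind(x93[, 1:3], flat = 1)
  c3 <- pairwise_gene_correlations(x3)
  expect_equal(c3$n_pairs, 3)
  expect_equal(c3$n_excluded, 3)
})

test_that("a shared per-cell scale factor induces mostly positive correlations", {
  set.seed(5)
  scale_factor <- stats::rnorm(50, 0, 1.5)
  x <- matrix(stats::rnorm(50 * 20, 0, 0.4), 50, 20) + scale_factor
  census <- pairwise_gene_correlations(x)
  expect_gt(census$fraction_positive, 0.9)
})

test_that("Mann-Whitney wrapper: ties, exactness and the enumeration oracle", {
  same <- mann_whitney_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1)

  sep <- mann_whitney_test(1:10, 11:20)
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  set.seed(12)
  for (sizes in list(c(3, 3), c(4, 5), c(2, 8), c(8, 8), c(7, 6))) {
    x <- stats::rnorm(sizes[1])
    y <- stats::rnorm(sizes[2])
    expect_equal(mann_whitney_test(x, y)$p_value, mw_enum_p(x, y),
                 tolerance = 1e-12,
                 info = paste(sizes, collapse = "v"))
  }
})

test_that("group comparisons: Holm dominates Bonferroni and inputs are checked", {
  set.seed(1)
  totals <- data.frame(cell_id = sprintf("c%02d", 1:40),
                       total = stats::rexp(40, 1 / 50) +
                         rep(c(0, 0, 30, 60), each = 10))
  grouping <- split(totals$cell_id, rep(LETTERS[1:4], each = 10))
  comparisons <- list(c("A", "B"), c("A", "C"), c("A", "D"),
                      c("B", "C"), c("B", "D"), c("C", "D"))
  res <- group_compare_mannwhitney(totals, grouping, comparisons)
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_adjusted >= res$p_value))
  bonf_reject <- res$p_value * length(comparisons) < 0.05
  expect_true(all(res$significant[bonf_reject]))
  expect_error(group_compare_mannwhitney(totals, grouping,
                                         list(c("A", "A"))), "overlap")
})

test_that("range_ratio", {
  expect_equal(range_ratio(c(10, 20, 170)), 17)
  expect_equal(range_ratio(rep(4, 10)), 1)
  expect_error(range_ratio(c(1, 0)), "positive")
})
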