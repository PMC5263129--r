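test_that("pca_embed: deterministic orientation, duplicates, null spectrum", {
  x <- make_blobs(10, rbind(c(0, 0, 0), c(4, 4, 0)), sd = 0.4, seed = 1)
  emb <- pca_embed(autoscale(x), 2)
  lab <- rep(1:2, each = 10)
  expect_gt(silhouette_mean(emb$scores[, 1, drop = FALSE], lab), 0.5)

  dup <- rbind(x, x[1:3, ])
  emb_dup <- pca_embed(autoscale(dup), 2)
  expect_equal(emb_dup$scores[21:23, ], emb_dup$scores[1:3, ],
               tolerance = 1e-9, ignore_attr = TRUE)

  # isotropic noise: leading share of variance approaches 1/n_genes
  set.seed(2)
  iso <- matrix(stats::rnorm(2000 * 5), 2000, 5)
  ev1 <- pca_embed(iso, 2)$explained_variance[1]
  expect_gt(ev1, 0.18)
  expect_lt(ev1, 0.27)

  expect_error(pca_embed(x[, 1, drop = FALSE], 2), "fewer genes")
})

test_that("ward_clusters recovers blobs and handles boundary k", {
  x <- make_blobs(15, rbind(c(0, 0), c(5, 5)), sd = 0.5, seed = 3)
  truth <- rep(1:2, each = 15)
  cl <- ward_clusters(x, 2)
  expect_gt(ari(cl$labels, truth), 0.9)

  singles <- ward_clusters(x, nrow(x))
  expect_equal(singles$k, nrow(x))

  perm <- sample(nrow(x))
  cl_perm <- ward_clusters(x[perm, ], 2)
  expect_equal(ari(cl_perm$labels[rownames(x)], cl$labels), 1)

  expect_error(ward_clusters(x, 0), "k must be")
})

test_that("som_clusters: recovery, determinism and degenerate cases", {
  x <- make_blobs(12, rbind(c(0, 0), c(4, 4), c(8, 8)), sd = 0.4, seed = 5)
  truth <- rep(1:3, each = 12)
  cl <- som_clusters(x, map_length = 3, seed = 7)
  expect_gt(ari(cl$labels, truth), 0.9)
  expect_identical(som_clusters(x, map_length = 3, seed = 7)$labels,
                   cl$labels)

  cl0 <- som_clusters(x, map_length = 3, iterations = 0, seed = 7)
  expect_equal(sort(unique(cl0$labels)), 1:3)  # labels from initial weights

  one <- som_clusters(x, map_length = 1, seed = 1)
  expect_true(all(one$labels == 1))

  flat <- matrix(1, 10, 3, dimnames = list(paste0("c", 1:10), NULL))
  expect_warning(cf <- som_clusters(flat, map_length = 3), "degenerate")
  expect_true(all(cf$labels == 1))
})

test_that("consensus subpopulation: agreement, disagreement, recovery", {
  x <- make_blobs(10, rbind(c(0, 0), c(5, 5)), sd = 0.4, seed = 9)
  score <- stats::setNames(c(rep(1, 10), rep(10, 10)), rownames(x))
  r1 <- ward_clusters(x, 2)
  r2 <- ward_clusters(x, 2)
  r3 <- pca_gate_clusters(x, 2)
  cons <- consensus_subpopulation(list(r1, r2, r3), score)
  expect_setequal(cons$members, rownames(x)[1:10])
  expect_equal(unname(cons$jaccard), rep(1, 3))

  # two methods nominating disjoint low-score clusters -> empty consensus
  fake <- function(labels) {
    structure(list(method = "fake", labels = labels, k = 2, params = list()),
              class = "clustering_result")
  }
  cells <- rownames(x)
  conflict_score <- stats::setNames(c(rep(1, 10), rep(0, 3), rep(2, 7)),
                                    cells)
  a <- fake(stats::setNames(rep(1:2, each = 10), cells))   # low: cells 1-10
  b <- fake(stats::setNames(c(rep(2L, 10), rep(1L, 3), rep(2L, 7)),
                            cells))                        # low: cells 11-13
  expect_warning(empty <- consensus_subpopulation(list(a, b), conflict_score),
                 "no consensus")
  expect_length(empty$members, 0)
})

test_that("planted low-transcription G1 subpopulation is recovered by consensus", {
  sim0 <- generate_dataset(sim_config(seed = 4))
  marker <- sim0$truth$phase_genes$gene[1]
  cfg <- sim_config(subpop = subpop_spec("G1", 0.3, -1.0, marker, 1.5),
                    seed = 4)
  sim <- generate_dataset(cfg)
  expr <- cq_to_molecules(sim$cq)
  lx <- log2_matrix(expr)
  totals <- total_transcripts(expr)
  g1 <- sim$annotation$cell_id[sim$annotation$phase == "G1"]
  sx <- autoscale(lx[g1, sim$truth$phase_genes$gene])
  scores <- pca_embed(sx, 2)$scores
  cons <- consensus_subpopulation(
    list(pca_gate_clusters(sx, 2), ward_clusters(scores, 2),
         som_clusters(scores, 3, seed = 4)),
    stats::setNames(totals$total, totals$cell_id)[g1])
  truth <- sim$truth$subpop_members
  expect_gte(length(intersect(cons$members, truth)) / length(cons$members),
             0.7)
  expect_gte(length(intersect(cons$members, truth)) / length(truth), 0.7)
})

test_that("volcano categories follow the fold-change and significance rules", {
  set.seed(11)
  n <- 10
  base <- matrix(stats::rnorm(2 * n * 4, 5, 0.2), 2 * n, 4,
                 dimnames = list(paste0("c", 1:(2 * n)),
                                 c("null", "strong", "weak2fold", "small_fc")))
  base[1:n, "strong"] <- base[1:n, "strong"] - 3       # huge, tiny p
  # exactly 2-fold mean difference ("at least two-fold" is inclusive)
  base[1:n, "weak2fold"] <- base[(n + 1):(2 * n), "weak2fold"] + 1
  base[1:n, "small_fc"] <- base[1:n, "small_fc"] + 0.5 # below 2-fold
  members <- paste0("c", 1:n)
  rest <- paste0("c", (n + 1):(2 * n))
  v <- volcano(base, members, rest, n_tests = 93)
  expect_equal(attr(v, "threshold"), 0.05 / 93)
  expect_equal(signif(attr(v, "threshold"), 2), 0.00054)
  cat_of <- function(g) v$category[v$gene == g]
  expect_equal(cat_of("null"), "not-regulated")
  expect_equal(cat_of("small_fc"), "not-regulated")
  expect_equal(cat_of("strong"), "green")
  expect_equal(v$log2_fc[v$gene == "weak2fold"], 1)
  expect_equal(cat_of("weak2fold"), "green")

  # category partition over >= 2-fold genes is exhaustive and exclusive
  reg <- v[abs(v$log2_fc) >= 1, ]
  expect_true(all(reg$category %in% c("red", "yellow", "green")))
  expect_true(all((reg$category == "green") == (reg$p_value < 0.05 / 93)))
  expect_error(volcano(base, members[1:2], rest), "3 cells")
})

test_that("subpopulation transcript contrast", {
  totals <- data.frame(cell_id = paste0("c", 1:12),
                       total = c(rep(50, 6), rep(100, 6)))
  res <- subpop_transcript_contrast(totals, paste0("c", 1:6),
                                    paste0("c", 7:12))
  expect_equal(res$percent_lower, 50)
  same <- subpop_transcript_contrast(totals, paste0("c", 1:3),
                                     paste0("c", 4:6))
  expect_equal(same$percent_lower, 0)
  expect_equal(same$p_value, 1)
})
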