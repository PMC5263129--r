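test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balanced_accuracy(matrix(c(9, 2, 1, 8), 2)), 0.85)
  expect_equal(balanced_accuracy(diag(c(12, 7))), 1)
  expect_equal(balanced_accuracy(matrix(c(10, 10, 0, 0), 2)), 0.5)
  expect_error(balanced_accuracy(matrix(c(0, 5, 0, 5), 2)), "zero")
})

test_that("fisher_exact_2x2: printed cases, degeneracies and input checks", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)),
               2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(3, 2, 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 0, 0), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "integer")
})

test_that("fisher_exact_2x2 matches stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:200) {
    tab <- matrix(stats::rpois(4, 4), 2)
    expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("forest OOB accounting is deterministic and complete", {
  set.seed(42)
  x <- matrix(stats::rnorm(40 * 6), 40, 6,
              dimnames = list(paste0("c", 1:40), paste0("g", 1:6)))
  y <- factor(rep(c("A", "B"), each = 20))
  f1 <- grow_forest(x, y, n_trees = 101, mtry = 2, seed = 5)
  f2 <- grow_forest(x, y, n_trees = 101, mtry = 2, seed = 5)
  expect_identical(f1, f2)
  expect_equal(unname(rowSums(f1$confusion)), c(20, 20))
  f3 <- grow_forest(x, y, n_trees = 101, mtry = 2, seed = 6)
  expect_false(identical(f1$importance, f3$importance))
})

test_that("a perfectly separating gene is found and carries the importance", {
  set.seed(9)
  x <- cbind(sep = rep(c(0, 4), each = 15), noise = stats::rnorm(30))
  rownames(x) <- paste0("c", 1:30)
  y <- factor(rep(c("A", "B"), each = 15))
  f <- grow_forest(x, y, n_trees = 51, mtry = 2, seed = 1)
  expect_equal(f$oob_error, 0)
  expect_equal(unname(f$importance["noise"]), 0)  # children pure after root
  # root Gini decrease is n * (1 - p^2 - q^2) for the bootstrap class split;
  # for n = 30 near-balanced classes this is just below 15 per tree
  expect_gt(unname(f$importance["sep"]), 13.5)
  expect_lt(unname(f$importance["sep"]), 15.01)
})

test_that("ensemble selects an mtry from the grid and reports coherent stats", {
  tc <- make_two_class(n_per = 15, n_genes = 12, n_signal = 6, delta = 2,
                       seed = 2)
  res <- train_forest_ensemble(tc$x, tc$y, n_forests = 6, n_trees = 100,
                               mtry_grid = c(1, 3, 6, 12), pilot_forests = 2,
                               seed = 3)
  expect_true(res$mtry %in% c(1, 3, 6, 12))
  expect_equal(res$mtry_scan$mtry, c(1, 3, 6, 12))
  expect_equal(unname(rowSums(res$confusion_mean)), c(15, 15),
               tolerance = 1e-9)
  expect_true(all(res$importance_mean >= 0))
  expect_gt(res$balanced_accuracy["mean"], 0.9)  # planted 4-fold signal
  expect_lt(res$fisher_p, 1e-4)
  # determinism
  res2 <- train_forest_ensemble(tc$x, tc$y, n_forests = 6, n_trees = 100,
                                mtry_grid = c(1, 3, 6, 12), pilot_forests = 2,
                                seed = 3)
  expect_equal(res$confusion_mean, res2$confusion_mean)
  expect_error(train_forest_ensemble(tc$x[1:8, ], factor(rep(c("A", "B"), 4)),
                                     n_forests = 2, n_trees = 10),
               ">= 5 cells")
})

test_that("planted informative genes rank at the top of the importance order", {
  hits <- vapply(1:10, function(s) {
    tc <- make_two_class(n_per = 15, n_genes = 8, n_signal = 2, delta = 2,
                         seed = 100 + s)
    res <- train_forest_ensemble(tc$x, tc$y, n_forests = 4, n_trees = 100,
                                 mtry_grid = c(1, 2, 4, 8), pilot_forests = 2,
                                 seed = s)
    all(tc$signal %in% rank_importances(res)[1:3])
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("single-gene task puts that gene first", {
  tc <- make_two_class(n_per = 10, n_genes = 1, n_signal = 1, delta = 3,
                       seed = 4)
  res <- train_forest_ensemble(tc$x, tc$y, n_forests = 3, n_trees = 50,
                               pilot_forests = 1, seed = 1)
  expect_equal(rank_importances(res), "g01")
})

test_that("ensemble-mean OOB error stabilizes as 1/sqrt(n_forests)", {
  tc <- make_two_class(n_per = 10, n_genes = 5, n_signal = 2, delta = 1,
                       noise_sd = 1, seed = 6)
  mean_oob <- function(n_forests, rep) {
    r <- train_forest_ensemble(tc$x, tc$y, n_forests = n_forests,
                               n_trees = 50, mtry_grid = 2,
                               pilot_forests = 1, seed = 1000 * rep)
    unname(r$oob_error["mean"])
  }
  sd_small <- stats::sd(vapply(1:15, function(r) mean_oob(5, r), numeric(1)))
  sd_large <- stats::sd(vapply(1:15, function(r) mean_oob(20, r), numeric(1)))
  expect_gt(sd_small / sd_large, 1.2)   # expected ratio 2 with wide tolerance
  expect_lt(sd_small / sd_large, 3.5)
})
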