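# Independent oracles and small fixtures used across the suite.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (no ties assumed); follows the two-sided convention min(1, 2*min(P<=, P>=)).
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  ws <- colSums(matrix(seq_len(n)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Adjusted Rand index between two partitions
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Mean silhouette width for a labelled partition (Euclidean)
silhouette_mean <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Gaussian blobs: one row of `centers` per cluster
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(stats::rnorm(n_per * ncol(centers),
                        mean = rep(centers[i, ], each = n_per), sd = sd),
           n_per)
  }))
  rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("g%02d", seq_len(ncol(x)))
  x
}

# Two-class log2 matrix with `n_signal` genes shifted by `delta` in class B
make_two_class <- function(n_per = 15, n_genes = 20, n_signal = 8, delta = 2,
                           noise_sd = 0.7, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(2 * n_per * n_genes, 5, noise_sd), 2 * n_per,
              n_genes)
  sig <- seq_len(n_signal)
  x[seq_len(n_per) + n_per, sig] <- x[seq_len(n_per) + n_per, sig] + delta
  dimnames(x) <- list(sprintf("c%03d", seq_len(2 * n_per)),
                      sprintf("g%02d", seq_len(n_genes)))
  list(x = x, y = factor(rep(c("A", "B"), each = n_per)),
       signal = colnames(x)[sig])
}

# coarse mtry grid used in scaled-down ensemble runs
coarse_grid <- function(p) unique(pmin(c(1, 2, 4, 8, 14, 20), p))
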