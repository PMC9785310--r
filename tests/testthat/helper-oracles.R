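# Independent oracle implementations used to cross-check the package.
# These are deliberately written as plain, slow reference code.

# Per-gene two-sample t statistic (Welch), first class vs second.
oracle_t_stats <- function(m, labels) {
  cls <- sort(unique(labels))
  a <- m[labels == cls[1], , drop = FALSE]
  b <- m[labels == cls[2], , drop = FALSE]
  va <- apply(a, 2, stats::var) / nrow(a)
  vb <- apply(b, 2, stats::var) / nrow(b)
  (colMeans(a) - colMeans(b)) / sqrt(va + vb)
}

# Nearest-centroid classifier, loop form.
oracle_nearest_centroid <- function(train_x, train_y, test_x) {
  classes <- sort(unique(train_y))
  cents <- lapply(classes, function(cl) {
    colMeans(train_x[train_y == cl, , drop = FALSE])
  })
  apply(test_x, 1, function(row) {
    d <- vapply(cents, function(ce) sum((row - ce)^2), numeric(1))
    classes[which.min(d)]
  })
}

# Dense solve of the cubic-RBF augmented system and direct evaluation.
oracle_rbf_predict <- function(points, values, probes) {
  t_n <- nrow(points)
  d <- ncol(points)
  phi <- matrix(0, t_n, t_n)
  for (i in seq_len(t_n)) {
    for (j in seq_len(t_n)) {
      phi[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))^3
    }
  }
  p_mat <- cbind(1, points)
  a_mat <- rbind(cbind(phi, p_mat), cbind(t(p_mat), matrix(0, d + 1, d + 1)))
  sol <- solve(a_mat, c(values, rep(0, d + 1)))
  lam <- sol[seq_len(t_n)]
  tail <- sol[t_n + seq_len(d + 1)]
  apply(probes, 1, function(h) {
    sum(lam * vapply(seq_len(t_n), function(i) {
      sqrt(sum((h - points[i, ])^2))^3
    }, numeric(1))) + tail[1] + sum(tail[-1] * h)
  })
}

# AUC as the Mann-Whitney pairwise-concordance statistic (ties = 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) {
    for (n in neg) {
      conc <- conc + (p > n) + 0.5 * (p == n)
    }
  }
  conc / (length(pos) * length(neg))
}

# Seeded uniform design, the random-search baseline.
with_seed_matrix <- function(seed, n, d) {
  set.seed(seed)
  matrix(runif(n * d), n, d)
}

# Deterministic label permutation for null-distribution checks.
with_seed_labels <- function(labels, seed) {
  set.seed(seed)
  labels[sample.int(length(labels))]
}

# A small well-separated two-class dataset, min-max normalized.
make_sep_dataset <- function(n = 60, genes = 100, informative = 30,
                             effect = 5, seed = 1) {
  d <- generate_dataset(generator_config(
    n_samples = n, n_genes = genes, n_informative = informative,
    effect_size = effect, seed = seed
  ))
  out <- normalize_dataset(d, "min_max")$dataset
  attr(out, "informative_genes") <- attr(d, "informative_genes")
  out
}
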