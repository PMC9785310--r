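# Binary particle swarm optimization (BPSO) wrapper feature selection.
#
# Each particle holds a continuous position x and velocity v per gene; the
# velocity update blends inertia, attraction to the particle's personal best
# (pbest) and to the swarm's global best (gbest):
#   v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x),   x <- x + v,
# with r1, r2 ~ Uniform(0,1) per dimension and v clamped to +/- v_max.
# Positions pass through a sigmoid to per-gene inclusion probabilities
# (canonical binary-PSO transfer); an all-zero mask is rescued by forcing
# one random bit. Fitness is a wrapper score: alpha * cross-validated
# accuracy of a fast reference classifier on the masked genes plus
# (1 - alpha) * sparsity bonus.

#' BPSO configuration
#'
#' @param n_particles Swarm size `m` (default 30).
#' @param n_iterations Number of update iterations (default 50).
#' @param c1,c2 Cognitive and social acceleration coefficients (default 2).
#' @param inertia_start,inertia_end Linearly decaying inertia weight
#'   schedule (defaults 0.9 to 0.4). Setting both to 1 recovers the
#'   inertia-free textbook update.
#' @param v_max Velocity clamp (default 4).
#' @param alpha Fitness weight between wrapper accuracy and sparsity, in
#'   `[0, 1]` (default 0.9).
#' @param classifier `"centroid"` (nearest centroid), `"majority"`
#'   (majority-class baseline, for calibration), or a function
#'   `(train_x, train_y, test_x) -> predicted labels`.
#' @param n_folds Stratified CV folds inside the fitness (default 3).
#' @param n_repeats CV repetitions averaged into the wrapper accuracy
#'   (default 5). Repetition refines the accuracy granularity from
#'   `1/n` to `1/(n * n_repeats)`, letting the swarm resolve the small
#'   accuracy gains of marginal genes against the sparsity bonus.
#' @param seed RNG seed.
#' @return A `pso_config` list.
#' @export
pso_config <- function(n_particles = 30L, n_iterations = 50L,
                       c1 = 2, c2 = 2,
                       inertia_start = 0.9, inertia_end = 0.4,
                       v_max = 4, alpha = 0.9,
                       classifier = "centroid", n_folds = 3L, n_repeats = 5L,
                       seed = 1L) {
  stopifnot(c1 >= 0, c2 >= 0, v_max > 0, alpha >= 0, alpha <= 1,
            inertia_end > 0, inertia_end <= inertia_start,
            n_particles >= 1, n_iterations >= 0, n_repeats >= 1)
  structure(
    list(n_particles = as.integer(n_particles),
         n_iterations = as.integer(n_iterations),
         c1 = c1, c2 = c2,
         inertia_start = inertia_start, inertia_end = inertia_end,
         v_max = v_max, alpha = alpha, classifier = classifier,
         n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
         seed = as.integer(seed)),
    class = "pso_config"
  )
}

#' One velocity/position update for a single particle
#'
#' `v' = inertia * v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with `r1, r2`
#' drawn Uniform(0,1) per dimension, `v'` clamped to `[-v_max, v_max]`, and
#' `x' = x + v'`.
#'
#' @param x,v Position and velocity vectors.
#' @param pbest,gbest Personal and global best position vectors.
#' @param c1,c2 Acceleration coefficients.
#' @param inertia Inertia weight.
#' @param v_max Velocity clamp (default `Inf` = unclamped).
#' @param r1,r2 Optional fixed random vectors (drawn from the current RNG
#'   stream when `NULL`); exposed so the update is unit-testable.
#' @return List with updated `x` and `v`.
#' @export
pso_update_particle <- function(x, v, pbest, gbest, c1, c2, inertia,
                                v_max = Inf, r1 = NULL, r2 = NULL) {
  d <- length(x)
  if (is.null(r1)) r1 <- stats::runif(d)
  if (is.null(r2)) r2 <- stats::runif(d)
  v <- inertia * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)
  v <- pmin(pmax(v, -v_max), v_max)
  list(x = x + v, v = v)
}

#' Map a continuous position to a binary gene mask
#'
#' Bit `d` is 1 with probability `sigmoid(x_d) = 1 / (1 + exp(-x_d))`. If
#' every bit comes out 0, one uniformly random bit is forced to 1 so the
#' mask always selects at least one gene.
#'
#' @param x Position vector.
#' @return Logical mask of the same length with at least one `TRUE`.
#' @export
binarize_position <- function(x) {
  p <- 1 / (1 + exp(-x))
  bits <- stats::runif(length(x)) < p
  if (!any(bits)) bits[sample.int(length(x), 1)] <- TRUE
  bits
}

# Nearest-centroid classifier: assign to the class with the closest
# training-set mean profile (Euclidean).
nearest_centroid_predict <- function(train_x, train_y, test_x) {
  classes <- sort(unique(train_y))
  cent <- vapply(classes, function(cl) {
    colMeans(train_x[train_y == cl, , drop = FALSE])
  }, numeric(ncol(train_x)))
  cent <- t(matrix(cent, nrow = ncol(train_x)))  # classes x genes, even for 1 gene
  # squared distances via ||a-b||^2 = ||a||^2 - 2 a.b + ||b||^2
  d2 <- outer(rowSums(test_x^2), rep(1, length(classes))) -
    2 * test_x %*% t(cent) +
    outer(rep(1, nrow(test_x)), rowSums(cent^2))
  classes[apply(d2, 1, which.min)]
}

# Deterministic stratified fold assignment (uses current RNG stream).
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Wrapper fitness of a gene mask
#'
#' `alpha * (repeated stratified k-fold CV accuracy of the reference
#' classifier on the masked genes) + (1 - alpha) * (1 - |mask| / D)`.
#' Deterministic given `config$seed`: every mask is scored against the same
#' `n_repeats` fold assignments.
#'
#' @param mask Logical gene mask (at least one gene selected).
#' @param dataset A normalized, imputed `expression_dataset`.
#' @param config A [pso_config()].
#' @return Fitness score in `[0, 1]`.
#' @export
pso_fitness <- function(mask, dataset, config) {
  if (!any(mask)) stop("mask must select at least one gene", call. = FALSE)
  acc <- mean(vapply(seq_len(config$n_repeats), function(r) {
    with_seed(derive_seed(config$seed, r), cv_accuracy(mask, dataset, config))
  }, numeric(1)))
  config$alpha * acc + (1 - config$alpha) * (1 - sum(mask) / length(mask))
}

cv_accuracy <- function(mask, dataset, config) {
  x <- dataset$matrix[, mask, drop = FALSE]
  y <- dataset$labels
  if (identical(config$classifier, "majority")) {
    maj <- names(which.max(table(y)))
    return(mean(y == maj))
  }
  predict_fun <- if (is.function(config$classifier)) {
    config$classifier
  } else {
    nearest_centroid_predict
  }
  k <- min(config$n_folds, min(table(y)))
  folds <- stratified_folds(y, k)
  correct <- 0L
  for (f in seq_len(k)) {
    te <- folds == f
    pred <- predict_fun(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

#' Run BPSO gene selection
#'
#' Standard global-best BPSO: positions initialized Uniform(-1, 1),
#' velocities Uniform(-v_max/2, v_max/2); inertia decays linearly from
#' `inertia_start` to `inertia_end` over the iterations; each particle's
#' mask is re-binarized and scored every iteration, and pbest/gbest track
#' the best mask each particle / the swarm has seen.
#'
#' @param dataset A normalized, imputed `expression_dataset`.
#' @param config A [pso_config()].
#' @return A `pso_result` list: `mask` (logical), `gene_ids` (selected),
#'   `score`, `trace` (per-iteration gbest score, length
#'   `n_iterations + 1` including the initial swarm), `config`.
#' @export
run_pso <- function(dataset, config) {
  stopifnot(inherits(dataset, "expression_dataset"), inherits(config, "pso_config"))
  d <- ncol(dataset$matrix)
  m <- config$n_particles
  with_seed(config$seed, {
    x <- matrix(stats::runif(m * d, -1, 1), m, d)
    v <- matrix(stats::runif(m * d, -config$v_max / 2, config$v_max / 2), m, d)
    masks <- lapply(seq_len(m), function(i) binarize_position(x[i, ]))
    scores <- vapply(masks, pso_fitness, numeric(1), dataset = dataset, config = config)
    pbest_x <- x
    pbest_score <- scores
    pbest_mask <- masks
    g <- which.max(scores)
    gbest_x <- x[g, ]
    gbest_score <- scores[g]
    gbest_mask <- masks[[g]]
    trace <- numeric(config$n_iterations + 1)
    trace[1] <- gbest_score

    iters <- config$n_iterations
    for (it in seq_len(iters)) {
      w <- if (iters == 1) config$inertia_start else {
        config$inertia_start -
          (config$inertia_start - config$inertia_end) * (it - 1) / (iters - 1)
      }
      for (i in seq_len(m)) {
        upd <- pso_update_particle(x[i, ], v[i, ], pbest_x[i, ], gbest_x,
                                   config$c1, config$c2, w, config$v_max)
        x[i, ] <- upd$x
        v[i, ] <- upd$v
        mask <- binarize_position(x[i, ])
        s <- pso_fitness(mask, dataset, config)
        if (s > pbest_score[i]) {
          pbest_score[i] <- s
          pbest_x[i, ] <- x[i, ]
          pbest_mask[[i]] <- mask
        }
        if (s > gbest_score) {
          gbest_score <- s
          gbest_x <- x[i, ]
          gbest_mask <- mask
        }
      }
      trace[it + 1] <- gbest_score
    }
    structure(
      list(mask = gbest_mask, gene_ids = dataset$gene_ids[gbest_mask],
           score = gbest_score, trace = trace, config = config),
      class = "pso_result"
    )
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("<pso_result> %d/%d genes selected, fitness %.4f (%d iterations)\n",
              sum(x$mask), length(x$mask), x$score, length(x$trace) - 1))
  invisible(x)
}

#' Write a BPSO selection result as structured text
#'
#' Lists the selected gene ids plus a run summary (final score and the
#' per-iteration gbest trace) for downstream stages and the CLI.
#'
#' @param result A `pso_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pso_result <- function(result, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("score\t%.17g", result$score),
    sprintf("n_selected\t%d", sum(result$mask)),
    sprintf("trace\t%s", paste(sprintf("%.17g", result$trace), collapse = ",")),
    "genes:",
    result$gene_ids
  ), con)
  invisible(path)
}
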