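# HORD: hyper-parameter optimization via an RBF surrogate with dynamic
# coordinate search.
#
# The loop: (1) evaluate an initial Latin-hypercube design of t0 points in
# the unit cube; (2) fit the cubic RBF surrogate to all evaluated points;
# (3) perturb the incumbent (best point so far) coordinate-wise, each
# coordinate independently with probability phi_t that decays
# logarithmically over the budget, by Normal(0, sigma^2) noise reflected
# back into [0,1]; (4) score the candidates by a weighted sum of the
# (negated, rescaled) surrogate prediction and the (rescaled) distance to
# previously evaluated points, and evaluate the true objective at the
# argmin; (5) append to the archive and repeat until n_max evaluations.
# The objective is MAXIMIZED; wrap losses by negation.

#' Define a mixed ordinal/categorical hyper-parameter space
#'
#' @param ... Named arguments, one per dimension, each a vector of levels
#'   (2 or more). Order of levels is meaningful for ordinal dimensions.
#' @param kinds Optional named character vector tagging dimensions as
#'   `"ordinal"` or `"categorical"` (informational; both map to level
#'   centers in `[0,1]`).
#' @return An `hp_space` object.
#' @export
hp_space <- function(..., kinds = NULL) {
  dims <- list(...)
  if (length(dims) == 0 || is.null(names(dims)) || any(names(dims) == "")) {
    stop("every dimension must be named", call. = FALSE)
  }
  if (any(lengths(dims) < 2)) stop("every dimension needs >= 2 levels", call. = FALSE)
  structure(list(dimensions = dims, names = names(dims), D = length(dims),
                 kinds = kinds),
            class = "hp_space")
}

#' The 10-dimensional CNN hyper-parameter space
#'
#' Neuron count, layer depth, kernel size, stride, activation, batch size,
#' kernel count, epochs, learning rate, and loss function, each over its
#' small discrete range (39366 configurations in total).
#'
#' @return An `hp_space` with `D = 10`.
#' @export
cnn_space <- function() {
  hp_space(
    neuron_count = c(8L, 16L, 32L),
    layer_depth = c(1L, 2L, 3L),
    kernel_size = c(1L, 2L, 3L),
    stride = c(1L, 2L, 3L),
    activation = c("sigmoid", "relu", "selu"),
    batch_size = c(8L, 16L, 32L),
    kernel_count = c(8L, 16L, 32L),
    epochs = c(20L, 50L, 100L),
    learning_rate = c(0.01, 0.001, 0.0001),
    loss = c("l2", "binary_crossentropy"),
    kinds = c(neuron_count = "ordinal", layer_depth = "ordinal",
              kernel_size = "ordinal", stride = "ordinal",
              activation = "categorical", batch_size = "ordinal",
              kernel_count = "ordinal", epochs = "ordinal",
              learning_rate = "ordinal", loss = "categorical")
  )
}

#' Encode a configuration into the unit cube / decode a point back
#'
#' A dimension with `k` levels maps level `i` (1-based) to the stratum
#' center `(i - 0.5) / k`; decoding rounds any point in `[0,1]` to the
#' nearest center, so `decode_point(encode_config(v)) == v` for every valid
#' configuration.
#'
#' @param values Named list (or vector) of one level per dimension.
#' @param space An [hp_space()].
#' @return `encode_config`: numeric vector in `[0,1]^D`;
#'   `decode_point`: named list of levels.
#' @export
encode_config <- function(values, space) {
  stopifnot(inherits(space, "hp_space"))
  vapply(space$names, function(nm) {
    lev <- space$dimensions[[nm]]
    i <- match(values[[nm]], lev)
    if (is.na(i)) {
      stop(sprintf("unknown level '%s' for dimension '%s'", values[[nm]], nm),
           call. = FALSE)
    }
    (i - 0.5) / length(lev)
  }, numeric(1))
}

#' @rdname encode_config
#' @param point Numeric vector in `[0,1]^D`.
#' @export
decode_point <- function(point, space) {
  stopifnot(inherits(space, "hp_space"), length(point) == space$D)
  out <- vector("list", space$D)
  names(out) <- space$names
  for (j in seq_len(space$D)) {
    lev <- space$dimensions[[j]]
    k <- length(lev)
    i <- min(k - 1, max(0, floor(point[j] * k)))
    out[[j]] <- lev[i + 1]
  }
  out
}

level_indices <- function(point, space) {
  vapply(seq_len(space$D), function(j) {
    k <- length(space$dimensions[[j]])
    min(k - 1L, max(0L, as.integer(floor(point[j] * k))))
  }, integer(1))
}

#' Latin-hypercube design on the unit cube
#'
#' Each column is an independent permutation of jittered strata:
#' `(perm(0..t0-1) + Uniform(0,1)) / t0`, so every column has exactly one
#' value in each stratum `[i/t0, (i+1)/t0)`.
#'
#' @param t0 Number of design points.
#' @param d Dimension.
#' @param seed Optional RNG seed (uses the current stream when `NULL`).
#' @return A `t0 x d` matrix with all entries in `[0, 1)`.
#' @export
latin_hypercube <- function(t0, d, seed = NULL) {
  stopifnot(t0 >= 1, d >= 1)
  draw <- function() {
    vapply(seq_len(d), function(j) {
      (sample.int(t0) - 1 + stats::runif(t0)) / t0
    }, numeric(t0)) |>
      matrix(nrow = t0)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Perturbation-probability schedule
#'
#' `phi_t = phi_0 * (1 - ln(t - t0 + 1) / ln(n_max - t0))`, clamped to
#' `[0, phi_0]`, with `phi_0 = min(20 / D, 1)`. Equals `phi_0` at `t = t0`
#' and decays to 0 as `t` approaches `n_max - 1`.
#'
#' @param t Current evaluation count (`t0 <= t < n_max`).
#' @param t0 Initial design size.
#' @param n_max Total evaluation budget (`>= t0 + 2`).
#' @param d Number of dimensions.
#' @return The perturbation probability `phi_t`.
#' @export
perturbation_probability <- function(t, t0, n_max, d) {
  if (n_max < t0 + 2) stop("n_max must be at least t0 + 2", call. = FALSE)
  if (t < t0 || t >= n_max) stop("t must satisfy t0 <= t < n_max", call. = FALSE)
  phi0 <- min(20 / d, 1)
  val <- phi0 * (1 - log(t - t0 + 1) / log(n_max - t0))
  min(max(val, 0), phi0)
}

#' Generate candidate points around the incumbent
#'
#' Each candidate perturbs every coordinate of the incumbent independently
#' with probability `phi`, adding Normal(0, sigma^2) noise; a candidate
#' where no coordinate was chosen gets one uniformly random coordinate
#' forced. Results are reflected back into `[0, 1]`.
#'
#' @param incumbent Numeric vector in `[0,1]^D`.
#' @param phi Per-coordinate perturbation probability.
#' @param sigma Perturbation standard deviation (encoded units).
#' @param n_candidates Number of candidates.
#' @return An `n_candidates x D` matrix in `[0,1]^D`.
#' @export
generate_candidates <- function(incumbent, phi, sigma, n_candidates) {
  d <- length(incumbent)
  sel <- matrix(stats::runif(n_candidates * d) < phi, n_candidates, d)
  none <- rowSums(sel) == 0
  if (any(none)) {
    forced <- sample.int(d, sum(none), replace = TRUE)
    sel[cbind(which(none), forced)] <- TRUE
  }
  delta <- matrix(0, n_candidates, d)
  delta[sel] <- stats::rnorm(sum(sel), 0, sigma)
  out <- sweep(delta, 2, incumbent, "+")
  # reflect into [0,1] (handles arbitrary overshoot)
  r <- abs(out) %% 2
  ifelse(r > 1, 2 - r, r)
}

#' Weighted candidate scores
#'
#' `W_cv` rescales the surrogate predictions so the highest-predicted
#' candidate scores 0 (all 1 when the predictions are constant); `W_dm`
#' rescales the distances to previously evaluated points so the farthest
#' candidate scores 0 (all 1 when degenerate); the final score is
#' `W = epsilon * W_cv + (1 - epsilon) * W_dm`, and the next point to
#' evaluate is the argmin (ties broken by lowest candidate index).
#'
#' @param surrogate_values Predicted objective values `S` per candidate.
#' @param distances Minimum Euclidean distance from each candidate to the
#'   evaluated points.
#' @param epsilon Weight in `[0, 1]` between the two criteria.
#' @return Numeric vector of scores `W`.
#' @export
weighted_scores <- function(surrogate_values, distances, epsilon) {
  if (length(surrogate_values) != length(distances)) {
    stop("surrogate_values and distances must have equal length", call. = FALSE)
  }
  s_max <- max(surrogate_values); s_min <- min(surrogate_values)
  w_cv <- if (s_max != s_min) (s_max - surrogate_values) / (s_max - s_min) else {
    rep(1, length(surrogate_values))
  }
  d_max <- max(distances); d_min <- min(distances)
  w_dm <- if (d_max != d_min) (d_max - distances) / (d_max - d_min) else {
    rep(1, length(distances))
  }
  epsilon * w_cv + (1 - epsilon) * w_dm
}

#' HORD optimizer configuration
#'
#' @param n_max Total objective-evaluation budget.
#' @param t0 Initial Latin-hypercube design size (default `2 * (D + 1)`,
#'   resolved at run time; must be at least `D + 1`).
#' @param n_candidates Candidates generated per iteration (default
#'   `100 * D`, resolved at run time).
#' @param sigma Initial perturbation standard deviation in encoded units
#'   (default 0.2). Halved after 3 consecutive non-improving iterations
#'   (floor 0.005) and doubled after 3 consecutive improvements (cap 0.2).
#' @param epsilon_cycle Cycling weight schedule for the candidate score
#'   (default `c(0.3, 0.5, 0.8, 0.95)`); a single value gives a fixed
#'   epsilon.
#' @param seed RNG seed.
#' @return An `hord_config` list.
#' @export
hord_config <- function(n_max = 50L, t0 = NULL, n_candidates = NULL,
                        sigma = 0.2, epsilon_cycle = c(0.3, 0.5, 0.8, 0.95),
                        seed = 1L) {
  stopifnot(sigma > 0, all(epsilon_cycle >= 0), all(epsilon_cycle <= 1))
  structure(list(n_max = as.integer(n_max), t0 = t0,
                 n_candidates = n_candidates, sigma = sigma,
                 epsilon_cycle = epsilon_cycle, seed = as.integer(seed)),
            class = "hord_config")
}

#' Run the HORD surrogate-optimization loop
#'
#' Maximizes `objective` over either a discrete [hp_space()] (the objective
#' receives a decoded named list of levels) or, when `space` is a plain
#' integer dimension, the continuous unit cube (the objective receives a
#' numeric vector). Candidates that decode to an already-evaluated
#' configuration are re-sampled up to 10 times, then accepted as archive
#' duplicates with the stored value copied (no re-evaluation). An objective
#' call that throws is recorded as a failed evaluation (value `NA`); more
#' than 10% failures aborts the run.
#'
#' @param objective Function to maximize.
#' @param space An [hp_space()], or an integer `D` for a continuous search
#'   over `[0,1]^D`.
#' @param config An [hord_config()].
#' @return An `hord_result`: `best_config` (decoded list or numeric point),
#'   `best_value`, `best_point` (encoded), `archive` (data frame with the
#'   evaluation order, per-dimension columns, `value`, `failed`),
#'   `incumbent_trace` (best value after each evaluation), `log` (per
#'   iteration: `t`, `phi`, `sigma`, `epsilon`, `incumbent`).
#' @export
run_hord <- function(objective, space, config = hord_config()) {
  discrete <- inherits(space, "hp_space")
  d <- if (discrete) space$D else as.integer(space)
  t0 <- if (is.null(config$t0)) 2L * (d + 1L) else as.integer(config$t0)
  n_cand <- if (is.null(config$n_candidates)) 100L * d else as.integer(config$n_candidates)
  n_max <- config$n_max
  if (t0 < d + 1) stop("t0 must be at least D + 1", call. = FALSE)
  if (n_max < t0 + 2) stop("n_max must be at least t0 + 2", call. = FALSE)

  eval_point <- function(pt) {
    arg <- if (discrete) decode_point(pt, space) else pt
    tryCatch(list(value = objective(arg), failed = FALSE),
             error = function(e) list(value = NA_real_, failed = TRUE,
                                      message = conditionMessage(e)))
  }
  point_key <- function(pt) {
    if (discrete) paste(level_indices(pt, space), collapse = ",") else {
      paste(sprintf("%.12f", pt), collapse = ",")
    }
  }

  with_seed(config$seed, {
    points <- latin_hypercube(t0, d)
    values <- numeric(t0)
    failed <- logical(t0)
    keys <- character(t0)
    for (i in seq_len(t0)) {
      keys[i] <- point_key(points[i, ])
      dup <- if (i > 1) match(keys[i], keys[seq_len(i - 1)]) else NA
      if (!is.na(dup) && discrete) {
        values[i] <- values[dup]
        failed[i] <- failed[dup]
      } else {
        r <- eval_point(points[i, ])
        values[i] <- r$value
        failed[i] <- r$failed
      }
    }
    sigma <- config$sigma
    n_fail_streak <- 0L
    n_succ_streak <- 0L
    log_rows <- list()
    trace <- cummax_na(values)

    t <- t0
    while (t < n_max) {
      if (sum(failed) > 0.1 * n_max) {
        stop(sprintf("aborting: %d of %d objective evaluations failed",
                     sum(failed), t), call. = FALSE)
      }
      valid <- which(!failed)
      inc_idx <- valid[which.max(values[valid])]
      incumbent <- points[inc_idx, ]
      inc_val <- values[inc_idx]

      model <- if (length(valid) >= d + 1) {
        suppressWarnings(rbf_fit(points[valid, , drop = FALSE], values[valid]))
      } else {
        NULL
      }

      phi <- perturbation_probability(t, t0, n_max, d)
      iter <- t - t0 + 1L
      eps <- config$epsilon_cycle[(iter - 1L) %% length(config$epsilon_cycle) + 1L]

      cands <- generate_candidates(incumbent, phi, sigma, n_cand)
      if (discrete) {
        # re-sample candidates colliding with evaluated configurations
        for (attempt in seq_len(10)) {
          ck <- apply(cands, 1, point_key)
          coll <- ck %in% keys
          if (!any(coll)) break
          cands[coll, ] <- generate_candidates(incumbent, phi, sigma, sum(coll))
        }
      }
      if (!is.null(model)) {
        s_vals <- predict(model, cands)
        dists <- candidate_min_dist(cands, points)
        w <- weighted_scores(s_vals, dists, eps)
        sel <- which.min(w)
      } else {
        sel <- 1L
      }
      h_star <- cands[sel, ]
      key <- point_key(h_star)
      dup <- match(key, keys)
      if (!is.na(dup) && discrete) {
        value <- values[dup]
        was_failed <- failed[dup]
      } else {
        r <- eval_point(h_star)
        value <- r$value
        was_failed <- r$failed
      }
      points <- rbind(points, h_star)
      values <- c(values, value)
      failed <- c(failed, was_failed)
      keys <- c(keys, key)
      t <- t + 1L

      improved <- !was_failed && !is.na(value) && value > inc_val
      if (improved) {
        n_succ_streak <- n_succ_streak + 1L
        n_fail_streak <- 0L
        if (n_succ_streak >= 3L) {
          sigma <- min(sigma * 2, 0.2)
          n_succ_streak <- 0L
        }
      } else {
        n_fail_streak <- n_fail_streak + 1L
        n_succ_streak <- 0L
        if (n_fail_streak >= 3L) {
          sigma <- max(sigma / 2, 0.005)
          n_fail_streak <- 0L
        }
      }
      trace <- c(trace, max(trace[length(trace)], if (was_failed) -Inf else value,
                            na.rm = TRUE))
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        t = t, phi = phi, sigma = sigma, epsilon = eps,
        incumbent = max(values[!failed], na.rm = TRUE)
      )
    }

    valid <- which(!failed)
    best_idx <- valid[which.max(values[valid])]
    best_point <- points[best_idx, ]
    archive <- as.data.frame(points)
    if (discrete) {
      decoded <- lapply(seq_len(nrow(points)), function(i) decode_point(points[i, ], space))
      archive <- as.data.frame(do.call(rbind, lapply(decoded, function(x) {
        lapply(x, function(v) v)
      })))
      archive[] <- lapply(archive, unlist)
      names(archive) <- space$names
    } else {
      names(archive) <- paste0("x", seq_len(d))
    }
    archive$value <- values
    archive$failed <- failed
    archive <- cbind(iteration = seq_len(nrow(archive)), archive)
    structure(
      list(
        best_config = if (discrete) decode_point(best_point, space) else best_point,
        best_value = values[best_idx],
        best_point = best_point,
        archive = archive,
        incumbent_trace = trace,
        log = if (length(log_rows)) do.call(rbind, log_rows) else NULL,
        config = config
      ),
      class = "hord_result"
    )
  })
}

# running maximum ignoring NA (failed evaluations)
cummax_na <- function(x) {
  out <- numeric(length(x))
  cur <- -Inf
  for (i in seq_along(x)) {
    if (!is.na(x[i]) && x[i] > cur) cur <- x[i]
    out[i] <- cur
  }
  out
}

candidate_min_dist <- function(cands, points) {
  d2 <- outer(rowSums(cands^2), rep(1, nrow(points))) -
    2 * cands %*% t(points) +
    outer(rep(1, nrow(cands)), rowSums(points^2))
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' @export
print.hord_result <- function(x, ...) {
  cat(sprintf("<hord_result> best value %.4f after %d evaluations\n",
              x$best_value, nrow(x$archive)))
  if (is.list(x$best_config)) {
    cat("  best configuration:\n")
    for (nm in names(x$best_config)) {
      cat(sprintf("    %s = %s\n", nm, format(x$best_config[[nm]])))
    }
  }
  invisible(x)
}

#' Write a HORD archive as CSV
#'
#' Columns: `iteration`, one column per hyper-parameter (by name), `value`,
#' `failed`.
#'
#' @param result An `hord_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hord_archive <- function(result, path) {
  utils::write.csv(result$archive, path, row.names = FALSE)
  invisible(path)
}
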