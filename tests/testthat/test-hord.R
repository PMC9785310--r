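test_that("level encoding maps to stratum centers and decoding inverts it", {
  sp <- cnn_space()
  expect_equal(sp$D, 10L)
  # all-zeros decodes to the first level of every dimension
  first <- decode_point(rep(0, 10), sp)
  expect_equal(first$neuron_count, 8L)
  expect_equal(first$layer_depth, 1L)
  expect_equal(first$loss, "l2")
  # middle level of a 3-level dimension sits at 0.5
  expect_equal(unname(encode_config(list(
    neuron_count = 8, layer_depth = 2, kernel_size = 1, stride = 1,
    activation = "sigmoid", batch_size = 8, kernel_count = 8, epochs = 20,
    learning_rate = 0.01, loss = "l2"
  ), sp)["layer_depth"]), 0.5)
  expect_error(encode_config(list(
    neuron_count = 9, layer_depth = 1, kernel_size = 1, stride = 1,
    activation = "sigmoid", batch_size = 8, kernel_count = 8, epochs = 20,
    learning_rate = 0.01, loss = "l2"
  ), sp), "unknown level")
})

test_that("encode/decode round-trips every one of the 39366 configurations", {
  sp <- cnn_space()
  grid <- do.call(expand.grid, c(lapply(sp$dimensions, seq_along),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  expect_equal(nrow(grid), 39366L)
  k <- lengths(sp$dimensions)
  # encode all rows at once: center (i - 0.5) / k per dimension
  enc <- sweep(sweep(as.matrix(grid), 2, 0.5, "-"), 2, k, "/")
  # decode all rows at once: floor(p * k) + 1 clamped
  dec <- sweep(enc, 2, k, "*")
  dec <- pmin(floor(dec) + 1, matrix(k, nrow(dec), ncol(dec), byrow = TRUE))
  expect_equal(unname(dec), unname(as.matrix(grid)))
  # spot-check the vectorized form against the package functions
  set.seed(7)
  for (i in sample.int(nrow(grid), 50)) {
    cfg <- Map(function(d, j) d[[j]], sp$dimensions, as.integer(grid[i, ]))
    expect_identical(decode_point(encode_config(cfg, sp), sp), cfg)
  }
})

test_that("latin hypercube designs put one point in every stratum", {
  lhs <- latin_hypercube(10, 4, seed = 2)
  expect_equal(dim(lhs), c(10L, 4L))
  expect_true(all(lhs >= 0 & lhs < 1))
  for (j in 1:4) {
    expect_equal(sort(floor(lhs[, j] * 10)), 0:9)
  }
  expect_equal(dim(latin_hypercube(1, 3, seed = 1)), c(1L, 3L))
  # stratification centers the column means on 0.5
  means <- vapply(1:200, function(s) {
    mean(latin_hypercube(10, 1, seed = s)[, 1])
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.03)
})

test_that("the perturbation probability schedule follows the printed rule", {
  expect_equal(perturbation_probability(8, 8, 58, 3), min(20 / 3, 1))
  expect_equal(perturbation_probability(10, 10, 60, 10), 1.0)  # phi0 = min(20/10, 1)
  expect_equal(perturbation_probability(17, 8, 58, 3),
               1 - log(10) / log(50), tolerance = 1e-12)
  # non-increasing in t, reaching 0 at the end of the budget
  phis <- vapply(8:57, perturbation_probability, numeric(1),
                 t0 = 8, n_max = 58, d = 3)
  expect_true(all(diff(phis) <= 0))
  expect_equal(phis[length(phis)], 0)
  expect_error(perturbation_probability(7, 8, 58, 3), "t0 <= t")
  expect_error(perturbation_probability(58, 8, 58, 3), "t0 <= t")
  expect_error(perturbation_probability(8, 8, 9, 3), "t0 \\+ 2")
})

test_that("candidate generation perturbs coordinates as scheduled and reflects", {
  inc <- rep(0.5, 6)
  set.seed(8)
  # phi = 0: exactly one forced coordinate differs
  cands <- generate_candidates(inc, 0, 0.2, 50)
  expect_equal(unname(rowSums(cands != rep(inc, each = 50))), rep(1, 50))
  # phi = 1: all coordinates perturbed; half-normal mean within 10%
  cands <- generate_candidates(inc, 1, 0.1, 2000)
  expect_equal(mean(abs(cands - 0.5)), 0.1 * sqrt(2 / pi), tolerance = 0.1)
  # reflection keeps everything in [0, 1] even with huge sigma
  cands <- generate_candidates(c(0.01, 0.99), 1, 0.5, 5e4)
  expect_true(all(cands >= 0 & cands <= 1))
})

test_that("weighted scores rescale surrogate value and distance per the rule", {
  w <- weighted_scores(c(0.9, 0.5, 0.7), c(0.3, 0.1, 0.2), 0.5)
  expect_equal(w, c(0, 1, 0.5))
  expect_equal(which.min(w), 1L)
  # degenerate branches give all-1 components
  expect_equal(weighted_scores(c(1, 1, 1), c(0.3, 0.1, 0.2), 1), c(1, 1, 1))
  expect_equal(weighted_scores(c(0.9, 0.5, 0.7), c(0.1, 0.1, 0.1), 0),
               c(1, 1, 1))
  # epsilon = 1 ignores distance entirely
  expect_equal(weighted_scores(c(0.9, 0.5, 0.7), c(0.3, 0.1, 0.2), 1),
               c(0, 1, 0.5))
  expect_error(weighted_scores(c(1, 2), c(1, 2, 3), 0.5), "equal length")
})

test_that("the optimizer spends its budget exactly and tracks the incumbent", {
  # flat landscape: any point works, value is the constant
  r <- run_hord(function(h) 1.25, space = 3L,
                config = hord_config(n_max = 12, t0 = 8, n_candidates = 20,
                                     seed = 1))
  expect_equal(nrow(r$archive), 12L)
  expect_equal(r$best_value, 1.25)
  expect_true(all(diff(r$incumbent_trace) >= 0))

  # monotone 1-D landscape: incumbent approaches the upper boundary
  r <- run_hord(function(h) h, space = 1L,
                config = hord_config(n_max = 40, t0 = 4, n_candidates = 100,
                                     seed = 3))
  expect_gte(r$best_value, 0.98)
  expect_length(r$incumbent_trace, 40)
})

test_that("runs are reproducible and duplicates/failures are handled", {
  obj <- function(h) -sum((h - 0.5)^2)
  cfg <- hord_config(n_max = 25, t0 = 8, n_candidates = 50, seed = 9)
  r1 <- run_hord(obj, space = 3L, config = cfg)
  r2 <- run_hord(obj, space = 3L, config = cfg)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$best_point, r2$best_point)
  # log has one row per post-design iteration
  expect_equal(nrow(r1$log), 25 - 8)
  expect_true(all(c("t", "phi", "sigma", "epsilon", "incumbent") %in%
                    names(r1$log)))

  # an always-failing objective aborts once failures exceed 10%
  expect_error(
    run_hord(function(h) stop("boom"), space = 2L,
             config = hord_config(n_max = 20, t0 = 5, n_candidates = 10,
                                  seed = 1)),
    "failed"
  )
})

test_that("discrete-space search returns a decoded configuration", {
  sp <- hp_space(a = c(1, 2, 3), b = c(10, 20), c = c(0.1, 0.2, 0.3))
  # objective prefers the largest level of every dimension
  obj <- function(cfg) cfg$a + cfg$b / 10 + cfg$c * 10
  r <- run_hord(obj, sp, hord_config(n_max = 30, t0 = 8, n_candidates = 60,
                                     seed = 4))
  expect_equal(nrow(r$archive), 30L)
  expect_named(r$best_config, c("a", "b", "c"))
  expect_equal(r$best_value, obj(r$best_config))
  expect_gte(r$best_value, obj(list(a = 3, b = 20, c = 0.3)) - 1e-9)
  f <- tempfile(fileext = ".csv")
  write_hord_archive(r, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 30L)
  expect_true(all(c("iteration", "a", "b", "c", "value") %in% names(back)))
})
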