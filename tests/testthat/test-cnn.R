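test_that("architecture shape arithmetic matches the convolution formula", {
  cfg <- cnn_config(layer_depth = 1, kernel_size = 3, stride = 1,
                    kernel_count = 16, neuron_count = 8)
  arch <- cnn_build(cfg, n_features = 100, n_classes = 2)
  types <- vapply(arch$layers, `[[`, "", "type")
  expect_equal(types, c("conv", "batchnorm", "maxpool", "dropout", "conv",
                        "flatten", "dense"))
  conv <- arch$layers[[1]]
  expect_equal(conv$out_len, 98L)            # (100 - 3) / 1 + 1
  pool <- arch$layers[[3]]
  expect_equal(pool$out_len, 49L)            # floor(98 / 2)
  proj <- arch$layers[[5]]
  expect_equal(proj$out_ch, 8L)              # neuron_count projection
  flat <- arch$layers[[6]]
  expect_equal(flat$out_dim, 49L * 8L)
  dense <- arch$layers[[7]]
  expect_equal(dense$out_dim, 1L)            # 2 classes + bce -> sigmoid unit
  # l2 loss keeps the softmax head even for 2 classes
  arch2 <- cnn_build(cnn_config(loss = "l2"), 100, 2)
  expect_equal(arch2$layers[[length(arch2$layers)]]$out_dim, 2L)

  # stride shrinks the map: (100 - 3) %/% 3 + 1 = 33
  arch3 <- cnn_build(cnn_config(layer_depth = 1, stride = 3), 100, 2)
  expect_equal(arch3$layers[[1]]$out_len, 33L)
})

test_that("infeasible configurations raise the dedicated condition", {
  expect_error(cnn_build(cnn_config(kernel_size = 3), 2, 2),
               class = "hordcnn_infeasible")
  # depth 3 with stride 3 collapses a short sequence
  expect_error(cnn_build(cnn_config(layer_depth = 3, stride = 3,
                                    kernel_size = 3), 10, 2),
               class = "hordcnn_infeasible")
  expect_error(cnn_config(neuron_count = 7), "invalid level")
})

test_that("training is deterministic and reaches high accuracy on separable data", {
  d <- make_sep_dataset(n = 40, genes = 60, informative = 20, effect = 5,
                        seed = 21)
  cfg <- cnn_config(epochs = 20)
  m1 <- cnn_train(d$matrix, d$labels, cfg, seed = 2)
  m2 <- cnn_train(d$matrix, d$labels, cfg, seed = 2)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_gte(utils::tail(m1$history$accuracy, 1), 0.95)
  # training-set predictions agree with the recorded training accuracy
  expect_equal(mean(predict_labels(m1, d$matrix) == d$labels),
               utils::tail(m1$history$accuracy, 1))
})

test_that("every activation and loss variant trains end to end", {
  d <- make_sep_dataset(n = 24, genes = 20, informative = 8, effect = 5,
                        seed = 22)
  for (act in c("relu", "sigmoid", "selu")) {
    for (loss in c("binary_crossentropy", "l2")) {
      m <- cnn_train(d$matrix, d$labels,
                     cnn_config(epochs = 20, activation = act, loss = loss,
                                layer_depth = 1, batch_size = 8),
                     seed = 3)
      expect_false(m$diverged)
      s <- predict(m, d$matrix)
      expect_equal(dim(s), c(24L, 2L))
      expect_equal(rowSums(s), rep(1, 24), tolerance = 1e-6)
    }
  }
})

test_that("three-class training uses a softmax head with rows summing to 1", {
  d <- generate_dataset(generator_config(
    n_samples = 36, n_genes = 30, n_informative = 10, effect_size = 5,
    class_proportions = c(ALL = 1 / 3, AML = 1 / 3, CML = 1 / 3), seed = 23
  ))
  nd <- normalize_dataset(d, "min_max")$dataset
  m <- cnn_train(nd$matrix, nd$labels, cnn_config(epochs = 20, batch_size = 8),
                 seed = 1)
  s <- predict(m, nd$matrix)
  expect_equal(dim(s), c(36L, 3L))
  expect_equal(rowSums(s), rep(1, 36), tolerance = 1e-6)
  expect_true(all(predict_labels(m, nd$matrix) %in% m$classes))
})

test_that("a sigmoid score of exactly 0.5 resolves to the first class", {
  d <- make_sep_dataset(n = 20, genes = 15, informative = 5, seed = 24)
  m <- cnn_train(d$matrix, d$labels,
                 cnn_config(epochs = 20, layer_depth = 1, batch_size = 8),
                 seed = 1)
  # zero the dense layer: the sigmoid unit outputs exactly 0.5 everywhere
  di <- which(vapply(m$architecture$layers, `[[`, "", "type") == "dense")
  m$params[[di]]$w[] <- 0
  m$params[[di]]$b[] <- 0
  s <- predict(m, d$matrix)
  expect_true(all(s == 0.5))
  expect_true(all(predict_labels(m, d$matrix) == m$classes[1]))
})

test_that("early stopping truncates the history and restores the best weights", {
  d <- make_sep_dataset(n = 40, genes = 40, informative = 10, effect = 3,
                        seed = 25)
  parts <- partition_dataset(d, split_spec(0.7, seed = 1))
  m <- cnn_train(parts$train$matrix, parts$train$labels,
                 cnn_config(epochs = 100, learning_rate = 0.01),
                 seed = 5,
                 validation = list(x = parts$test$matrix, y = parts$test$labels),
                 patience = 5)
  h <- m$history
  if (nrow(h) < 100) {
    best <- which.min(h$val_loss)
    expect_lte(best, nrow(h) - 5)           # stopped after `patience` bad epochs
    expect_true(all(h$val_loss[(best + 1):nrow(h)] >= h$val_loss[best] - 1e-9))
  }
  expect_true(all(c("val_loss", "val_accuracy") %in% names(h)))
})

test_that("prediction rejects mismatched feature widths", {
  d <- make_sep_dataset(n = 20, genes = 15, informative = 5, seed = 26)
  m <- cnn_train(d$matrix, d$labels,
                 cnn_config(epochs = 20, layer_depth = 1, batch_size = 8),
                 seed = 1)
  expect_error(predict(m, d$matrix[, 1:10]), "width")
  expect_error(predict_labels(m, d$matrix[, 1:10]), "width")
})

test_that("the holdout objective scores configurations in [0,1] and flags failures", {
  d <- make_sep_dataset(n = 60, genes = 100, informative = 30, effect = 5,
                        seed = 27)
  g <- objective_accuracy(cnn_config(epochs = 20), d, seed = 4)
  expect_gte(as.numeric(g), 0)
  expect_lte(as.numeric(g), 1)
  expect_false(attr(g, "failed"))
  # infeasible architecture: kernel wider than the feature count
  tiny <- d[, 1:2]
  g0 <- objective_accuracy(cnn_config(kernel_size = 3), tiny, seed = 4)
  expect_equal(as.numeric(g0), 0)
  expect_true(attr(g0, "failed"))
})

test_that("the default configuration recovers separable structure across seeds", {
  hits <- 0L
  for (s in 1:10) {
    d <- make_sep_dataset(n = 60, genes = 100, informative = 30, effect = 5,
                          seed = 100 + s)
    g <- objective_accuracy(cnn_config(), d, seed = s)
    if (as.numeric(g) >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("label shuffling pulls accuracy to chance and never helps", {
  g_int <- numeric(5)
  g_shuf <- numeric(5)
  for (s in 1:5) {
    d <- make_sep_dataset(n = 40, genes = 40, informative = 15, effect = 5,
                          seed = 200 + s)
    g_int[s] <- as.numeric(objective_accuracy(cnn_config(epochs = 20), d,
                                              seed = s))
    shuf <- d
    shuf$labels <- with_seed_labels(d$labels, s)
    g_shuf[s] <- as.numeric(objective_accuracy(cnn_config(epochs = 20), shuf,
                                               seed = s))
  }
  maj <- 47 / 72
  expect_lte(abs(mean(g_shuf) - maj), 0.15)
  expect_gte(mean(g_int), mean(g_shuf))
})
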