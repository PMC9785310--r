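test_that("generated datasets have the requested shape and exact class counts", {
  cfg <- generator_config(n_samples = 72, n_genes = 500, n_informative = 20,
                          seed = 4)
  d <- generate_dataset(cfg)
  expect_s3_class(d, "expression_dataset")
  expect_equal(dim(d$matrix), c(72L, 500L))
  expect_equal(unname(table(d$labels)[c("AML", "ALL")]),
               table(factor(c(rep("AML", 25), rep("ALL", 47))))[c("AML", "ALL")],
               ignore_attr = TRUE)
  expect_equal(d$n_classes, 2L)
  expect_true(all(d$matrix >= 0 & d$matrix <= cfg$value_scale))
  expect_true(all(d$matrix == round(d$matrix)))
  expect_equal(anyDuplicated(d$gene_ids), 0L)
})

test_that("class counts follow largest-remainder apportionment for any proportions", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    p <- stats::runif(k)
    p <- p / sum(p)
    names(p) <- paste0("C", seq_len(k))
    n <- sample(10:90, 1)
    d <- generate_dataset(generator_config(
      n_samples = n, n_genes = 10, n_informative = 2,
      class_proportions = p, seed = rep
    ))
    got <- as.integer(table(factor(d$labels, levels = names(p))))
    expect_equal(got, largest_remainder(n, p))
    expect_equal(sum(got), n)
  }
})

test_that("informative genes rank highly by an independent t-statistic oracle", {
  cfg <- generator_config(n_samples = 40, n_genes = 200, n_informative = 10,
                          effect_size = 3, seed = 1)
  d <- generate_dataset(cfg)
  tstat <- oracle_t_stats(d$matrix, d$labels)
  top20 <- d$gene_ids[order(abs(tstat), decreasing = TRUE)][1:20]
  expect_gte(sum(attr(d, "informative_genes") %in% top20), 8)
})

test_that("zero effect size leaves informative genes indistinguishable from noise", {
  d <- generate_dataset(generator_config(n_samples = 60, n_genes = 200,
                                         n_informative = 20, effect_size = 0,
                                         seed = 9))
  tstat <- abs(oracle_t_stats(d$matrix, d$labels))
  inf <- d$gene_ids %in% attr(d, "informative_genes")
  # same null distribution: mean |t| of the two groups within sampling noise
  expect_lt(abs(mean(tstat[inf]) - mean(tstat[!inf])), 0.5)
})

test_that("generation is deterministic down to the CSV bytes", {
  cfg <- generator_config(n_samples = 20, n_genes = 30, n_informative = 5,
                          missing_rate = 0.05, seed = 77)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_dataset(generate_dataset(cfg), f1)
  write_dataset(generate_dataset(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("nearest-centroid on informative genes separates strong-signal data", {
  # signal property: effect >= 3 and >= 10 informative genes give >= 90%
  # holdout accuracy in the majority of seeds
  hits <- 0L
  for (s in 1:20) {
    d <- generate_dataset(generator_config(n_samples = 60, n_genes = 50,
                                           n_informative = 10, effect_size = 3,
                                           seed = s))
    inf <- d$gene_ids %in% attr(d, "informative_genes")
    parts <- partition_dataset(d, split_spec(0.7, seed = s))
    pred <- oracle_nearest_centroid(parts$train$matrix[, inf],
                                    parts$train$labels,
                                    parts$test$matrix[, inf])
    if (mean(pred == parts$test$labels) >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 11L)
})

test_that("missing-value injection hits the requested rate and is reproducible", {
  d <- generate_dataset(generator_config(n_samples = 100, n_genes = 100,
                                         n_informative = 5, seed = 3))
  expect_identical(inject_missing(d, 0), d)
  m1 <- inject_missing(d, 0.1, seed = 5)
  m2 <- inject_missing(d, 0.1, seed = 5)
  expect_identical(which(is.na(m1$matrix)), which(is.na(m2$matrix)))
  expect_identical(m1$labels, d$labels)
  n_miss <- sum(is.na(m1$matrix))
  expect_gte(n_miss, qbinom(0.0005, 10000, 0.1))
  expect_lte(n_miss, qbinom(0.9995, 10000, 0.1))
  expect_error(inject_missing(d, 1), "rate")
})

test_that("CSV round-trip reproduces values, ids, labels and missing cells", {
  d <- expression_dataset(matrix(c(1, 2, 3, 4, NA, 6, 7, 8, 9, 10, 11, 12), 3, 4),
                          labels = c("ALL", "AML", "ALL"),
                          sample_ids = c("s1", "s2", "s3"),
                          gene_ids = c("g1", "g2", "g3", "g4"))
  f <- tempfile(fileext = ".csv")
  write_dataset(d, f)
  back <- read_dataset(f)
  expect_identical(back$matrix, d$matrix)
  expect_identical(back$labels, d$labels)
  expect_identical(back$sample_ids, d$sample_ids)
  expect_identical(back$gene_ids, d$gene_ids)
})

test_that("CSV parser reports shape and names malformed lines", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,label,g1,g2,g3,g4,g5",
               "s1,A,1,2,3,4,5",
               "s2,B,6,7,8,9,10"), f)
  d <- read_dataset(f)
  expect_equal(dim(d$matrix), c(2L, 5L))

  writeLines(c("sample_id,label,g1,g2,g3",
               "s1,A,1,2,3",
               "s2,B,1,2"), f)
  expect_error(read_dataset(f), "line 3")
  writeLines(c("id,label,g1", "s1,A,1"), f)
  expect_error(read_dataset(f), "line 1")
})

test_that("generator configuration is validated", {
  expect_error(generator_config(n_samples = 0), "positive")
  expect_error(generator_config(class_proportions = c(a = 0.5, b = 0.2)), "sum")
  expect_error(generator_config(n_genes = 5, n_informative = 10), "n_informative")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
})
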