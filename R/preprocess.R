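# Normalization, imputation, and train/test partitioning.
#
# Digit scaling maps a positive integer X with n decimal digits and leading
# digit F to ND = (X - F * 10^(n-1)) / 10^(n-1): it strips the leading digit
# and rescales by its place value, landing every value in [0, 1). It is
# stateless (per-value), so the same transform applies to unseen data with
# no stored statistics. Min-max scaling is the usual per-gene
# (x - min) / (max - min), with the statistics kept in a record so test data
# reuse the training-set ranges (no information leakage).

#' Digit-scaling normalization of integer values
#'
#' For a positive integer `X` with `n` decimal digits and leading digit `F`,
#' returns `(X - F * 10^(n-1)) / 10^(n-1)`, which lies in `[0, 1)`. By
#' convention 0 maps to 0; negative integers are transformed on their
#' absolute value and the sign restored. Vectorized.
#'
#' @param x Integer-valued numeric vector.
#' @return Numeric vector of the same length, each element in `(-1, 1)`
#'   (non-negative inputs give `[0, 1)`).
#' @examples
#' digit_scale(c(7129, 999, 5))  # 0.129, 0.99, 0
#' @export
digit_scale <- function(x) {
  if (any(!is.finite(x) & !is.na(x))) stop("x must be finite", call. = FALSE)
  ok <- !is.na(x)
  if (any(x[ok] != round(x[ok]))) {
    stop("digit scaling requires integer values; use min_max for real-valued data",
         call. = FALSE)
  }
  out <- x
  nz <- ok & x != 0
  ax <- abs(x[nz])
  n <- floor(log10(ax)) + 1
  place <- 10^(n - 1)
  f <- ax %/% place
  out[nz] <- sign(x[nz]) * (ax - f * place) / place
  out[ok & x == 0] <- 0
  out
}

#' Normalize an expression matrix into [0, 1]
#'
#' `digit_scaling` applies [digit_scale()] cell-wise (integer matrices only;
#' missing cells skipped). `min_max` rescales each gene column by its
#' observed range; constant columns map to 0. The returned record stores
#' what is needed to apply the identical transform to new data (per-gene
#' min/max for `min_max`; just the method tag for the stateless
#' `digit_scaling`).
#'
#' @param dataset An `expression_dataset`.
#' @param method `"digit_scaling"` or `"min_max"`.
#' @return A list with `dataset` (normalized) and `record` (a
#'   `normalization_record` reusable via [apply_normalization()]).
#' @export
normalize_dataset <- function(dataset, method = c("digit_scaling", "min_max")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  method <- match.arg(method)
  m <- dataset$matrix
  if (method == "digit_scaling") {
    vals <- digit_scale(as.vector(m))
    out <- matrix(vals, nrow(m), ncol(m))
    record <- structure(list(method = "digit_scaling"), class = "normalization_record")
  } else {
    mins <- apply(m, 2, min, na.rm = TRUE)
    maxs <- apply(m, 2, max, na.rm = TRUE)
    record <- structure(
      list(method = "min_max", min = mins, max = maxs, gene_ids = dataset$gene_ids),
      class = "normalization_record"
    )
    out <- min_max_apply(m, mins, maxs)
  }
  ds <- expression_dataset(out, dataset$labels, dataset$sample_ids, dataset$gene_ids)
  attr(ds, "informative_genes") <- attr(dataset, "informative_genes")
  list(dataset = ds, record = record)
}

min_max_apply <- function(m, mins, maxs) {
  rng <- maxs - mins
  out <- sweep(m, 2, mins, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out
}

#' Apply a stored normalization record to new data
#'
#' Re-applies the transform learned by [normalize_dataset()] — for `min_max`,
#' the training-set per-gene min/max — so test data are scaled consistently
#' with training data.
#'
#' @param dataset An `expression_dataset` with the same genes as the record.
#' @param record A `normalization_record`.
#' @return The normalized `expression_dataset`.
#' @export
apply_normalization <- function(dataset, record) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(record, "normalization_record"))
  if (record$method == "digit_scaling") {
    return(normalize_dataset(dataset, "digit_scaling")$dataset)
  }
  if (!identical(record$gene_ids, dataset$gene_ids)) {
    stop("record gene_ids do not match dataset", call. = FALSE)
  }
  out <- min_max_apply(dataset$matrix, record$min, record$max)
  ds <- expression_dataset(out, dataset$labels, dataset$sample_ids, dataset$gene_ids)
  attr(ds, "informative_genes") <- attr(dataset, "informative_genes")
  ds
}

#' Write / read a normalization record as structured text
#'
#' Plain-text serialization (method tag plus per-gene min/max for `min_max`)
#' so test-set transforms are bit-reproducible across runs.
#'
#' @param record A `normalization_record`.
#' @param path File path.
#' @return `path` invisibly (write); the record (read).
#' @export
write_normalization_record <- function(record, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("method\t", record$method), con)
  if (record$method == "min_max") {
    writeLines(sprintf("%s\t%.17g\t%.17g", record$gene_ids, record$min, record$max), con)
  }
  invisible(path)
}

#' @rdname write_normalization_record
#' @export
read_normalization_record <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  method <- sub("^method\t", "", lines[1])
  if (method == "digit_scaling") {
    return(structure(list(method = "digit_scaling"), class = "normalization_record"))
  }
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  structure(
    list(
      method = "min_max",
      min = as.numeric(vapply(parts, `[`, "", 2)),
      max = as.numeric(vapply(parts, `[`, "", 3)),
      gene_ids = vapply(parts, `[`, "", 1)
    ),
    class = "normalization_record"
  )
}

#' Impute missing expression values
#'
#' @param dataset An `expression_dataset` (possibly with `NA` cells).
#' @param strategy `"column_mean"`, `"column_median"`, or `"zero"`.
#' @return The dataset with no missing cells; non-missing cells unchanged.
#' @export
impute_missing <- function(dataset,
                           strategy = c("column_mean", "column_median", "zero")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  strategy <- match.arg(strategy)
  m <- dataset$matrix
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    if (strategy == "zero") {
      fill <- rep(0, ncol(m))
    } else {
      fun <- if (strategy == "column_mean") mean else stats::median
      cols <- unique(nas[, 2])
      all_na <- cols[colSums(!is.na(m[, cols, drop = FALSE])) == 0]
      if (length(all_na) > 0) {
        stop(sprintf("gene %s has no observed values; cannot impute",
                     dataset$gene_ids[all_na[1]]), call. = FALSE)
      }
      fill <- apply(m, 2, fun, na.rm = TRUE)
    }
    m[nas] <- fill[nas[, 2]]
  }
  ds <- expression_dataset(m, dataset$labels, dataset$sample_ids, dataset$gene_ids)
  attr(ds, "informative_genes") <- attr(dataset, "informative_genes")
  ds
}

#' Train/test split specification
#'
#' @param train_fraction Fraction of samples for training, in `(0, 1)`.
#' @param stratified Preserve class proportions across the split
#'   (default `TRUE`).
#' @param seed RNG seed for sample shuffling.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.7, stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition a dataset into train and test sets
#'
#' The training set holds exactly `floor(train_fraction * n)` samples. Under
#' stratification the per-class training counts come from largest-remainder
#' apportionment of the class sizes, so e.g. 72 samples at 0.7 give 50
#' train / 22 test, and at 0.8 give 57 / 15. Samples are shuffled within
#' class by the seed; train and test are disjoint and exhaustive.
#'
#' @param dataset An `expression_dataset`.
#' @param spec A [split_spec()].
#' @return A list with `train` and `test` `expression_dataset`s.
#' @export
partition_dataset <- function(dataset, spec) {
  stopifnot(inherits(dataset, "expression_dataset"), inherits(spec, "split_spec"))
  n <- nrow(dataset$matrix)
  n_train <- floor(spec$train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop("train_fraction leaves an empty train or test set", call. = FALSE)
  }
  with_seed(spec$seed, {
    if (spec$stratified) {
      tab <- table(dataset$labels)
      if (any(tab < 2)) {
        stop("stratified split needs >= 2 samples per class", call. = FALSE)
      }
      per_class <- largest_remainder(n_train, as.numeric(tab) / n)
      names(per_class) <- names(tab)
      train_idx <- integer(0)
      for (cl in names(tab)) {
        idx <- which(dataset$labels == cl)
        idx <- idx[sample.int(length(idx))]
        train_idx <- c(train_idx, idx[seq_len(per_class[[cl]])])
      }
      train_idx <- sort(train_idx)
    } else {
      train_idx <- sort(sample.int(n, n_train))
    }
    list(train = dataset[train_idx, ], test = dataset[setdiff(seq_len(n), train_idx), ])
  })
}
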