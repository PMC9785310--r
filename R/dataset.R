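# Labelled sample x gene expression container and the synthetic generator.
#
# The generator emulates the classic acute-leukemia microarray layout:
# 72 samples x 7129 genes, 2-4 classes (ALL/AML/CML/CLL), integer-valued
# intensities, p >> n, and a small informative-gene subset. Expression is
# drawn class-conditionally on the log scale, exponentiated and rounded,
# because microarray intensities are positive, right-skewed integers.

#' Construct an expression dataset
#'
#' A labelled sample-by-gene expression matrix: the core container passed
#' between every stage of the pipeline. Missing cells are `NA` in `matrix`.
#'
#' @param matrix Numeric matrix, samples in rows, genes in columns.
#' @param labels Character vector of per-sample class names.
#' @param sample_ids Character vector of sample identifiers
#'   (default `"S1"..."Sn"`).
#' @param gene_ids Character vector of unique gene identifiers
#'   (default `"G1"..."Gp"`).
#' @return An object of class `expression_dataset` with fields `matrix`
#'   (rownames = sample_ids, colnames = gene_ids), `sample_ids`, `gene_ids`,
#'   `labels`, and `n_classes`.
#' @export
expression_dataset <- function(matrix, labels, sample_ids = NULL, gene_ids = NULL) {
  matrix <- as.matrix(matrix)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(matrix)))
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(matrix)))
  labels <- as.character(labels)
  if (nrow(matrix) != length(sample_ids) || nrow(matrix) != length(labels)) {
    stop("matrix rows, sample_ids and labels must have equal length", call. = FALSE)
  }
  if (ncol(matrix) != length(gene_ids)) {
    stop("matrix columns and gene_ids must have equal length", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  dimnames(matrix) <- list(sample_ids, gene_ids)
  structure(
    list(
      matrix = matrix,
      sample_ids = as.character(sample_ids),
      gene_ids = as.character(gene_ids),
      labels = labels,
      n_classes = length(unique(labels))
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d samples x %d genes, %d classes (%s)\n",
    nrow(x$matrix), ncol(x$matrix), x$n_classes,
    paste(sprintf("%s: %d", names(table(x$labels)), table(x$labels)), collapse = ", ")
  ))
  n_miss <- sum(is.na(x$matrix))
  if (n_miss > 0) cat(sprintf("  %d missing cells (%.2f%%)\n", n_miss, 100 * n_miss / length(x$matrix)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Subset an expression dataset by samples and/or genes
#'
#' @param x An `expression_dataset`.
#' @param i Sample (row) index vector.
#' @param j Gene (column) index vector.
#' @param ... Unused.
#' @return An `expression_dataset` with the selected samples and genes.
#' @export
`[.expression_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$matrix))
  if (missing(j)) j <- seq_len(ncol(x$matrix))
  expression_dataset(
    x$matrix[i, j, drop = FALSE],
    labels = x$labels[i],
    sample_ids = x$sample_ids[i],
    gene_ids = x$gene_ids[j]
  )
}

#' Configuration for the synthetic expression-data generator
#'
#' Defaults reproduce the acute-leukemia microarray layout: 72 samples by
#' 7129 genes with two classes, ALL and AML, at 47/72 and 25/72.
#'
#' @param n_samples Number of samples (default 72).
#' @param n_genes Number of genes (default 7129).
#' @param class_proportions Named per-class fractions summing to 1; names are
#'   the class labels. Default `c(ALL = 47, AML = 25) / 72`.
#' @param n_informative Number of genes carrying class signal (default 50).
#' @param effect_size Mean shift of informative genes between classes, in
#'   units of the within-class standard deviation on the log scale
#'   (default 2).
#' @param value_scale Ceiling for the integer expression values
#'   (default 16000, a typical raw microarray intensity range).
#' @param missing_rate Fraction of cells set missing, in `[0, 1)` (default 0).
#' @param seed RNG seed (default 1).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 72L,
                             n_genes = 7129L,
                             class_proportions = c(ALL = 47, AML = 25) / 72,
                             n_informative = 50L,
                             effect_size = 2,
                             value_scale = 16000L,
                             missing_rate = 0,
                             seed = 1L) {
  if (n_samples < 1 || n_genes < 1) {
    stop("n_samples and n_genes must be positive", call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    stop("class_proportions must be non-negative and sum to 1", call. = FALSE)
  }
  if (n_informative > n_genes) {
    stop("n_informative must not exceed n_genes", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(names(class_proportions))) {
    names(class_proportions) <- paste0("C", seq_along(class_proportions))
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
      class_proportions = class_proportions,
      n_informative = as.integer(n_informative), effect_size = effect_size,
      value_scale = as.integer(value_scale), missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Generate a synthetic labelled expression dataset
#'
#' Class counts come from largest-remainder apportionment of the class
#' proportions (deterministic shape). Each gene has a baseline log-mean
#' drawn once; the first `n_informative` genes additionally shift their
#' class-conditional log-means apart by `effect_size` within-class standard
#' deviations (classes spread evenly across the shift range). Log-normal
#' draws are exponentiated, rounded, and clamped to `[0, value_scale]`.
#'
#' @param config A [generator_config()].
#' @return An `expression_dataset`; the identities of the informative genes
#'   are recorded in attribute `"informative_genes"` (gene ids) for use as a
#'   ground-truth oracle in recovery experiments.
#' @examples
#' d <- generate_dataset(generator_config(n_samples = 20, n_genes = 50, seed = 7))
#' table(d$labels)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_genes
    counts <- largest_remainder(n, config$class_proportions)
    labels <- rep(names(config$class_proportions), counts)
    k <- length(counts)

    # log-scale parameters: baseline per gene, within-class sd 0.5
    sd_log <- 0.5
    base <- stats::runif(p, min = log(50), max = log(config$value_scale / 4))
    mu <- matrix(base, nrow = k, ncol = p, byrow = TRUE)
    if (config$n_informative > 0 && k > 1) {
      idx <- seq_len(config$n_informative)
      # classes placed at -1/2, ..., +1/2 of the total shift range
      offsets <- (seq_len(k) - (k + 1) / 2) / (k - 1) * config$effect_size * sd_log
      # random sign per gene so signal direction varies
      sgn <- sample(c(-1, 1), config$n_informative, replace = TRUE)
      for (ci in seq_len(k)) {
        mu[ci, idx] <- mu[ci, idx] + sgn * offsets[ci]
      }
    }
    class_of <- rep(seq_len(k), counts)
    logx <- matrix(stats::rnorm(n * p, mean = mu[class_of, ], sd = sd_log), n, p)
    x <- pmin(pmax(round(exp(logx)), 0), config$value_scale)
    ds <- expression_dataset(x, labels = labels)
    attr(ds, "informative_genes") <- ds$gene_ids[seq_len(config$n_informative)]
    if (config$missing_rate > 0) {
      ds <- inject_missing(ds, config$missing_rate, seed = derive_seed(config$seed, 1L))
    }
    ds
  })
}

#' Flag a random fraction of cells as missing
#'
#' Each cell is independently set to `NA` with probability `rate`; labels and
#' identifiers are untouched. The mask is reproducible from `seed`.
#'
#' @param dataset An `expression_dataset`.
#' @param rate Missingness fraction in `[0, 1)`.
#' @param seed RNG seed.
#' @return The dataset with `NA`s injected.
#' @export
inject_missing <- function(dataset, rate, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(dataset)
  with_seed(seed, {
    mask <- stats::runif(length(dataset$matrix)) < rate
    m <- dataset$matrix
    m[mask] <- NA
    out <- expression_dataset(m, dataset$labels, dataset$sample_ids, dataset$gene_ids)
    attr(out, "informative_genes") <- attr(dataset, "informative_genes")
    out
  })
}

#' Write an expression dataset to CSV
#'
#' Format: header `sample_id,label,<gene ids...>`; one row per sample;
#' empty field = missing. UTF-8, comma-separated.
#'
#' @param dataset An `expression_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(
    sample_id = dataset$sample_ids,
    label = dataset$labels,
    dataset$matrix,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expression dataset from CSV
#'
#' Inverse of [write_dataset()]: expects columns `sample_id`, `label`, then
#' one column per gene; empty fields become `NA`. Malformed files raise a
#' parse error naming the offending line.
#'
#' @param path CSV file path.
#' @return An `expression_dataset`.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("parse error: file has no data rows", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "sample_id" || header[2] != "label") {
    stop("parse error at line 1: header must start with 'sample_id,label'",
         call. = FALSE)
  }
  nf <- length(header)
  fields <- strsplit(lines[-1], ",", fixed = TRUE)
  # trailing empty fields are dropped by strsplit; pad only those
  for (i in seq_along(fields)) {
    ncomma <- lengths(regmatches(lines[i + 1], gregexpr(",", lines[i + 1], fixed = TRUE)))
    got <- ncomma + 1
    if (got != nf) {
      stop(sprintf("parse error at line %d: %d fields, expected %d",
                   i + 1, got, nf), call. = FALSE)
    }
    if (length(fields[[i]]) < nf) fields[[i]] <- c(fields[[i]], rep("", nf - length(fields[[i]])))
  }
  tab <- do.call(rbind, fields)
  vals <- tab[, -(1:2), drop = FALSE]
  vals[vals == ""] <- NA
  m <- matrix(as.numeric(vals), nrow = nrow(tab))
  expression_dataset(m, labels = tab[, 2], sample_ids = tab[, 1],
                     gene_ids = header[-(1:2)])
}
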