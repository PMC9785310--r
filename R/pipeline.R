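# End-to-end orchestration: simulate/load -> preprocess -> select (BPSO) ->
# optimize (HORD) -> train (CNN) -> evaluate -> report.
#
# Stage order per experiment: normalize -> impute -> split -> BPSO on the
# training split only -> HORD with the objective evaluated inside the
# training split -> final training on the full training split -> test-set
# evaluation. Feature selection and hyper-parameter search never see the
# test partition. One global seed fans out to per-stage seeds via
# derive_seed(), so a run is reproducible from its config snapshot.

#' Pipeline configuration
#'
#' @param dataset A [generator_config()] (synthetic source) or a CSV path
#'   accepted by [read_dataset()].
#' @param normalization `"digit_scaling"` (stateless, applied before the
#'   split) or `"min_max"` (fitted on the training partition, applied to
#'   the test partition).
#' @param imputation Strategy for [impute_missing()].
#' @param splits Named list of [split_spec()]s, one per experiment; the
#'   defaults are the 70-30, 80-20 and non-stratified random partitions.
#' @param pso A [pso_config()] to enable BPSO gene selection, or `NULL` to
#'   skip.
#' @param hord An [hord_config()] to enable CNN hyper-parameter search over
#'   [cnn_space()], or `NULL` to skip (requires the CNN stage, which is
#'   always on).
#' @param cnn_default The [cnn_config()] used for the non-optimized arms.
#' @param select_on `"train"` (default, leak-free) or `"all"` to mimic
#'   whole-dataset selection for comparison.
#' @param out_dir Output directory for artifacts, or `NULL` for none.
#' @param seed Global RNG seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dataset = generator_config(),
                            normalization = c("digit_scaling", "min_max"),
                            imputation = "column_mean",
                            splits = list(
                              "(70-30)" = split_spec(0.7),
                              "(80-20)" = split_spec(0.8),
                              "Random" = split_spec(0.75, stratified = FALSE)
                            ),
                            pso = NULL, hord = NULL,
                            cnn_default = cnn_config(),
                            select_on = c("train", "all"),
                            out_dir = NULL, seed = 1L) {
  normalization <- match.arg(normalization)
  select_on <- match.arg(select_on)
  if (length(splits) < 1) stop("at least one split is required", call. = FALSE)
  if (is.null(names(splits)) || any(names(splits) == "")) {
    names(splits) <- paste0("Exp", seq_along(splits))
  }
  structure(
    list(dataset = dataset, normalization = normalization,
         imputation = imputation, splits = splits, pso = pso, hord = hord,
         cnn_default = cnn_default, select_on = select_on,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

macro_metrics <- function(truth, predicted) {
  tab <- per_class_report(truth, predicted)
  list(accuracy = mean(tab$accuracy), recall = mean(tab$recall),
       specificity = mean(tab$specificity), f1_score = mean(tab$f1_score),
       precision = mean(tab$precision))
}

train_and_eval <- function(train, test, config, seed) {
  model <- cnn_train(train$matrix, train$labels, config, seed = seed)
  pred <- predict_labels(model, test$matrix)
  scores <- predict(model, test$matrix)
  m <- macro_metrics(test$labels, pred)
  m$auc <- macro_auc(scores, test$labels)
  list(metrics = m, model = model, predicted = pred)
}

#' Run the full pipeline
#'
#' For every configured split, runs the enabled arms — CNN-only, PSO + CNN
#' (when `pso` is set), and PSO + HORD + CNN (when `hord` is set) — and
#' assembles the comparison report (one block per arm, each with its Mean
#' row). Metrics on the test partition are macro-averaged one-vs-rest
#' percentages.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print progress lines (default `FALSE`).
#' @return A `pipeline_run`: `report` (the assembled data frame), `arms`
#'   (per-arm per-experiment metrics and details), `config`, `timings`
#'   (seconds per stage), `artifacts` (paths written, if `out_dir` was
#'   set), `log` (character lines, one per HORD iteration among others),
#'   `version`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  timings <- c()
  tick <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[label]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # --- data -----------------------------------------------------------------
  raw <- tick("data", {
    if (inherits(config$dataset, "generator_config")) {
      generate_dataset(config$dataset)
    } else {
      read_dataset(config$dataset)
    }
  })
  say("dataset: %d samples x %d genes, %d classes",
      nrow(raw$matrix), ncol(raw$matrix), raw$n_classes)

  arms <- list()
  exp_names <- names(config$splits)
  has_missing <- anyNA(raw$matrix)

  for (e in seq_along(config$splits)) {
    ename <- exp_names[e]
    sp <- config$splits[[e]]
    sp$seed <- derive_seed(config$seed, 1000L + e)

    if (config$normalization == "digit_scaling") {
      norm <- normalize_dataset(raw, "digit_scaling")$dataset
      if (has_missing) norm <- impute_missing(norm, config$imputation)
      parts <- partition_dataset(norm, sp)
      train <- parts$train
      test <- parts$test
    } else {
      ds <- if (has_missing) impute_missing(raw, config$imputation) else raw
      parts <- partition_dataset(ds, sp)
      fit <- normalize_dataset(parts$train, "min_max")
      train <- fit$dataset
      test <- apply_normalization(parts$test, fit$record)
    }
    say("experiment %s: %d train / %d test", ename,
        nrow(train$matrix), nrow(test$matrix))

    # arm 1: CNN only
    res <- tick(paste0("cnn_", ename), {
      train_and_eval(train, test, config$cnn_default,
                     seed = derive_seed(config$seed, 2000L + e))
    })
    arms[["None"]][[ename]] <- res["metrics"]
    say("  CNN only: accuracy %.1f", res$metrics$accuracy)

    mask <- NULL
    if (!is.null(config$pso)) {
      pcfg <- config$pso
      pcfg$seed <- derive_seed(config$seed, 3000L + e)
      sel_data <- if (config$select_on == "train") train else {
        if (config$normalization == "digit_scaling") norm else stop(
          "select_on='all' requires digit_scaling normalization", call. = FALSE)
      }
      sel <- tick(paste0("pso_", ename), run_pso(sel_data, pcfg))
      mask <- sel$mask
      say("  PSO: %d/%d genes, fitness %.4f", sum(mask), length(mask), sel$score)
      res <- tick(paste0("psocnn_", ename), {
        train_and_eval(train[, mask], test[, mask], config$cnn_default,
                       seed = derive_seed(config$seed, 4000L + e))
      })
      arms[["PSO"]][[ename]] <- c(res["metrics"], list(selection = sel))
      say("  PSO + CNN: accuracy %.1f", res$metrics$accuracy)
    }

    if (!is.null(config$hord)) {
      if (is.null(mask)) mask <- rep(TRUE, ncol(train$matrix))
      hcfg <- config$hord
      hcfg$seed <- derive_seed(config$seed, 5000L + e)
      tr_masked <- train[, mask]
      obj_seed <- derive_seed(config$seed, 6000L + e)
      # infeasible/diverged configurations score 0 (flagged inside
      # objective_accuracy); the optimizer then steers away from them
      objective <- function(cfg) {
        as.numeric(objective_accuracy(cfg, tr_masked, seed = obj_seed))
      }
      hres <- tick(paste0("hord_", ename), {
        run_hord(objective, cnn_space(), hcfg)
      })
      if (!is.null(hres$log)) {
        for (i in seq_len(nrow(hres$log))) {
          say("  hord %s t=%d phi=%.4f sigma=%.4f epsilon=%.2f incumbent=%.4f",
              ename, hres$log$t[i], hres$log$phi[i], hres$log$sigma[i],
              hres$log$epsilon[i], hres$log$incumbent[i])
        }
      }
      best_cfg <- do.call(cnn_config, hres$best_config)
      res <- tick(paste0("hordcnn_", ename), {
        train_and_eval(train[, mask], test[, mask], best_cfg,
                       seed = derive_seed(config$seed, 7000L + e))
      })
      arms[["PSO + Hyper-parameter"]][[ename]] <-
        c(res["metrics"], list(hord = hres, best_config = best_cfg))
      say("  PSO + HORD + CNN: best G %.4f, test accuracy %.1f",
          hres$best_value, res$metrics$accuracy)
    }
  }

  # --- report ---------------------------------------------------------------
  blocks <- lapply(names(arms), function(fs) {
    reports <- lapply(exp_names, function(en) arms[[fs]][[en]]$metrics)
    experiment_report(reports, exp_names, feature_selection = fs,
                      classifier = "CNN")
  })
  report <- do.call(rbind, blocks)

  artifacts <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(config$out_dir, "report.csv")
    utils::write.csv(report, p, row.names = FALSE)
    artifacts <- c(artifacts, report = p)
    for (fs in names(arms)) {
      for (en in exp_names) {
        a <- arms[[fs]][[en]]
        tag <- gsub("[^A-Za-z0-9]+", "_", paste(fs, en))
        if (!is.null(a$selection)) {
          p <- file.path(config$out_dir, paste0("pso_", tag, ".txt"))
          write_pso_result(a$selection, p)
          artifacts <- c(artifacts, p)
        }
        if (!is.null(a$hord)) {
          p <- file.path(config$out_dir, paste0("hord_archive_", tag, ".csv"))
          write_hord_archive(a$hord, p)
          artifacts <- c(artifacts, p)
        }
      }
    }
    p <- file.path(config$out_dir, "run_log.txt")
    writeLines(log_lines, p)
    artifacts <- c(artifacts, log = p)
  }

  structure(
    list(report = report, arms = arms, config = config, timings = timings,
         artifacts = artifacts, log = log_lines,
         elapsed = round(proc.time()[["elapsed"]] - t_start, 3),
         version = as.character(utils::packageVersion("hordcnn"))),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> seed %d, %.1f s\n", x$config$seed, x$elapsed))
  format_report(x$report)
  invisible(x)
}
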