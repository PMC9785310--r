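# A 1-D convolutional network for expression profiles: standard
# backpropagation with Adam, with the convolution/batch-norm/pooling hot
# path in compiled kernels (src/cnn_kernels.cpp, im2col patch extraction +
# BLAS matrix products) and all stochastic steps driven by R's RNG.
#
# Architecture, per configuration: `layer_depth` blocks of
#   [conv1d(kernel_count filters, kernel_size, stride, activation)
#    -> batch normalization -> max-pool(width 2; skipped when length < 2)
#    -> dropout],
# the final block additionally projecting through `neuron_count` channels
# via a pointwise (width-1) convolution, then flatten -> dense output:
# softmax over n_classes, or a single sigmoid unit for 2 classes under
# binary cross-entropy. Losses: "l2" (mean squared error on one-hot
# targets) and "binary_crossentropy" (generalized to categorical
# cross-entropy for more than 2 classes).
#
# Activations are internal tensors of shape (batch, length, channels).

#' CNN hyper-parameter configuration
#'
#' One value per tuned dimension; defaults are a mid-range configuration.
#' Values are validated against [cnn_space()] levels.
#'
#' @param neuron_count Channels of the final pointwise projection (8/16/32).
#' @param layer_depth Number of convolutional blocks (1/2/3).
#' @param kernel_size Convolution kernel width (1/2/3).
#' @param stride Convolution stride (1/2/3).
#' @param activation `"sigmoid"`, `"relu"`, or `"selu"`.
#' @param batch_size Mini-batch size (8/16/32).
#' @param kernel_count Convolution filters per block (8/16/32).
#' @param epochs Maximum training epochs (20/50/100).
#' @param learning_rate Adam step size (0.01/0.001/0.0001).
#' @param loss `"l2"` or `"binary_crossentropy"`.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(neuron_count = 16L, layer_depth = 2L, kernel_size = 3L,
                       stride = 1L, activation = "relu", batch_size = 16L,
                       kernel_count = 16L, epochs = 50L, learning_rate = 0.001,
                       loss = "binary_crossentropy") {
  cfg <- list(neuron_count = as.integer(neuron_count),
              layer_depth = as.integer(layer_depth),
              kernel_size = as.integer(kernel_size),
              stride = as.integer(stride),
              activation = activation,
              batch_size = as.integer(batch_size),
              kernel_count = as.integer(kernel_count),
              epochs = as.integer(epochs),
              learning_rate = learning_rate,
              loss = loss)
  sp <- cnn_space()
  for (nm in sp$names) {
    if (!cfg[[nm]] %in% sp$dimensions[[nm]]) {
      stop(sprintf("invalid level '%s' for %s", format(cfg[[nm]]), nm), call. = FALSE)
    }
  }
  structure(cfg, class = "cnn_config")
}

infeasible <- function(msg) {
  stop(structure(class = c("hordcnn_infeasible", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Build the layer-by-layer architecture for a configuration
#'
#' Performs the shape arithmetic for every layer (valid convolution:
#' `out_len = floor((len - kernel) / stride) + 1`; pooling halves the
#' length) and fails with an infeasibility error (condition class
#' `hordcnn_infeasible`) when the sequence length collapses before the
#' dense layer or the kernel exceeds the input width.
#'
#' @param config A [cnn_config()].
#' @param n_features Input sequence length (number of genes).
#' @param n_classes Number of classes (>= 2).
#' @return A `cnn_architecture`: list of layer descriptors (`type`,
#'   shapes, parameter counts), plus `n_features`, `n_classes`,
#'   `output_units`, `config`.
#' @export
cnn_build <- function(config, n_features, n_classes) {
  stopifnot(inherits(config, "cnn_config"), n_classes >= 2)
  if (config$kernel_size > n_features) {
    infeasible(sprintf("kernel size %d exceeds feature count %d",
                       config$kernel_size, n_features))
  }
  layers <- list()
  len <- n_features
  ch <- 1L
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  for (b in seq_len(config$layer_depth)) {
    if (len < config$kernel_size) {
      infeasible(sprintf("sequence length %d shorter than kernel %d in block %d",
                         len, config$kernel_size, b))
    }
    out_len <- (len - config$kernel_size) %/% config$stride + 1L
    if (out_len < 1L) infeasible("sequence length collapsed to 0")
    add(list(type = "conv", kernel = config$kernel_size, stride = config$stride,
             in_ch = ch, out_ch = config$kernel_count, in_len = len,
             out_len = out_len, activation = config$activation,
             n_params = config$kernel_size * ch * config$kernel_count +
               config$kernel_count))
    len <- out_len
    ch <- config$kernel_count
    add(list(type = "batchnorm", channels = ch, n_params = 2L * ch))
    if (len >= 2L) {
      out_len <- len %/% 2L
      add(list(type = "maxpool", width = 2L, in_len = len, out_len = out_len))
      len <- out_len
    }
    add(list(type = "dropout", rate = 0.25))
    if (b == config$layer_depth) {
      # top-block projection through neuron_count channels (pointwise conv)
      add(list(type = "conv", kernel = 1L, stride = 1L, in_ch = ch,
               out_ch = config$neuron_count, in_len = len, out_len = len,
               activation = config$activation,
               n_params = ch * config$neuron_count + config$neuron_count))
      ch <- config$neuron_count
    }
  }
  if (len < 1L) infeasible("sequence length collapsed to 0 before dense layer")
  out_units <- if (n_classes == 2L && config$loss == "binary_crossentropy") 1L else n_classes
  add(list(type = "flatten", in_len = len, in_ch = ch, out_dim = len * ch))
  add(list(type = "dense", in_dim = len * ch, out_dim = out_units,
           head = if (out_units == 1L) "sigmoid" else "softmax",
           n_params = len * ch * out_units + out_units))
  structure(list(layers = layers, n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes), output_units = out_units,
                 config = config),
            class = "cnn_architecture")
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf("<cnn_architecture> input %d x 1, %d classes\n",
              x$n_features, x$n_classes))
  for (l in x$layers) {
    desc <- switch(l$type,
      conv = sprintf("conv1d  k=%d s=%d %d->%d ch, len %d->%d, %s",
                     l$kernel, l$stride, l$in_ch, l$out_ch, l$in_len, l$out_len,
                     l$activation),
      batchnorm = sprintf("batchnorm  %d ch", l$channels),
      maxpool = sprintf("maxpool  w=2, len %d->%d", l$in_len, l$out_len),
      dropout = sprintf("dropout  p=%.2f", l$rate),
      flatten = sprintf("flatten  %d x %d -> %d", l$in_len, l$in_ch, l$out_dim),
      dense = sprintf("dense  %d -> %d (%s)", l$in_dim, l$out_dim, l$head))
    cat("  ", desc, "\n", sep = "")
  }
  invisible(x)
}

# ---- layer forward/backward ------------------------------------------------

# patch-extraction column index for im2col, laid out (out_len, R) with
# R = kernel * in_ch rows of the conv weight matrix ordered r = (c-1)*K + k.
# With this layout xm[, idx] reshapes straight to a (nb*out_len, R) patch
# matrix with no aperm.
conv_col_index <- function(in_len, in_ch, kernel, stride, out_len) {
  idx <- matrix(0L, out_len, kernel * in_ch)
  for (c in seq_len(in_ch)) {
    for (k in seq_len(kernel)) {
      idx[, (c - 1L) * kernel + k] <-
        (c - 1L) * in_len + (seq_len(out_len) - 1L) * stride + k
    }
  }
  idx
}

act_code <- function(type) {
  switch(type, relu = 0L, sigmoid = 1L, selu = 2L)
}

conv_forward <- function(x, w, b, layer, idx) {
  nb <- dim(x)[1]
  xm <- x
  dim(xm) <- c(nb, layer$in_len * layer$in_ch)
  r <- cpp_conv_forward(xm, idx, w, b, act_code(layer$activation))
  out <- r$a
  dim(out) <- c(nb, layer$out_len, layer$out_ch)
  list(out = out, cache = list(p = r$p, z = r$z, a = r$a, nb = nb))
}

conv_backward <- function(dout, w, layer, idx, cache) {
  nb <- cache$nb
  dym <- dout
  dim(dym) <- c(nb * layer$out_len, layer$out_ch)
  r <- cpp_conv_backward(dym, cache$p, cache$z, cache$a, w, idx,
                         act_code(layer$activation), nb,
                         layer$in_len * layer$in_ch)
  dx <- r$dx
  dim(dx) <- c(nb, layer$in_len, layer$in_ch)
  list(dx = dx, dw = r$dw, db = as.vector(r$db))
}

bn_forward <- function(x, gamma, beta, running, training, momentum = 0.9,
                       eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(m, d[3])
  r <- cpp_bn_forward(xm, gamma, beta, running$mean, running$var, training,
                      momentum, eps)
  y <- r$y
  dim(y) <- d
  list(out = y,
       running = list(mean = as.vector(r$run_mean), var = as.vector(r$run_var)),
       cache = list(xhat = r$xhat, invstd = as.vector(r$invstd), dims = d))
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$dims
  dym <- dout
  dim(dym) <- c(d[1] * d[2], d[3])
  r <- cpp_bn_backward(dym, cache$xhat, cache$invstd, gamma)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dgamma = as.vector(r$dgamma), dbeta = as.vector(r$dbeta))
}

pool_forward <- function(x, layer) {
  o <- layer$out_len
  d <- dim(x)
  r <- cpp_pool_forward(as.vector(x), d[1], d[2], d[3], o)
  y <- r$y
  dim(y) <- c(d[1], o, d[3])
  list(out = y,
       cache = list(first = r$first, in_len = layer$in_len, nb = d[1],
                    f_dim = d[3], out_len = o))
}

pool_backward <- function(dout, cache) {
  dx <- cpp_pool_backward(as.vector(dout), cache$first, cache$nb,
                          cache$in_len, cache$f_dim, cache$out_len)
  dim(dx) <- c(cache$nb, cache$in_len, cache$f_dim)
  dx
}

# ---- the model -------------------------------------------------------------

init_params <- function(arch) {
  params <- list()
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$type == "conv") {
      fan_in <- l$kernel * l$in_ch
      sd <- if (l$activation == "sigmoid") sqrt(1 / fan_in) else sqrt(2 / fan_in)
      params[[i]] <- list(
        w = matrix(stats::rnorm(fan_in * l$out_ch, 0, sd), fan_in, l$out_ch),
        b = rep(0, l$out_ch))
    } else if (l$type == "batchnorm") {
      params[[i]] <- list(gamma = rep(1, l$channels), beta = rep(0, l$channels),
                          running = list(mean = rep(0, l$channels),
                                         var = rep(1, l$channels)))
    } else if (l$type == "dense") {
      sd <- sqrt(2 / (l$in_dim + l$out_dim))
      params[[i]] <- list(
        w = matrix(stats::rnorm(l$in_dim * l$out_dim, 0, sd), l$in_dim, l$out_dim),
        b = rep(0, l$out_dim))
    } else {
      params[[i]] <- list()
    }
  }
  params
}

forward_pass <- function(arch, params, x, training, dropout_rate, idx_cache) {
  caches <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$type == "conv") {
      r <- conv_forward(x, params[[i]]$w, params[[i]]$b, l, idx_cache[[i]])
      x <- r$out
      caches[[i]] <- r$cache
    } else if (l$type == "batchnorm") {
      r <- bn_forward(x, params[[i]]$gamma, params[[i]]$beta,
                      params[[i]]$running, training)
      x <- r$out
      params[[i]]$running <- r$running
      caches[[i]] <- r$cache
    } else if (l$type == "maxpool") {
      r <- pool_forward(x, l)
      x <- r$out
      caches[[i]] <- r$cache
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- array(stats::runif(length(x)) >= l$rate, dim(x))
        x <- x * mask / (1 - l$rate)
        caches[[i]] <- list(mask = mask, rate = l$rate)
      }
    } else if (l$type == "flatten") {
      caches[[i]] <- dim(x)
      dim(x) <- c(dim(x)[1], l$out_dim)
    } else if (l$type == "dense") {
      z <- x %*% params[[i]]$w
      z <- z + rep(params[[i]]$b, each = nrow(z))
      caches[[i]] <- list(x = x, z = z)
      x <- if (l$head == "softmax") {
        e <- exp(z - apply(z, 1, max))
        e / rowSums(e)
      } else {
        1 / (1 + exp(-z))
      }
    }
  }
  list(out = x, caches = caches, params = params)
}

# gradient of the loss w.r.t. the dense-layer pre-activations z
loss_grad_z <- function(probs, y_onehot, loss, head) {
  nb <- nrow(probs)
  if (head == "sigmoid") {
    # binary cross-entropy with a single sigmoid unit: dL/dz = p - y
    return((probs - y_onehot) / nb)
  }
  if (loss == "binary_crossentropy") {
    # categorical cross-entropy with softmax: dL/dz = p - y
    (probs - y_onehot) / nb
  } else {
    # mean squared error on one-hot targets through softmax:
    # dL/dp = 2 (p - y) / (nb * K); dz_i = p_i (dp_i - sum_j dp_j p_j)
    dp <- 2 * (probs - y_onehot) / (nb * ncol(probs))
    probs * (dp - rowSums(dp * probs))
  }
}

loss_value <- function(probs, y_onehot, loss, head) {
  eps <- 1e-12
  if (head == "sigmoid") {
    return(-mean(y_onehot * log(probs + eps) + (1 - y_onehot) * log(1 - probs + eps)))
  }
  if (loss == "binary_crossentropy") {
    -mean(log(rowSums(probs * y_onehot) + eps))
  } else {
    mean((probs - y_onehot)^2)
  }
}

backward_pass <- function(arch, params, caches, dz_dense) {
  grads <- vector("list", length(arch$layers))
  dx <- NULL
  for (i in rev(seq_along(arch$layers))) {
    l <- arch$layers[[i]]
    if (l$type == "dense") {
      cache <- caches[[i]]
      grads[[i]] <- list(w = crossprod(cache$x, dz_dense),
                         b = colSums(dz_dense))
      dx <- dz_dense %*% t(params[[i]]$w)
    } else if (l$type == "flatten") {
      dim(dx) <- caches[[i]]
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]])) {
        dx <- dx * caches[[i]]$mask / (1 - caches[[i]]$rate)
      }
    } else if (l$type == "maxpool") {
      dx <- pool_backward(dx, caches[[i]])
    } else if (l$type == "batchnorm") {
      r <- bn_backward(dx, params[[i]]$gamma, caches[[i]])
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dx <- r$dx
    } else if (l$type == "conv") {
      r <- conv_backward(dx, params[[i]]$w, l, attr(caches, "idx")[[i]], caches[[i]])
      grads[[i]] <- list(w = r$dw, b = r$db)
      dx <- r$dx
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) {
    lapply(p[names(p) %in% c("w", "b", "gamma", "beta")], function(v) {
      list(m = v * 0, v = v * 0)
    })
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

one_hot <- function(y_idx, k) {
  m <- matrix(0, length(y_idx), k)
  m[cbind(seq_along(y_idx), y_idx)] <- 1
  m
}

#' Train a 1-D CNN classifier
#'
#' Backpropagation with Adam at the configured learning rate; mini-batches
#' of `batch_size` (one epoch = every batch traversing the network once);
#' optional early stopping on validation loss with patience 10, restoring
#' the best weights. Fully deterministic given `(config, data, seed)`.
#'
#' @param x Numeric matrix, samples x features, values in `[0, 1]`.
#' @param y Character (or factor) class labels.
#' @param config A [cnn_config()].
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param validation Optional list `list(x = , y = )` used for the
#'   per-epoch validation metrics and early stopping.
#' @param early_stopping Enable early stopping when validation data are
#'   given (default `TRUE`).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param dropout_rate Dropout probability in each block (default 0.25).
#' @return A `cnn_model`: `architecture`, `params` (opaque weights),
#'   `classes`, `history` (per-epoch data frame with train/validation loss
#'   and accuracy), `config`, `seed`, `diverged` flag.
#' @export
cnn_train <- function(x, y, config = cnn_config(), seed = 1L,
                      validation = NULL, early_stopping = TRUE,
                      patience = 10L, dropout_rate = 0.25) {
  stopifnot(inherits(config, "cnn_config"))
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  arch <- cnn_build(config, ncol(x), length(classes))
  for (i in seq_along(arch$layers)) {
    if (arch$layers[[i]]$type == "dropout") arch$layers[[i]]$rate <- dropout_rate
  }
  y_idx <- match(y, classes)
  k_out <- arch$output_units
  targets <- if (k_out == 1L) matrix(y_idx - 1, ncol = 1) else one_hot(y_idx, k_out)

  idx_cache <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$type == "conv") {
      idx_cache[[i]] <- conv_col_index(l$in_len, l$in_ch, l$kernel, l$stride,
                                       l$out_len)
    }
  }

  with_seed(seed, {
    params <- init_params(arch)
    state <- adam_init(params)
    n <- nrow(x)
    history <- list()
    best_val <- Inf
    best_params <- NULL
    wait <- 0L
    step <- 0L
    diverged <- FALSE

    evaluate <- function(px, py_idx, pt) {
      fw <- forward_pass(arch, params, array(px, c(nrow(px), ncol(px), 1)),
                         training = FALSE, dropout_rate, idx_cache)
      lv <- loss_value(fw$out, pt, config$loss, if (k_out == 1L) "sigmoid" else "softmax")
      pred <- if (k_out == 1L) as.integer(fw$out[, 1] > 0.5) + 1L else {
        apply(fw$out, 1, which.max)
      }
      list(loss = lv, acc = mean(pred == py_idx))
    }
    val_targets <- NULL
    if (!is.null(validation)) {
      vy_idx <- match(as.character(validation$y), classes)
      val_targets <- if (k_out == 1L) matrix(vy_idx - 1, ncol = 1) else {
        one_hot(vy_idx, k_out)
      }
    }

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bi in batches) {
        xb <- array(x[bi, , drop = FALSE], c(length(bi), ncol(x), 1))
        fw <- forward_pass(arch, params, xb, training = TRUE, dropout_rate,
                           idx_cache)
        params <- fw$params  # batch-norm running stats updated in-place
        lv <- loss_value(fw$out, targets[bi, , drop = FALSE], config$loss,
                         if (k_out == 1L) "sigmoid" else "softmax")
        if (!is.finite(lv)) {
          diverged <- TRUE
          break
        }
        dz <- loss_grad_z(fw$out, targets[bi, , drop = FALSE], config$loss,
                          if (k_out == 1L) "sigmoid" else "softmax")
        caches <- fw$caches
        attr(caches, "idx") <- idx_cache
        grads <- backward_pass(arch, params, caches, dz)
        step <- step + 1L
        upd <- adam_step(params, grads, state, config$learning_rate, step)
        params <- upd$params
        state <- upd$state
      }
      if (diverged) break
      tr <- evaluate(x, y_idx, targets)
      row <- data.frame(epoch = epoch, loss = tr$loss, accuracy = tr$acc,
                        val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(validation)) {
        va <- evaluate(as.matrix(validation$x), vy_idx, val_targets)
        row$val_loss <- va$loss
        row$val_accuracy <- va$acc
        if (va$loss < best_val - 1e-9) {
          best_val <- va$loss
          best_params <- params
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      history[[epoch]] <- row
      if (!is.null(validation) && early_stopping && wait >= patience) break
    }
    if (!is.null(best_params)) params <- best_params
    structure(
      list(architecture = arch, params = params, classes = classes,
           history = do.call(rbind, history), config = config, seed = seed,
           diverged = diverged, idx_cache = idx_cache,
           dropout_rate = dropout_rate),
      class = "cnn_model"
    )
  })
}

#' Per-class prediction scores
#'
#' Softmax rows sum to 1; the sigmoid head returns the probability of the
#' second (alphabetically later) class alongside its complement, so the
#' returned matrix always has one column per class.
#'
#' @param object A `cnn_model`.
#' @param newdata Feature matrix with the training feature width.
#' @param ... Unused.
#' @return Numeric matrix, one row per sample, one column per class.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$architecture$n_features) {
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(x), object$architecture$n_features), call. = FALSE)
  }
  fw <- forward_pass(object$architecture, object$params,
                     array(x, c(nrow(x), ncol(x), 1)),
                     training = FALSE, object$dropout_rate, object$idx_cache)
  scores <- fw$out
  if (object$architecture$output_units == 1L) {
    scores <- cbind(1 - scores[, 1], scores[, 1])
  }
  colnames(scores) <- object$classes
  scores
}

#' Predicted class labels
#'
#' Argmax over the class scores (threshold 0.5 for the sigmoid head), ties
#' resolved to the lowest class index.
#'
#' @param model A `cnn_model`.
#' @param newdata Feature matrix.
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(model, newdata) {
  x <- as.matrix(newdata)
  if (ncol(x) != model$architecture$n_features) {
    stop("feature width does not match training width", call. = FALSE)
  }
  fw <- forward_pass(model$architecture, model$params,
                     array(x, c(nrow(x), ncol(x), 1)),
                     training = FALSE, model$dropout_rate, model$idx_cache)
  if (model$architecture$output_units == 1L) {
    model$classes[as.integer(fw$out[, 1] > 0.5) + 1L]
  } else {
    model$classes[apply(fw$out, 1, which.max)]
  }
}

#' @export
print.cnn_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<cnn_model> %d classes, %d epochs trained%s\n",
              length(x$classes), if (is.null(h)) 0L else nrow(h),
              if (x$diverged) " [diverged]" else ""))
  if (!is.null(h) && nrow(h) > 0) {
    last <- h[nrow(h), ]
    cat(sprintf("  final train loss %.4f, accuracy %.4f", last$loss, last$accuracy))
    if (!is.na(last$val_loss)) {
      cat(sprintf("; val loss %.4f, accuracy %.4f", last$val_loss, last$val_accuracy))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write trained-model metadata and history (structured text + CSV)
#'
#' The architecture and run metadata go to `<path>.txt` and the per-epoch
#' history to `<path>_history.csv`. Weights are R objects and are not
#' portable text; they stay in memory.
#'
#' @param model A `cnn_model`.
#' @param path Output path stem.
#' @return `path`, invisibly.
#' @export
write_cnn_metadata <- function(model, path) {
  con <- file(paste0(path, ".txt"), "w", encoding = "UTF-8")
  sink(con)
  print(model$architecture)
  cat(sprintf("seed\t%d\ndiverged\t%s\n", model$seed, model$diverged))
  sink()
  close(con)
  if (!is.null(model$history)) {
    utils::write.csv(model$history, paste0(path, "_history.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Holdout-accuracy objective for hyper-parameter search
#'
#' Evaluates a CNN configuration by stratified holdout within the supplied
#' (training) data: train on `train_fraction` of it, return validation
#' accuracy as the objective value `G` in `[0, 1]`. Infeasible
#' architectures and diverged trainings return `G = 0` with attribute
#' `failed = TRUE` instead of raising, so a surrogate optimizer can keep
#' running.
#'
#' @param config A [cnn_config()] or a named list of levels (as decoded by
#'   [run_hord()]).
#' @param dataset A preprocessed `expression_dataset`.
#' @param eval_spec A [split_spec()] for the inner holdout (default 80/20
#'   stratified).
#' @param seed RNG seed (fans out to the split and the training).
#' @param repeats Number of holdout repeats averaged into `G` (default 1).
#' @return Numeric `G` in `[0, 1]`, with attribute `failed`.
#' @export
objective_accuracy <- function(config, dataset,
                               eval_spec = split_spec(0.8, stratified = TRUE),
                               seed = 1L, repeats = 1L) {
  if (!inherits(config, "cnn_config")) config <- do.call(cnn_config, config)
  accs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    sp <- split_spec(eval_spec$train_fraction, eval_spec$stratified,
                     seed = derive_seed(seed, 100L + r))
    parts <- tryCatch(partition_dataset(dataset, sp), error = function(e) NULL)
    if (is.null(parts)) return(structure(0, failed = TRUE))
    model <- tryCatch(
      cnn_train(parts$train$matrix, parts$train$labels, config,
                seed = derive_seed(seed, 200L + r),
                validation = list(x = parts$test$matrix, y = parts$test$labels)),
      hordcnn_infeasible = function(e) NULL,
      error = function(e) NULL
    )
    if (is.null(model) || model$diverged) return(structure(0, failed = TRUE))
    accs[r] <- mean(predict_labels(model, parts$test$matrix) == parts$test$labels)
  }
  structure(mean(accs), failed = FALSE)
}
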