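# Base-graphics diagnostics for the search and training objects.

#' @importFrom graphics plot lines legend
NULL

#' Plot the HORD incumbent trace
#'
#' Best objective value found as a function of the number of evaluations.
#'
#' @param x An `hord_result`.
#' @param ... Passed to [plot()].
#' @export
plot.hord_result <- function(x, ...) {
  tr <- x$incumbent_trace
  plot(seq_along(tr), tr, type = "s", xlab = "objective evaluations",
       ylab = "best value", main = "HORD incumbent trace", ...)
  invisible(x)
}

#' Plot BPSO search progress
#'
#' Global-best fitness per iteration (iteration 0 is the initial swarm).
#'
#' @param x A `pso_result`.
#' @param ... Passed to [plot()].
#' @export
plot.pso_result <- function(x, ...) {
  plot(seq_along(x$trace) - 1, x$trace, type = "s", xlab = "iteration",
       ylab = "gbest fitness", main = "BPSO search progress", ...)
  invisible(x)
}

#' Plot CNN training history
#'
#' Train (and validation, when present) loss per epoch.
#'
#' @param x A `cnn_model`.
#' @param ... Passed to [plot()].
#' @export
plot.cnn_model <- function(x, ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0) {
    warning("no training history to plot", call. = FALSE)
    return(invisible(x))
  }
  ylim <- range(c(h$loss, h$val_loss), na.rm = TRUE)
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = ylim, main = "CNN training history", ...)
  if (any(!is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                     bty = "n")
  }
  invisible(x)
}
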