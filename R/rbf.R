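# Cubic radial-basis-function interpolation with a linear polynomial tail.
#
# The surrogate is S(h) = sum_d lambda_d * ||h - h_d||^3 + p(h) with p an
# affine polynomial p(h) = c_0 + c' h. Coefficients solve the standard
# augmented symmetric system
#
#   [ Phi  P ] [ lambda ]   [ f ]        Phi_ij = ||h_i - h_j||^3
#   [ P'   0 ] [   c    ] = [ 0 ],       P      = [1, h_1; ...; 1, h_t]
#
# whose second block row imposes the orthogonality side conditions
# sum_d lambda_d [1, h_d] = 0. The solve is exact (interpolation at every
# center); a ridge of 1e-8 on the Phi block is used as a fallback when the
# system is numerically singular (e.g. duplicate centers), and the model
# records that the fallback was taken.

rbf_phi <- function(a, b) {
  # pairwise Euclidean distances cubed, rows of a vs rows of b
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) -
    2 * a %*% t(b) +
    outer(rep(1, nrow(a)), rowSums(b^2))
  pmax(d2, 0)^1.5
}

#' Fit a cubic RBF interpolation surrogate
#'
#' @param points Numeric `t x D` matrix of evaluated points (the centers).
#' @param values Numeric length-`t` vector of objective values at the
#'   centers.
#' @param ridge Regularization added to the RBF block only when the exact
#'   solve fails (default `1e-8`).
#' @return An object of class `rbf_model` with fields `centers`,
#'   `rbf_coefficients` (lambda), `tail_coefficients` (length `D + 1`:
#'   intercept then linear terms), `dimension`, `n_points`, `values`, and
#'   `ridged` (`TRUE` if the ridge fallback was engaged).
#' @examples
#' m <- rbf_fit(matrix(c(0, 1, 2), 3, 1), c(0, 1, 8))
#' predict(m, 1.5)
#' @export
rbf_fit <- function(points, values, ridge = 1e-8) {
  points <- as.matrix(points)
  t_n <- nrow(points)
  d <- ncol(points)
  if (length(values) != t_n) stop("values length must match points rows", call. = FALSE)
  if (t_n < d + 1) {
    stop(sprintf("need at least D + 1 = %d points to fit, got %d", d + 1, t_n),
         call. = FALSE)
  }
  phi <- rbf_phi(points, points)
  p_mat <- cbind(1, points)
  a_mat <- rbind(cbind(phi, p_mat),
                 cbind(t(p_mat), matrix(0, d + 1, d + 1)))
  rhs <- c(values, rep(0, d + 1))
  sol <- tryCatch(solve(a_mat, rhs), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(sol) || any(!is.finite(sol))) {
    a_mat[seq_len(t_n), seq_len(t_n)] <- phi + diag(ridge, t_n)
    sol <- tryCatch(solve(a_mat, rhs), error = function(e) NULL)
    ridged <- TRUE
    if (is.null(sol)) {
      # last resort: minimum-norm least squares
      sol <- qr.coef(qr(a_mat, LAPACK = TRUE), rhs)
      sol[is.na(sol)] <- 0
    }
    warning("RBF system singular; ridge fallback engaged", call. = FALSE)
  }
  structure(
    list(centers = points, rbf_coefficients = sol[seq_len(t_n)],
         tail_coefficients = sol[t_n + seq_len(d + 1)],
         dimension = d, n_points = t_n, values = values, ridged = ridged),
    class = "rbf_model"
  )
}

#' Evaluate the RBF surrogate
#'
#' @param object An `rbf_model`.
#' @param newdata Numeric vector of length `D`, or an `n x D` matrix of
#'   points.
#' @param ... Unused.
#' @return Numeric vector of surrogate values.
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  h <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(h) != object$dimension) {
    stop(sprintf("point dimension %d does not match model dimension %d",
                 ncol(h), object$dimension), call. = FALSE)
  }
  phi <- rbf_phi(h, object$centers)
  as.vector(phi %*% object$rbf_coefficients +
              cbind(1, h) %*% object$tail_coefficients)
}

#' Add an evaluated point to an RBF surrogate
#'
#' Refits over the `t + 1` points (a full refit; the systems here are small
#' enough that incremental factorizations buy nothing). A point numerically
#' identical (within 1e-12) to an existing center is skipped with a warning
#' and the model returned unchanged.
#'
#' @param model An `rbf_model`.
#' @param new_point Numeric vector of length `D`.
#' @param new_value Objective value at the new point.
#' @return The refitted `rbf_model`.
#' @export
rbf_update <- function(model, new_point, new_value) {
  stopifnot(inherits(model, "rbf_model"))
  if (length(new_point) != model$dimension) {
    stop("point dimension does not match model dimension", call. = FALSE)
  }
  dmin <- min(sqrt(rowSums(sweep(model$centers, 2, new_point)^2)))
  if (dmin < 1e-12) {
    warning("duplicate center skipped; value recorded in archive only", call. = FALSE)
    return(model)
  }
  rbf_fit(rbind(model$centers, new_point), c(model$values, new_value))
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("<rbf_model> cubic + linear tail, %d centers in %d-D%s\n",
              x$n_points, x$dimension, if (x$ridged) " (ridged)" else ""))
  invisible(x)
}

#' Dump an RBF model to structured text (debugging aid)
#'
#' @param model An `rbf_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rbf_model <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("dimension\t%d", model$dimension),
    sprintf("n_points\t%d", model$n_points),
    sprintf("ridged\t%s", model$ridged),
    sprintf("tail\t%s", paste(sprintf("%.17g", model$tail_coefficients), collapse = ",")),
    "centers\tlambda\tvalue:",
    sprintf("%s\t%.17g\t%.17g",
            apply(model$centers, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")),
            model$rbf_coefficients, model$values)
  ), con)
  invisible(path)
}
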