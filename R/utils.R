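#' @keywords internal
#' @useDynLib hordcnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run `expr` under `set.seed(seed)`, restoring the caller's RNG state on exit
# so library functions never disturb the user's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Largest-remainder apportionment of integer counts
#'
#' Splits `n` items across groups in proportion to `proportions`, assigning
#' each group `floor(p * n)` and distributing the leftover units to the
#' groups with the largest fractional remainders (ties broken by group
#' order). Deterministic, and the result always sums to `n` exactly.
#'
#' @param n Total number of items (non-negative integer).
#' @param proportions Non-negative numeric vector summing to 1 (within 1e-9).
#' @return Integer vector of per-group counts summing to `n`.
#' @examples
#' largest_remainder(72, c(25, 47) / 72)  # exactly 25 and 47
#' @export
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  quota <- proportions * n
  counts <- floor(quota)
  left <- round(n - sum(counts))
  if (left > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Round half away from zero
#'
#' Presentation rounding for report tables (base [round()] rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed fans out to reproducible per-stage seeds. The map is a
#' fixed affine hash modulo the largest 32-bit prime, documented so runs can
#' be reconstructed stage by stage: `(seed * 48271 + index * 7919) mod
#' (2^31 - 1)`, with 0 mapped to 1.
#'
#' @param seed Global integer seed.
#' @param index Stage index (any non-negative integer; each stage uses its own).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 7919
  s <- s %% m
  as.integer(if (s == 0) 1 else s)
}
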