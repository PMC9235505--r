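# Random Fourier feature approximation of the Gaussian kernel.
#
# The map uses both cos and sin columns with normalizing constant 1/sqrt(D),
# so every mapped row has squared norm exactly 1 and Z %*% t(Z) has a unit
# diagonal — the property the exact Gaussian kernel also has.

#' Kernel-width heuristic from mean pairwise distance
#'
#' Draws `S` rows of `X` without replacement and returns the mean Euclidean
#' distance over the `S*(S-1)/2` distinct unordered pairs (the zero diagonal
#' is excluded and pairs are not double-counted). Uses the current RNG state;
#' call `set.seed()` beforehand for reproducibility.
#'
#' @param X Numeric matrix, samples in rows.
#' @param S Subset size, between 2 and `nrow(X)`; default `min(nrow(X), 1000)`.
#' @return Positive scalar bandwidth sigma.
#' @export
estimate_sigma <- function(X, S = min(nrow(X), 1000L)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to estimate sigma")
  S <- as.integer(S)
  if (S < 2L || S > n) stop("S must satisfy 2 <= S <= nrow(X)")
  rows <- if (S == n) seq_len(n) else sample.int(n, S)
  sigma <- mean(stats::dist(X[rows, , drop = FALSE]))
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate bandwidth: sampled rows are identical (mean distance 0)")
  }
  sigma
}

#' Sample a random Fourier feature map for the Gaussian kernel
#'
#' Frequencies `Delta` (one column per Fourier sample) are drawn i.i.d. from
#' the Fourier transform of the Gaussian kernel with width `sigma`: a
#' spherical zero-mean Gaussian with per-coordinate standard deviation
#' `1/sigma`. Offsets `b` are uniform on `[0, 2*pi)`. Uses the current RNG
#' state.
#'
#' @param input_dim Number of input features d.
#' @param D Number of random Fourier samples (the map has 2D output columns).
#' @param sigma Gaussian kernel width, > 0.
#' @return An `rff_map`: list with `sigma`, `Delta` (d x D), `offsets`
#'   (length D), `D`, `input_dim`.
#' @export
rff_sample_map <- function(input_dim, D, sigma) {
  input_dim <- as.integer(input_dim)
  D <- as.integer(D)
  if (D < 1L) stop("D must be a positive integer")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  Delta <- matrix(stats::rnorm(input_dim * D, sd = 1 / sigma),
                  nrow = input_dim, ncol = D)
  offsets <- stats::runif(D, 0, 2 * pi)
  structure(
    list(sigma = sigma, Delta = Delta, offsets = offsets,
         D = D, input_dim = input_dim),
    class = "rff_map"
  )
}

#' Apply a random Fourier feature map
#'
#' Computes `Z = (1/sqrt(D)) [cos(X Delta + b) | sin(X Delta + b)]`, an
#' `N x 2D` matrix. Every row of `Z` has unit Euclidean norm, and
#' `Z %*% t(Z)` approximates the exact Gaussian kernel matrix. Deterministic
#' given the map: all randomness lives in [rff_sample_map()].
#'
#' @param X Numeric matrix `N x input_dim`.
#' @param map An `rff_map`.
#' @return Numeric matrix `N x 2D`.
#' @export
rff_transform <- function(X, map) {
  stopifnot(inherits(map, "rff_map"))
  X <- as.matrix(X)
  if (ncol(X) != map$input_dim) {
    stop("dimension mismatch: X has ", ncol(X), " columns, map expects ",
         map$input_dim)
  }
  A <- sweep(X %*% map$Delta, 2L, map$offsets, `+`)
  cbind(cos(A), sin(A)) / sqrt(map$D)
}

#' Exact Gaussian kernel matrix
#'
#' `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`. Serves as the oracle against
#' which the random-feature approximation is checked.
#'
#' @param X Numeric matrix, samples in rows.
#' @param Y Numeric matrix with the same column count (default `X`).
#' @param sigma Kernel width, > 0.
#' @return `nrow(X) x nrow(Y)` kernel matrix with entries in (0, 1].
#' @export
gaussian_kernel <- function(X, Y = X, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same column count")
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0  # guard FP negatives
  exp(-d2 / (2 * sigma^2))
}

#' @export
print.rff_map <- function(x, ...) {
  cat("rff_map: input_dim =", x$input_dim, ", D =", x$D,
      ", sigma =", format(x$sigma, digits = 4), "\n")
  invisible(x)
}
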