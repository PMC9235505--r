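# Independent oracles and small fixture builders used across the suite.

# Brute-force AUROC over all positive-negative pairs, ties counted one half.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# Reference group-lasso optimizer, independent of the package's solver:
# BFGS on the objective with each block norm smoothed to
# sqrt(||b||^2 + eps^2). The smoothed optimum is within lambda * P * eps of
# the true optimum, far below the comparison tolerance.
reference_group_lasso_objective <- function(Z, y, lambda, weights, cols,
                                            eps = 1e-8) {
  obj <- function(par) {
    b0 <- par[1]; beta <- par[-1]
    s <- 2 * y - 1
    u <- -s * (b0 + drop(Z %*% beta))
    loss <- sum(pmax(u, 0) + log1p(exp(-abs(u))))
    pen <- sum(vapply(seq_along(cols), function(p) {
      weights[p] * sqrt(sum(beta[cols[[p]]]^2) + eps^2)
    }, 0))
    loss + lambda * pen
  }
  grad <- function(par) {
    b0 <- par[1]; beta <- par[-1]
    r <- stats::plogis(b0 + drop(Z %*% beta)) - y
    g <- drop(crossprod(Z, r))
    for (p in seq_along(cols)) {
      ix <- cols[[p]]
      g[ix] <- g[ix] +
        lambda * weights[p] * beta[ix] / sqrt(sum(beta[ix]^2) + eps^2)
    }
    c(sum(r), g)
  }
  fit <- stats::optim(rep(0, ncol(Z) + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 3000, reltol = 1e-14))
  fit$value
}

# Small random group-lasso instance with both classes present.
random_gl_instance <- function(N = 40L, P = 3L, width = 8L) {
  Z <- matrix(stats::rnorm(N * P * width), N, P * width)
  y <- sample(rep(c(0L, 1L), length.out = N))
  list(Z = Z, y = y,
       gs = group_structure(rep(seq_len(P), each = width)))
}

# Tiny GMT file on disk; returns its path (session tempdir, cleaned on exit).
write_tiny_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# Small synthetic dataset for fast end-to-end tests.
small_synthetic <- function(seed = 7L, N = 120L, d = 60L, P = 6L,
                            genes_per_set = 10L, k_informative = 2L) {
  generate_dataset(synthetic_spec(N = N, d = d, P = P,
                                  genes_per_set = genes_per_set,
                                  k_informative = k_informative,
                                  seed = seed))
}
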