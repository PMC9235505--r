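# Synthetic expression-like data with named gene sets and a known nonlinear
# (radial) pathway signal. The generator targets the statistical structure
# the method exploits — correlated gene blocks, set-level nonlinearity —
# not sequencing physics (no count marginals or library-size effects).

#' Specification for a synthetic expression dataset
#'
#' @param N Number of samples.
#' @param d Number of genes.
#' @param P Number of gene sets.
#' @param genes_per_set Genes per set; sets are disjoint consecutive blocks
#'   unless `overlap_fraction > 0`.
#' @param k_informative Number of sets carrying signal.
#' @param rho Within-set equicorrelation in \[0, 1).
#' @param signal_scale Effect size: the standardized set-level signal is
#'   multiplied by this before unit-variance noise is added.
#' @param label_noise Label flip probability in \[0, 0.5).
#' @param overlap_fraction Fraction of each set's genes shared with the next
#'   set (default 0 = disjoint sets).
#' @param seed Integer seed driving every random draw.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(N = 500L, d = 500L, P = 20L, genes_per_set = 25L,
                           k_informative = 3L, rho = 0.5, signal_scale = 6,
                           label_noise = 0.05, overlap_fraction = 0,
                           seed = 7L) {
  spec <- list(N = as.integer(N), d = as.integer(d), P = as.integer(P),
               genes_per_set = as.integer(genes_per_set),
               k_informative = as.integer(k_informative), rho = rho,
               signal_scale = signal_scale, label_noise = label_noise,
               overlap_fraction = overlap_fraction, seed = as.integer(seed))
  if (spec$k_informative > spec$P) stop("k_informative must be <= P")
  if (spec$rho < 0 || spec$rho >= 1) stop("rho must be in [0, 1)")
  if (spec$label_noise < 0 || spec$label_noise >= 0.5) {
    stop("label_noise must be in [0, 0.5)")
  }
  if (spec$overlap_fraction < 0 || spec$overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  if (spec$P * spec$genes_per_set > spec$d) {
    stop("P * genes_per_set must not exceed d")
  }
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic expression dataset with known informative sets
#'
#' Genes in each set are equicorrelated Gaussians (correlation `rho` within a
#' set, independent across sets); leftover genes are independent noise. Each
#' informative set p contributes a radial bump
#' `exp(-||u_p - c_p||^2 / (4 * genes_per_set))` with a fixed random center
#' `c_p` drawn once per dataset. The summed bump signal is standardized,
#' scaled by `signal_scale`, degraded with unit-variance Gaussian noise,
#' thresholded at its median (balancing the classes), and finally labels are
#' flipped with probability `label_noise`. The radial signal has essentially
#' no linear component, so a linear classifier on raw genes cannot exploit
#' it — the property that motivates kernels.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `X` (N x d matrix, gene column names `G0001...`,
#'   sample row names `S0001...`), `y` (0/1 labels), `sets` (unresolved
#'   [feature_set_collection()], names `SET01...`), `informative`
#'   (character vector of ground-truth set names).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  N <- spec$N; d <- spec$d; P <- spec$P; gps <- spec$genes_per_set
  gene_names <- sprintf("G%04d", seq_len(d))
  set_names <- sprintf("SET%02d", seq_len(P))

  # membership: consecutive blocks, optionally overlapping into the next set
  n_extra <- floor(spec$overlap_fraction * gps)
  members <- lapply(seq_len(P), function(p) {
    own <- ((p - 1L) * gps + 1L):(p * gps)
    if (n_extra > 0L) {
      nxt <- (p %% P) * gps + seq_len(n_extra)
      nxt[nxt > d] <- nxt[nxt > d] - P * gps
      own <- unique(c(own, nxt))
    }
    gene_names[own]
  })
  names(members) <- set_names

  X <- matrix(stats::rnorm(N * d), nrow = N, ncol = d,
              dimnames = list(sprintf("S%04d", seq_len(N)), gene_names))
  rho <- spec$rho
  if (rho > 0) {
    for (p in seq_len(P)) {
      block <- ((p - 1L) * gps + 1L):(p * gps)
      shared <- stats::rnorm(N)
      X[, block] <- sqrt(rho) * shared + sqrt(1 - rho) * X[, block]
    }
  }

  informative <- sort(sample(set_names, spec$k_informative))
  gamma <- 4 * gps
  bump_sum <- numeric(N)
  for (nm in informative) {
    cols <- match(members[[nm]][seq_len(gps)], gene_names)
    center <- stats::rnorm(gps, sd = 0.3)
    r2 <- rowSums(sweep(X[, cols, drop = FALSE], 2L, center, `-`)^2)
    bump_sum <- bump_sum + exp(-r2 / gamma)
  }
  if (spec$k_informative > 0L && stats::sd(bump_sum) > 0) {
    signal <- (bump_sum - mean(bump_sum)) / stats::sd(bump_sum)
  } else {
    signal <- numeric(N)
  }
  latent <- spec$signal_scale * signal + stats::rnorm(N)
  y <- as.integer(latent > stats::median(latent))
  flips <- stats::runif(N) < spec$label_noise
  y[flips] <- 1L - y[flips]

  list(X = X, y = y, sets = feature_set_collection(members),
       informative = informative, spec = spec)
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Emits `expression.csv` (samples x genes; first column `sample_id`, then
#' one column per gene, doubles printed with 17 significant digits so the
#' matrix round-trips bit for bit), `labels.csv` (`sample_id,label`), and
#' `sets.gmt` (round-trippable by [read_gmt()]).
#'
#' @param data Output of [generate_dataset()] (or any list with `X`, `y`,
#'   `sets`).
#' @param dir Output directory, created if needed.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_path <- file.path(dir, "expression.csv")
  labels_path <- file.path(dir, "labels.csv")
  gmt_path <- file.path(dir, "sets.gmt")

  X <- data$X
  txt <- matrix(sprintf("%.17g", X), nrow = nrow(X))
  lines <- c(
    paste(c("sample_id", colnames(X)), collapse = ","),
    vapply(seq_len(nrow(X)), function(i) {
      paste(c(rownames(X)[i], txt[i, ]), collapse = ",")
    }, "")
  )
  writeLines(lines, expr_path)
  writeLines(c("sample_id,label",
               paste(rownames(X), data$y, sep = ",")), labels_path)
  write_gmt(data$sets, gmt_path)
  invisible(c(expression = expr_path, labels = labels_path, gmt = gmt_path))
}
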