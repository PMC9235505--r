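# End-to-end MAKL: per-set kernel approximation blocks concatenated into a
# logistic group Lasso. Selection is read off the block norms eta_p.

# stable small hash of a set name, for name-keyed RNG substreams
name_hash <- function(name) {
  sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 1000003L
}

# Build the concatenated approximation design from (already normalized) data:
# per set, bandwidth -> random map -> N x 2D block; degenerate-bandwidth sets
# are dropped with a warning. One integer is drawn from the current RNG
# state and each set's substream is derived from it and the set NAME, so the
# design for a given set does not depend on the order or presence of other
# sets (permutation equivariance).
makl_design <- function(X, sets, D, S = min(nrow(X), 1000L)) {
  base_seed <- sample.int(2147483646L, 1L)
  P0 <- length(sets$names)
  maps <- vector("list", P0)
  blocks <- vector("list", P0)
  ok <- logical(P0)
  for (p in seq_len(P0)) {
    set.seed(derive_seed(base_seed, name_hash(sets$names[p])))
    Xp <- X[, sets$resolved_indices[[p]], drop = FALSE]
    sigma <- tryCatch(estimate_sigma(Xp, S), error = function(e) NULL)
    if (is.null(sigma)) {
      warning("feature set '", sets$names[p],
              "' dropped: degenerate bandwidth")
      next
    }
    maps[[p]] <- rff_sample_map(ncol(Xp), D, sigma)
    blocks[[p]] <- rff_transform(Xp, maps[[p]])
    ok[p] <- TRUE
  }
  if (!any(ok)) stop("no feature set with a usable bandwidth")
  keep <- which(ok)
  sets_used <- new_feature_set_collection(
    sets$names[keep], sets$members[keep],
    resolved_indices = sets$resolved_indices[keep],
    gene_names = sets$gene_names
  )
  maps <- maps[keep]
  names(maps) <- sets_used$names
  list(maps = maps, Z = do.call(cbind, blocks[keep]), sets = sets_used)
}

# Transform new (already normalized) data with a fitted design's maps.
makl_design_transform <- function(X_new, maps, sets_used) {
  blocks <- lapply(seq_along(maps), function(p) {
    rff_transform(X_new[, sets_used$resolved_indices[[p]], drop = FALSE],
                  maps[[p]])
  })
  do.call(cbind, blocks)
}

#' Fit a MAKL model
#'
#' For each resolved feature set p the training columns are extracted, a
#' Gaussian-kernel bandwidth `sigma_p` is estimated from mean pairwise
#' distances on those columns, a random Fourier feature map is sampled, and
#' the `N x 2D` approximation block `Z_p` is computed. Blocks are concatenated
#' in set order into `Z` (width `2*D*P`) and a logistic group Lasso is fitted
#' with one group per set. The block norms `eta_p = ||beta_p||` rank set
#' relevance; `eta_p > 0` marks set p as selected.
#'
#' Feature normalization: when `normalize = TRUE` (default) per-gene training
#' means and standard deviations (sample SD) are computed, stored in the
#' model, and applied to training data before the kernel step; prediction
#' re-applies the same statistics. Sets whose bandwidth degenerates (all
#' sampled rows identical) are dropped with a warning rather than aborting.
#'
#' Uses the current RNG state for the bandwidth subsample and the random
#' maps; call `set.seed()` for reproducibility.
#'
#' @param X Numeric matrix, samples x genes, with column names when `sets`
#'   was resolved against gene names.
#' @param y Binary labels in \{0, 1\}, both classes present.
#' @param sets A resolved [feature_set_collection()].
#' @param D Number of random Fourier samples per set (block width `2*D`).
#' @param S Subset size for the bandwidth heuristic
#'   (default `min(nrow(X), 1000)`).
#' @param lambda_multiplier Fraction of `lambda_max` in (0, 1].
#' @param normalize Z-score features using training statistics (default TRUE).
#' @param tol,max_iter Passed to [group_lasso_fit()].
#' @return A `makl_model`: `maps` (per-set `rff_map`), `normalization`
#'   (`mean`, `sd` per gene or NULL), `gl_model`, `etas`, `set_names`,
#'   `sets` (the collection actually used), `D`, `lambda_multiplier`.
#' @export
makl_fit <- function(X, y, sets, D = 150L, S = min(nrow(X), 1000L),
                     lambda_multiplier = 0.9, normalize = TRUE,
                     tol = 1e-6, max_iter = 5000L) {
  stopifnot(inherits(sets, "feature_set_collection"))
  if (!sets$resolved) stop("sets must be resolved against gene names first")
  X <- as.matrix(X)
  check_binary(y)
  norm_stats <- NULL
  if (normalize) {
    zs <- zscore_fit_apply(X, NULL)
    norm_stats <- list(mean = zs$means, sd = zs$sds)
    X <- zs$train
  }

  design <- makl_design(X, sets, D, S)
  sets_used <- design$sets
  maps <- design$maps
  Z <- design$Z
  P <- length(sets_used$names)
  gs <- group_structure(rep(seq_len(P), each = 2L * D))
  gl <- group_lasso_fit(Z, y, gs, lambda_multiplier = lambda_multiplier,
                        tol = tol, max_iter = max_iter)
  etas <- vapply(gl$blocks, function(b) sqrt(sum(b^2)), 0)
  names(etas) <- sets_used$names
  out <- list(maps = maps, normalization = norm_stats, gl_model = gl,
              etas = etas, set_names = sets_used$names, sets = sets_used,
              D = as.integer(D), lambda_multiplier = lambda_multiplier,
              train_scores = gl$intercept + drop(Z %*% gl$beta))
  class(out) <- "makl_model"
  out
}

#' Score new samples with a fitted MAKL model
#'
#' Applies the stored training normalization, transforms each set's columns
#' with its stored random map (identical sigma, frequencies and offsets as in
#' fitting), and returns the raw linear scores
#' `beta_0 + sum_p Z_p beta_p` (log-odds scale, monotone in predicted
#' probability).
#'
#' @param object A `makl_model`.
#' @param X_new Numeric matrix, samples x genes; columns matched by
#'   `gene_names`.
#' @param gene_names Column gene symbols of `X_new`
#'   (default `colnames(X_new)`); must cover all genes used in training.
#' @param ... Unused.
#' @return Numeric vector of linear scores, one per row of `X_new`.
#' @export
predict.makl_model <- function(object, X_new, gene_names = colnames(X_new),
                               ...) {
  X_new <- as.matrix(X_new)
  needed <- object$sets$gene_names
  if (is.null(gene_names)) {
    if (ncol(X_new) != length(needed)) {
      stop("X_new has no gene names and its width does not match training")
    }
    col_of <- seq_along(needed)
  } else {
    col_of <- match(needed, gene_names)
    used <- sort(unique(unlist(object$sets$resolved_indices)))
    missing <- needed[used][is.na(col_of[used])]
    if (length(missing) > 0L) {
      stop("missing required gene column(s): ",
           paste(utils::head(missing, 10L), collapse = ", "),
           if (length(missing) > 10L) ", ..." else "")
    }
  }
  score <- rep(object$gl_model$intercept, nrow(X_new))
  for (p in seq_along(object$set_names)) {
    block_beta <- object$gl_model$blocks[[p]]
    if (all(block_beta == 0)) next
    idx <- object$sets$resolved_indices[[p]]
    Xp <- X_new[, col_of[idx], drop = FALSE]
    if (!is.null(object$normalization)) {
      mu <- object$normalization$mean[idx]
      sd <- object$normalization$sd[idx]
      Xp <- sweep(Xp, 2L, mu, `-`)
      Xp <- sweep(Xp, 2L, ifelse(sd > 0, sd, 1), `/`)
      Xp[, sd == 0] <- 0
    }
    score <- score + drop(rff_transform(Xp, object$maps[[p]]) %*% block_beta)
  }
  score
}

#' Names of selected feature sets
#'
#' Sets with `eta_p > 0` (exact zeros come from the proximal operator, so no
#' epsilon is involved), ordered by descending `eta_p`.
#'
#' @param model A `makl_model`.
#' @return Character vector, possibly empty.
#' @export
selected_sets <- function(model) {
  stopifnot(inherits(model, "makl_model"))
  nz <- model$etas[model$etas > 0]
  names(nz)[order(-nz)]
}

#' Fraction of the gene universe covered by selected sets
#'
#' Size of the union of resolved genes over selected sets, divided by
#' `total_genes`.
#'
#' @param model A `makl_model`.
#' @param sets A resolved collection (default: the one stored in the model).
#' @param total_genes Size of the gene universe (default: the number of gene
#'   names the collection was resolved against).
#' @return Real in \[0, 1\].
#' @export
gene_coverage_fraction <- function(model, sets = model$sets,
                                   total_genes = length(sets$gene_names)) {
  stopifnot(total_genes >= 1L)
  sel <- selected_sets(model)
  if (length(sel) == 0L) return(0)
  covered <- unique(unlist(sets$resolved_indices[match(sel, sets$names)]))
  length(covered) / total_genes
}

#' @export
print.makl_model <- function(x, ...) {
  sel <- selected_sets(x)
  cat("makl_model: P =", length(x$set_names), "sets, D =", x$D,
      ", lambda multiplier =", x$lambda_multiplier, "\n")
  cat("  selected:", length(sel), "set(s)",
      if (length(sel) > 0) paste0("(top: ", sel[1L], ")") else "", "\n")
  invisible(x)
}

#' Save a MAKL model as a JSON archive
#'
#' Serializes maps (sigma, frequency matrix, offsets), normalization
#' statistics, coefficients and set definitions to a single JSON file at full
#' double precision.
#'
#' @param model A `makl_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
makl_save <- function(model, path) {
  stopifnot(inherits(model, "makl_model"))
  arch <- list(
    format = "makl-model-1",
    D = model$D,
    lambda_multiplier = model$lambda_multiplier,
    set_names = model$set_names,
    gene_names = model$sets$gene_names,
    resolved_indices = model$sets$resolved_indices,
    members = model$sets$members,
    normalization = model$normalization,
    maps = lapply(model$maps, function(m) {
      list(sigma = m$sigma, Delta = as.vector(m$Delta),
           offsets = m$offsets, D = m$D, input_dim = m$input_dim)
    }),
    intercept = model$gl_model$intercept,
    blocks = model$gl_model$blocks,
    lambda = model$gl_model$lambda,
    weights = model$gl_model$structure$weights,
    etas = as.vector(model$etas)
  )
  jsonlite::write_json(arch, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a MAKL model saved with [makl_save()]
#'
#' @param path Path to the JSON archive.
#' @return A `makl_model` (without training scores).
#' @export
makl_load <- function(path) {
  arch <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(arch$format, "makl-model-1")) {
    stop("not a makl model archive: ", path)
  }
  num <- function(x) as.numeric(unlist(x, use.names = FALSE))
  chr <- function(x) as.character(unlist(x, use.names = FALSE))
  set_names <- chr(arch$set_names)
  P <- length(set_names)
  D <- as.integer(arch$D)
  maps <- lapply(seq_len(P), function(p) {
    m <- arch$maps[[p]]
    map <- list(sigma = as.numeric(m$sigma),
                Delta = matrix(num(m$Delta), nrow = as.integer(m$input_dim),
                               ncol = as.integer(m$D)),
                offsets = num(m$offsets), D = as.integer(m$D),
                input_dim = as.integer(m$input_dim))
    class(map) <- "rff_map"
    map
  })
  names(maps) <- set_names
  sets <- new_feature_set_collection(
    set_names,
    lapply(arch$members, chr),
    resolved_indices = lapply(arch$resolved_indices,
                              function(i) as.integer(unlist(i))),
    gene_names = chr(arch$gene_names)
  )
  blocks <- lapply(arch$blocks, num)
  beta <- unlist(blocks, use.names = FALSE)
  gs <- group_structure(rep(seq_len(P), each = 2L * D),
                        weights = num(arch$weights))
  lm_mult <- if (is.null(arch$lambda_multiplier)) NA_real_
             else as.numeric(arch$lambda_multiplier)
  gl <- list(intercept = as.numeric(arch$intercept), beta = beta,
             blocks = blocks, lambda = as.numeric(arch$lambda),
             lambda_multiplier = lm_mult,
             converged = TRUE, kkt = NA_real_, objective = NA_real_,
             n_iter = NA_integer_, structure = gs)
  class(gl) <- "group_lasso_model"
  etas <- vapply(blocks, function(b) sqrt(sum(b^2)), 0)
  names(etas) <- set_names
  norm <- arch$normalization
  if (!is.null(norm)) norm <- list(mean = num(norm$mean), sd = num(norm$sd))
  out <- list(maps = maps, normalization = norm, gl_model = gl, etas = etas,
              set_names = set_names, sets = sets, D = D,
              lambda_multiplier = lm_mult)
  class(out) <- "makl_model"
  out
}
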