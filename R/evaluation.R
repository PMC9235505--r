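# Evaluation protocol: stratified 80/20 splits, train-statistic feature
# normalization, 4-fold inner cross-validation over a lambda-multiplier grid,
# AUROC, and a replication harness reporting per-set selection frequencies.

#' Stratified 80/20 train/test split
#'
#' Per class, `min(round(0.8 * n_class), n_class - 1)` samples go to the
#' training set (so every class appears in both parts); the split is
#' disjoint and exhaustive.
#'
#' @param y Binary labels in \{0, 1\}.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_80_20 <- function(y, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  if (n < 5L) stop("need at least 5 samples to split")
  check_binary(y)
  train <- integer(0)
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    if (length(idx) < 2L) stop("class ", cls, " has fewer than 2 samples")
    n_tr <- min(round(0.8 * length(idx)), length(idx) - 1L)
    n_tr <- max(n_tr, 1L)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Z-score features with training statistics
#'
#' Each training column is centered and scaled to zero mean and unit sample
#' (n-1) standard deviation; test columns are transformed with the training
#' mean and SD. Constant training columns map to all-zeros in both matrices
#' (no division by zero).
#'
#' @param train_X Numeric training matrix (>= 2 rows).
#' @param test_X Optional numeric test matrix with the same columns.
#' @return List with `train`, `test` (NULL if `test_X` was NULL), `means`,
#'   `sds`.
#' @export
zscore_fit_apply <- function(train_X, test_X = NULL) {
  train_X <- as.matrix(train_X)
  if (nrow(train_X) < 2L) stop("need at least 2 training rows")
  means <- colMeans(train_X)
  sds <- apply(train_X, 2L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  scale_by <- ifelse(const, 1, sds)
  tr <- sweep(sweep(train_X, 2L, means, `-`), 2L, scale_by, `/`)
  tr[, const] <- 0
  te <- NULL
  if (!is.null(test_X)) {
    test_X <- as.matrix(test_X)
    te <- sweep(sweep(test_X, 2L, means, `-`), 2L, scale_by, `/`)
    te[, const] <- 0
  }
  list(train = tr, test = te, means = means, sds = sds)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a uniformly chosen positive sample outscores a uniformly
#' chosen negative one, ties counted one half. Computed from midranks, which
#' is exactly the pairwise definition.
#'
#' @param scores Numeric vector.
#' @param labels Binary labels in \{0, 1\}, both classes present.
#' @return Real in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  check_binary(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment; retries (new derived seed) if any fold lacks
# a class, errors after 5 attempts.
make_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (attempt in 1:5) {
    fold <- integer(length(y))
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    complete <- all(vapply(seq_len(k), function(f) {
      length(unique(y[fold == f])) == 2L
    }, TRUE))
    if (complete) return(fold)
  }
  stop("could not build ", k, "-fold stratified folds with both classes ",
       "in every fold after 5 attempts")
}

#' Inner cross-validation over the lambda-multiplier grid
#'
#' Stratified k-fold cross-validation on the training set: per fold, features
#' are z-scored with fold-training statistics, one random map per feature set
#' is sampled on the fold-training data and reused across the whole grid, and
#' the group Lasso is fitted down the grid with warm starts. The multiplier
#' with the best mean validation AUROC wins; ties break toward the larger
#' multiplier (sparser model).
#'
#' @param X Training expression matrix (samples x genes), raw scale.
#' @param y Binary labels.
#' @param sets Resolved [feature_set_collection()].
#' @param D Random Fourier samples per set.
#' @param S Bandwidth subsample size.
#' @param grid Lambda multipliers in (0, 1]; default `c(0.9, 0.8, 0.7, 0.6)`.
#' @param folds Number of folds (default 4).
#' @param seed Optional integer seed.
#' @param criterion Model-selection criterion: `"auroc"` (default, mean
#'   validation AUROC) or `"deviance"` (negative mean binomial deviance).
#' @param tol,max_iter Passed to [group_lasso_fit()].
#' @return List with `multiplier` (the choice), and `cv_auroc` (named mean
#'   validation criterion per multiplier; larger is better for both
#'   criteria).
#' @export
inner_cv_select_lambda <- function(X, y, sets, D, S = min(nrow(X), 1000L),
                                   grid = c(0.9, 0.8, 0.7, 0.6),
                                   folds = 4L, seed = NULL,
                                   criterion = c("auroc", "deviance"),
                                   tol = 1e-6, max_iter = 5000L) {
  criterion <- match.arg(criterion)
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (any(grid <= 0 | grid > 1)) stop("grid values must be in (0, 1]")
  grid <- sort(unique(grid), decreasing = TRUE)
  if (length(grid) == 1L) {
    return(list(multiplier = grid, cv_auroc = stats::setNames(NA_real_,
                                                              grid)))
  }
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  fold <- make_folds(y, folds)
  cv <- matrix(NA_real_, nrow = folds, ncol = length(grid))
  for (f in seq_len(folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    zs <- zscore_fit_apply(X[tr, , drop = FALSE], X[va, , drop = FALSE])
    des <- makl_design(zs$train, sets, D, S = min(length(tr), S))
    Zva <- makl_design_transform(zs$test, des$maps, des$sets)
    P <- length(des$sets$names)
    gs <- group_structure(rep(seq_len(P), each = 2L * D))
    lmax <- lambda_max(des$Z, y[tr], gs)
    Lp <- vapply(gs$cols, function(ix) {
      0.25 * (1.05 * spectral_norm(des$Z[, ix, drop = FALSE]))^2
    }, 0)
    init <- NULL
    for (g in seq_along(grid)) {
      fit <- group_lasso_fit(des$Z, y[tr], gs, lambda = grid[g] * lmax,
                             tol = tol, max_iter = max_iter, init = init,
                             block_lipschitz = Lp)
      fit$lambda_multiplier <- grid[g]
      init <- list(intercept = fit$intercept, beta = fit$beta)
      scores <- fit$intercept + drop(Zva %*% fit$beta)
      cv[f, g] <- if (criterion == "auroc") {
        auroc(scores, y[va])
      } else {
        # negative mean binomial deviance, so larger is better either way
        s <- 2 * y[va] - 1
        -2 * mean(log1pexp(-s * scores))
      }
    }
  }
  mean_crit <- colMeans(cv)
  names(mean_crit) <- format(grid)
  best <- which(mean_crit >= max(mean_crit) - 1e-12)[1L]  # grid sorted desc
  list(multiplier = grid[best], cv_auroc = mean_crit)
}

#' Replication harness: repeated split, tune, fit, test
#'
#' Runs `R` independent replications of the full protocol: stratified 80/20
#' split, inner cross-validation on the training part to choose the lambda
#' multiplier, a final fit on the whole training part at that multiplier,
#' and AUROC on the held-out test part. Per-replication seeds are derived
#' from the master seed, so adding replications never perturbs earlier ones.
#'
#' @param X Expression matrix (samples x genes), raw scale.
#' @param y Binary labels in \{0, 1\}.
#' @param sets Resolved [feature_set_collection()].
#' @param D Random Fourier samples per set (default 150).
#' @param S Bandwidth subsample size (default `min(N, 1000)`).
#' @param grid Lambda-multiplier grid (default `c(0.9, 0.8, 0.7, 0.6)`).
#' @param R Number of replications (default 100).
#' @param folds Inner-CV folds (default 4).
#' @param seed Master seed (default 1).
#' @param tol,max_iter Passed to [group_lasso_fit()] for the final
#'   per-replication fit.
#' @param cv_tol KKT tolerance for the inner-CV fits (default 1e-4; model
#'   selection does not need final-fit precision).
#' @return An `evaluation_report`: `replications` (data.frame with
#'   replication, multiplier, auroc, n_selected, gene_fraction),
#'   `selection` (data.frame with set, frequency, mean_eta),
#'   `auroc_per_replication`, `mean_auroc`, `mean_sets_selected`,
#'   `mean_gene_fraction`, `chosen_multipliers`.
#' @export
run_replications <- function(X, y, sets, D = 150L,
                             S = min(nrow(X), 1000L),
                             grid = c(0.9, 0.8, 0.7, 0.6),
                             R = 100L, folds = 4L, seed = 1L,
                             tol = 1e-6, cv_tol = 1e-4, max_iter = 5000L) {
  stopifnot(R >= 1L)
  X <- as.matrix(X)
  P <- length(sets$names)
  eta_sum <- stats::setNames(numeric(P), sets$names)
  sel_count <- stats::setNames(numeric(P), sets$names)
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    rec <- tryCatch({
      sp <- split_80_20(y, seed = derive_seed(seed, r, 1L))
      Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
      Xte <- X[sp$test, , drop = FALSE];  yte <- y[sp$test]
      cv <- inner_cv_select_lambda(Xtr, ytr, sets, D,
                                   S = min(nrow(Xtr), S), grid = grid,
                                   folds = folds,
                                   seed = derive_seed(seed, r, 2L),
                                   tol = cv_tol, max_iter = max_iter)
      set.seed(derive_seed(seed, r, 3L))
      model <- makl_fit(Xtr, ytr, sets, D = D, S = min(nrow(Xtr), S),
                        lambda_multiplier = cv$multiplier,
                        tol = tol, max_iter = max_iter)
      scores <- predict(model, Xte, gene_names = colnames(X))
      test_auc <- auroc(scores, yte)
      sel <- selected_sets(model)
      eta_sum[names(model$etas)] <- eta_sum[names(model$etas)] + model$etas
      sel_count[sel] <- sel_count[sel] + 1
      data.frame(replication = r, multiplier = cv$multiplier,
                 auroc = test_auc, n_selected = length(sel),
                 gene_fraction = gene_coverage_fraction(
                   model, total_genes = ncol(X)))
    }, error = function(e) {
      stop("replication ", r, " failed: ", conditionMessage(e), call. = FALSE)
    })
    rows[[r]] <- rec
  }
  reps <- do.call(rbind, rows)
  report <- list(
    replications = reps,
    selection = data.frame(set = sets$names,
                           frequency = as.numeric(sel_count / R),
                           mean_eta = as.numeric(eta_sum / R)),
    auroc_per_replication = reps$auroc,
    mean_auroc = mean(reps$auroc),
    mean_sets_selected = mean(reps$n_selected),
    mean_gene_fraction = mean(reps$gene_fraction),
    chosen_multipliers = reps$multiplier
  )
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", nrow(x$replications), "replications\n")
  cat("  mean test AUROC:      ", format(x$mean_auroc, digits = 4), "\n")
  cat("  mean sets selected:   ", format(x$mean_sets_selected, digits = 4),
      "\n")
  cat("  mean gene fraction:   ", format(x$mean_gene_fraction, digits = 4),
      "\n")
  top <- x$selection[order(-x$selection$frequency), ][1:min(5,
                                                      nrow(x$selection)), ]
  cat("  most selected sets:   ",
      paste0(top$set, " (", format(top$frequency, digits = 2), ")",
             collapse = ", "), "\n")
  invisible(x)
}
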