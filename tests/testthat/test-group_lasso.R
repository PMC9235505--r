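test_that("block soft-thresholding matches its closed form", {
  expect_equal(group_prox(c(3, 4), 2.5), c(1.5, 2.0))
  expect_identical(group_prox(c(3, 4), 5), c(0, 0))   # exact zeros at boundary
  expect_identical(group_prox(c(3, 4), 6), c(0, 0))
  v <- c(-1.2, 0.4, 7)
  expect_equal(group_prox(v, 0), v)
  expect_error(group_prox(v, -0.1), ">= 0")
})

test_that("objective has the null-model closed form and scale equivalences", {
  set.seed(3)
  inst <- random_gl_instance(N = 30)
  null_model <- list(intercept = 0, beta = rep(0, ncol(inst$Z)), lambda = 2,
                     structure = inst$gs)
  expect_equal(logistic_objective(inst$Z, inst$y, null_model),
               30 * log(2), tolerance = 1e-12)
  # lambda = 0 reduces to the plain logistic loss
  model <- list(intercept = 0.3, beta = rnorm(ncol(inst$Z)), lambda = 0,
                structure = inst$gs)
  s <- 2 * inst$y - 1
  f <- 0.3 + drop(inst$Z %*% model$beta)
  expect_equal(logistic_objective(inst$Z, inst$y, model),
               sum(log(1 + exp(-s * f))), tolerance = 1e-10)
  # doubling weights at fixed lambda = doubling lambda at fixed weights
  gs2 <- group_structure(inst$gs$group_of_column, weights = 2 * inst$gs$weights)
  model1 <- model; model1$lambda <- 3
  model2 <- model; model2$lambda <- 6
  expect_equal(logistic_objective(inst$Z, inst$y, model1, gs2),
               logistic_objective(inst$Z, inst$y, model2, inst$gs),
               tolerance = 1e-12)
  expect_error(logistic_objective(inst$Z, c(inst$y[-1], 2), model),
               "binary")
})

test_that("lambda_max is the exact onset of the all-zero solution", {
  set.seed(21)
  inst <- random_gl_instance()
  lmax <- lambda_max(inst$Z, inst$y, inst$gs)
  at_max <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda_multiplier = 1.0)
  expect_true(all(vapply(at_max$blocks, function(b) all(b == 0), TRUE)))
  expect_equal(at_max$intercept, qlogis(mean(inst$y)), tolerance = 1e-8)
  # just below lambda_max at least one block activates
  below <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda = 0.99 * lmax)
  expect_gte(sum(vapply(below$blocks, function(b) any(b != 0), TRUE)), 1L)
  # gradient homogeneity: scaling Z scales lambda_max
  expect_equal(lambda_max(3 * inst$Z, inst$y, inst$gs), 3 * lmax,
               tolerance = 1e-10)
  expect_error(lambda_max(inst$Z, rep(1, length(inst$y)), inst$gs), "classes")
})

test_that("fitted solutions satisfy the KKT conditions within tolerance", {
  set.seed(77)
  for (mult in c(0.8, 0.5, 0.2)) {
    inst <- random_gl_instance()
    fit <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda_multiplier = mult,
                           tol = 1e-6)
    expect_true(fit$converged)
    expect_lte(fit$kkt, 1e-6)
    expect_lte(fit$objective,
               length(inst$y) * log(2) + 1e-9)  # beats the null model
    # recomputed residual agrees with the stored one
    expect_equal(kkt_residual(inst$Z, inst$y, fit), fit$kkt,
                 tolerance = 1e-10)
  }
})

test_that("perturbing a nonzero block strictly increases the KKT residual", {
  set.seed(13)
  inst <- random_gl_instance()
  fit <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda_multiplier = 0.3,
                         tol = 1e-8, max_iter = 20000L)
  nz <- which(vapply(fit$blocks, function(b) any(b != 0), TRUE))[1L]
  pert <- fit
  pert$beta[fit$structure$cols[[nz]][1L]] <-
    pert$beta[fit$structure$cols[[nz]][1L]] + 0.1
  expect_gt(kkt_residual(inst$Z, inst$y, pert), fit$kkt)
})

test_that("solver matches the independent smoothed-BFGS reference optimizer", {
  set.seed(42)
  for (i in 1:5) {
    inst <- random_gl_instance(N = 40L, P = 3L, width = 8L)
    fit <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda_multiplier = 0.5,
                           tol = 1e-8, max_iter = 20000L)
    ref <- reference_group_lasso_objective(inst$Z, inst$y, fit$lambda,
                                           inst$gs$weights, inst$gs$cols)
    expect_equal(fit$objective, ref, tolerance = 1e-6)
  }
})

test_that("number of active groups shrinks along the multiplier grid", {
  set.seed(55)
  inst <- random_gl_instance(N = 80L, P = 5L, width = 6L)
  nz <- vapply(c(0.6, 0.7, 0.8, 0.9, 1.0), function(m) {
    fit <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda_multiplier = m)
    sum(vapply(fit$blocks, function(b) any(b != 0), TRUE))
  }, 0)
  expect_true(all(diff(nz) <= 0))
  expect_identical(nz[5], 0)
})

test_that("permuting group order permutes the fitted blocks", {
  set.seed(31)
  inst <- random_gl_instance(N = 60L, P = 3L, width = 4L)
  fit1 <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda_multiplier = 0.4,
                          tol = 1e-8, max_iter = 20000L)
  perm <- c(3L, 1L, 2L)
  col_perm <- unlist(inst$gs$cols[perm])
  gs2 <- group_structure(rep(1:3, each = 4L))
  fit2 <- group_lasso_fit(inst$Z[, col_perm], inst$y, gs2,
                          lambda = fit1$lambda, tol = 1e-8,
                          max_iter = 20000L)
  for (p in 1:3) {
    expect_equal(fit2$blocks[[p]], fit1$blocks[[perm[p]]], tolerance = 1e-5)
  }
})

test_that("warm starts reproduce the cold-start solution", {
  set.seed(61)
  inst <- random_gl_instance()
  cold <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda_multiplier = 0.5,
                          tol = 1e-8, max_iter = 20000L)
  warm_init <- group_lasso_fit(inst$Z, inst$y, inst$gs,
                               lambda_multiplier = 0.8)
  warm <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda_multiplier = 0.5,
                          tol = 1e-8, max_iter = 20000L,
                          init = list(intercept = warm_init$intercept,
                                      beta = warm_init$beta))
  expect_equal(warm$objective, cold$objective, tolerance = 1e-8)
})

test_that("non-convergence is reported, never silent", {
  set.seed(91)
  inst <- random_gl_instance()
  expect_warning(
    fit <- group_lasso_fit(inst$Z, inst$y, inst$gs, lambda_multiplier = 0.1,
                           tol = 1e-12, max_iter = 3L),
    "not converged"
  )
  expect_false(fit$converged)
})
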