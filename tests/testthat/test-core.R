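test_that("standardize_columns: invariants, dropped columns, round trip", {
  set.seed(1)
  X <- cbind(rnorm(50, 5, 2), rnorm(50), rep(3, 50))
  d <- standardize_columns(X)
  expect_equal(d$dropped, 3L)
  expect_true(all(abs(colMeans(d$X[, 1:2])) < 1e-10))
  expect_true(all(abs(apply(d$X[, 1:2], 2, sd) - 1) < 1e-10))
  expect_true(all(d$X[, 3] == 0))
  # inverse transform reproduces the input
  back <- sweep(sweep(d$X, 2, ifelse(d$column_sds == 0, 1, d$column_sds),
                      "*"), 2, d$column_means, "+")
  expect_equal(back, X, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(standardize_columns(X[1, , drop = FALSE]), "2 rows")
})

test_that("ridge_coefficients: closed form, shrinkage, linear-solve oracle", {
  expect_equal(ridge_coefficients(diag(2), c(1, 0), alpha = 1), c(0.5, 0))
  set.seed(2)
  X <- matrix(rnorm(200), 40, 5)
  y <- rnorm(40)
  expect_lt(sqrt(sum(ridge_coefficients(X, y, alpha = 1e12)^2)), 1e-6)
  # generic linear solver as oracle
  for (alpha in c(0.1, 1, 10)) {
    expect_equal(ridge_coefficients(X, y, alpha),
                 drop(qr.solve(t(X) %*% X + alpha * diag(5), t(X) %*% y)),
                 tolerance = 1e-8)
  }
  # dropped columns carry zero coefficients
  d <- standardize_columns(cbind(X, 7))
  expect_equal(ridge_coefficients(d, y, 1)[6], 0)
  expect_error(ridge_coefficients(X, c(y[-1], NA), 1), "non-finite")
})

test_that("sparse_weight_vector: threshold arithmetic and identity case", {
  sd1 <- sparse_weight_vector(c(3, -1, 0.5), 1, c(1, 1, 1))
  expect_equal(sd1$raw, c(2, 0, 0))
  expect_equal(sd1$u, c(1, 0, 0))
  expect_equal(sd1$support, 1L)
  m <- c(2, -1, 0.3)
  sd0 <- sparse_weight_vector(m, 0)
  expect_equal(sd0$u, m / sqrt(sum(m^2)), tolerance = 1e-12)
  expect_false(sd0$all_zero)
  sdz <- sparse_weight_vector(m, 100)
  expect_true(sdz$all_zero)
  expect_equal(sqrt(sum(sdz$u^2)), 0)
  # spec example with unequal shrinkage
  sd2 <- sparse_weight_vector(c(2, -1), 0.5, c(1, 1))
  expect_equal(sd2$raw, c(1.5, -0.5))
  expect_equal(sd2$u, c(1.5, -0.5) / sqrt(2.5), tolerance = 1e-6)
})

test_that("sparse direction minimizes the penalized objective (small oracle)", {
  set.seed(3)
  for (i in 1:20) {
    p <- sample(2:4, 1)
    m <- rnorm(p, 0, 2)
    omega <- runif(p, 0.2, 3)
    lam <- runif(1, 0, max(abs(m)))
    raw <- sparse_weight_vector(m, lam, omega)$raw
    f0 <- sparse_objective(raw, m, lam, omega)
    cand <- matrix(rnorm(2000 * p, mean = raw, sd = 0.5), 2000, p)
    fc <- apply(cand, 1, sparse_objective, m = m, lambda1 = lam,
                omega = omega)
    expect_lte(f0, min(fc) + 1e-9)
  }
})

test_that("fit_sparse_pls: PLS1 reduction, single column, degenerate penalty", {
  set.seed(4)
  X <- matrix(rnorm(100 * 8), 100, 8)
  y <- ifelse(X[, 1] - X[, 2] + rnorm(100, 0, 0.3) >= 0, 1, -1)
  # lambda1 = 0, unit omega, A = 1: weight vector proportional to X'y
  m1 <- fit_sparse_pls(X, y, n_components = 1, lambda1 = 0)
  d <- standardize_columns(X)
  mref <- drop(crossprod(d$X, y - mean(y)))
  expect_equal(m1$weight_vectors[, 1], mref / sqrt(sum(mref^2)),
               tolerance = 1e-10)
  # single column: fitted scores reproduce simple least squares
  x1 <- X[, 1, drop = FALSE]
  ms <- fit_sparse_pls(x1, y, n_components = 1, lambda1 = 0)
  ls <- lm.fit(cbind(1, x1), y)
  expect_equal(predict(ms, x1)$scores, drop(cbind(1, x1) %*% ls$coefficients),
               tolerance = 1e-8)
  # over-large penalty: all-zero first direction is an error with advice
  expect_error(fit_sparse_pls(X, y, n_components = 1, lambda1 = 1e6),
               "lambda1/eta")
  expect_error(fit_sparse_pls(X, y, n_components = 500), "rank bound")
})

test_that("lambda1 = 0 collapses IASPLS to textbook PLS1", {
  for (s in 1:5) {
    tc <- random_two_class(60, 12, seed = s)
    fit <- fit_iaspls(tc$X, tc$y, n_components = 3, eta = 0)
    ora <- oracle_pls1(tc$X, tc$y, A = 3)
    expect_equal(fit$coefficients, ora$coefficients, tolerance = 1e-8)
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-12)
  }
})

test_that("fit_iaspls: recovery, iteration audit, determinism", {
  d <- generate_sparse_linear_data(300, 50, 1, effect_size = 5,
                                   noise_sd = 0.2, seed = 9)
  fit <- fit_iaspls(d$X, d$y)
  expect_true(d$informative %in% which(fit$coefficients != 0))
  expect_gte(mean(predict(fit, d$X)$labels == d$y), 0.95)
  expect_lte(fit$iterations_run, 10)
  expect_true(fit$converged)
  # coefficients zero outside the union of component supports
  supp <- unique(unlist(apply(fit$weight_vectors != 0, 2, which)))
  expect_true(all(which(fit$coefficients != 0) %in% supp))
  # bit-identical refit
  fit2 <- fit_iaspls(d$X, d$y)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_error(fit_iaspls(d$X, rep(1, 300)), "both classes")
})

test_that("support stabilizes within max_iter on moderate problems", {
  stable <- vapply(1:20, function(s) {
    tc <- random_two_class(100, 30, seed = 100 + s)
    fit <- fit_iaspls(tc$X, tc$y, max_iter = 10)
    fit$converged
  }, logical(1))
  expect_gte(sum(stable), 18)
})

test_that("prediction: intercept row, degenerate model, scale equivariance", {
  tc <- random_two_class(80, 6, seed = 77)
  fit <- fit_iaspls(tc$X, tc$y)
  mu <- matrix(colMeans(tc$X), 1)
  expect_equal(predict(fit, mu)$scores, fit$intercept, tolerance = 1e-10)
  expect_error(predict(fit, tc$X[, 1:3]), "columns")
  # all-zero coefficients: labels decided by intercept sign alone
  z <- fit
  z$coefficients[] <- 0
  expect_true(all(predict(z, tc$X)$labels == ifelse(z$intercept >= 0, 1, -1)))
  # multiplying a raw column by a constant leaves labels unchanged
  X2 <- tc$X
  X2[, 3] <- X2[, 3] * 250
  fit2 <- fit_iaspls(X2, tc$y)
  expect_equal(predict(fit2, X2)$labels, predict(fit, tc$X)$labels)
  # separable blobs reproduce training labels exactly
  set.seed(12)
  Xb <- rbind(matrix(rnorm(40 * 4, 0), 40, 4), matrix(rnorm(40 * 4, 6), 40, 4))
  yb <- rep(c(-1, 1), each = 40)
  fb <- fit_iaspls(Xb, yb)
  expect_equal(predict(fb, Xb)$labels, yb)
})

test_that("model serialization round-trips exactly", {
  tc <- random_two_class(60, 10, seed = 5)
  fit <- fit_iaspls(tc$X, tc$y)
  f <- withr::local_tempfile(fileext = ".json")
  write_iaspls_model(fit, f)
  back <- read_iaspls_model(f)
  expect_identical(back$coefficients, fit$coefficients)
  expect_identical(back$standardization$column_means,
                   unname(fit$standardization$column_means))
  expect_equal(predict(back, tc$X)$scores, predict(fit, tc$X)$scores,
               tolerance = 0)
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"schema\": \"other\"}", f2)
  expect_error(read_iaspls_model(f2), "schema")
})

test_that("tune_iaspls picks a sensible grid point and is parsimonious", {
  d <- generate_sparse_linear_data(120, 20, 2, effect_size = 4,
                                   noise_sd = 0.5, seed = 21)
  tuned <- tune_iaspls(d$X, d$y, eta_grid = c(0, 0.4, 0.8),
                       ncomp_grid = c(1, 2), n_folds = 3, seed = 2)
  expect_true(tuned$eta %in% c(0, 0.4, 0.8))
  expect_equal(nrow(tuned$cv_table), 6L)
  best_acc <- max(tuned$cv_table$cv_acc)
  ties <- tuned$cv_table[tuned$cv_table$cv_acc == best_acc, ]
  expect_equal(tuned$eta, max(ties$eta))  # sparser model wins ties
})
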