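# IASPLS numerical engine.
#
# Fitting works on column-standardized predictors and class labels coded
# -1/+1. One sparse PLS pass extracts A latent components whose weight
# vectors are adaptively soft-thresholded; the outer loop re-estimates
# per-variable importances (ridge first, then the model's own coefficients)
# and re-weights the penalties until the coefficient vector stabilizes.

#' Column standardization with zero-variance bookkeeping
#'
#' Centers and scales each column to mean 0, sd 1 (denominator n-1).
#' Zero-variance columns are recorded in `dropped` and set to all-zero in
#' the standardized matrix -- they keep their index and carry zero weight
#' downstream, rather than being silently removed.
#'
#' @param X raw numeric matrix, n >= 2 rows.
#' @return an object of class `std_design`: list with `X` (standardized),
#'   `column_means`, `column_sds` (raw sds, 0 for dropped), `dropped`
#'   (integer indices), `p`.
#' @export
standardize_columns <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite entries in X", call. = FALSE)
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  dropped <- which(sds < 1e-12)
  scale_safe <- ifelse(sds < 1e-12, 1, sds)
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, scale_safe, "/")
  if (length(dropped)) Xs[, dropped] <- 0
  structure(list(X = Xs, column_means = mu,
                 column_sds = ifelse(sds < 1e-12, 0, sds),
                 dropped = dropped, p = ncol(X)),
            class = "std_design")
}

as_std_design <- function(X) {
  if (inherits(X, "std_design")) return(X)
  standardize_columns(X)
}

check_response <- function(y, require_both = TRUE) {
  y <- as.numeric(y)
  if (any(!y %in% c(-1, 1))) {
    stop("response must be coded -1/+1", call. = FALSE)
  }
  if (require_both && length(unique(y)) < 2) {
    stop("both classes must be present for fitting", call. = FALSE)
  }
  y
}

#' Ridge regression coefficients
#'
#' Solves (X'X + alpha I) beta = X'y on the retained (non-constant)
#' columns; dropped columns get coefficient 0.
#'
#' @param design a `std_design` or a numeric matrix (used as-is).
#' @param y numeric response vector.
#' @param alpha positive ridge penalty.
#' @return numeric p-vector.
#' @export
ridge_coefficients <- function(design, y, alpha = 1) {
  stopifnot(alpha > 0)
  d <- if (inherits(design, "std_design")) design else
    list(X = as.matrix(design), dropped = integer(0),
         p = ncol(as.matrix(design)))
  if (any(!is.finite(d$X)) || any(!is.finite(y))) {
    stop("non-finite entries in inputs", call. = FALSE)
  }
  keep <- setdiff(seq_len(d$p), d$dropped)
  beta <- numeric(d$p)
  if (length(keep)) {
    Xr <- d$X[, keep, drop = FALSE]
    A <- crossprod(Xr)
    diag(A) <- diag(A) + alpha
    beta[keep] <- drop(solve(A, crossprod(Xr, y)))
  }
  beta
}

#' Adaptively soft-thresholded sparse weight vector
#'
#' Elementwise minimizer of `||m - u||^2 + 2*lambda1*sum(omega_i |u_i|)`:
#' `raw_i = sign(m_i) * max(|m_i| - lambda1*omega_i, 0)`, normalized to unit
#' length. An all-zero result is a flagged state, not an error.
#'
#' @param m numeric p-vector (here X'y of the current deflation step).
#' @param lambda1 nonnegative penalty.
#' @param omega positive p-vector of adaptive penalty weights.
#' @return object of class `sparse_direction`: list with `u` (unit-norm or
#'   all-zero), `raw`, `lambda1`, `omega`, `support`, `all_zero`.
#' @export
sparse_weight_vector <- function(m, lambda1, omega = rep(1, length(m))) {
  stopifnot(lambda1 >= 0, length(omega) == length(m), all(omega > 0))
  raw <- sign(m) * pmax(abs(m) - lambda1 * omega, 0)
  nrm <- sqrt(sum(raw^2))
  u <- if (nrm > 0) raw / nrm else raw
  structure(list(u = u, raw = raw, lambda1 = lambda1, omega = omega,
                 support = which(raw != 0), all_zero = nrm == 0),
            class = "sparse_direction")
}

resolve_lambda <- function(m, eta, lambda1, omega) {
  if (!is.null(lambda1)) return(lambda1)
  score <- abs(m) / omega
  eta * max(score)
}

#' One sparse PLS pass with fixed penalty weights
#'
#' Extracts up to `n_components` latent components. Per component:
#' `m = X_a' y_c`, sparse direction by adaptive soft-thresholding, score
#' `t = X_a u`, X-loading `p_a = X_a' t / (t' t)`, y-loading
#' `c_a = y_c' t / (t' t)`, deflation `X_{a+1} = X_a - t p_a'` (X-side
#' only). Coefficients on the standardized scale are
#' `B = W (P'W)^{-1} C`; the intercept is mean(y). The sparsity level is
#' given either directly (`lambda1`) or as a fraction `eta` of the largest
#' penalty that would empty the support, `lambda1 = eta * max(|m|/omega)`,
#' re-evaluated at each component.
#'
#' @param design `std_design` or raw matrix.
#' @param y response in -1/+1.
#' @param n_components maximum number of latent components A.
#' @param eta sparsity fraction in \[0, 1); ignored when `lambda1` given.
#' @param lambda1 absolute penalty (optional).
#' @param omega positive penalty weight p-vector (default all 1).
#' @return an `iaspls_model`.
#' @export
fit_sparse_pls <- function(design, y, n_components = 3, eta = 0.5,
                           lambda1 = NULL, omega = NULL) {
  design <- as_std_design(design)
  y <- check_response(y)
  n <- nrow(design$X)
  p <- design$p
  stopifnot(n_components >= 1)
  if (n_components > min(n - 1, p)) {
    stop("n_components exceeds rank bound min(n-1, p)", call. = FALSE)
  }
  if (is.null(omega)) omega <- rep(1, p)
  stopifnot(length(omega) == p, all(omega > 0))

  yc <- y - mean(y)
  Xa <- design$X
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  C <- numeric(n_components)
  used <- 0L
  for (a in seq_len(n_components)) {
    m <- drop(crossprod(Xa, yc))
    lam <- resolve_lambda(m, eta, lambda1, omega)
    dir_a <- sparse_weight_vector(m, lam, omega)
    if (dir_a$all_zero) {
      if (a == 1L) {
        stop("all-zero first direction: penalty too large; ",
             "decrease lambda1/eta", call. = FALSE)
      }
      break
    }
    t_a <- drop(Xa %*% dir_a$u)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    W[, a] <- dir_a$u
    P[, a] <- drop(crossprod(Xa, t_a)) / tt
    C[a] <- sum(yc * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, P[, a])
    used <- a
  }
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  C <- C[seq_len(used)]
  B <- drop(W %*% solve(crossprod(P, W), C))
  structure(list(weight_vectors = W, loadings = P, y_loadings = C,
                 coefficients = B, intercept = mean(y),
                 omega_final = omega, n_components = used,
                 hyperparams = list(eta = if (is.null(lambda1)) eta else NULL,
                                    lambda1 = lambda1,
                                    n_components = n_components),
                 iterations_run = 1L,
                 converged = NA,
                 standardization = design[c("column_means", "column_sds",
                                            "dropped", "p")]),
            class = "iaspls_model")
}

#' Fit the iteratively adaptive sparse PLS classifier
#'
#' Initializes variable importances by ridge regression, then alternates
#' (a) penalty weights `omega_i = 1 / max(|beta_i|, eps)` and (b) a sparse
#' PLS pass with those weights, until the relative change of the
#' coefficient vector drops below `tol`, the support stops changing, or
#' `max_iter` is reached (non-convergence is a logged warning, not an
#' error).
#'
#' @param X raw predictor matrix (or `std_design`, or `feature_matrix`).
#' @param y response in -1/+1, both classes present.
#' @param n_components latent components per pass (default 3).
#' @param eta sparsity fraction in \[0, 1) (default 0.5; 0 disables
#'   sparsity and reduces the fit to classical PLS1).
#' @param ridge_alpha ridge penalty for the initial importances (default 1).
#' @param max_iter maximum re-weighting iterations (default 10).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param eps floor for |beta| in the penalty weights (default 1e-12).
#' @return an `iaspls_model` with `iterations_run`, `converged`,
#'   `omega_final` recorded.
#' @export
fit_iaspls <- function(X, y, n_components = 3, eta = 0.5, ridge_alpha = 1,
                       max_iter = 10, tol = 1e-6, eps = 1e-12) {
  design <- as_std_design(X)
  y <- check_response(y)
  beta <- ridge_coefficients(design, y, ridge_alpha)
  model <- NULL
  support_old <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    omega <- 1 / pmax(abs(beta), eps)
    model <- fit_sparse_pls(design, y, n_components = n_components,
                            eta = eta, omega = omega)
    beta_new <- model$coefficients
    rel <- sqrt(sum((beta_new - beta)^2)) / max(sqrt(sum(beta^2)), eps)
    support_new <- which(beta_new != 0)
    if (rel < tol ||
        (!is.null(support_old) && identical(support_new, support_old))) {
      converged <- TRUE
      beta <- beta_new
      break
    }
    support_old <- support_new
    beta <- beta_new
  }
  if (!converged) {
    ias_log("fit_iaspls: no convergence within ", max_iter,
            " iterations; returning last model", level = "WARN")
  }
  model$iterations_run <- iter
  model$converged <- converged
  model$hyperparams <- list(eta = eta, n_components = n_components,
                            ridge_alpha = ridge_alpha, max_iter = max_iter,
                            tol = tol, eps = eps)
  model
}

#' Predict decision scores and class labels
#'
#' New rows are standardized with the TRAINING means and sds; the score is
#' `X_std B + intercept` and the label `+1` when the score is `>= 0`
#' (ties to the coding class), else `-1`.
#'
#' @param object an `iaspls_model`.
#' @param newdata numeric matrix with the training column count.
#' @param ... unused.
#' @return list with `scores` and `labels`.
#' @export
predict.iaspls_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  st <- object$standardization
  if (ncol(Xn) != st$p) {
    stop(sprintf("newdata has %d columns; model was trained on %d",
                 ncol(Xn), st$p), call. = FALSE)
  }
  scale_safe <- ifelse(st$column_sds == 0, 1, st$column_sds)
  Xs <- sweep(sweep(Xn, 2, st$column_means, "-"), 2, scale_safe, "/")
  if (length(st$dropped)) Xs[, st$dropped] <- 0
  scores <- drop(Xs %*% object$coefficients) + object$intercept
  list(scores = scores, labels = ifelse(scores >= 0, 1, -1))
}

#' @export
print.iaspls_model <- function(x, ...) {
  cat(sprintf(paste0("iaspls_model: %d component(s), %d/%d nonzero ",
                     "coefficients, %d iteration(s)%s\n"),
              x$n_components, sum(x$coefficients != 0),
              length(x$coefficients), x$iterations_run,
              if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

#' Select sparsity and component count by stratified cross-validation
#'
#' Grid search maximizing cross-validated accuracy; ties are broken toward
#' the sparser model (larger `eta`, then fewer components).
#'
#' @param X raw predictor matrix.
#' @param y response in -1/+1.
#' @param eta_grid candidate sparsity fractions.
#' @param ncomp_grid candidate component counts.
#' @param n_folds stratified folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param ... passed to [fit_iaspls()].
#' @return list with `eta`, `n_components` and the full `cv_table`.
#' @export
tune_iaspls <- function(X, y, eta_grid = seq(0, 0.9, by = 0.1),
                        ncomp_grid = 1:10, n_folds = 5, seed = 1, ...) {
  X <- as.matrix(X)
  y <- check_response(y)
  folds <- local({
    set.seed(seed)
    stratified_folds(y, n_folds)
  })
  ncomp_grid <- ncomp_grid[ncomp_grid <= min(nrow(X) - 1, ncol(X))]
  grid <- expand.grid(eta = eta_grid, n_components = ncomp_grid)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- fit_iaspls(X[tr, , drop = FALSE], y[tr],
                        n_components = grid$n_components[g],
                        eta = grid$eta[g], ...)
      pred <- predict(fit, X[!tr, , drop = FALSE])$labels
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  grid$cv_acc <- acc
  ord <- order(-grid$cv_acc, -grid$eta, grid$n_components)
  best <- grid[ord[1], ]
  list(eta = best$eta, n_components = best$n_components, cv_table = grid)
}
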