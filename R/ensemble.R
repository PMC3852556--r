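# Majority-voting training/prediction protocol and the repeated,
# stratified cross-validation harness.

# Stratified fold/block assignment: within each class, indices are
# shuffled (caller controls the RNG state) and dealt round-robin, so fold
# class ratios match the global ratio within one sample.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a majority-voting ensemble
#'
#' Shuffles the training rows with the given seed, splits them into K
#' nearly equal stratified sub-blocks and fits one member model per block.
#' K must be odd so that majority votes cannot tie.
#'
#' @param X numeric predictor matrix.
#' @param y response in -1/+1.
#' @param K odd number of sub-blocks/members (default 3).
#' @param hyperparams named list passed to the member fitting function.
#' @param seed RNG seed for the shuffle.
#' @param fit_member function `(X, y, ...)` returning a model understood by
#'   `predict_member`; defaults to [fit_iaspls()].
#' @param predict_member function `(model, X)` returning -1/+1 labels;
#'   defaults to `predict(model, X)$labels`.
#' @return object of class `voting_ensemble`.
#' @export
train_voting_ensemble <- function(X, y, K = 3, hyperparams = list(),
                                  seed = 1, fit_member = NULL,
                                  predict_member = NULL) {
  if (K < 1 || K %% 2 == 0) {
    stop("K must be an odd number for majority voting (got K = ", K, ")",
         call. = FALSE)
  }
  X <- as.matrix(X)
  y <- check_response(y)
  if (is.null(fit_member)) {
    # cap the per-member component count at the sub-block's rank bound:
    # blocks hold ~n/K rows and must stay fittable for small classes
    fit_member <- function(X, y, ...) {
      args <- list(...)
      a <- args$n_components %||% 3
      args$n_components <- max(1L, min(a, nrow(X) - 1L, ncol(X)))
      do.call(fit_iaspls, c(list(X, y), args))
    }
  }
  if (is.null(predict_member)) {
    predict_member <- function(model, X) predict(model, X)$labels
  }
  set.seed(seed)
  block <- stratified_folds(y, K)
  members <- vector("list", K)
  for (b in seq_len(K)) {
    rows <- which(block == b)
    if (length(unique(y[rows])) < 2) {
      stop("sub-block ", b, " lost a class; use a smaller K", call. = FALSE)
    }
    members[[b]] <- do.call(fit_member,
                            c(list(X[rows, , drop = FALSE], y[rows]),
                              hyperparams))
  }
  structure(list(K = K, members = members, seed = seed,
                 predict_member = predict_member,
                 hyperparams = hyperparams),
            class = "voting_ensemble")
}

#' Predict by majority vote
#'
#' Each member votes -1/+1; the ensemble label is +1 iff strictly more
#' than K/2 votes are +1 (no ties are possible with odd K).
#'
#' @param object a `voting_ensemble`.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @return list with `labels` and the n x K `votes` matrix.
#' @export
predict.voting_ensemble <- function(object, newdata, ...) {
  votes <- vapply(object$members,
                  function(m) object$predict_member(m, as.matrix(newdata)),
                  numeric(nrow(as.matrix(newdata))))
  votes <- matrix(votes, ncol = object$K)
  list(labels = ifelse(rowSums(votes) > 0, 1, -1), votes = votes)
}

#' Evaluation plan for repeated stratified cross-validation
#'
#' @param n_folds folds (default 5).
#' @param n_repeats number of reshuffled repetitions whose metrics are
#'   averaged (default 20).
#' @param train_fraction training fraction for single holdout splits
#'   (default 2/3; used by [holdout_split()]).
#' @param seed base RNG seed; repeat r uses `seed + r`.
#' @param balanced if TRUE, the larger class is downsampled to the smaller
#'   per repeat.
#' @return an `evaluation_plan` list.
#' @export
evaluation_plan <- function(n_folds = 5, n_repeats = 20,
                            train_fraction = 2 / 3, seed = 1,
                            balanced = FALSE) {
  stopifnot(n_folds >= 2, n_repeats >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_folds = n_folds, n_repeats = n_repeats,
                 train_fraction = train_fraction, seed = seed,
                 balanced = balanced),
            class = "evaluation_plan")
}

#' Stratified holdout split
#'
#' @param y response in -1/+1.
#' @param train_fraction fraction per class assigned to training.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(y, train_fraction = 2 / 3, seed = 1) {
  set.seed(seed)
  train <- integer(0)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    train <- c(train, idx[seq_len(round(train_fraction * length(idx)))])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Repeated stratified cross-validation with voting ensembles
#'
#' Per repeat r = 1..n_repeats the data are reshuffled with `seed + r`
#' into stratified folds; each training fold trains a [train_voting_ensemble()]
#' whose majority vote is evaluated on the held-out fold. Per-repeat
#' metrics come from the summed confusion counts over folds; the summary is
#' their arithmetic mean over repeats.
#'
#' @param X numeric predictor matrix.
#' @param y response in -1/+1.
#' @param plan an [evaluation_plan()].
#' @param K odd ensemble size.
#' @param hyperparams passed to the member fits.
#' @param fit_member,predict_member see [train_voting_ensemble()].
#' @return object of class `cv_result`: list with data.frames `folds`
#'   (one row per repeat x fold) and `repeats`, and a named `summary`
#'   vector of mean Sn/Sp/ACC/MCC.
#' @export
cross_validate <- function(X, y, plan = evaluation_plan(), K = 3,
                           hyperparams = list(), fit_member = NULL,
                           predict_member = NULL) {
  X <- as.matrix(X)
  y <- check_response(y)
  if (length(y) < plan$n_folds) stop("fewer samples than folds", call. = FALSE)
  fold_rows <- list()
  rep_rows <- list()
  for (r in seq_len(plan$n_repeats)) {
    set.seed(plan$seed + r)
    rows <- seq_along(y)
    if (plan$balanced) {
      n_min <- min(table(y))
      rows <- unlist(lapply(unique(y), function(cls) {
        idx <- which(y == cls)
        if (length(idx) > n_min) sample(idx, n_min) else idx
      }))
      rows <- sort(rows)
    }
    yr <- y[rows]
    folds <- stratified_folds(yr, plan$n_folds)
    agg <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
    for (f in seq_len(plan$n_folds)) {
      tr <- rows[folds != f]
      te <- rows[folds == f]
      if (length(unique(y[tr])) < 2) {
        stop("degenerate stratification: training fold lost a class",
             call. = FALSE)
      }
      ens <- train_voting_ensemble(X[tr, , drop = FALSE], y[tr], K = K,
                                   hyperparams = hyperparams,
                                   seed = (plan$seed + r) * 131L + f,
                                   fit_member = fit_member,
                                   predict_member = predict_member)
      pred <- predict(ens, X[te, , drop = FALSE])$labels
      cc <- confusion_counts(y[te], pred)
      met <- classification_metrics(cc)
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(rep = r, fold = f, TP = cc$TP, TN = cc$TN,
                   FP = cc$FP, FN = cc$FN, Sn = met["Sn"], Sp = met["Sp"],
                   ACC = met["ACC"], MCC = met["MCC"], row.names = NULL)
      for (nm in names(agg)) agg[[nm]] <- agg[[nm]] + cc[[nm]]
    }
    met_r <- classification_metrics(agg)
    rep_rows[[r]] <- data.frame(rep = r, TP = agg$TP, TN = agg$TN,
                                FP = agg$FP, FN = agg$FN,
                                Sn = met_r["Sn"], Sp = met_r["Sp"],
                                ACC = met_r["ACC"], MCC = met_r["MCC"],
                                row.names = NULL)
  }
  folds_df <- do.call(rbind, fold_rows)
  reps_df <- do.call(rbind, rep_rows)
  structure(list(folds = folds_df, repeats = reps_df,
                 summary = colMeans(reps_df[, c("Sn", "Sp", "ACC", "MCC")]),
                 plan = plan, K = K),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("cv_result: %d-fold x %d repeat(s), K = %d\n",
                     "  mean Sn = %.4f  Sp = %.4f  ACC = %.4f  MCC = %.4f\n"),
              x$plan$n_folds, x$plan$n_repeats, x$K,
              s["Sn"], s["Sp"], s["ACC"], s["MCC"]))
  invisible(x)
}
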