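#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive sample outscores a
#' randomly chosen negative one, with ties counted one half — the normalized
#' Mann-Whitney U statistic, computed from midranks.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or a two-level factor whose
#'   second level is the positive class).
#' @return the AUROC in \[0,1\].
#' @export
evaluate_auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop_input("both classes must be present")
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validation protocol for the gradient-boosted classifier
#'
#' @param reps number of repetitions of the train/test evaluation.
#' @param train_frac stratified training fraction (default 2/3).
#' @param inner_folds folds of the inner hyperparameter-selection CV.
#' @param grid data.frame of hyperparameter combinations with columns
#'   `max_depth`, `eta`, `nrounds`; the default grid is deliberately small.
#' @param colsample_bytree fraction of features sampled per tree. The
#'   sub-unity default decorrelates trees over redundant CpGs (neighbouring
#'   or co-shifted probes carry near-identical signal), so gain importance
#'   spreads over the contributing probe set instead of collapsing onto one
#'   representative; sampling is deterministic under the seed.
#' @param seed master seed; all splits derive from it and the sample ids.
#' @return a `cv_protocol` list.
#' @export
cv_protocol <- function(reps = 25, train_frac = 2 / 3, inner_folds = 5,
                        grid = expand.grid(max_depth = c(2, 3),
                                           eta = c(0.1, 0.3),
                                           nrounds = c(50, 200)),
                        colsample_bytree = 0.5, seed = 1L) {
  stopifnot(reps >= 1, train_frac > 0, train_frac < 1, inner_folds >= 2,
            all(c("max_depth", "eta", "nrounds") %in% names(grid)),
            colsample_bytree > 0, colsample_bytree <= 1)
  structure(list(reps = reps, train_frac = train_frac,
                 inner_folds = inner_folds, grid = grid,
                 colsample_bytree = colsample_bytree,
                 seed = as.integer(seed)),
            class = "cv_protocol")
}

# coerce labels to 0/1 integers, preserving names (as.integer drops them)
.canon_labels <- function(labels) {
  nm <- names(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  names(labels) <- nm
  labels
}

# Stratified deterministic split: within each class, samples are ordered by
# a hash of (seed, repetition, sample id) and the first round(train_frac * n)
# go to training. Depending only on ids makes every result invariant to the
# input ordering of samples.
.split_train_test <- function(ids, labels, train_frac, seed, rep) {
  train <- logical(length(ids))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    key <- vapply(ids[idx], function(s) str_seed(seed, "split", rep, s), 0L)
    ord <- idx[order(key, ids[idx])]
    n_train <- round(train_frac * length(idx))
    n_train <- max(1L, min(n_train, length(idx) - 1L))
    train[ord[seq_len(n_train)]] <- TRUE
  }
  train
}

# Stratified inner-fold assignment by hashed order, cyclic within class.
.inner_folds <- function(ids, labels, k, seed, rep) {
  fold <- integer(length(ids))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    key <- vapply(ids[idx], function(s) str_seed(seed, "fold", rep, s), 0L)
    ord <- idx[order(key, ids[idx])]
    fold[ord] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# The R xgboost binding draws its column subsampling from R's global RNG,
# so every fit runs under a seed derived from the protocol seed and the
# fit's context, making the whole procedure deterministic and independent
# of caller RNG state.
.fit_xgb <- function(x, y, params_row, colsample, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params_row$max_depth, eta = params_row$eta,
                  colsample_bytree = colsample,
                  nthread = 1),
    data = dtrain, nrounds = params_row$nrounds, verbose = 0))
}

#' Repeated train/test evaluation of a gradient-boosted classifier
#'
#' For each repetition, the samples are split into a stratified 2/3 training
#' and 1/3 test set; hyperparameters are chosen on the training set only, by
#' inner cross-validated AUROC over the protocol's grid (ties go to the
#' first, i.e. smallest, grid row); the model is refit on the full training
#' set and its AUROC on the withheld test set recorded. The final AUROC is
#' the arithmetic mean over repetitions. Feature importances (xgboost gain)
#' are averaged over the repetition models. Samples and features are
#' canonicalized by name internally, and splits depend on sample ids rather
#' than positions, so results are invariant to input ordering and
#' byte-identical under a fixed seed.
#'
#' @param features samples x features numeric matrix with sample-id rownames
#'   and feature colnames.
#' @param labels binary labels named by (or aligned with) the samples;
#'   positive class = 1.
#' @param protocol a [cv_protocol()].
#' @return a `classifier_report` list: `per_rep_auroc`, `mean_auroc`,
#'   `importance` (named per-feature mean gain), `chosen` (data.frame of
#'   per-repetition selected hyperparameters), `protocol`.
#' @export
repeated_cv_classify <- function(features, labels, protocol = cv_protocol()) {
  stopifnot(!is.null(rownames(features)), !is.null(colnames(features)))
  labels <- .canon_labels(labels)
  if (!is.null(names(labels))) labels <- labels[rownames(features)]
  stopifnot(length(labels) == nrow(features), all(labels %in% 0:1))
  if (min(table(labels)) < 4) {
    stop_input("each class needs >= 4 samples for a stratified 2/3 split")
  }
  # canonical order: samples and features by name
  ord_s <- order(rownames(features))
  ord_f <- order(colnames(features))
  x <- features[ord_s, ord_f, drop = FALSE]
  y <- labels[ord_s]
  ids <- rownames(x)

  grid <- protocol$grid
  per_rep <- numeric(protocol$reps)
  chosen <- vector("list", protocol$reps)
  imp_sum <- setNames(numeric(ncol(x)), colnames(x))

  for (r in seq_len(protocol$reps)) {
    in_train <- .split_train_test(ids, y, protocol$train_frac,
                                  protocol$seed, r)
    x_tr <- x[in_train, , drop = FALSE]
    y_tr <- y[in_train]
    fold <- .inner_folds(ids[in_train], y_tr, protocol$inner_folds,
                         protocol$seed, r)

    inner_auc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      pred <- rep(NA_real_, length(y_tr))
      for (f in sort(unique(fold))) {
        hold <- fold == f
        if (all(hold) || length(unique(y_tr[!hold])) < 2) next
        fit <- .fit_xgb(x_tr[!hold, , drop = FALSE], y_tr[!hold],
                        grid[gi, ], protocol$colsample_bytree,
                        seed = str_seed(protocol$seed, "inner", r, gi, f))
        pred[hold] <- predict(fit, xgboost::xgb.DMatrix(
          x_tr[hold, , drop = FALSE], nthread = 1))
      }
      ok <- !is.na(pred)
      inner_auc[gi] <- if (length(unique(y_tr[ok])) == 2) {
        evaluate_auroc(pred[ok], y_tr[ok])
      } else NA_real_
    }
    best <- which.max(inner_auc)          # ties -> first (smallest) grid row
    chosen[[r]] <- cbind(rep = r, grid[best, , drop = FALSE])

    fit <- .fit_xgb(x_tr, y_tr, grid[best, ], protocol$colsample_bytree,
                    seed = str_seed(protocol$seed, "final", r))
    test_pred <- predict(fit, xgboost::xgb.DMatrix(
      x[!in_train, , drop = FALSE], nthread = 1))
    per_rep[r] <- evaluate_auroc(test_pred, y[!in_train])

    imp <- xgboost::xgb.importance(model = fit)
    if (!is.null(imp) && nrow(imp) > 0) {
      imp_sum[imp$Feature] <- imp_sum[imp$Feature] + imp$Gain
    }
  }

  structure(list(per_rep_auroc = per_rep, mean_auroc = mean(per_rep),
                 importance = imp_sum / protocol$reps,
                 chosen = do.call(rbind, chosen), protocol = protocol),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Repeated CV gradient boosting: %d repetitions\n",
              length(x$per_rep_auroc)))
  cat(sprintf("Mean test AUROC: %.3f (range %.3f-%.3f)\n", x$mean_auroc,
              min(x$per_rep_auroc), max(x$per_rep_auroc)))
  top <- sort(x$importance, decreasing = TRUE)
  top <- top[top > 0]
  cat("Top features by mean gain:\n")
  print(round(head(top, 10), 4))
  invisible(x)
}

#' Label-permutation null of the repeated-CV AUROC
#'
#' Reference distribution for the classifier's mean AUROC: each repetition
#' draws a fresh label permutation and runs one full train/test evaluation
#' (split, inner hyperparameter selection, refit, test AUROC). Averaging
#' over fresh permutations keeps the null centred at 0.5; keeping one fixed
#' permutation across repetitions instead inherits a finite-population
#' anti-learning bias on strongly clustered features (train/test label
#' balances are negatively dependent), which can push the mean AUROC well
#' below 0.5.
#'
#' @inheritParams repeated_cv_classify
#' @return list with `per_rep_auroc` (one per permutation) and `mean_auroc`.
#' @export
null_auroc <- function(features, labels, protocol = cv_protocol()) {
  labels <- .canon_labels(labels)
  if (!is.null(names(labels))) labels <- labels[rownames(features)]
  per_rep <- numeric(protocol$reps)
  for (r in seq_len(protocol$reps)) {
    perm <- with_seed(str_seed(protocol$seed, "null-perm", r), sample(labels))
    names(perm) <- rownames(features)
    proto_r <- protocol
    proto_r$reps <- 1L
    proto_r$seed <- str_seed(protocol$seed, "null-run", r)
    per_rep[r] <- repeated_cv_classify(features, perm, proto_r)$mean_auroc
  }
  list(per_rep_auroc = per_rep, mean_auroc = mean(per_rep))
}

#' Permutation significance of classifier features
#'
#' The observed importance of each feature is its mean learner gain across
#' the repetitions of [repeated_cv_classify()]. The null distribution comes
#' from `B_perm` label-permuted reruns of the same protocol (with an
#' optionally reduced repetition count `null_reps` to keep the cost
#' proportionate); the per-feature empirical p-value is
#' (#\{null importance >= observed\} + 1)/(B_perm + 1), pooling every
#' permutation's importance for that feature. Features are selected at
#' BH-adjusted p < 0.05. This is a permutation-importance criterion with an
#' empirical null — a transparent stand-in for information-decomposition
#' importance methods, preserving the falsifiable claim that specific CpGs
#' contribute significantly to the model.
#'
#' @param features samples x features matrix (as [repeated_cv_classify()]).
#' @param labels binary labels.
#' @param protocol a [cv_protocol()].
#' @param B_perm number of label permutations (>= 20).
#' @param null_reps repetitions per permuted rerun (default
#'   `min(protocol$reps, 5)`).
#' @param alpha BH selection level.
#' @return a `feature_significance` list: `observed` (named importances),
#'   `p` (named empirical p-values), `adj_p`, `selected` (feature names),
#'   `report` (the observed `classifier_report`).
#' @export
permutation_feature_significance <- function(features, labels,
                                             protocol = cv_protocol(),
                                             B_perm = 50,
                                             null_reps = min(protocol$reps, 5),
                                             alpha = 0.05) {
  stopifnot(B_perm >= 20)
  report <- repeated_cv_classify(features, labels, protocol)
  observed <- report$importance

  null_proto <- protocol
  null_proto$reps <- null_reps
  labels <- .canon_labels(labels)
  if (!is.null(names(labels))) labels <- labels[rownames(features)]

  exceed <- setNames(numeric(length(observed)), names(observed))
  for (b in seq_len(B_perm)) {
    perm <- with_seed(str_seed(protocol$seed, "perm", b),
                      sample(labels))
    names(perm) <- rownames(features)
    null_proto$seed <- str_seed(protocol$seed, "perm-run", b)
    null_rep <- repeated_cv_classify(features, perm, null_proto)
    exceed <- exceed + (null_rep$importance[names(observed)] >= observed)
  }
  p <- (exceed + 1) / (B_perm + 1)
  adj <- bh_adjust(p)
  structure(list(observed = observed, p = p, adj_p = setNames(adj, names(p)),
                 selected = names(p)[!is.na(adj) & adj < alpha],
                 report = report),
            class = "feature_significance")
}
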