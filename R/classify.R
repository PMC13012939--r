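# ---------------------------------------------------------------------------
# Pairwise subtype classification: leak-free nested stratified CV with
# per-fold covariate residualization, min-max scaling, LASSO feature
# selection, an L2-regularized logistic final model, pooled-ROC Youden
# evaluation and a label-permutation significance test.
# ---------------------------------------------------------------------------

#' Assemble a feature matrix for classification
#'
#' @param values Numeric matrix / data frame, subjects x features, no
#'   missing values.
#' @param labels Binary class label per subject (0/1 or a two-level
#'   factor/character; the second sorted level is coded 1).
#' @param subject_ids Optional subject identifiers (default rownames).
#' @param task Name of the pairwise task (e.g. `"EMCI-LMCI"`).
#' @param require_both_classes Enforce >= 2 subjects per class (the
#'   assembly invariant); internal fold partitions relax this.
#' @return List of class `klsnet_features`: `values` (matrix), `labels`
#'   (0/1 integer), `subject_ids`, `feature_ids`, `task`.
#' @export
feature_matrix <- function(values, labels, subject_ids = NULL,
                           task = "task", require_both_classes = TRUE) {
  values <- as.matrix(values)
  assert_that(all(is.finite(values)), "feature matrix has missing values",
              "klsnet_validation_error")
  if (!is.numeric(labels) || !all(labels %in% c(0, 1))) {
    lev <- sort(unique(as.character(labels)))
    assert_that(length(lev) == 2, "labels must have exactly 2 classes",
                "klsnet_validation_error")
    labels <- as.integer(as.character(labels) == lev[2])
  }
  labels <- as.integer(labels)
  if (require_both_classes) {
    assert_that(length(unique(labels)) == 2 && min(table(labels)) >= 2,
                "need >= 2 subjects per class", "klsnet_validation_error")
  }
  subject_ids <- subject_ids %||% rownames(values) %||%
    sprintf("S%04d", seq_len(nrow(values)))
  feature_ids <- colnames(values) %||%
    sprintf("f%02d", seq_len(ncol(values)))
  dimnames(values) <- list(subject_ids, feature_ids)
  structure(list(values = values, labels = labels,
                 subject_ids = subject_ids, feature_ids = feature_ids,
                 task = task), class = "klsnet_features")
}

.subset_features <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], fm$labels[idx],
                 fm$subject_ids[idx], fm$task,
                 require_both_classes = FALSE)
}

.cov_rows <- function(covariates, subject_ids) {
  covariates <- as.data.frame(covariates)
  if ("subject_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$subject_id
    covariates$subject_id <- NULL
  }
  assert_that(all(subject_ids %in% rownames(covariates)),
              "covariates must cover all subjects (by subject_id/rowname)",
              "klsnet_validation_error")
  covariates[subject_ids, , drop = FALSE]
}

#' Train-fold covariate residualization
#'
#' Fits, per feature, a linear model on the covariates using the TRAIN
#' partition only, and replaces values in both partitions by residuals
#' computed with the train-fitted coefficients.  No test-set statistic
#' influences the fit (leak-freedom).
#'
#' @param train,test `klsnet_features` partitions.
#' @param covariates Covariate data frame indexed by `subject_id` column
#'   or rownames, covering both partitions.
#' @return List `train`, `test` of residualized `klsnet_features`.
#' @export
residualize_features <- function(train, test, covariates) {
  ctr <- .cov_rows(covariates, train$subject_ids)
  cte <- .cov_rows(covariates, test$subject_ids)
  Xtr <- stats::model.matrix(~ ., data = ctr)
  Xte <- stats::model.matrix(~ ., data = rbind(ctr, cte))
  Xte <- Xte[-seq_len(nrow(ctr)), , drop = FALSE]
  q <- qr(Xtr)
  if (q$rank < ncol(Xtr)) {
    stop_klsnet("rank-deficient covariate design in residualization",
                "klsnet_rank_error")
  }
  beta <- qr.coef(q, train$values)
  rtr <- train$values - Xtr %*% beta
  rte <- test$values - Xte %*% beta
  list(train = feature_matrix(rtr, train$labels, train$subject_ids,
                              train$task, require_both_classes = FALSE),
       test = feature_matrix(rte, test$labels, test$subject_ids,
                             test$task, require_both_classes = FALSE))
}

#' Min-max scaling with train-derived parameters
#'
#' Maps each train feature to \[0, 1\] using its train minimum and range;
#' the test partition is transformed with the same parameters, so test
#' values may legitimately fall outside \[0, 1\] (they are not clipped,
#' preserving monotone ordering).  Zero-range train features are dropped
#' from both partitions with a warning.
#'
#' @param train,test `klsnet_features` partitions.
#' @return List `train`, `test` of scaled `klsnet_features`.
#' @export
minmax_scale <- function(train, test) {
  lo <- apply(train$values, 2, min)
  hi <- apply(train$values, 2, max)
  keep <- hi > lo
  if (!all(keep)) {
    warning(sprintf("dropping zero-range feature(s): %s",
                    paste(train$feature_ids[!keep], collapse = ", ")))
  }
  assert_that(any(keep), "all features have zero range",
              "klsnet_degenerate_error")
  sc <- function(v) sweep(sweep(v[, keep, drop = FALSE], 2, lo[keep]),
                          2, (hi - lo)[keep], "/")
  list(train = feature_matrix(sc(train$values), train$labels,
                              train$subject_ids, train$task,
                              require_both_classes = FALSE),
       test = feature_matrix(sc(test$values), test$labels,
                             test$subject_ids, test$task,
                             require_both_classes = FALSE))
}

# stratified k-fold assignment: shuffled round-robin per class keeps the
# class ratio of every fold within +/- 1 subject
.stratified_folds <- function(y, k, seed) {
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# trapezoidal AUC over the empirical ROC (equals the Mann-Whitney
# statistic with half-weight ties)
.auc_trapezoid <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.default_penalty_grid <- function() 10^seq(3, -3, length.out = 20)

# inner stratified CV over a lambda grid, criterion mean AUC; returns the
# best lambda (ties -> larger penalty, i.e. more regularization)
.tune_lambda <- function(x, y, alpha, grid, inner_folds, seed) {
  grid <- sort(grid, decreasing = TRUE)
  fold <- .stratified_folds(y, inner_folds, seed)
  aucs <- matrix(NA_real_, inner_folds, length(grid))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = alpha,
                          lambda = grid, standardize = FALSE)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE], s = grid,
                           type = "response")
    aucs[f, seq_len(ncol(pred))] <-
      apply(pred, 2, .auc_trapezoid, labels = y[!tr])
  }
  mauc <- colMeans(aucs, na.rm = TRUE)
  if (all(!is.finite(mauc))) return(grid[ceiling(length(grid) / 2)])
  grid[which.max(replace(mauc, !is.finite(mauc), -Inf))]
}

#' LASSO feature selection by inner cross-validated logistic regression
#'
#' Fits L1-regularized logistic regressions over a penalty grid, picks
#' the penalty maximizing mean AUC over stratified inner folds, and
#' returns the features with non-zero coefficients at that penalty.
#'
#' @param train A scaled `klsnet_features` (train partition only).
#' @param penalty_grid Lambda grid (default 20 log-spaced values,
#'   1e-3 to 1e3).
#' @param inner_folds Number of stratified inner folds.
#' @param seed Integer seed for fold assignment.
#' @return Character vector of selected feature ids (may be empty; the
#'   caller is expected to fall back to all features with a warning).
#' @export
lasso_select <- function(train, penalty_grid = .default_penalty_grid(),
                         inner_folds = 5L, seed = 1L) {
  x <- train$values
  y <- train$labels
  assert_that(min(table(y)) >= inner_folds,
              "need >= inner_folds subjects per class",
              "klsnet_contract_error")
  if (ncol(x) < 2) return(colnames(x))
  lam <- .tune_lambda(x, y, alpha = 1, grid = penalty_grid,
                      inner_folds = inner_folds, seed = seed)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = sort(penalty_grid, decreasing = TRUE),
                        standardize = FALSE)
  cf <- as.matrix(stats::coef(fit, s = lam))[-1, 1]
  names(cf)[cf != 0]
}

# final L2-penalized logistic model on the selected features; inner-CV
# tuned ridge penalty.  Falls back to unpenalized glm for one feature.
.fit_final <- function(x, y, penalty_grid, inner_folds, seed) {
  if (ncol(x) >= 2) {
    lam <- .tune_lambda(x, y, alpha = 0, grid = penalty_grid,
                        inner_folds = inner_folds, seed = seed)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = sort(penalty_grid, decreasing = TRUE),
                          standardize = FALSE)
    function(newx) as.numeric(stats::predict(fit, newx, s = lam,
                                             type = "response"))
  } else {
    df <- data.frame(y = y, x = x[, 1])
    fit <- suppressWarnings(stats::glm(y ~ x, data = df,
                                       family = stats::binomial()))
    function(newx) as.numeric(stats::predict(
      fit, data.frame(x = newx[, 1]), type = "response"))
  }
}

#' Nested cross-validated pairwise classification
#'
#' Outer stratified 10-fold CV; within each outer training fold the
#' pipeline is: covariate residualization (train-fitted), min-max scaling
#' (train parameters), LASSO feature selection, then an L2-regularized
#' logistic model on the selected features with its penalty tuned by
#' inner stratified 5-fold CV (criterion: mean AUC).  Held-out
#' probabilities from all outer folds are pooled into one ROC.
#'
#' @param features A `klsnet_features`.
#' @param covariates Covariate data frame covering all subjects (or
#'   `NULL` to skip residualization).
#' @param outer_folds,inner_folds Fold counts (defaults 10 and 5).
#' @param penalty_grid Lambda grid used for both selection and the final
#'   ridge tuning.
#' @param seed Integer seed; identical config + seed gives an identical
#'   report.
#' @return List of class `klsnet_classification`: `task`,
#'   `pooled_scores` (out-of-fold probability per subject), `labels`,
#'   `fold_id`, `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `threshold`, `selected` (per-fold feature sets),
#'   `selection_frequency`, `permutation_p` (`NA` until
#'   [permutation_test_auc()]).
#' @export
nested_cv_classify <- function(features, covariates = NULL,
                               outer_folds = 10L, inner_folds = 5L,
                               penalty_grid = .default_penalty_grid(),
                               seed = 1L) {
  y <- features$labels
  if (min(table(y)) < outer_folds) {
    stop_klsnet(sprintf(
      "smallest class (n=%d) < outer_folds (%d); use fewer folds",
      min(table(y)), outer_folds), "klsnet_argument_error")
  }
  fold <- .stratified_folds(y, outer_folds, seed)
  scores <- rep(NA_real_, length(y))
  selected <- vector("list", outer_folds)
  for (f in seq_len(outer_folds)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    tr <- .subset_features(features, tr_idx)
    te <- .subset_features(features, te_idx)
    if (!is.null(covariates)) {
      rz <- residualize_features(tr, te, covariates)
      tr <- rz$train; te <- rz$test
    }
    sc <- minmax_scale(tr, te)
    tr <- sc$train; te <- sc$test
    fold_seed <- derive_seed(seed, paste0("outer", f))
    sel <- lasso_select(tr, penalty_grid, inner_folds, seed = fold_seed)
    if (!length(sel)) {
      warning(sprintf(
        "fold %d: LASSO selected no features; falling back to all", f))
      sel <- tr$feature_ids
    }
    selected[[f]] <- sel
    xtr <- tr$values[, sel, drop = FALSE]
    xte <- te$values[, sel, drop = FALSE]
    predict_fun <- .fit_final(xtr, tr$labels, penalty_grid, inner_folds,
                              seed = fold_seed)
    scores[te_idx] <- predict_fun(xte)
  }
  perf <- pooled_roc_youden(scores, y)
  freq <- sort(table(unlist(selected)) / outer_folds, decreasing = TRUE)
  structure(list(task = features$task, pooled_scores = scores, labels = y,
                 fold_id = fold, auc = perf$auc, accuracy = perf$accuracy,
                 sensitivity = perf$sensitivity,
                 specificity = perf$specificity,
                 threshold = perf$threshold, degenerate = perf$degenerate,
                 selected = selected, selection_frequency = freq,
                 permutation_p = NA_real_, seed = seed),
            class = "klsnet_classification")
}

#' Pooled ROC with Youden-optimal operating point
#'
#' AUC is the trapezoidal area under the empirical ROC of the pooled
#' out-of-fold scores (rank / Mann-Whitney form, ties half-weighted).
#' The operating threshold maximizes Youden's J = sensitivity +
#' specificity - 1 over the distinct score values (classification rule:
#' positive when score >= threshold); ties take the lowest threshold.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1), both classes present.
#' @return List `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `threshold`, `degenerate` (TRUE for constant scores, AUC 0.5).
#' @export
pooled_roc_youden <- function(scores, labels) {
  labels <- as.integer(labels)
  assert_that(all(labels %in% c(0, 1)) && length(unique(labels)) == 2,
              "labels must contain both classes",
              "klsnet_contract_error")
  assert_that(all(is.finite(scores)), "scores must be finite",
              "klsnet_contract_error")
  if (max(scores) == min(scores)) {
    # constant scores carry no ranking information
    sens <- 1; spec <- 0
    acc <- mean(labels == 1)
    return(list(auc = 0.5, accuracy = acc, sensitivity = sens,
                specificity = spec, threshold = scores[1],
                degenerate = TRUE))
  }
  auc <- .auc_trapezoid(scores, labels)
  cand <- sort(unique(scores))
  stats_at <- function(t) {
    pred <- scores >= t
    c(sens = sum(pred & labels == 1) / sum(labels == 1),
      spec = sum(!pred & labels == 0) / sum(labels == 0))
  }
  ss <- vapply(cand, stats_at, numeric(2))
  j <- ss["sens", ] + ss["spec", ] - 1
  best <- which(j == max(j))[1]  # ties -> lowest threshold
  thr <- cand[best]
  pred <- scores >= thr
  list(auc = auc,
       accuracy = mean(pred == (labels == 1)),
       sensitivity = unname(ss["sens", best]),
       specificity = unname(ss["spec", best]),
       threshold = thr, degenerate = FALSE)
}

#' Permutation significance of a pooled cross-validated AUC
#'
#' Permutes the class labels `B` times and reruns the complete nested-CV
#' pipeline (including per-fold residualization, scaling and feature
#' selection) on each permutation; the p-value is
#' `(1 + #\{AUC_perm >= AUC_obs\}) / (B + 1)`.
#'
#' @param features A `klsnet_features`.
#' @param covariates Covariates forwarded to [nested_cv_classify()].
#' @param observed_auc The AUC whose significance is tested (typically
#'   from [nested_cv_classify()] on the unpermuted labels).
#' @param B Number of permutations (study default 5000; use ~200 at desk
#'   scale).
#' @param seed Integer seed; fold generation inside each permutation
#'   reuses the same seed policy as the observed run.
#' @param ... Further arguments to [nested_cv_classify()]
#'   (`outer_folds`, `inner_folds`, `penalty_grid`).
#' @return List `p` (permutation p-value), `B`, `perm_auc` (vector of
#'   permuted AUCs).
#' @export
permutation_test_auc <- function(features, covariates = NULL,
                                 observed_auc, B = 5000L, seed = 1L,
                                 ...) {
  assert_that(B >= 1, "B must be >= 1", "klsnet_contract_error")
  perm_auc <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, paste0("perm", b)))
    yp <- sample(features$labels)
    fp <- feature_matrix(features$values, yp, features$subject_ids,
                         features$task)
    rep_b <- suppressWarnings(
      nested_cv_classify(fp, covariates, seed = seed, ...))
    perm_auc[b] <- rep_b$auc
  }
  p <- (1 + sum(perm_auc >= observed_auc)) / (B + 1)
  list(p = p, B = B, perm_auc = perm_auc)
}
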