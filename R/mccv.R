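#' Balanced Monte-Carlo cross-validation splits
#'
#' Draws `n_iterations` independent stratified train/test splits: within
#' each class, `round(train_fraction * class size)` samples (half-up
#' rounding, so a 36/40 cohort trains on 24 cases + 27 controls) go to
#' training, the rest to test. Deterministic given `seed`; samples recur
#' across test sets, never within one iteration.
#'
#' @param labels Case/control labels for all samples (named vector or a
#'   [sample_table()] `group`); both classes need at least 3 samples.
#' @param n_iterations Number of splits (default 10).
#' @param train_fraction Fraction of each class used for training
#'   (default 2/3).
#' @param seed Integer seed.
#' @return Object of class `mccv_plan`: list with `splits` (each a list of
#'   integer `train` / `test` indices), `n_iterations`, `train_fraction`,
#'   `seed`.
#' @export
make_splits <- function(labels, n_iterations = 10, train_fraction = 2 / 3,
                        seed = 1) {
  y <- as_case_indicator(labels)
  if (n_iterations < 1) stop("`n_iterations` must be at least 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)")
  i_case <- which(y); i_ctrl <- which(!y)
  if (length(i_case) < 3 || length(i_ctrl) < 3)
    stop("each class needs at least 3 samples")
  n_tr <- function(k) {
    m <- floor(train_fraction * k + 0.5)        # round half up
    min(max(m, 1L), k - 1L)                     # keep both sides non-empty
  }
  set.seed(as.integer(seed))
  splits <- lapply(seq_len(n_iterations), function(i) {
    tr <- c(sample(i_case, n_tr(length(i_case))),
            sample(i_ctrl, n_tr(length(i_ctrl))))
    list(train = sort(tr), test = sort(setdiff(seq_along(y), tr)))
  })
  structure(list(splits = splits, n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "mccv_plan")
}

#' Rank features by training-fold discrimination
#'
#' Orders features by decreasing absolute Welch t statistic computed on the
#' training fold only (constant features rank last with |t| = 0).
#'
#' @param X_train Numeric matrix with column names.
#' @param y_train Labels with both classes present.
#' @return Character vector of feature names, most discriminative first.
#' @export
rank_features_fold <- function(X_train, y_train) {
  y <- as_case_indicator(y_train)
  tt <- vapply(seq_len(ncol(X_train)), function(j) {
    x1 <- X_train[y, j]; x0 <- X_train[!y, j]
    if (stats::var(x1) == 0 && stats::var(x0) == 0) return(0)
    abs(welch_t(x1, x0)$t_stat)
  }, 0)
  colnames(X_train)[order(-tt, colnames(X_train))]
}

#' Run Monte-Carlo cross-validation
#'
#' Per iteration of the plan: rank the candidate features on the training
#' fold, keep the top `top_k`, fit the model on the training fold, and score
#' the held-out third. A model failure in a fold is recorded and the fold
#' skipped with a warning; the run never aborts.
#'
#' By default the table is consumed as-is (normalize once globally, then
#' cross-validate -- the design this pipeline mirrors). With
#' `rescale_in_fold = TRUE` the table must be raw: each fold then
#' median-normalizes per sample and fits the Pareto parameters on its
#' training fold only, applying them to the test fold (leakage-safe mode).
#'
#' @param table A [sample_table()] without missing values (Pareto-scaled by
#'   default usage; raw if `rescale_in_fold`).
#' @param features Candidate feature names (subset of the table's
#'   metabolites).
#' @param spec A [model_spec()].
#' @param plan A [make_splits()] plan for the table's samples.
#' @param top_k Number of top-ranked features kept per fold (default: all
#'   candidates, i.e. ranking reorders but drops nothing).
#' @param rescale_in_fold Re-fit normalization inside each training fold.
#' @return Object of class `mccv_folds`: per-iteration list with `test_ids`,
#'   `prob` (case probability per test sample), `auc`, `features_used`;
#'   plus `labels` and `failed` (indices of skipped folds).
#' @export
run_mccv <- function(table, features, spec, plan,
                     top_k = length(features), rescale_in_fold = FALSE) {
  stopifnot(inherits(table, "sample_table"), inherits(spec, "model_spec"),
            inherits(plan, "mccv_plan"))
  if (!all(features %in% colnames(table$values)))
    stop("unknown feature(s): ",
         paste(setdiff(features, colnames(table$values)), collapse = ", "))
  if (anyNA(table$values)) stop("missing values present; impute first")
  if (rescale_in_fold) check_scale_state(table, "raw", "run_mccv(rescale_in_fold)")

  v <- if (rescale_in_fold) median_normalize(table)$values
       else table$values
  v <- v[, features, drop = FALSE]
  y <- table$group
  iterations <- vector("list", plan$n_iterations)
  failed <- integer()
  for (i in seq_len(plan$n_iterations)) {
    sp <- plan$splits[[i]]
    Xtr <- v[sp$train, , drop = FALSE]
    Xte <- v[sp$test, , drop = FALSE]
    if (rescale_in_fold) {
      m <- colMeans(Xtr)
      s <- apply(Xtr, 2L, stats::sd)
      if (any(s == 0)) s[s == 0] <- 1          # degenerate fold feature
      Xtr <- sweep(sweep(Xtr, 2L, m), 2L, sqrt(s), "/")
      Xte <- sweep(sweep(Xte, 2L, m), 2L, sqrt(s), "/")
    }
    res <- tryCatch({
      ranked <- rank_features_fold(Xtr, y[sp$train])
      use <- ranked[seq_len(min(top_k, length(ranked)))]
      fold_spec <- spec
      fold_spec$seed <- (spec$seed + 1009L * i) %% 2147483647L
      fit <- train_model(fold_spec, Xtr[, use, drop = FALSE], y[sp$train])
      prob <- score_model(fit, Xte[, use, drop = FALSE])
      list(test_ids = rownames(v)[sp$test],
           prob = stats::setNames(prob, rownames(v)[sp$test]),
           auc = roc_auc(prob, y[sp$test]),
           features_used = use)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("fold ", i, " failed and was skipped: ", conditionMessage(res))
      failed <- c(failed, i)
    } else {
      iterations[[i]] <- res
    }
  }
  structure(list(iterations = iterations[!vapply(iterations, is.null, TRUE)],
                 failed = failed,
                 labels = stats::setNames(as.character(y), rownames(v))),
            class = "mccv_folds")
}

# internal: step-interpolate a fold ROC curve onto a common FPR grid
tpr_at_fpr <- function(curve, grid) {
  # collapse to the max TPR attained at each FPR, then carry forward
  agg <- tapply(curve$tpr, curve$fpr, max)
  fp <- as.numeric(names(agg))
  vapply(grid, function(g) {
    ok <- fp <= g + 1e-12
    if (any(ok)) max(agg[ok]) else 0
  }, 0)
}

#' Aggregate MCCV folds
#'
#' Combines fold predictions into the study-style summary: the vertically
#' averaged ROC curve on a common FPR grid (0, 0.01, ..., 1), the mean of
#' the fold AUCs with a percentile interval across folds, each sample's mean
#' case probability over the iterations where it was held out, and the
#' confusion matrix obtained by calling a sample `case` when that mean
#' probability is at least 0.5. With `roc_method = "pool"` the ROC curve and
#' AUC are instead computed from all test-set predictions pooled.
#'
#' @param folds A [run_mccv()] result with at least one successful fold.
#' @param roc_method `"average"` (default) or `"pool"`.
#' @return Object of class `mccv_result`: `averaged_roc` (data frame `fpr`,
#'   `tpr`), `auc_mean`, `ci`, `fold_aucs`, `per_sample_prob`, `confusion`
#'   (list `tp`, `fn`, `tn`, `fp`), `n_folds`.
#' @export
aggregate_mccv <- function(folds, roc_method = c("average", "pool")) {
  roc_method <- match.arg(roc_method)
  stopifnot(inherits(folds, "mccv_folds"))
  its <- folds$iterations
  if (!length(its)) stop("no successful folds to aggregate")
  labels <- folds$labels

  fold_aucs <- vapply(its, `[[`, 0, "auc")
  grid <- seq(0, 1, by = 0.01)
  if (roc_method == "average") {
    curves <- lapply(its, function(it)
      roc_curve(it$prob, labels[it$test_ids], orient = FALSE))
    tprs <- vapply(curves, tpr_at_fpr, numeric(length(grid)), grid = grid)
    avg_roc <- data.frame(fpr = grid, tpr = rowMeans(tprs))
    auc_mean <- mean(fold_aucs)
  } else {
    all_prob <- unlist(lapply(its, `[[`, "prob"))
    all_lab <- labels[unlist(lapply(its, `[[`, "test_ids"))]
    pooled <- roc_curve(all_prob, all_lab, orient = FALSE)
    avg_roc <- data.frame(fpr = pooled$fpr, tpr = pooled$tpr)
    auc_mean <- pooled$auc
  }
  ci <- if (length(fold_aucs) > 1)
    unname(stats::quantile(fold_aucs, c(0.025, 0.975)))
  else rep(fold_aucs, 2)

  # mean probability per sample over its test-set appearances
  all_ids <- unlist(lapply(its, `[[`, "test_ids"))
  all_prob <- unlist(lapply(its, `[[`, "prob"))
  agg <- tapply(all_prob, all_ids, mean)
  per_sample <- stats::setNames(as.numeric(agg), names(agg))
  never <- setdiff(names(labels), names(per_sample))
  if (length(never))
    warning(length(never), " sample(s) never appeared in a test set and are ",
            "excluded from the confusion matrix: ",
            paste(never, collapse = ", "))
  pred_case <- per_sample >= 0.5
  is_case <- labels[names(per_sample)] == "case"
  confusion <- list(tp = sum(pred_case & is_case),
                    fn = sum(!pred_case & is_case),
                    tn = sum(!pred_case & !is_case),
                    fp = sum(pred_case & !is_case))
  structure(list(averaged_roc = avg_roc, auc_mean = auc_mean, ci = ci,
                 fold_aucs = fold_aucs,
                 per_sample_prob = per_sample[order(names(per_sample))],
                 confusion = confusion, n_folds = length(its),
                 roc_method = roc_method),
            class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("<mccv_result> %d folds, AUC %.3f (95%% fold interval %.3f-%.3f)\n",
              x$n_folds, x$auc_mean, x$ci[1], x$ci[2]))
  cm <- x$confusion
  cat(sprintf("  confusion @0.5: tp=%d fn=%d tn=%d fp=%d\n",
              cm$tp, cm$fn, cm$tn, cm$fp))
  invisible(x)
}

#' @export
plot.mccv_result <- function(x, ...) {
  graphics::plot(x$averaged_roc$fpr, x$averaged_roc$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Cross-validated ROC evaluation of a biomarker panel
#'
#' Convenience wrapper: build the split plan, run MCCV and aggregate, for
#' one model kind.
#'
#' @param table A Pareto-scaled [sample_table()] (or raw with
#'   `rescale_in_fold`).
#' @param features Biomarker panel (metabolite names).
#' @param kind Model kind, see [model_spec()].
#' @param n_iterations,seed Passed to [make_splits()]; `seed` also seeds the
#'   model.
#' @param ... Further arguments to [model_spec()].
#' @inheritParams run_mccv
#' @return An `mccv_result`.
#' @export
evaluate_panel <- function(table, features, kind = "linear_svm",
                           n_iterations = 10, seed = 1,
                           rescale_in_fold = FALSE, ...) {
  plan <- make_splits(table$group, n_iterations = n_iterations, seed = seed)
  spec <- model_spec(kind, seed = seed, ...)
  folds <- run_mccv(table, features, spec, plan,
                    rescale_in_fold = rescale_in_fold)
  aggregate_mccv(folds)
}
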