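test_that("splits are stratified, two-thirds per class, and partition the cohort", {
  labels <- rep(c("case", "control"), c(36, 40))
  plan <- make_splits(labels, n_iterations = 10, seed = 3)
  is_case <- labels == "case"
  for (sp in plan$splits) {
    expect_identical(sum(is_case[sp$train]), 24L)   # round(2/3 * 36)
    expect_identical(sum(!is_case[sp$train]), 27L)  # round(2/3 * 40)
    expect_identical(sum(is_case[sp$test]), 12L)
    expect_identical(sum(!is_case[sp$test]), 13L)
    expect_identical(sort(c(sp$train, sp$test)), 1:76)   # exact partition
    expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_identical(plan, make_splits(labels, n_iterations = 10, seed = 3))
  expect_error(make_splits(rep(c("case", "control"), c(2, 40))), "at least 3")
})

test_that("fold feature ranking orders by training-fold |t|", {
  set.seed(23)
  n <- 30
  y <- rep(c("case", "control"), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[, "f4"] <- 7                                   # constant: |t| = 0
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    Xs <- X
    Xs[, -4] <- matrix(rnorm(n * 4), n, 4)
    Xs[, "f2"] <- Xs[, "f2"] + 2 * (y == "case")   # planted
    ranked <- rank_features_fold(Xs, y)
    hits <- hits + (ranked[1] == "f2")
    expect_identical(ranked[5], "f4")              # constant ranks last
  }
  expect_gte(hits, 18)
})

test_that("MCCV is deterministic, perfect on separable data, and near 0.5 under permutation", {
  # separable synthetic data: huge planted shift
  mets <- c(lapply(1:2, function(i)
    metabolite_spec(paste0("sig", i), log_sd = 0.2, fold_change = 50)),
    list(metabolite_spec("noise1"), metabolite_spec("noise2")))
  tab <- preprocess_table(generate_cohort(cohort_spec(12, 12, mets), seed = 4))
  plan <- make_splits(tab$group, n_iterations = 5, seed = 4)
  folds <- run_mccv(tab, c("sig1", "sig2"), model_spec("linear_svm"), plan)
  expect_true(all(vapply(folds$iterations, `[[`, 0, "auc") == 1))
  folds2 <- run_mccv(tab, c("sig1", "sig2"), model_spec("linear_svm"), plan)
  expect_identical(folds, folds2)

  # label permutation: mean fold AUC near chance
  null_tab <- tab
  set.seed(99)
  null_tab$group <- sample(null_tab$group)
  aucs <- c()
  for (s in 1:5) {
    pl <- make_splits(null_tab$group, n_iterations = 10, seed = s)
    fl <- run_mccv(null_tab, c("sig1", "sig2", "noise1", "noise2"),
                   model_spec("pls_da"), pl)
    aucs <- c(aucs, mean(vapply(fl$iterations, `[[`, 0, "auc")))
  }
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("aggregation reproduces a single fold and averages identical folds exactly", {
  tab <- preprocess_table(generate_cohort(crc_cohort_spec(), seed = 21))
  plan <- make_splits(tab$group, n_iterations = 1, seed = 6)
  folds <- run_mccv(tab, names(effect_fcs), model_spec("pls_da"), plan)
  res <- suppressWarnings(aggregate_mccv(folds))
  it <- folds$iterations[[1]]
  expect_equal(res$auc_mean, it$auc)
  expect_equal(res$ci, rep(it$auc, 2))
  expect_equal(res$per_sample_prob[it$test_ids][order(it$test_ids)],
               it$prob[order(it$test_ids)])

  # vertical averaging of identical curves returns that curve (on the grid)
  fake <- folds
  fake$iterations <- rep(folds$iterations, 3)
  res3 <- suppressWarnings(aggregate_mccv(fake))
  expect_equal(res3$averaged_roc, res$averaged_roc)
  expect_equal(res3$auc_mean, res$auc_mean)
})

test_that("aggregate confusion counts come from mean probabilities at 0.5", {
  labels <- rep(c("case", "control"), each = 3)
  names(labels) <- paste0("s", 1:6)
  folds <- structure(list(
    iterations = list(
      list(test_ids = names(labels), prob = setNames(c(1, 1, 1, 0, 0, 0),
                                                     names(labels)),
           auc = 1, features_used = "f")),
    failed = integer(), labels = labels), class = "mccv_folds")
  res <- aggregate_mccv(folds)
  expect_identical(res$confusion, list(tp = 3L, fn = 0L, tn = 3L, fp = 0L))
  expect_true(res$auc_mean >= min(res$fold_aucs) &&
              res$auc_mean <= max(res$fold_aucs))
})

test_that("samples never held out are excluded from confusion with a warning", {
  labels <- setNames(rep(c("case", "control"), each = 2), paste0("s", 1:4))
  folds <- structure(list(
    iterations = list(list(test_ids = c("s1", "s3"),
                           prob = c(s1 = 0.9, s3 = 0.2),
                           auc = 1, features_used = "f")),
    failed = integer(), labels = labels), class = "mccv_folds")
  expect_warning(res <- aggregate_mccv(folds), "never appeared")
  expect_identical(res$confusion$tp + res$confusion$fn, 1L)
  expect_identical(res$confusion$tn + res$confusion$fp, 1L)
})

test_that("a failing fold is skipped with a warning, not fatal", {
  tab <- preprocess_table(generate_cohort(crc_cohort_spec(), seed = 22))
  plan <- make_splits(tab$group, n_iterations = 3, seed = 7)
  # sabotage fold 2: its training fold contains a single class, which no
  # model can train on
  is_case <- which(tab$group == "case")
  plan$splits[[2]] <- list(train = is_case[1:20],
                           test = setdiff(seq_along(tab$group), is_case[1:20]))
  expect_warning(
    folds <- run_mccv(tab, names(effect_fcs), model_spec("pls_da"), plan),
    "fold 2.*skipped")
  expect_identical(folds$failed, 2L)
  expect_length(folds$iterations, 2L)
  res <- suppressWarnings(aggregate_mccv(folds))
  expect_identical(res$n_folds, 2L)
})

test_that("leakage-safe mode cannot learn a test-set-only signal", {
  # training folds carry pure noise; only the held-out third of each
  # single-split plan is given a strong case signal. If ranking or scaling
  # leaked test data, the fold AUCs would exceed the permutation-null band.
  mets <- lapply(1:4, function(i) metabolite_spec(paste0("m", i)))
  aucs <- vapply(1:8, function(s) {
    tab <- generate_cohort(cohort_spec(18, 18, mets), seed = 100 + s)
    plan <- make_splits(tab$group, n_iterations = 1, seed = s)
    sp <- plan$splits[[1]]
    boost <- sp$test[tab$group[sp$test] == "case"]
    tab$values[boost, "m1"] <- tab$values[boost, "m1"] * 20
    folds <- run_mccv(tab, paste0("m", 1:4), model_spec("pls_da"), plan,
                      rescale_in_fold = TRUE)
    folds$iterations[[1]]$auc
  }, 0)
  expect_gt(mean(aucs), 0.25)
  expect_lt(mean(aucs), 0.75)
})

test_that("pooled aggregation matches a pooled ROC over all predictions", {
  tab <- preprocess_table(generate_cohort(crc_cohort_spec(), seed = 24))
  plan <- make_splits(tab$group, n_iterations = 4, seed = 9)
  folds <- run_mccv(tab, names(effect_fcs), model_spec("pls_da"), plan)
  pooled <- suppressWarnings(aggregate_mccv(folds, roc_method = "pool"))
  all_prob <- unlist(lapply(folds$iterations, `[[`, "prob"))
  all_lab <- folds$labels[unlist(lapply(folds$iterations, `[[`, "test_ids"))]
  expect_equal(pooled$auc_mean, roc_auc(all_prob, all_lab))
})
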