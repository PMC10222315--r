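feat_mat <- function(v, names = "f1") matrix(v, ncol = length(names),
                                             dimnames = list(NULL, names))

test_that("linear SVM places the boundary between two symmetric points", {
  X <- feat_mat(c(-1, 1))
  fit <- train_model(model_spec("linear_svm", C = 1000), X, c("control", "case"))
  p <- score_model(fit, X)
  expect_lt(p[1], 0.5)
  expect_gt(p[2], 0.5)
  # decision value changes sign between the two points
  d <- metevroc:::svm_decision(fit$fit, X)
  expect_lt(d[1], 0)
  expect_gt(d[2], 0)
})

test_that("SVM decision values are invariant to balanced duplication of interior points", {
  set.seed(15)
  X <- rbind(feat_mat(rnorm(20, 2), c("f1")), feat_mat(rnorm(20, -2), c("f1")))
  X <- cbind(X, f2 = rnorm(40))
  y <- rep(c("case", "control"), each = 20)
  fit <- train_model(model_spec("linear_svm"), X, y)
  # duplicate the most interior (largest-margin) sample of each class
  d <- metevroc:::svm_decision(fit$fit, X)
  add <- c(which.max(d), which.min(d))
  X2 <- rbind(X, X[add, ]); y2 <- c(y, y[add])
  fit2 <- train_model(model_spec("linear_svm"), X2, y2)
  # agreement is limited by the solver's own convergence tolerance (1e-3)
  expect_lt(max(abs(metevroc:::svm_decision(fit2$fit, X) - d)), 1e-2)
})

test_that("PLS-DA on a single perfectly informative feature ranks classes perfectly", {
  y <- rep(c("case", "control"), each = 5)
  X <- feat_mat(as.numeric(y == "case") )
  fit <- train_model(model_spec("pls_da", n_components = 1), X, y)
  p <- score_model(fit, X)
  expect_equal(roc_auc(p, y), 1)
  expect_equal(p, as.numeric(y == "case"), tolerance = 1e-8)
})

test_that("NIPALS score vectors are orthogonal and full-rank PLS equals least squares", {
  set.seed(16)
  n <- 30; p <- 4
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- ifelse(X[, 1] - X[, 3] + rnorm(n) > 0, "case", "control")
  fit <- train_model(model_spec("pls_da", n_components = p), X, y)
  S <- fit$scores
  for (i in seq_len(ncol(S) - 1))
    for (j in seq((i + 1), ncol(S)))
      expect_lt(abs(sum(S[, i] * S[, j])),
                1e-8 * sqrt(sum(S[, i]^2)) * sqrt(sum(S[, j]^2)))
  # with as many components as the rank, fitted values match OLS
  y01 <- as.numeric(y == "case")
  ols <- lm.fit(cbind(1, X), y01)
  pls_fitted <- drop(X %*% fit$coefs) + fit$intercept
  expect_equal(pls_fitted, unname(ols$fitted.values), tolerance = 1e-6)
})

test_that("PLS-DA with no X-y covariance predicts the class prevalence", {
  y <- rep(c("case", "control"), c(3, 7))
  X <- matrix(5, 10, 2, dimnames = list(NULL, c("f1", "f2")))  # constant
  expect_silent(fit <- train_model(model_spec("pls_da"), X, y))
  expect_equal(score_model(fit, X), rep(0.3, 10))
})

test_that("PLS-DA component count is capped with a warning", {
  X <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_warning(train_model(model_spec("pls_da", n_components = 5),
                             X, c("case", "control", "case")), "capped")
})

test_that("random forest memorizes distinct training points and is seed-deterministic", {
  set.seed(17)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("case", "control"), 10)
  fit <- train_model(model_spec("random_forest", n_trees = 200, seed = 5), X, y)
  p <- score_model(fit, X)
  expect_true(all((p >= 0.5) == (y == "case")))   # training accuracy 1

  fit2 <- train_model(model_spec("random_forest", n_trees = 200, seed = 5), X, y)
  expect_identical(p, score_model(fit2, X))

  # unanimous vote far from the boundary scores exactly 1
  Xsep <- rbind(matrix(10 + rnorm(20, sd = 0.1), 10, 2),
                matrix(-10 + rnorm(20, sd = 0.1), 10, 2))
  colnames(Xsep) <- c("f1", "f2")
  fsep <- train_model(model_spec("random_forest", n_trees = 100, seed = 1),
                      Xsep, rep(c("case", "control"), each = 10))
  far <- matrix(c(20, 20), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_identical(score_model(fsep, far), 1)
})

test_that("scoring requires the training feature layout", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  fit <- train_model(model_spec("pls_da"), X, rep(c("case", "control"), 5))
  expect_error(score_model(fit, X[, c("f2", "f1")]), "match")
})

test_that("feature importances are normalized and find a planted feature", {
  for (kind in c("linear_svm", "pls_da", "random_forest")) {
    hits <- 0
    for (s in 1:15) {
      set.seed(s)
      n <- 40
      y <- rep(c("case", "control"), each = n / 2)
      X <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, paste0("f", 1:6)))
      X[, "f3"] <- X[, "f3"] + 2 * (y == "case")      # planted signal
      fit <- train_model(model_spec(kind, seed = s), X, y)
      imp <- feature_importance(fit)
      expect_equal(sum(imp), 1, tolerance = 1e-9)
      expect_true(all(imp >= 0))
      hits <- hits + (names(which.max(imp)) == "f3")
    }
    expect_gte(hits, 12)   # clear majority for every model kind
  }
})

test_that("importances are equivariant under feature permutation (deterministic kinds)", {
  set.seed(18)
  n <- 30
  y <- rep(c("case", "control"), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[, 2] <- X[, 2] + (y == "case")
  perm <- c(3, 1, 4, 2)
  for (kind in c("linear_svm", "pls_da")) {
    imp <- feature_importance(train_model(model_spec(kind), X, y))
    imp_p <- feature_importance(train_model(model_spec(kind),
                                            X[, perm], y))
    expect_equal(imp_p[names(imp)], imp, tolerance = 1e-6)
  }
})
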