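#' Specify a classification model
#'
#' One uniform contract over the three multivariate models of the pipeline:
#' soft-margin linear SVM, PLS-DA (partial least squares against a 0/1
#' class indicator, NIPALS), and random forest.
#'
#' @param kind `"linear_svm"`, `"pls_da"` or `"random_forest"`.
#' @param C SVM cost parameter (default 1).
#' @param n_components PLS-DA components (default 2; capped at
#'   `min(n - 1, p)` when training).
#' @param n_trees Random-forest trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))` at
#'   training time).
#' @param seed Seed for the stochastic models (random forest); default 1.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("linear_svm", "pls_da", "random_forest"),
                       C = 1, n_components = 2, n_trees = 500,
                       mtry = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (C <= 0) stop("`C` must be positive")
  if (n_components < 1) stop("`n_components` must be at least 1")
  if (n_trees < 1) stop("`n_trees` must be at least 1")
  structure(list(kind = kind, C = C, n_components = as.integer(n_components),
                 n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Train a classifier
#'
#' Fits the model named by `spec` on a feature matrix and case/control
#' labels; `case` is the positive class.
#'
#' * `linear_svm`: soft-margin linear SVM (via \pkg{e1071}), no internal
#'   rescaling; decision values are oriented so larger = more case-like, and
#'   a logistic (Platt-style) link is fitted on the training decision values
#'   to map them to probabilities.
#' * `pls_da`: PLS1 regression of the 0/1 class indicator on X, fitted here
#'   by NIPALS; predictions are clipped to `[0, 1]`.
#' * `random_forest`: bagged CART with Gini impurity (via
#'   \pkg{randomForest}); deterministic given `spec$seed`.
#'
#' @param spec A [model_spec()].
#' @param X Numeric matrix (samples x features) with column names.
#' @param y Labels (`"case"`/`"control"` or logical case indicator), both
#'   classes present.
#' @return Object of class `trained_model` with fields `kind`, `fit`,
#'   `feature_names`, plus model-specific components.
#' @export
train_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.matrix(X) || is.null(colnames(X)))
    stop("`X` must be a matrix with column names")
  ycase <- as_case_indicator(y)
  if (nrow(X) != length(ycase)) stop("rows of `X` must match length of `y`")
  if (anyNA(X)) stop("missing values in `X`")

  out <- switch(spec$kind,
    linear_svm = train_svm(spec, X, ycase),
    pls_da = train_plsda(spec, X, ycase),
    random_forest = train_rf(spec, X, ycase))
  out$kind <- spec$kind
  out$feature_names <- colnames(X)
  class(out) <- "trained_model"
  out
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> ", x$kind, " on ", length(x$feature_names),
      " features\n", sep = "")
  invisible(x)
}

# ---- linear SVM -----------------------------------------------------------

# decision values from e1071 are reported for an arbitrary level order;
# orient them so positive = case before any downstream use
svm_decision <- function(fit, X) {
  pred <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  d <- as.numeric(dv[, 1])
  if (identical(colnames(dv)[1], "control/case")) d <- -d
  d
}

train_svm <- function(spec, X, ycase) {
  yf <- factor(ifelse(ycase, "case", "control"), levels = c("control", "case"))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = spec$C, scale = FALSE)
  d <- svm_decision(fit, X)
  # Platt-style calibration; separation makes glm non-convergent but the
  # fitted monotone link is still a usable probability map
  platt <- suppressWarnings(
    stats::glm(ycase ~ d, family = stats::binomial()))
  list(fit = fit, platt = stats::coef(platt))
}

# ---- PLS-DA (NIPALS, PLS1) ------------------------------------------------

train_plsda <- function(spec, X, ycase) {
  y <- as.numeric(ycase)
  n <- nrow(X); p <- ncol(X)
  ncomp <- spec$n_components
  cap <- min(n - 1L, p)
  if (ncomp > cap) {
    warning("n_components capped at ", cap)
    ncomp <- cap
  }
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  W <- P <- matrix(0, p, ncomp)
  Q <- tt <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)                    # p x 1
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                     # no covariance left
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tta <- sum(t_a^2)
    if (tta < 1e-12) break
    p_a <- drop(crossprod(Xc, t_a)) / tta
    q_a <- sum(yc * t_a) / tta
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Q[a] <- q_a
    Tm[, a] <- t_a; tt[a] <- tta
    a_used <- a
  }
  if (a_used == 0L) {
    # no X-y covariance at all: intercept-only model
    return(list(coefs = rep(0, p), intercept = ym, ncomp = 0L,
                scores = matrix(0, n, 0), W = W[, 0, drop = FALSE],
                Q = numeric(0), tt = numeric(0)))
  }
  Wa <- W[, seq_len(a_used), drop = FALSE]
  Pa <- P[, seq_len(a_used), drop = FALSE]
  Qa <- Q[seq_len(a_used)]
  B <- Wa %*% solve(crossprod(Pa, Wa), Qa)
  list(coefs = drop(B), intercept = ym - drop(crossprod(xm, B)),
       ncomp = a_used, scores = Tm[, seq_len(a_used), drop = FALSE],
       W = Wa, Q = Qa, tt = tt[seq_len(a_used)])
}

# ---- random forest --------------------------------------------------------

train_rf <- function(spec, X, ycase) {
  yf <- factor(ifelse(ycase, "case", "control"), levels = c("control", "case"))
  mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(ncol(X)))) else spec$mtry
  set.seed(spec$seed)
  fit <- randomForest::randomForest(X, yf, ntree = spec$n_trees, mtry = mtry)
  list(fit = fit)
}

#' Case-class score of a trained model
#'
#' Returns, per row of `X`, a score in `[0, 1]` where higher = more
#' case-like: the Platt-calibrated probability for the SVM, the clipped
#' PLS-DA prediction, or the fraction of trees voting `case` for the random
#' forest.
#'
#' @param model A [train_model()] result.
#' @param X Matrix whose columns match the training `feature_names` (order
#'   included).
#' @return Numeric vector of case scores.
#' @export
score_model <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  if (!is.matrix(X) || !identical(colnames(X), model$feature_names))
    stop("columns of `X` must match the training features in order")
  switch(model$kind,
    linear_svm = {
      d <- svm_decision(model$fit, X)
      unname(stats::plogis(model$platt[1] + model$platt[2] * d))
    },
    pls_da = {
      yhat <- drop(X %*% model$coefs) + model$intercept
      pmin(pmax(yhat, 0), 1)
    },
    random_forest =
      unname(stats::predict(model$fit, X, type = "prob")[, "case"]))
}

#' Normalized feature importance
#'
#' Per-feature non-negative importances summing to 1: absolute hyperplane
#' coefficients (SVM), VIP scores (PLS-DA), or mean decrease in Gini
#' impurity (random forest).
#'
#' @param model A [train_model()] result.
#' @return Named numeric vector over the training features.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "trained_model"))
  imp <- switch(model$kind,
    linear_svm = {
      w <- drop(crossprod(model$fit$coefs, model$fit$SV))
      abs(w)
    },
    pls_da = {
      if (model$ncomp == 0L) rep(1 / length(model$feature_names),
                                 length(model$feature_names))
      else {
        # VIP_j = sqrt(p * sum_a ssy_a * w_aj^2 / sum_a ssy_a),
        # ssy_a = q_a^2 * t_a't_a (y-variance explained by component a)
        ssy <- model$Q^2 * model$tt
        p <- nrow(model$W)
        sqrt(p * drop(model$W^2 %*% ssy) / sum(ssy))
      }
    },
    random_forest = randomForest::importance(model$fit)[, "MeanDecreaseGini"])
  imp <- pmax(as.numeric(imp), 0)
  if (sum(imp) == 0) imp <- rep(1, length(imp))   # degenerate: uniform
  stats::setNames(imp / sum(imp), model$feature_names)
}
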