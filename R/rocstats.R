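# internal: coerce labels (factor/character case-control, or 0/1, or logical)
# to a logical case indicator, requiring both classes
as_case_indicator <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  y <- if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("case", "control"))
    if (length(bad)) stop("labels must be 'case'/'control', found: ",
                          paste(bad, collapse = ", "))
    labels == "case"
  } else as.logical(labels)
  if (anyNA(y)) stop("labels contain NA")
  if (!any(y) || all(y)) stop("both classes must be present")
  y
}

#' Empirical AUC by pair counting
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, ties counting one half (the Mann-Whitney form, computed via
#' midranks; exactly the trapezoidal area under the tie-collapsed empirical
#' ROC curve).
#'
#' @param scores Finite numeric scores, higher = more case-like.
#' @param labels `"case"`/`"control"` labels (or logical/0-1 case
#'   indicator), both classes present.
#' @param orient If `TRUE`, a score with AUC < 0.5 is sign-flipped so the
#'   reported AUC is always >= 0.5 (standard biomarker-panel behavior, so
#'   down-regulated markers report their discriminative strength).
#' @return The AUC.
#' @export
roc_auc <- function(scores, labels, orient = FALSE) {
  y <- as_case_indicator(labels)
  if (!all(is.finite(scores))) stop("scores must be finite")
  r <- rank(scores)
  n1 <- as.numeric(sum(y)); n0 <- as.numeric(sum(!y))
  a <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient && a < 0.5) 1 - a else a
}

#' Empirical ROC curve
#'
#' Builds the empirical curve over all distinct score thresholds (rule:
#' predict case when `score >= threshold`); tied scores collapse into a
#' single curve point. The first point is (FPR 0, TPR 0) at threshold
#' `Inf`, the last (1, 1) at the minimum score. If `orient = TRUE` and the
#' raw AUC is below 0.5 the score sign is flipped and the flip recorded in
#' the `flipped` field (reported thresholds are then on the flipped scale).
#'
#' @inheritParams roc_auc
#' @return Object of class `roc_curve`: list with `thresholds` (descending),
#'   `fpr`, `tpr` (both non-decreasing), `auc`, `flipped`.
#' @export
roc_curve <- function(scores, labels, orient = TRUE) {
  y <- as_case_indicator(labels)
  if (!all(is.finite(scores))) stop("scores must be finite")
  flipped <- FALSE
  if (orient && roc_auc(scores, y) < 0.5) {
    scores <- -scores
    flipped <- TRUE
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(y); n0 <- sum(!y)
  tpr <- vapply(thr, function(t) sum(scores[y] >= t), 0) / n1
  fpr <- vapply(thr, function(t) sum(scores[!y] >= t), 0) / n0
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr,
                 auc = roc_auc(scores, y), flipped = flipped),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", length(x$thresholds), " thresholds, AUC = ",
      format(x$auc, digits = 4),
      if (x$flipped) " (score sign flipped)", "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve A [roc_curve()].
#' @return The trapezoidal AUC (equal to the pair-counting [roc_auc()]).
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples cases and controls independently with replacement (so every
#' replicate keeps both classes), recomputes the AUC, and returns the
#' percentile interval. Deterministic given `seed`.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap replicates (>= 100; default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (default 1).
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                             seed = 1, orient = FALSE) {
  y <- as_case_indicator(labels)
  if (n_boot < 100) stop("`n_boot` must be at least 100")
  if (orient && roc_auc(scores, y) < 0.5) scores <- -scores
  i_case <- which(y); i_ctrl <- which(!y)
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i_case, replace = TRUE), sample(i_ctrl, replace = TRUE))
    roc_auc(scores[idx], y[idx])
  }, 0)
  alpha <- (1 - level) / 2
  unname(stats::quantile(reps, c(alpha, 1 - alpha)))
}

#' Optimal cutoff on a ROC curve
#'
#' `closest_topleft` minimizes `(1 - TPR)^2 + FPR^2`; `youden` maximizes
#' `TPR - FPR`. Ties are broken toward the lower threshold (higher
#' sensitivity). The returned cutoff is the curve threshold attaining the
#' optimum, on the score scale the curve was built from.
#'
#' @param curve A [roc_curve()].
#' @param method `"closest_topleft"` (default) or `"youden"`.
#' @return List with `cutoff`, `sensitivity`, `specificity`.
#' @export
optimal_cutoff <- function(curve, method = c("closest_topleft", "youden")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "roc_curve"))
  obj <- if (method == "youden") -(curve$tpr - curve$fpr)
         else (1 - curve$tpr)^2 + curve$fpr^2
  best <- which(obj == min(obj))
  pick <- best[which.min(curve$thresholds[best])]   # lower threshold on ties
  list(cutoff = curve$thresholds[pick],
       sensitivity = curve$tpr[pick],
       specificity = 1 - curve$fpr[pick])
}

#' Univariate ROC summary for one score
#'
#' Curve, AUC, stratified-bootstrap CI and optimal cutoff with its
#' sensitivity/specificity, in one call. With `orient = TRUE` (default) a
#' marker whose raw AUC falls below 0.5 (e.g. a down-regulated metabolite)
#' is sign-flipped before all computations.
#'
#' @inheritParams bootstrap_auc_ci
#' @param cutoff_method Passed to [optimal_cutoff()].
#' @return List of class `roc_summary`: `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, `flipped`.
#' @export
roc_summary <- function(scores, labels, n_boot = 2000, level = 0.95,
                        seed = 1, cutoff_method = "closest_topleft",
                        orient = TRUE) {
  curve <- roc_curve(scores, labels, orient = orient)
  if (curve$flipped) scores <- -scores
  ci <- bootstrap_auc_ci(scores, labels, n_boot = n_boot, level = level,
                         seed = seed, orient = FALSE)
  cut <- optimal_cutoff(curve, method = cutoff_method)
  structure(list(auc = curve$auc, ci_low = ci[1], ci_high = ci[2],
                 cutoff = cut$cutoff, sensitivity = cut$sensitivity,
                 specificity = cut$specificity, flipped = curve$flipped),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> AUC %.3f (95%% CI %.3f-%.3f), cutoff %.3g, sens %.3f, spec %.3f%s\n",
              x$auc, x$ci_low, x$ci_high, x$cutoff, x$sensitivity,
              x$specificity, if (x$flipped) " [flipped]" else ""))
  invisible(x)
}

#' Per-metabolite ROC summary table
#'
#' Runs [roc_summary()] on every metabolite column of a (typically
#' Pareto-scaled) table and assembles the diagnostic-value table: cutoff,
#' AUC, CI bounds, sensitivity, specificity per metabolite.
#'
#' @param table A [sample_table()] without missing values (any scale;
#'   cutoffs are reported on the table's current scale).
#' @inheritParams roc_summary
#' @return Data frame with columns `metabolite`, `cutoff`, `auc`, `ci_low`,
#'   `ci_high`, `sensitivity`, `specificity`.
#' @export
roc_summary_table <- function(table, n_boot = 2000, level = 0.95, seed = 1,
                              cutoff_method = "closest_topleft") {
  stopifnot(inherits(table, "sample_table"))
  v <- table$values
  if (anyNA(v)) stop("missing values present; impute first")
  rows <- lapply(seq_len(ncol(v)), function(j) {
    s <- roc_summary(v[, j], table$group, n_boot = n_boot, level = level,
                     seed = seed, cutoff_method = cutoff_method)
    data.frame(metabolite = colnames(v)[j], cutoff = s$cutoff, auc = s$auc,
               ci_low = s$ci_low, ci_high = s$ci_high,
               sensitivity = s$sensitivity, specificity = s$specificity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
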