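#' Two-sample t-test (Welch by default)
#'
#' Thin wrapper over [stats::t.test()] that adds the degenerate cases a
#' screening loop can encounter: if both groups have zero variance the test
#' returns `t = 0, p = 1` for equal means, and `p = 0` (infinite `t`) with a
#' warning for unequal means. Welch's unequal-variance form is the default;
#' `variant = "student"` pools variances.
#'
#' @param x,y Numeric vectors (cases and controls), each of length >= 2.
#' @param variant `"welch"` or `"student"`.
#' @return List with `t_stat`, `df`, `p_value` (two-sided).
#' @export
welch_t <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need at least 2 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t_stat = 0, df = length(x) + length(y) - 2, p_value = 1))
    warning("both groups constant with unequal means; p-value degenerate at 0")
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p_value = 0))
  }
  fit <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t_stat = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()], with
#' domain validation: inputs must lie in (0, 1].
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Raw-scale fold changes
#'
#' Per metabolite, the ratio of the case-group mean to the control-group
#' mean on the raw intensity scale, and its log2. Fold changes are only
#' meaningful before centering, so the table must be in `scale_state = "raw"`.
#'
#' @param table A raw-scale [sample_table()] with both groups present.
#' @return Data frame with columns `metabolite`, `fc`, `log2_fc`.
#' @export
fold_change <- function(table) {
  check_scale_state(table, "raw", "fold_change")
  if (nlevels(droplevels(table$group)) < 2L)
    stop("both groups must be present")
  v <- table$values
  m_case <- colMeans(v[table$group == "case", , drop = FALSE], na.rm = TRUE)
  m_ctrl <- colMeans(v[table$group == "control", , drop = FALSE], na.rm = TRUE)
  bad <- which(m_ctrl <= 0)
  if (length(bad))
    stop("control mean not positive for metabolite '",
         colnames(v)[bad[1]], "'")
  fc <- m_case / m_ctrl
  data.frame(metabolite = colnames(v), fc = unname(fc),
             log2_fc = unname(log2(fc)), stringsAsFactors = FALSE)
}

#' Dual-criterion selection rule
#'
#' The thresholds of the biomarker filter: FDR-adjusted p-value below
#' `p_adj_max` combined with univariate AUC strictly above `auc_min`
#' (selection), and the volcano fold-change thresholds `fc_up_min` /
#' `fc_down_max` (regulation calls). Defaults are the study rule:
#' adjusted p < 0.05, AUC > 0.70, FC >= 1.5 up / <= 1/1.5 down.
#'
#' @param p_adj_max Adjusted-p threshold in (0, 1).
#' @param auc_min AUC threshold in `[0.5, 1)` (strict `>` at selection).
#' @param fc_up_min Up-regulation fold-change threshold (> 1).
#' @param fc_down_max Down-regulation threshold (between 0 and 1).
#' @return A list of class `selection_rule`.
#' @export
selection_rule <- function(p_adj_max = 0.05, auc_min = 0.70,
                           fc_up_min = 1.5, fc_down_max = 1 / 1.5) {
  if (!(p_adj_max > 0 && p_adj_max < 1))
    stop("`p_adj_max` must lie in (0, 1)")
  if (!(auc_min >= 0.5 && auc_min < 1))
    stop("`auc_min` must lie in [0.5, 1)")
  if (!(fc_up_min > 1 && fc_down_max < 1 && fc_down_max > 0))
    stop("need fc_up_min > 1 > fc_down_max > 0")
  structure(list(p_adj_max = p_adj_max, auc_min = auc_min,
                 fc_up_min = fc_up_min, fc_down_max = fc_down_max),
            class = "selection_rule")
}

#' Volcano regulation call
#'
#' `UP` if `p_adj < p_adj_max` and `fc >= fc_up_min`; `DOWN` if
#' `p_adj < p_adj_max` and `fc <= fc_down_max`; otherwise `NS`. Vectorized.
#'
#' @param fc Positive fold changes.
#' @param p_adj Adjusted p-values.
#' @param rule A [selection_rule()].
#' @return Character vector in `{"UP", "DOWN", "NS"}`.
#' @export
volcano_classify <- function(fc, p_adj, rule = selection_rule()) {
  stopifnot(inherits(rule, "selection_rule"), length(fc) == length(p_adj))
  out <- rep("NS", length(fc))
  sig <- p_adj < rule$p_adj_max
  out[sig & fc >= rule$fc_up_min] <- "UP"
  out[sig & fc <= rule$fc_down_max] <- "DOWN"
  out
}

#' Per-metabolite differential screening
#'
#' For every metabolite: raw-scale fold change, two-sample t statistic and
#' p-value, Benjamini-Hochberg adjusted p (over the full panel in the
#' table), `-log10` raw p, and the volcano regulation call. The t-test runs
#' on the Pareto-scaled table (per-feature affine transforms leave the t
#' statistic unchanged, so this matches testing the normalized data);
#' fold changes come from the raw table.
#'
#' @param table A raw-scale [sample_table()] (missing values allowed; they
#'   are imputed with `impute_policy` before normalization).
#' @param rule A [selection_rule()] for the volcano call.
#' @param ttest_variant `"welch"` (default) or `"student"`.
#' @param impute_policy Passed to [impute_missing()].
#' @return Data frame with one row per metabolite and columns `metabolite`,
#'   `fc`, `log2_fc`, `t_stat`, `p_raw`, `p_adj`, `neg_log10_p`,
#'   `regulation`.
#' @export
univariate_screen <- function(table, rule = selection_rule(),
                              ttest_variant = "welch",
                              impute_policy = "half_min") {
  check_scale_state(table, "raw", "univariate_screen")
  issues <- validate_table(table)
  if (length(issues))
    stop("table not fit for screening: ", paste(issues, collapse = "; "))
  raw <- impute_missing(table, impute_policy)
  scaled <- pareto_scale(median_normalize(raw))

  fcs <- fold_change(raw)
  v <- scaled$values
  is_case <- scaled$group == "case"
  tests <- lapply(seq_len(ncol(v)), function(j)
    welch_t(v[is_case, j], v[!is_case, j], variant = ttest_variant))
  p_raw <- vapply(tests, `[[`, 0, "p_value")
  res <- data.frame(
    metabolite = fcs$metabolite,
    fc = fcs$fc,
    log2_fc = fcs$log2_fc,
    t_stat = vapply(tests, `[[`, 0, "t_stat"),
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    neg_log10_p = -log10(p_raw),
    stringsAsFactors = FALSE)
  res$regulation <- volcano_classify(res$fc, res$p_adj, rule)
  res
}

#' Dual-criterion biomarker selection
#'
#' Keeps the metabolites passing both statistical approaches: FDR-adjusted
#' p-value below `rule$p_adj_max` *and* univariate AUC strictly above
#' `rule$auc_min`. Returned in order of decreasing AUC (alphabetical on
#' ties).
#'
#' @param univ Data frame with columns `metabolite` and `p_adj` (e.g. from
#'   [univariate_screen()]).
#' @param aucs Named numeric vector of per-metabolite AUCs covering the same
#'   metabolite set.
#' @param rule A [selection_rule()].
#' @return Character vector of selected metabolite names.
#' @export
select_biomarkers <- function(univ, aucs, rule = selection_rule()) {
  stopifnot(inherits(rule, "selection_rule"))
  if (!all(c("metabolite", "p_adj") %in% names(univ)))
    stop("`univ` must have columns 'metabolite' and 'p_adj'")
  if (!setequal(univ$metabolite, names(aucs)))
    stop("metabolite sets of `univ` and `aucs` differ")
  auc <- aucs[univ$metabolite]
  keep <- univ$p_adj < rule$p_adj_max & auc > rule$auc_min
  sel <- univ$metabolite[keep]
  sel[order(-auc[keep], sel)]
}
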