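#' Impute or drop missing intensities
#'
#' `half_min` replaces each missing cell with half the smallest observed
#' positive intensity of that metabolite (a common limit-of-detection
#' surrogate in metabolomics); `drop_feature` removes any metabolite with a
#' missing cell. Either way no missing values remain.
#'
#' @param table A raw-scale [sample_table()].
#' @param policy `"half_min"` or `"drop_feature"`.
#' @return A raw-scale [sample_table()] without missing values.
#' @export
impute_missing <- function(table, policy = c("half_min", "drop_feature")) {
  policy <- match.arg(policy)
  check_scale_state(table, "raw", "impute_missing")
  v <- table$values
  if (!anyNA(v)) return(table)
  if (policy == "drop_feature") {
    keep <- colSums(is.na(v)) == 0L
    if (!any(keep)) stop("every metabolite has missing values; nothing left")
    table$values <- v[, keep, drop = FALSE]
    return(table)
  }
  for (j in which(colSums(is.na(v)) > 0L)) {
    obs <- v[, j]
    pos <- obs[!is.na(obs) & obs > 0]
    if (!length(pos))
      stop("metabolite '", colnames(v)[j],
           "' has no observed positive value to impute from")
    v[is.na(obs), j] <- min(pos) / 2
  }
  table$values <- v
  table
}

#' Sample-median normalization
#'
#' Divides each sample's intensity vector by that sample's median across
#' metabolites, removing sample-level loading differences. After the
#' operation every sample's row median is exactly 1. The per-sample medians
#' are recorded on the returned table.
#'
#' @param table A raw-scale [sample_table()] without missing values.
#' @return A [sample_table()] with `scale_state = "median_normalized"`.
#' @export
median_normalize <- function(table) {
  check_scale_state(table, "raw", "median_normalize")
  v <- table$values
  if (anyNA(v)) stop("missing values present; run impute_missing() first")
  med <- apply(v, 1L, stats::median)
  bad <- which(med <= 0)
  if (length(bad))
    stop("sample median not positive for sample '",
         rownames(v)[bad[1]], "'")
  table$values <- v / med
  table$sample_medians <- stats::setNames(med, rownames(v))
  table$scale_state <- "median_normalized"
  table
}

#' Pareto scaling
#'
#' Replaces each metabolite column `x` by `(x - mean(x)) / sqrt(sd(x))`
#' (sample standard deviation, n-1 denominator): mean-centering with a
#' square-root-of-SD divisor, the usual compromise between centering only
#' and unit-variance autoscaling. The scaled column's variance equals
#' `sd(x)`, not 1. Fitted means and SDs are recorded on the returned table.
#'
#' @param table A median-normalized [sample_table()].
#' @return A [sample_table()] with `scale_state = "pareto_scaled"`.
#' @export
pareto_scale <- function(table) {
  check_scale_state(table, "median_normalized", "pareto_scale")
  v <- table$values
  m <- colMeans(v)
  s <- apply(v, 2L, stats::sd)
  bad <- which(s == 0)
  if (length(bad))
    stop("zero-variance metabolite '", colnames(v)[bad[1]],
         "' cannot be Pareto-scaled")
  table$values <- sweep(sweep(v, 2L, m, "-"), 2L, sqrt(s), "/")
  table$scaling <- list(per_feature_mean = m, per_feature_sd = s)
  table$scale_state <- "pareto_scaled"
  table
}

#' Run the full normalization chain
#'
#' Convenience wrapper: [impute_missing()] (if needed), then
#' [median_normalize()], then [pareto_scale()].
#'
#' @param table A raw-scale [sample_table()].
#' @param impute_policy Passed to [impute_missing()].
#' @return A Pareto-scaled [sample_table()].
#' @export
preprocess_table <- function(table, impute_policy = "half_min") {
  pareto_scale(median_normalize(impute_missing(table, impute_policy)))
}
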