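# internal: fan one global seed out to per-stage seeds, deterministically.
# 32-bit-safe multiplicative hash of the stage name mixed with the seed.
derive_seed <- function(global_seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((h + as.numeric(global_seed) * 48271) %% 2147483646 + 1)
}

#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with full defaulting.
#' Input is either a table on disk (`input` + `input_format`) or a synthetic
#' cohort spec (`synth`; default the calibrated CRC cohort of
#' [crc_cohort_spec()]). Thresholds are validated here, before any compute.
#'
#' @param out_dir Output directory (created if absent).
#' @param input Optional path to an intensity table.
#' @param input_format Format for [read_sample_table()].
#' @param synth A [cohort_spec()] used when `input` is `NULL`.
#' @param seed Global seed; stage seeds are derived from it and recorded in
#'   the manifest.
#' @param impute_policy Passed to [impute_missing()].
#' @param ttest_variant `"welch"` or `"student"`.
#' @param rule A [selection_rule()].
#' @param n_boot,cutoff_method Univariate ROC settings, see [roc_summary_table()].
#' @param models Character vector of model kinds to evaluate.
#' @param n_iterations,train_fraction MCCV plan settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL, input_format = "csv",
                            synth = crc_cohort_spec(), seed = 1,
                            impute_policy = "half_min",
                            ttest_variant = "welch",
                            rule = selection_rule(),
                            n_boot = 2000, cutoff_method = "closest_topleft",
                            models = c("linear_svm", "pls_da",
                                       "random_forest"),
                            n_iterations = 10, train_fraction = 2 / 3) {
  stopifnot(inherits(rule, "selection_rule"))
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input)
  models <- match.arg(models, c("linear_svm", "pls_da", "random_forest"),
                      several.ok = TRUE)
  if (n_boot < 100) stop("`n_boot` must be at least 100")
  if (n_iterations < 1) stop("`n_iterations` must be at least 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)")
  structure(list(out_dir = out_dir, input = input,
                 input_format = input_format, synth = synth,
                 seed = as.integer(seed), impute_policy = impute_policy,
                 ttest_variant = ttest_variant, rule = rule,
                 n_boot = n_boot, cutoff_method = cutoff_method,
                 models = models, n_iterations = n_iterations,
                 train_fraction = train_fraction),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `rule` is a mapping
#' with keys `p_adj_max`, `auc_min`, `fc_up_min`, `fc_down_max`.
#'
#' @param path Path to the YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  rule <- do.call(selection_rule, as.list(y$rule %||% list()))
  args <- y[setdiff(names(y), "rule")]
  args$rule <- rule
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: wrap a stage so failures abort with the stage name
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end analysis
#'
#' Executes, in order: ingest (or simulate) and validate the table;
#' normalize (impute, median-normalize, Pareto-scale); univariate screen
#' (fold changes, t-tests, BH FDR, volcano calls); per-metabolite ROC
#' summary; dual-criterion biomarker selection; and MCCV evaluation of the
#' selected panel for each configured model. All artifacts are plain CSV
#' plus one JSON manifest recording the configuration, derived stage seeds,
#' package version, and row/feature counts at each stage. Idempotent for a
#' fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character()
  stage_counts <- list()
  seeds <- list(global = config$seed,
                simulate = derive_seed(config$seed, "simulate"),
                roc = derive_seed(config$seed, "roc"),
                mccv = derive_seed(config$seed, "mccv"))

  table <- run_stage("ingest", {
    tab <- if (!is.null(config$input))
      read_sample_table(config$input, config$input_format)
    else generate_cohort(config$synth, seed = seeds$simulate)
    issues <- validate_table(tab)
    if (length(issues)) stop(paste(issues, collapse = "; "))
    tab
  })
  write_sample_table(table, out("cohort_raw.csv"))
  artifacts <- c(artifacts, "cohort_raw.csv")
  stage_counts$ingest <- list(samples = nrow(table$values),
                              features = ncol(table$values))

  scaled <- run_stage("normalize", {
    pareto_scale(median_normalize(impute_missing(table, config$impute_policy)))
  })
  write_sample_table(scaled, out("cohort_pareto_scaled.csv"))
  artifacts <- c(artifacts, "cohort_pareto_scaled.csv")
  stage_counts$normalize <- list(samples = nrow(scaled$values),
                                 features = ncol(scaled$values))

  univ <- run_stage("univariate", {
    univariate_screen(table, rule = config$rule,
                      ttest_variant = config$ttest_variant,
                      impute_policy = config$impute_policy)
  })
  write_results(univ, out("univariate_screen.csv"))
  artifacts <- c(artifacts, "univariate_screen.csv")
  stage_counts$univariate <- list(features = nrow(univ))

  roc_tab <- run_stage("roc", {
    roc_summary_table(scaled, n_boot = config$n_boot, seed = seeds$roc,
                      cutoff_method = config$cutoff_method)
  })
  write_results(roc_tab, out("roc_summary.csv"))
  artifacts <- c(artifacts, "roc_summary.csv")
  stage_counts$roc <- list(features = nrow(roc_tab))

  panel <- run_stage("selection", {
    select_biomarkers(univ, stats::setNames(roc_tab$auc, roc_tab$metabolite),
                      rule = config$rule)
  })
  writeLines(panel, out("selected_biomarkers.txt"))
  artifacts <- c(artifacts, "selected_biomarkers.txt")
  stage_counts$selection <- list(features = length(panel))

  mccv_summaries <- list()
  if (length(panel) >= 1) {
    for (kind in config$models) {
      res <- run_stage(paste0("mccv_", kind), {
        evaluate_panel(scaled, panel, kind = kind,
                       n_iterations = config$n_iterations,
                       seed = seeds$mccv)
      })
      stem <- paste0("mccv_", kind)
      write_results(res$averaged_roc, out(paste0(stem, "_roc.csv")))
      write_results(data.frame(sample_id = names(res$per_sample_prob),
                               group = unname(run_stage("labels", {
                                 as.character(table$group)[match(
                                   names(res$per_sample_prob),
                                   rownames(table$values))]
                               })),
                               mean_case_prob = unname(res$per_sample_prob),
                               stringsAsFactors = FALSE),
                    out(paste0(stem, "_sample_probs.csv")))
      write_results(data.frame(fold = seq_along(res$fold_aucs),
                               auc = res$fold_aucs),
                    out(paste0(stem, "_fold_aucs.csv")))
      write_results(data.frame(tp = res$confusion$tp, fn = res$confusion$fn,
                               tn = res$confusion$tn, fp = res$confusion$fp),
                    out(paste0(stem, "_confusion.csv")))
      artifacts <- c(artifacts, paste0(stem, c("_roc.csv",
                                               "_sample_probs.csv",
                                               "_fold_aucs.csv",
                                               "_confusion.csv")))
      mccv_summaries[[kind]] <- list(auc_mean = res$auc_mean,
                                     ci = res$ci,
                                     confusion = res$confusion)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("metevroc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seeds = seeds,
    settings = list(impute_policy = config$impute_policy,
                    ttest_variant = config$ttest_variant,
                    rule = unclass(config$rule),
                    n_boot = config$n_boot,
                    cutoff_method = config$cutoff_method,
                    ci_method = "stratified percentile bootstrap",
                    models = config$models,
                    n_iterations = config$n_iterations,
                    train_fraction = config$train_fraction),
    stage_counts = stage_counts,
    selected_biomarkers = panel,
    mccv = mccv_summaries,
    artifacts = artifacts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
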