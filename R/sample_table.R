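#' Construct a samples-by-metabolites intensity table
#'
#' The central data container of the pipeline: a numeric matrix of metabolite
#' intensities (rows = samples, columns = metabolites) together with a binary
#' group label per sample. The `case` group (e.g. CRC patients) is the
#' positive class in every downstream ROC computation; `control` (e.g.
#' healthy subjects) is the reference. A `scale_state` attribute tracks the
#' preprocessing stage and only ever advances
#' `raw -> median_normalized -> pareto_scaled`.
#'
#' @param values Numeric matrix with unique row names (sample IDs) and unique
#'   column names (metabolite names). Missing intensities are `NA`, never 0.
#' @param group Character or factor of per-sample labels, values in
#'   `"case"` / `"control"`, same length as `nrow(values)`.
#' @param scale_state One of `"raw"`, `"median_normalized"`,
#'   `"pareto_scaled"`.
#'
#' @return An object of class `sample_table`: a list with elements `values`,
#'   `group` (factor with levels `control`, `case`), `scale_state`, and --
#'   once preprocessing has run -- `sample_medians` and `scaling`.
#' @seealso [read_sample_table()], [validate_table()], [median_normalize()]
#' @export
#' @examples
#' x <- matrix(rlnorm(12), 4, 3,
#'             dimnames = list(paste0("s", 1:4), c("ala", "leu", "ile")))
#' tab <- sample_table(x, c("case", "case", "control", "control"))
#' tab
sample_table <- function(values, group, scale_state = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x metabolites)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample IDs as row names and metabolite names as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate metabolite names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (length(group) != nrow(values))
    stop("`group` must have one label per sample (", nrow(values), " expected)")
  group <- as.character(group)
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad))
    stop("group labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), " (use `group_map` when reading)")
  scale_state <- match.arg(scale_state,
                           c("raw", "median_normalized", "pareto_scaled"))
  structure(
    list(values = values,
         group = factor(group, levels = c("control", "case")),
         scale_state = scale_state,
         sample_medians = NULL,
         scaling = NULL),
    class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat("<sample_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " metabolites [", x$scale_state, "]\n", sep = "")
  cat("  groups: ", sum(x$group == "case"), " case / ",
      sum(x$group == "control"), " control\n", sep = "")
  n_miss <- sum(is.na(x$values))
  if (n_miss) cat("  missing cells: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$values)

# internal: stop unless the table is at the required preprocessing stage
check_scale_state <- function(table, required, op) {
  if (!identical(table$scale_state, required))
    stop(op, " requires a table in scale_state '", required,
         "', got '", table$scale_state, "'")
  invisible(TRUE)
}

#' Read an intensity table from disk
#'
#' Supports two plain-text dialects: (a) delimited tables (`csv`/`tsv`) with
#' one row per sample, required columns `sample_id` and `group` and one
#' numeric column per metabolite; (b) the `MS_METABOLITE_DATA` block of an
#' mwTab file as deposited at the Metabolomics Workbench (`mwtab` format:
#' a `Samples` header row, a `Factors` row carrying the group label, then one
#' tab-delimited row per metabolite). Empty cells become missing values
#' (`NA`), never 0.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"tsv"` or `"mwtab"`.
#' @param group_map Named character vector mapping the labels found in the
#'   file onto `"case"` / `"control"`. The default maps `CRC` to `case` and
#'   `HC`/`Healthy` to `control`, and passes `case`/`control` through.
#' @return A [sample_table()] with `scale_state = "raw"`.
#' @export
read_sample_table <- function(path, format = c("csv", "tsv", "mwtab"),
                              group_map = c(case = "case", control = "control",
                                            CRC = "case", HC = "control",
                                            Healthy = "control")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mwtab") return(read_mwtab_block(path, group_map))

  df <- utils::read.table(path, sep = if (format == "csv") "," else "\t",
                          header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  required <- c("sample_id", "group")
  if (!all(required %in% names(df)))
    stop("table must contain columns 'sample_id' and 'group'")
  met_cols <- names(df)[!(names(df) %in% required)]
  if (!length(met_cols)) stop("no metabolite columns found")
  if (anyDuplicated(met_cols))
    stop("duplicate metabolite names in header: ",
         paste(unique(met_cols[duplicated(met_cols)]), collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))

  vals <- matrix(NA_real_, nrow(df), length(met_cols),
                 dimnames = list(df$sample_id, met_cols))
  for (j in met_cols) {
    raw <- df[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("non-numeric intensity in column '", j, "', sample '",
           df$sample_id[bad[1]], "': \"", raw[bad[1]], "\"")
    vals[, j] <- num
  }
  sample_table(vals, map_group_labels(df$group, group_map))
}

# internal: translate file labels to case/control via group_map
map_group_labels <- function(labels, group_map) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), names(group_map))
  if (length(unknown))
    stop("group label(s) not covered by `group_map`: ",
         paste(unknown, collapse = ", "))
  unname(group_map[labels])
}

# internal: parse the MS_METABOLITE_DATA block of an mwTab export.
# Full mwTab semantics are out of scope; only the Samples row, Factors row
# and metabolite rows between the START/END markers are read.
read_mwtab_block <- function(path, group_map) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("MS_METABOLITE_DATA_START", lines, fixed = TRUE)
  end <- grep("MS_METABOLITE_DATA_END", lines, fixed = TRUE)
  if (!length(start) || !length(end) || end[1] <= start[1])
    stop("no MS_METABOLITE_DATA block found in ", path)
  block <- lines[(start[1] + 1):(end[1] - 1)]
  rows <- strsplit(block, "\t", fixed = TRUE)
  key <- vapply(rows, `[[`, "", 1L)
  i_samp <- which(key == "Samples")
  i_fact <- which(key == "Factors")
  if (!length(i_samp) || !length(i_fact))
    stop("MS_METABOLITE_DATA block must contain 'Samples' and 'Factors' rows")
  ids <- rows[[i_samp[1]]][-1]
  # Factors cells look like "Group:CRC" (possibly several ';'-separated);
  # take the value after the last ':' of the first factor.
  fac <- vapply(rows[[i_fact[1]]][-1], function(cell) {
    first <- strsplit(cell, ";", fixed = TRUE)[[1]][1]
    parts <- strsplit(first, ":", fixed = TRUE)[[1]]
    trimws(parts[length(parts)])
  }, "")
  data_rows <- rows[-c(i_samp, i_fact)]
  met <- vapply(data_rows, `[[`, "", 1L)
  if (anyDuplicated(met))
    stop("duplicate metabolite names: ",
         paste(unique(met[duplicated(met)]), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate sample IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_real_, length(ids), length(met),
                 dimnames = list(ids, met))
  for (k in seq_along(data_rows)) {
    cells <- data_rows[[k]][-1]
    length(cells) <- length(ids)               # right-pad short rows
    cells[!is.na(cells) & cells == ""] <- NA
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!is.na(cells) & is.na(num))
    if (length(bad))
      stop("non-numeric intensity for metabolite '", met[k], "', sample '",
           ids[bad[1]], "': \"", cells[bad[1]], "\"")
    vals[, met[k]] <- num
  }
  sample_table(vals, map_group_labels(fac, group_map))
}

#' Write a sample table to CSV
#'
#' Writes the dialect [read_sample_table()] reads back: columns `sample_id`,
#' `group`, then one column per metabolite. Round-trips values, IDs and
#' labels.
#'
#' @param table A [sample_table()].
#' @param path Output path.
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  df <- data.frame(sample_id = rownames(table$values),
                   group = as.character(table$group),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a per-metabolite result table to CSV
#'
#' @param table Non-empty data frame with one row per metabolite (e.g. the
#'   output of [univariate_screen()] or [roc_summary_table()]).
#' @param path Output path.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("`table` must be a non-empty data frame")
  ok <- tryCatch({
    utils::write.csv(table, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path Path to the CSV.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Validate a sample table
#'
#' Reports (never raises) structural issues: duplicated names, missing or
#' single group labels, and metabolites with fewer than two non-missing
#' values in either group (the minimum for any two-sample statistic).
#'
#' @param table A [sample_table()].
#' @return Character vector of issue descriptions; empty if the table is fit
#'   for statistical analysis.
#' @export
validate_table <- function(table) {
  issues <- character()
  v <- table$values
  if (anyDuplicated(rownames(v)))
    issues <- c(issues, "duplicate sample IDs")
  if (anyDuplicated(colnames(v)))
    issues <- c(issues, "duplicate metabolite names")
  tab <- table(table$group)
  if (sum(tab > 0) < 2L)
    issues <- c(issues, "only one group label present")
  for (g in c("case", "control")) {
    if (!any(table$group == g)) next
    sub <- v[table$group == g, , drop = FALSE]
    n_ok <- colSums(!is.na(sub))
    low <- colnames(v)[n_ok < 2L]
    if (length(low))
      issues <- c(issues, paste0("metabolite '", low, "' has fewer than 2 ",
                                 "non-missing values in group ", g))
  }
  issues
}
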