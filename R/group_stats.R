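# Group-level summaries (mean +/- s.e.m. tables) and two-sample Student's
# t comparisons, with the four-level significance-star legend
# (* p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001).

#' Standard error of the mean
#'
#' Sample standard deviation (n-1 denominator) divided by sqrt(n);
#' `NA` for a single observation.
#'
#' @param x numeric vector.
#' @return the s.e.m., or `NA` if `length(x) < 2`.
#' @export
sem <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return `"****"`, `"***"`, `"**"`, `"*"` or `"n.s."`.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "n.s.")))))
}

#' Mean and s.e.m. per group and metric
#'
#' Builds the long-format group summary behind a Table-1-style report:
#' one row per (group, metric) with n, mean and s.e.m. Groups of size 1
#' get `NA` s.e.m. (flagged, not dropped).
#'
#' @param df data.frame of per-neuron records.
#' @param group_col name of the grouping column.
#' @param metric_cols character vector of numeric metric columns; defaults
#'   to all numeric columns except the grouping column.
#' @return data.frame with columns `group`, `metric`, `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(df, group_col = "group", metric_cols = NULL) {
  if (!group_col %in% names(df)) {
    proj_error("empty_group", sprintf("no grouping column '%s'", group_col))
  }
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], group_col)
  }
  groups <- unique(df[[group_col]])
  out <- lapply(groups, function(g) {
    sub <- df[df[[group_col]] == g, , drop = FALSE]
    if (nrow(sub) == 0) proj_error("empty_group", sprintf("group '%s' empty", g))
    do.call(rbind, lapply(metric_cols, function(mc) {
      x <- sub[[mc]]
      data.frame(group = g, metric = mc, n = sum(!is.na(x)),
                 mean = mean(x, na.rm = TRUE), sem = sem(x),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

#' Two-sample comparison (Student's t)
#'
#' Classical pooled-variance two-sided Student's t-test by default
#' (df = n1 + n2 - 2); Welch's unequal-variance form behind `welch = TRUE`.
#' When both samples are constant the t statistic is undefined (equal
#' means) or infinite (different means); such cases are returned flagged
#' (`degenerate = TRUE`) rather than raised.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param metric label carried into the result.
#' @param labels length-2 group labels.
#' @param welch use Welch's t instead of the pooled form.
#' @return one-row data.frame: `metric`, `group_a`, `group_b`, `n_a`,
#'   `n_b`, `t`, `df`, `p`, `stars`, `method`, `degenerate`.
#' @export
compare_groups <- function(a, b, metric = "", labels = c("A", "B"),
                           welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    proj_error("empty_group", "both samples need n >= 2")
  }
  res <- tryCatch(
    stats::t.test(a, b, var.equal = !welch),
    error = function(e) NULL)
  if (is.null(res)) {
    # both samples constant: t undefined (equal) or infinite (different)
    tval <- if (isTRUE(all.equal(mean(a), mean(b)))) NA_real_ else
      sign(mean(a) - mean(b)) * Inf
    out <- data.frame(metric = metric, group_a = labels[1], group_b = labels[2],
                      n_a = length(a), n_b = length(b),
                      t = tval, df = length(a) + length(b) - 2,
                      p = if (is.na(tval)) NA_real_ else 0,
                      stars = NA_character_,
                      method = if (welch) "welch" else "student",
                      degenerate = TRUE, stringsAsFactors = FALSE)
    return(out)
  }
  data.frame(metric = metric, group_a = labels[1], group_b = labels[2],
             n_a = length(a), n_b = length(b),
             t = unname(res$statistic), df = unname(res$parameter),
             p = res$p.value, stars = significance_stars(res$p.value),
             method = if (welch) "welch" else "student",
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Optional multiple-testing adjustment
#'
#' Benjamini-Hochberg adjustment of a table of [compare_groups()] results.
#' Off by default in the pipeline (single comparisons are reported
#' unadjusted); provided for users running many comparisons.
#'
#' @param comparisons data.frame with a `p` column.
#' @param method passed to [stats::p.adjust()] (default `"BH"`).
#' @return the table with `p_adj` and `stars_adj` columns appended.
#' @export
adjust_comparisons <- function(comparisons, method = "BH") {
  comparisons$p_adj <- stats::p.adjust(comparisons$p, method = method)
  comparisons$stars_adj <- significance_stars(comparisons$p_adj)
  comparisons
}

#' Render a group summary as a markdown table
#'
#' Table-1-style layout: metrics as rows, groups as columns, cells
#' "mean ± sem (n)".
#'
#' @param summary output of [summarize_groups()].
#' @param digits significant digits for means and sems.
#' @return character vector of markdown lines.
#' @export
format_group_table <- function(summary, digits = 2) {
  groups <- unique(summary$group)
  metrics <- unique(summary$metric)
  fmt <- function(m, s, n) {
    sprintf("%s ± %s (n=%d)", format(round(m, digits), nsmall = digits),
            if (is.na(s)) "NA" else format(round(s, digits), nsmall = digits),
            n)
  }
  header <- paste0("| Metric | ", paste(groups, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(groups) + 1), collapse = "|"), "|")
  rows <- vapply(metrics, function(mc) {
    cells <- vapply(groups, function(g) {
      r <- summary[summary$group == g & summary$metric == mc, ]
      if (nrow(r) == 0) "—" else fmt(r$mean, r$sem, r$n)
    }, "")
    paste0("| ", mc, " | ", paste(cells, collapse = " | "), " |")
  }, "")
  c(header, sep, rows)
}
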