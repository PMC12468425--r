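#' Round half away from zero
#'
#' Table values are rounded half-up (0.8165 -> 0.817) rather than with
#' R's banker's rounding, matching how results tables are conventionally
#' printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt3 <- function(x) sprintf("%.3f", round_half_up(x, 3))

fmt_signed3 <- function(x) sprintf("%+.3f", round_half_up(x, 3))

#' Render a metrics table
#'
#' Formats metric reports as a display table with the conventional
#' columns Model, Precision, Recall, F1-Score, all cells rounded half-up
#' to three decimals.
#'
#' @param reports list of `metrics_report` objects (or a single one).
#' @return data frame of formatted strings; zero rows when `reports` is
#'   empty (header-only when written to CSV).
#' @export
render_metrics_table <- function(reports) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  if (!length(reports)) {
    return(data.frame(Model = character(), Precision = character(),
                      Recall = character(), `F1-Score` = character(),
                      check.names = FALSE))
  }
  data.frame(
    Model = vapply(reports, `[[`, character(1), "model_id"),
    Precision = vapply(reports, function(r) fmt3(r$precision), character(1)),
    Recall = vapply(reports, function(r) fmt3(r$recall), character(1)),
    `F1-Score` = vapply(reports, function(r) fmt3(r$f1), character(1)),
    check.names = FALSE)
}

#' Render a stepwise-selection trace table
#'
#' One row per ensemble stage with the fused operating metrics, mirroring
#' the usual progressive-fusion results layout.
#'
#' @param trace a `selection_trace`.
#' @return data frame of formatted strings.
#' @export
render_selection_table <- function(trace) {
  stopifnot(inherits(trace, "selection_trace"))
  df <- trace$steps
  data.frame(
    `Ensemble Model` = df$members,
    Precision = fmt3(df$precision),
    Recall = fmt3(df$recall),
    `F1-Score` = fmt3(df$f1),
    check.names = FALSE)
}

#' Render a paired-comparison table
#'
#' One row per system pair: signed recall difference, bootstrap CI
#' bounds, McNemar p-value and P-score. A Holm-adjusted p-value column
#' (an extension beyond the per-pair tests; adjusted across the rows
#' given) is appended when `holm = TRUE` and more than one row is
#' present.
#'
#' @param reports list of `comparison_report` objects (or a single one).
#' @param holm append a Holm-adjusted McNemar p-value column.
#' @return data frame of formatted strings; zero rows for empty input.
#' @export
render_comparison_table <- function(reports, holm = TRUE) {
  if (inherits(reports, "comparison_report")) reports <- list(reports)
  if (!length(reports)) {
    return(data.frame(`Ensemble Model` = character(), `YOLO Model` = character(),
                      `Recall Diff` = character(), `CI low` = character(),
                      `CI high` = character(), `McNemar p` = character(),
                      `PS Value` = character(), check.names = FALSE))
  }
  p <- vapply(reports, `[[`, numeric(1), "mcnemar_p")
  out <- data.frame(
    `Ensemble Model` = vapply(reports, `[[`, character(1), "label1"),
    `YOLO Model` = vapply(reports, `[[`, character(1), "label2"),
    `Recall Diff` = vapply(reports, function(r) fmt_signed3(r$recall_diff),
                           character(1)),
    `CI low` = vapply(reports, function(r) fmt3(r$ci_low), character(1)),
    `CI high` = vapply(reports, function(r) fmt3(r$ci_high), character(1)),
    `McNemar p` = sprintf("%.3f", round_half_up(p, 3)),
    `PS Value` = vapply(reports, function(r) fmt3(r$p_score), character(1)),
    check.names = FALSE)
  if (holm && length(reports) > 1L) {
    out$`McNemar p (Holm)` <- sprintf("%.3f",
                                      round_half_up(stats::p.adjust(p, "holm"), 3))
  }
  out
}

#' Write a rendered table to CSV and/or Markdown
#'
#' @param table data frame of formatted strings from one of the
#'   `render_*` functions.
#' @param csv,markdown output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_table <- function(table, csv = NULL, markdown = NULL) {
  written <- character(0)
  if (!is.null(csv)) {
    utils::write.csv(table, csv, row.names = FALSE)
    written <- c(written, csv)
  }
  if (!is.null(markdown)) {
    writeLines(markdown_table(table), markdown)
    written <- c(written, markdown)
  }
  invisible(written)
}

markdown_table <- function(df) {
  if (nrow(df) == 0L) {
    return(c(paste0("| ", paste(names(df), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")))
  }
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    body)
}
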