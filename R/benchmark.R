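#' Bundled reference benchmark: YOLO variants on Barrett's esophagus frames
#'
#' Published operating-point metrics (precision, recall, reported F1) for
#' five small YOLO variants and their stepwise NMS ensembles on an
#' endoscopic Barrett's-esophagus lesion benchmark, bundled as a
#' plain-text CSV. Three row groups: `tuning` (one detector across
#' IoU/confidence settings), `single` (the five variants at IoU 0.3,
#' confidence 0.1) and `ensemble` (progressively deeper fusions at the
#' same operating point). Used as regression input for the metric
#' arithmetic: recomputing F1 from the precision/recall columns via
#' [f1_score()] reproduces `f1_reported` to within printing precision for
#' most rows (a few rows carry about 0.004 of upstream rounding drift, a
#' known artifact of harmonic means over 3-decimal inputs).
#'
#' @param group optional filter: `"tuning"`, `"single"` or `"ensemble"`.
#' @return data frame with columns `group`, `id`, `precision`, `recall`,
#'   `f1_reported`.
#' @examples
#' b <- benchmark_metrics("single")
#' cbind(b$id, f1 = round(f1_score(b$precision, b$recall), 3))
#' @export
benchmark_metrics <- function(group = NULL) {
  path <- system.file("extdata", "be_yolo_benchmark.csv", package = "detfuse",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  if (!is.null(group)) {
    group <- match.arg(group, unique(df$group))
    df <- df[df$group == group, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
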