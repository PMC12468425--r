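#' Paired per-lesion outcomes of two detection systems
#'
#' Evaluates both systems on the same ground truth at one operating point
#' and tabulates, per lesion, the paired detected/missed flags. The
#' discordant counts are `b` (only system 1 detects) and `c` (only system
#' 2 detects); `b + c + concordant =` total lesions.
#'
#' @param s a `detfuse_study`.
#' @param system1,system2 model_id strings or detections data frames.
#' @param iou_threshold,confidence_threshold the operating point.
#' @return an object of class `paired_outcomes` with elements `flags1`,
#'   `flags2` (named logical), `b`, `c`, `concordant`, `n`.
#' @export
paired_outcomes <- function(s, system1, system2, iou_threshold = 0.3,
                            confidence_threshold = 0.1) {
  f1 <- lesion_flags(s, system1, iou_threshold, confidence_threshold)
  f2 <- lesion_flags(s, system2, iou_threshold, confidence_threshold)
  if (!identical(names(f1), names(f2))) {
    stop("systems were evaluated on different lesion sets", call. = FALSE)
  }
  structure(list(flags1 = f1, flags2 = f2,
                 b = sum(f1 & !f2), c = sum(!f1 & f2),
                 concordant = sum(f1 == f2), n = length(f1)),
            class = "paired_outcomes")
}

#' @export
print.paired_outcomes <- function(x, ...) {
  cat(sprintf("<paired_outcomes> n %d  b %d (sys1 only)  c %d (sys2 only)  concordant %d\n",
              x$n, x$b, x$c, x$concordant))
  invisible(x)
}

#' McNemar's test on discordant detection outcomes
#'
#' Tests whether two paired systems miss different lesions at different
#' rates, using only the discordant pairs. Small samples
#' (`b + c < 25`) use the exact two-sided binomial test
#' `min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`;
#' larger samples use the continuity-corrected chi-square
#' `(|b - c| - 1)^2 / (b + c)` on 1 df. No discordance gives p = 1.
#'
#' @param outcomes a [paired_outcomes()] object, or `NULL` when `b` and
#'   `c` are given directly.
#' @param b,c discordant counts (overridden by `outcomes` when supplied).
#' @return list with `p_value`, `method`, `b`, `c`.
#' @export
mcnemar_test <- function(outcomes = NULL, b = NULL, c = NULL) {
  if (!is.null(outcomes)) {
    stopifnot(inherits(outcomes, "paired_outcomes"))
    b <- outcomes$b; c <- outcomes$c
  }
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) {
    return(list(p_value = 1, method = "exact binomial", b = b, c = c))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    method <- "exact binomial"
  } else {
    x2 <- (abs(b - c) - 1)^2 / n
    p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
    method <- "chi-square with continuity correction"
  }
  list(p_value = p, method = method, b = b, c = c)
}

#' P-score comparing two error rates
#'
#' A z-like statistic on the error rates `E = 1 - recall` of two systems:
#' `PS = |E1 - E2| / sqrt(q (1 - q) (1/n1 + 1/n2))` with
#' `q = (E1 + E2) / 2`. A value of 2 or more is conventionally read as a
#' significant difference at the 95% level. When `q` is 0 or 1 (both
#' systems perfect, or both completely wrong) the statistic is undefined
#' and is returned as 0 with attribute `degenerate = TRUE`.
#'
#' @param recall1,recall2 recalls in `[0, 1]`.
#' @param n1,n2 sample sizes (lesion counts) behind each recall.
#' @return the P-score (numeric scalar) with attributes `significant`
#'   (`PS >= 2`) and `degenerate`.
#' @examples
#' p_score(0.9, 0.8, 100, 100) # about 1.980
#' @export
p_score <- function(recall1, recall2, n1, n2) {
  stopifnot(recall1 >= 0, recall1 <= 1, recall2 >= 0, recall2 <= 1,
            n1 >= 1, n2 >= 1)
  e1 <- 1 - recall1
  e2 <- 1 - recall2
  q <- (e1 + e2) / 2
  if (q <= 0 || q >= 1) {
    ps <- 0
    attr(ps, "significant") <- FALSE
    attr(ps, "degenerate") <- TRUE
    return(ps)
  }
  ps <- abs(e1 - e2) / sqrt(q * (1 - q) * (1 / n1 + 1 / n2))
  attr(ps, "significant") <- ps >= 2
  attr(ps, "degenerate") <- FALSE
  ps
}

# Per-image sufficient statistics for recall: number of lesions and
# number detected by each system. Bootstrap resampling then only needs
# index sampling and sums.
per_image_recall_stats <- function(s, system1, system2, iou_threshold,
                                   confidence_threshold) {
  f1 <- lesion_flags(s, system1, iou_threshold, confidence_threshold)
  f2 <- lesion_flags(s, system2, iou_threshold, confidence_threshold)
  img_of <- s$ground_truth$image_id[match(names(f1), s$ground_truth$lesion_id)]
  ids <- s$images$image_id
  tab <- function(x) {
    v <- stats::setNames(numeric(length(ids)), ids)
    agg <- tapply(x, img_of, sum)
    v[names(agg)] <- agg
    v
  }
  list(n_lesions = tab(rep(1, length(f1))), tp1 = tab(f1), tp2 = tab(f2),
       stratum = s$images$stratum)
}

#' Stratified bootstrap CI for a recall difference
#'
#' Resamples images with replacement within each stratum (lesion-bearing
#' and lesion-free), preserving the stratum sizes — lesions and
#' detections travel with their image, so within-image correlation is
#' respected. Each resample recomputes both systems' micro-averaged
#' recalls and their difference; the 95% interval is the 2.5/97.5
#' percentile of the `B` resampled differences. The point estimate is the
#' full-data difference (system 1 minus system 2).
#'
#' @inheritParams paired_outcomes
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed; recorded in the result.
#' @return list with `recall_diff`, `ci_low`, `ci_high`, `B`, `seed`, and
#'   the resampled differences `reps`.
#' @export
bootstrap_recall_diff <- function(s, system1, system2, iou_threshold = 0.3,
                                  confidence_threshold = 0.1, B = 1000,
                                  seed = 20250910) {
  stopifnot(B >= 1)
  st <- per_image_recall_stats(s, system1, system2, iou_threshold,
                               confidence_threshold)
  pos <- which(st$stratum == "lesion_bearing")
  neg <- which(st$stratum == "lesion_free")
  if (sum(st$n_lesions) == 0) {
    stop("no ground-truth lesions: recall difference undefined", call. = FALSE)
  }
  point <- sum(st$tp1) / sum(st$n_lesions) - sum(st$tp2) / sum(st$n_lesions)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(B), function(i) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             if (length(neg)) sample(neg, length(neg), replace = TRUE))
    n <- sum(st$n_lesions[idx])
    if (n == 0) return(NA_real_)
    (sum(st$tp1[idx]) - sum(st$tp2[idx])) / n
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  list(recall_diff = point, ci_low = ci[1], ci_high = ci[2],
       B = B, seed = seed, reps = reps)
}

#' Full paired comparison of two detection systems
#'
#' Assembles, for one system pair at one operating point: the recall
#' difference (system 1 minus system 2), its stratified-bootstrap 95% CI,
#' McNemar's p-value on the discordant lesions, and the P-score computed
#' with `n1 = n2 =` number of ground-truth lesions. Mirrors the row
#' layout of an ensemble-vs-single-model comparison table.
#'
#' @inheritParams bootstrap_recall_diff
#' @param label1,label2 display names for the two systems (defaults: the
#'   model ids when systems are given by name).
#' @return an object of class `comparison_report`.
#' @export
compare_systems <- function(s, system1, system2, iou_threshold = 0.3,
                            confidence_threshold = 0.1, B = 1000,
                            seed = 20250910,
                            label1 = NULL, label2 = NULL) {
  name_of <- function(sys, fallback) {
    if (is.character(sys)) sys
    else if (is.data.frame(sys) && nrow(sys)) sys$model_id[1]
    else fallback
  }
  label1 <- label1 %||% name_of(system1, "system1")
  label2 <- label2 %||% name_of(system2, "system2")

  m1 <- evaluate_model(s, system1, iou_threshold, confidence_threshold)
  m2 <- evaluate_model(s, system2, iou_threshold, confidence_threshold)
  po <- paired_outcomes(s, system1, system2, iou_threshold,
                        confidence_threshold)
  mc <- mcnemar_test(po)
  bs <- bootstrap_recall_diff(s, system1, system2, iou_threshold,
                              confidence_threshold, B = B, seed = seed)
  n_lesions <- nrow(s$ground_truth)
  ps <- p_score(m1$recall, m2$recall, n_lesions, n_lesions)

  structure(list(
    label1 = label1, label2 = label2,
    recall1 = m1$recall, recall2 = m2$recall,
    recall_diff = bs$recall_diff,
    ci_low = bs$ci_low, ci_high = bs$ci_high,
    mcnemar_p = mc$p_value, mcnemar_method = mc$method,
    b = po$b, c = po$c,
    p_score = as.numeric(ps),
    ps_significant = attr(ps, "significant"),
    ps_degenerate = attr(ps, "degenerate"),
    ci_excludes_zero = bs$ci_low > 0 || bs$ci_high < 0,
    mcnemar_significant = mc$p_value < 0.05,
    n_lesions = n_lesions, B = B, seed = seed,
    iou_threshold = iou_threshold,
    confidence_threshold = confidence_threshold),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s (n = %d lesions)\n",
              x$label1, x$label2, x$n_lesions))
  cat(sprintf("  recall %.3f vs %.3f, diff %s\n",
              round_half_up(x$recall1, 3), round_half_up(x$recall2, 3),
              fmt_signed3(x$recall_diff)))
  cat(sprintf("  95%% bootstrap CI [%.3f, %.3f] (B = %d, seed = %d)\n",
              round_half_up(x$ci_low, 3), round_half_up(x$ci_high, 3),
              x$B, x$seed))
  cat(sprintf("  McNemar p = %.4g (%s; b = %d, c = %d)\n",
              x$mcnemar_p, x$mcnemar_method, x$b, x$c))
  cat(sprintf("  P-score = %.3f%s\n", round_half_up(x$p_score, 3),
              if (isTRUE(x$ps_significant)) " (>= 2: significant)" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
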