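#' Greedy recall-first stepwise ensemble selection
#'
#' Builds an ensemble incrementally: step 1 takes the candidate with the
#' highest standalone recall (evaluated as a singleton fused system, i.e.
#' after NMS at the operating point); each subsequent step fuses every
#' remaining candidate with the current member set and adds the one whose
#' fused recall is maximal. Ties are broken by higher fused precision,
#' then lexicographic `model_id`. Models keep being added up to
#' `max_size` even when the recall gain is zero or negative — screening
#' ensembles are typically grown to full depth and the gains audited
#' afterwards — unless `stop_on_no_gain` is set.
#'
#' The returned trace records, for every step, the fused metrics of the
#' chosen member set and the recall of every candidate evaluated at that
#' step, so greedy choices are fully auditable.
#'
#' @param s a `detfuse_study`.
#' @param candidates character vector of candidate model ids (non-empty).
#' @param config a [fusion_config()] supplying the operating point; its
#'   `members` field is ignored in favour of the growing member set.
#' @param max_size maximum ensemble size (default: all candidates).
#' @param stop_on_no_gain stop early when the best available addition does
#'   not increase recall (default `FALSE`).
#' @return an object of class `selection_trace`: a data frame `steps` with
#'   columns `step`, `added`, `members`, `TP`, `FP`, `FN`, `precision`,
#'   `recall`, `f1`, `recall_gain`, and a list `audit` of per-step
#'   candidate evaluations.
#' @export
stepwise_select <- function(s, candidates, config = fusion_config(candidates),
                            max_size = length(candidates),
                            stop_on_no_gain = FALSE) {
  candidates <- as.character(candidates)
  if (length(candidates) == 0L) stop("no candidate models", call. = FALSE)
  if (anyDuplicated(candidates)) stop("duplicate candidates", call. = FALSE)
  if (max_size < 1L || max_size > length(candidates)) {
    stop("max_size must lie in [1, number of candidates]", call. = FALSE)
  }
  missing <- setdiff(candidates, unique(s$detections$model_id))
  if (length(missing)) {
    stop("candidate(s) absent from study: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  members <- character(0)
  remaining <- sort(candidates)  # lexicographic base order for tie-breaks
  steps <- list()
  audit <- list()
  prev_recall <- NA_real_

  for (k in seq_len(max_size)) {
    evals <- lapply(remaining, function(cand) {
      cfg <- fusion_config(c(members, cand), config$iou_threshold,
                           config$confidence_threshold)
      fused <- fuse_ensemble(s, cfg)
      evaluate_model(s, fused, iou_threshold = config$iou_threshold,
                     confidence_threshold = config$confidence_threshold)
    })
    rec <- vapply(evals, `[[`, numeric(1), "recall")
    prec <- vapply(evals, `[[`, numeric(1), "precision")
    audit[[k]] <- data.frame(step = k, candidate = remaining,
                             recall = rec, precision = prec)
    best <- order(-rec, -prec, remaining)[1L]
    gain <- if (k == 1L) NA_real_ else rec[best] - prev_recall
    if (stop_on_no_gain && k > 1L && gain <= 0) break
    chosen <- remaining[best]
    members <- c(members, chosen)
    rep_best <- evals[[best]]
    steps[[k]] <- data.frame(
      step = k, added = chosen, members = paste(members, collapse = "+"),
      TP = rep_best$TP, FP = rep_best$FP, FN = rep_best$FN,
      precision = rep_best$precision, recall = rep_best$recall,
      f1 = rep_best$f1, recall_gain = gain)
    prev_recall <- rep_best$recall
    remaining <- setdiff(remaining, chosen)
  }

  trace <- do.call(rbind, steps)
  rownames(trace) <- NULL
  structure(list(steps = trace, audit = audit,
                 iou_threshold = config$iou_threshold,
                 confidence_threshold = config$confidence_threshold),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d step(s) @ IoU %.3g, conf %.3g\n",
              nrow(x$steps), x$iou_threshold, x$confidence_threshold))
  df <- x$steps
  df$precision <- sprintf("%.3f", round_half_up(df$precision, 3))
  df$recall <- sprintf("%.3f", round_half_up(df$recall, 3))
  df$f1 <- sprintf("%.3f", round_half_up(df$f1, 3))
  print(df[, c("step", "members", "precision", "recall", "f1")],
        row.names = FALSE)
  invisible(x)
}
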