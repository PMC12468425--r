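#' Match detections to ground-truth lesions
#'
#' Confidence-prioritized one-to-one assignment per image: detections are
#' processed in descending confidence (same deterministic tie-break as
#' NMS) and each claims the ground-truth lesion with the highest IoU at
#' or above `iou_threshold` (IoU ties broken by lower ground-truth
#' `x_min`). When every candidate lesion is already claimed, the incoming
#' detection may displace an earlier claimant to one of its own
#' alternative lesions (an augmenting path), so the number of matched
#' lesions always equals the exhaustive-optimal one-to-one matching —
#' plain one-pass greedy can strand a lesion when one detection overlaps
#' two. A detection that ends up unmatched is a false positive — this
#' includes duplicate detections of an already-matched lesion; an
#' unclaimed lesion is a false negative. Counts are aggregated over images
#' by summation (micro-averaging).
#'
#' Detections are assumed to be already at the chosen confidence operating
#' point; no filtering is applied here.
#'
#' @param dets data frame of detections (may span several images).
#' @param gts data frame of ground-truth boxes with `lesion_id`.
#' @param iou_threshold minimum IoU for a detection to claim a lesion.
#' @return an object of class `match_result`: per-lesion `lesion_detected`
#'   flags (named logical), per-detection `detection_label` (`"TP"`/`"FP"`,
#'   in the row order of `dets`), and counts `TP`, `FP`, `FN`.
#' @export
match_detections <- function(dets, gts, iou_threshold) {
  n_det <- nrow(dets)
  lesion_detected <- stats::setNames(logical(nrow(gts)), gts$lesion_id)
  detection_label <- rep("FP", n_det)

  if (n_det > 0L && nrow(gts) > 0L) {
    images <- union(unique(dets$image_id), unique(gts$image_id))
    det_img <- match(dets$image_id, images)
    gt_img <- match(gts$image_id, images)
    for (img in seq_along(images)) {
      di <- which(det_img == img)
      gi <- which(gt_img == img)
      if (!length(di) || !length(gi)) next
      d <- dets[di, , drop = FALSE]
      g <- gts[gi, , drop = FALSE]
      ord <- detection_order(d)
      ious <- iou_matrix(d, g)
      # candidate lesions per detection: highest IoU first, ties -> lower
      # ground-truth x_min
      cand <- lapply(seq_len(nrow(d)), function(j) {
        k <- which(ious[j, ] >= iou_threshold)
        k[order(-ious[j, k], g$x_min[k])]
      })
      st <- new.env(parent = emptyenv())
      st$owner <- integer(nrow(g))  # detection currently holding each lesion
      augment <- function(j) {
        for (k in cand[[j]]) {
          if (st$visited[k]) next
          st$visited[k] <- TRUE
          if (st$owner[k] == 0L || augment(st$owner[k])) {
            st$owner[k] <- j
            return(TRUE)
          }
        }
        FALSE
      }
      for (j in ord) {
        st$visited <- logical(nrow(g))
        augment(j)
      }
      matched <- which(st$owner > 0L)
      lesion_detected[g$lesion_id[matched]] <- TRUE
      detection_label[di[st$owner[matched]]] <- "TP"
    }
  }
  tp <- sum(lesion_detected)
  structure(list(lesion_detected = lesion_detected,
                 detection_label = detection_label,
                 TP = tp, FP = n_det - tp, FN = nrow(gts) - tp),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d  FP %d  FN %d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * P * R / (P + R)`; defined as 0 when both are 0.
#' Useful for recomputing F1 from reported precision/recall pairs.
#'
#' @param precision,recall numeric vectors in `[0, 1]`.
#' @return numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Precision, recall and F1 from matched counts
#'
#' Precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, F1 their harmonic
#' mean. Degenerate denominators (no detections, no lesions) yield 0 with
#' `degenerate = TRUE` so reports stay total. Alongside full-precision
#' values, 3-decimal half-up roundings are provided for table display.
#'
#' @param match a `match_result`, or a list with elements `TP`, `FP`, `FN`.
#' @param model_id optional model identifier carried into the report.
#' @param iou_threshold,confidence_threshold the operating point, recorded
#'   in the report.
#' @return an object of class `metrics_report`.
#' @export
compute_metrics <- function(match, model_id = NA_character_,
                            iou_threshold = NA_real_,
                            confidence_threshold = NA_real_) {
  tp <- match$TP; fp <- match$FP; fn <- match$FN
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  if (tp + fp > 0) precision <- tp / (tp + fp) else { precision <- 0; degenerate <- TRUE }
  if (tp + fn > 0) recall <- tp / (tp + fn) else { recall <- 0; degenerate <- TRUE }
  f1 <- f1_score(precision, recall)
  if (precision + recall == 0) degenerate <- degenerate || (tp + fp + fn > 0)
  structure(list(model_id = model_id,
                 iou_threshold = iou_threshold,
                 confidence_threshold = confidence_threshold,
                 TP = tp, FP = fp, FN = fn,
                 precision = precision, recall = recall, f1 = f1,
                 precision_3 = round_half_up(precision, 3),
                 recall_3 = round_half_up(recall, 3),
                 f1_3 = round_half_up(f1, 3),
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s @ IoU %.3g, conf %.3g\n",
              ifelse(is.na(x$model_id), "(unnamed)", x$model_id),
              x$iou_threshold, x$confidence_threshold))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$TP, x$FP, x$FN))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f%s\n",
              x$precision_3, x$recall_3, x$f1_3,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Evaluate a detector (or fused detections) on a study
#'
#' Applies the confidence floor, matches detections to lesions per image
#' at the IoU threshold, and micro-averages counts over the whole test
#' set. Lesion-free images contribute only false positives. With
#' `recall_unit = "image"` the recall denominator switches from lesions to
#' lesion-bearing images (an image counts as detected when at least one of
#' its lesions is matched) — a sensitivity-analysis mode; precision is
#' always detection-level.
#'
#' @param s a `detfuse_study`.
#' @param system a model_id string, or a detections data frame such as the
#'   output of [fuse_ensemble()].
#' @param iou_threshold matching threshold (default 0.3).
#' @param confidence_threshold confidence floor (default 0.1).
#' @param recall_unit `"lesion"` (default) or `"image"`.
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(s, system, iou_threshold = 0.3,
                            confidence_threshold = 0.1,
                            recall_unit = c("lesion", "image")) {
  recall_unit <- match.arg(recall_unit)
  dets <- resolve_detections(s, system)
  dets <- dets[dets$confidence >= confidence_threshold, , drop = FALSE]
  m <- match_detections(dets, s$ground_truth, iou_threshold)
  model_id <- if (is.character(system)) system else
    if (nrow(dets)) dets$model_id[1] else "(empty)"
  if (recall_unit == "image") {
    img_of <- s$ground_truth$image_id[match(names(m$lesion_detected),
                                            s$ground_truth$lesion_id)]
    hit <- tapply(m$lesion_detected, img_of, any)
    m <- list(TP = sum(hit), FP = m$FP, FN = sum(!hit))
  }
  compute_metrics(m, model_id = model_id, iou_threshold = iou_threshold,
                  confidence_threshold = confidence_threshold)
}

#' Per-lesion detection flags for a system
#'
#' Convenience wrapper used by the paired statistics: evaluates a system
#' at an operating point and returns the named logical vector of
#' detected/missed flags over every ground-truth lesion in the study.
#'
#' @inheritParams evaluate_model
#' @return named logical vector, one entry per lesion.
#' @export
lesion_flags <- function(s, system, iou_threshold = 0.3,
                         confidence_threshold = 0.1) {
  dets <- resolve_detections(s, system)
  dets <- dets[dets$confidence >= confidence_threshold, , drop = FALSE]
  match_detections(dets, s$ground_truth, iou_threshold)$lesion_detected
}
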