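#' Fusion configuration
#'
#' Bundles the operating point used for ensemble fusion: the IoU threshold
#' at which overlapping boxes suppress each other, the confidence floor
#' below which detections are discarded, and the ordered ensemble member
#' list. The defaults (IoU 0.3, confidence 0.1) are the recall-first
#' operating point typical of screening applications, where sensitivity is
#' preferred over precision.
#'
#' @param members character vector of member model ids (non-empty, unique).
#' @param iou_threshold suppression threshold in `(0, 1]`.
#' @param confidence_threshold confidence floor in `[0, 1)`.
#' @return an object of class `fusion_config`.
#' @export
fusion_config <- function(members, iou_threshold = 0.3,
                          confidence_threshold = 0.1) {
  if (length(members) == 0L) stop("members must be non-empty", call. = FALSE)
  if (anyDuplicated(members)) stop("members must be unique", call. = FALSE)
  if (!(iou_threshold > 0 && iou_threshold <= 1)) {
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (!(confidence_threshold >= 0 && confidence_threshold < 1)) {
    stop("confidence_threshold must lie in [0, 1)", call. = FALSE)
  }
  structure(list(members = as.character(members),
                 iou_threshold = iou_threshold,
                 confidence_threshold = confidence_threshold),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat(sprintf("<fusion_config> iou >= %.3g suppresses, confidence >= %.3g kept\n",
              x$iou_threshold, x$confidence_threshold))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

# Deterministic processing order for NMS: descending confidence, ties by
# larger area, then lexicographic (model_id, image_id, x_min). The total
# order makes suppression reproducible bit-exactly.
detection_order <- function(d) {
  area <- box_area(d)
  mid <- if ("model_id" %in% names(d)) d$model_id else ""
  iid <- if ("image_id" %in% names(d)) d$image_id else ""
  order(-d$confidence, -area, mid, iid, d$x_min)
}

#' Non-maximum suppression on one image
#'
#' Standard greedy NMS: detections below the confidence floor are removed
#' first; survivors are processed in descending confidence (deterministic
#' tie-break: larger area, then lexicographic model/image id and `x_min`);
#' a candidate is suppressed when its IoU with any already-kept box is at
#' or above `iou_threshold`. Kept boxes are the original input boxes — no
#' averaging, re-scoring or weighting — returned sorted by descending
#' confidence.
#'
#' @param dets data frame of detections sharing one `image_id`.
#' @param iou_threshold suppression threshold; overlap at or above it
#'   suppresses.
#' @param confidence_threshold confidence floor (default 0: keep all).
#' @return data frame of surviving detections.
#' @export
nms <- function(dets, iou_threshold, confidence_threshold = 0) {
  if (nrow(dets) == 0L) return(dets)
  if ("image_id" %in% names(dets) && length(unique(dets$image_id)) > 1L) {
    stop("nms() operates on a single image; got ",
         length(unique(dets$image_id)), " image ids", call. = FALSE)
  }
  dets <- dets[dets$confidence >= confidence_threshold, , drop = FALSE]
  if (nrow(dets) <= 1L) {
    rownames(dets) <- NULL
    return(dets)
  }
  dets <- dets[detection_order(dets), , drop = FALSE]
  n <- nrow(dets)
  keep <- logical(n)
  xmin <- dets$x_min; ymin <- dets$y_min
  xmax <- dets$x_max; ymax <- dets$y_max
  area <- (xmax - xmin) * (ymax - ymin)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept_idx)) {
      iw <- pmax(pmin(xmax[kept_idx], xmax[i]) - pmax(xmin[kept_idx], xmin[i]), 0)
      ih <- pmax(pmin(ymax[kept_idx], ymax[i]) - pmax(ymin[kept_idx], ymin[i]), 0)
      inter <- iw * ih
      ov <- inter / (area[kept_idx] + area[i] - inter)
      if (any(ov >= iou_threshold)) next
    }
    kept_idx <- c(kept_idx, i)
  }
  out <- dets[kept_idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fuse an ensemble of detectors by joint NMS
#'
#' The ensemble strategy: per image, the member models' detections are
#' pooled, the confidence floor is applied, and a single joint NMS pass
#' removes cross-model duplicates, retaining the most confident
#' non-overlapping predictions. Confidences are the original per-model
#' scores — no averaging or weighting — so a fused box is always one of
#' the members' own boxes.
#'
#' @param s a `detfuse_study`.
#' @param config a [fusion_config()]; every member must be present in the
#'   study's detections.
#' @return data frame of fused detections with
#'   `model_id = "ensemble:<m1>+<m2>+..."`; split by `image_id` to recover
#'   the per-image view.
#' @export
fuse_ensemble <- function(s, config) {
  stopifnot(inherits(config, "fusion_config"))
  missing <- setdiff(config$members, unique(s$detections$model_id))
  if (length(missing)) {
    stop("ensemble member(s) absent from study: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ens_id <- paste0("ensemble:", paste(config$members, collapse = "+"))
  pool <- s$detections[s$detections$model_id %in% config$members, , drop = FALSE]
  pool <- pool[pool$confidence >= config$confidence_threshold, , drop = FALSE]
  if (nrow(pool) == 0L) {
    out <- pool
    out$model_id <- character(0)
    return(out)
  }
  pieces <- lapply(split(pool, pool$image_id), nms,
                   iou_threshold = config$iou_threshold)
  out <- do.call(rbind, pieces)
  out$model_id <- ens_id
  rownames(out) <- NULL
  out
}
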