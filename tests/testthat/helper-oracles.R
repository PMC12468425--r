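# Independent reference implementations used as oracles. These are written
# as plainly as possible (scalar loops, no shared code with the package
# beyond data frames) so that agreement with the package is informative.

# IoU of two boxes given as c(x_min, y_min, x_max, y_max)
oracle_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# IoU by counting cells of a fine raster whose centers fall in each box
raster_iou <- function(a, b, n = 500) {
  x0 <- min(a[1], b[1]); x1 <- max(a[3], b[3])
  y0 <- min(a[2], b[2]); y1 <- max(a[4], b[4])
  xs <- seq(x0, x1, length.out = n + 1); xs <- (xs[-1] + xs[-(n + 1)]) / 2
  ys <- seq(y0, y1, length.out = n + 1); ys <- (ys[-1] + ys[-(n + 1)]) / 2
  gx <- rep(xs, times = n); gy <- rep(ys, each = n)
  in_a <- gx >= a[1] & gx <= a[3] & gy >= a[2] & gy <= a[4]
  in_b <- gx >= b[1] & gx <= b[3] & gy >= b[2] & gy <= b[4]
  sum(in_a & in_b) / sum(in_a | in_b)
}

# Brute-force O(n^2) NMS with a full precomputed IoU matrix.
brute_nms <- function(dets, iou_threshold, confidence_threshold = 0) {
  dets <- dets[dets$confidence >= confidence_threshold, , drop = FALSE]
  n <- nrow(dets)
  if (n == 0L) { rownames(dets) <- NULL; return(dets) }
  area <- (dets$x_max - dets$x_min) * (dets$y_max - dets$y_min)
  mid <- if ("model_id" %in% names(dets)) dets$model_id else rep("", n)
  iid <- if ("image_id" %in% names(dets)) dets$image_id else rep("", n)
  ord <- order(-dets$confidence, -area, mid, iid, dets$x_min)
  bx <- cbind(dets$x_min, dets$y_min, dets$x_max, dets$y_max)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M[i, j] <- oracle_iou(bx[i, ], bx[j, ])
  }
  kept <- integer(0)
  for (i in ord) {
    if (all(M[i, kept] < iou_threshold)) kept <- c(kept, i)
  }
  out <- dets[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Maximum one-to-one matching count (detections x ground truths at an IoU
# threshold) by exhaustive enumeration of injective assignments.
optimal_match_count <- function(dets, gts, iou_threshold) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0L || ng == 0L) return(0L)
  ok <- matrix(FALSE, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng)) {
    ok[i, j] <- oracle_iou(as.numeric(dets[i, c("x_min", "y_min", "x_max", "y_max")]),
                           as.numeric(gts[j, c("x_min", "y_min", "x_max", "y_max")])) >=
      iou_threshold
  }
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    recurse(i + 1, used, count)  # leave detection i unmatched
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1, used, count + 1L)
      used[j] <- FALSE
    }
  }
  recurse(1L, logical(ng), 0L)
  best
}

# Monte-Carlo union recall of the coupled/independent miss model,
# implemented independently of the generator.
mc_union_recall <- function(sensitivities, rho, n_lesions = 1e5) {
  coupled <- stats::runif(n_lesions) < rho
  v <- stats::runif(n_lesions)
  any_hit <- rep(FALSE, n_lesions)
  for (s in sensitivities) {
    hit <- ifelse(coupled, v <= s, stats::runif(n_lesions) <= s)
    any_hit <- any_hit | hit
  }
  mean(any_hit)
}
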