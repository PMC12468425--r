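# Fixture builders shared across test files. Everything is constructed in
# code; nothing is read from disk except through the package's own I/O.

det_row <- function(image_id, model_id, x_min, y_min, x_max, y_max, conf) {
  data.frame(image_id = image_id, model_id = model_id,
             x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
             confidence = conf)
}

gt_row <- function(image_id, lesion_id, x_min, y_min, x_max, y_max) {
  data.frame(image_id = image_id, lesion_id = lesion_id,
             x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
}

manifest_df <- function(ids, width = 100, height = 100,
                        stratum = "lesion_bearing") {
  data.frame(image_id = ids, width = width, height = height,
             stratum = stratum, modality = NA_character_)
}

# A study where each of n images carries one 20x20 lesion, and each named
# detector reproduces the truth box (confidence `conf`) on the images
# listed in `detected[[model_id]]` (indices into 1:n).
flagged_study <- function(n, detected, conf = 0.9) {
  ids <- sprintf("im%03d", seq_len(n))
  gt <- do.call(rbind, lapply(seq_len(n), function(i) {
    gt_row(ids[i], paste0("L", i), 10, 10, 30, 30)
  }))
  dets <- do.call(rbind, lapply(names(detected), function(m) {
    idx <- detected[[m]]
    if (!length(idx)) return(NULL)
    det_row(ids[idx], m, 10, 10, 30, 30, conf)
  }))
  study(manifest_df(ids), gt, dets)
}

# Random single-image detection sets for NMS property tests.
random_dets <- function(n, width = 100, height = 100) {
  w <- stats::runif(n, 5, 50)
  h <- stats::runif(n, 5, 50)
  x <- stats::runif(n) * (width - w)
  y <- stats::runif(n) * (height - h)
  det_row("img", sample(c("m1", "m2", "m3"), n, replace = TRUE),
          x, y, x + w, y + h, stats::runif(n))
}

# Random matching instance: up to 3 lesions (pairwise IoU < 0.3) and up to
# 3 detections, a mix of jittered truth copies and unrelated boxes.
random_match_instance <- function(max_boxes = 3) {
  ng <- sample(0:max_boxes, 1)
  gts <- gt_row(character(0), character(0), numeric(0), numeric(0),
                numeric(0), numeric(0))
  tries <- 0
  while (nrow(gts) < ng && tries <= 200) {
    tries <- tries + 1
    w <- stats::runif(1, 15, 40); h <- stats::runif(1, 15, 40)
    x <- stats::runif(1) * (100 - w); y <- stats::runif(1) * (100 - h)
    cand <- gt_row("img", paste0("L", nrow(gts) + 1), x, y, x + w, y + h)
    ious <- vapply(seq_len(nrow(gts)), function(i) {
      oracle_iou(as.numeric(gts[i, c("x_min", "y_min", "x_max", "y_max")]),
                 as.numeric(cand[, c("x_min", "y_min", "x_max", "y_max")]))
    }, numeric(1))
    if (all(ious < 0.3)) gts <- rbind(gts, cand)
  }
  nd <- sample(0:max_boxes, 1)
  dets <- det_row(character(0), character(0), numeric(0), numeric(0),
                  numeric(0), numeric(0), numeric(0))
  for (k in seq_len(nd)) {
    if (nrow(gts) > 0 && stats::runif(1) < 0.6) {
      g <- gts[sample(nrow(gts), 1), ]
      jit <- stats::rnorm(4, 0, 6)
      dets <- rbind(dets, det_row("img", "m", g$x_min + jit[1], g$y_min + jit[2],
                                  pmax(g$x_max + jit[3], g$x_min + jit[1] + 2),
                                  pmax(g$y_max + jit[4], g$y_min + jit[2] + 2),
                                  stats::runif(1)))
    } else {
      w <- stats::runif(1, 10, 45); h <- stats::runif(1, 10, 45)
      x <- stats::runif(1) * (100 - w); y <- stats::runif(1) * (100 - h)
      dets <- rbind(dets, det_row("img", "m", x, y, x + w, y + h, stats::runif(1)))
    }
  }
  list(dets = dets, gts = gts)
}
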