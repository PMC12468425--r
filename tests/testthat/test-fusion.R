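test_that("iou handles identity, disjointness and partial overlap", {
  a <- box_df(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(box_df(0, 0, 1, 1), box_df(5, 5, 6, 6)), 0)
  expect_equal(iou(box_df(0, 0, 2, 2), box_df(1, 0, 3, 2)), 1 / 3)
})

test_that("iou agrees with a rasterization oracle and is symmetric", {
  expect_equal(iou(box_df(0, 0, 2, 2), box_df(1, 0, 3, 2)),
               raster_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), tolerance = 0.01)
  set.seed(7)
  for (i in 1:25) {
    a <- c(runif(1, 0, 50), runif(1, 0, 50), 0, 0)
    a[3] <- a[1] + runif(1, 1, 40); a[4] <- a[2] + runif(1, 1, 40)
    b <- c(runif(1, 0, 50), runif(1, 0, 50), 0, 0)
    b[3] <- b[1] + runif(1, 1, 40); b[4] <- b[2] + runif(1, 1, 40)
    da <- box_df(a[1], a[2], a[3], a[4]); db <- box_df(b[1], b[2], b[3], b[4])
    expect_equal(iou(da, db), iou(db, da))
    expect_equal(iou(da, db), raster_iou(a, b), tolerance = 0.01)
  }
})

test_that("iou_matrix matches scalar iou entrywise", {
  set.seed(13)
  a <- random_dets(6); b <- random_dets(4)
  M <- iou_matrix(a, b)
  for (i in 1:6) for (j in 1:4) {
    expect_equal(M[i, j], iou(a[i, ], b[j, ]))
  }
})

test_that("nms base cases: empty input, duplicate suppression", {
  empty <- det_row(character(0), character(0), numeric(0), numeric(0),
                   numeric(0), numeric(0), numeric(0))
  expect_equal(nrow(nms(empty, 0.3)), 0L)

  dup <- rbind(det_row("i", "m", 0, 0, 10, 10, 0.9),
               det_row("i", "m", 0, 0, 10, 10, 0.8))
  kept <- nms(dup, 0.3)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, 0.9)
})

test_that("nms keeps the worked three-box configuration correctly", {
  # C suppresses A (IoU 81/119 ~ 0.681 >= 0.3); B survives (both cross-IoUs < 0.3)
  dets <- rbind(det_row("i", "m", 0, 0, 10, 10, 0.9),    # A
                det_row("i", "m", 8, 0, 18, 10, 0.7),    # B
                det_row("i", "m", 1, 1, 11, 11, 0.95))   # C
  expect_equal(iou(dets[1, ], dets[3, ]), 81 / 119)
  expect_lt(iou(dets[1, ], dets[2, ]), 0.3)
  expect_lt(iou(dets[3, ], dets[2, ]), 0.3)
  kept <- nms(dets, 0.3)
  expect_equal(kept$confidence, c(0.95, 0.7))
  expect_equal(kept$x_min, c(1, 8))
})

test_that("nms rejects mixed image ids and filters by confidence first", {
  mixed <- rbind(det_row("a", "m", 0, 0, 1, 1, 0.5),
                 det_row("b", "m", 0, 0, 1, 1, 0.5))
  expect_error(nms(mixed, 0.3), "single image")

  dets <- rbind(det_row("i", "m", 0, 0, 10, 10, 0.05),
                det_row("i", "m", 20, 20, 30, 30, 0.5))
  kept <- nms(dets, 0.3, confidence_threshold = 0.1)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, 0.5)
})

test_that("nms output is an antichain and matches the brute-force oracle", {
  set.seed(2024)
  for (trial in 1:60) {
    dets <- random_dets(sample(1:50, 1))
    thr <- sample(c(0.2, 0.3, 0.5), 1)
    kept <- nms(dets, thr, confidence_threshold = 0.1)
    # no two kept boxes overlap at or above the threshold
    if (nrow(kept) > 1) {
      M <- iou_matrix(kept, kept)
      diag(M) <- 0
      expect_lt(max(M), thr)
    }
    ref <- brute_nms(dets, thr, 0.1)
    expect_equal(kept, ref)
  }
})

test_that("singleton fusion equals per-image NMS of that model", {
  s <- generate_study(study_spec(list(detector_profile("solo", 0.9, 0.5)),
                                 n_images = 30, seed = 21))
  fused <- fuse_ensemble(s, fusion_config("solo"))
  ref <- do.call(rbind, lapply(split(model_detections(s, "solo"),
                                     model_detections(s, "solo")$image_id),
                               nms, iou_threshold = 0.3,
                               confidence_threshold = 0.1))
  # nms() also drops sub-threshold confidences when asked; compare boxes
  rownames(ref) <- NULL
  ref <- ref[ref$confidence >= 0.1, , drop = FALSE]
  expect_equal(fused[, c("x_min", "confidence")], ref[, c("x_min", "confidence")],
               ignore_attr = TRUE)
})

test_that("fusing identical member copies is idempotent", {
  base <- generate_study(study_spec(list(detector_profile("m1", 0.85, 0.4)),
                                    n_images = 25, seed = 31))
  d <- base$detections
  copies <- do.call(rbind, lapply(c("m1", "m2", "m3"), function(id) {
    d2 <- d; d2$model_id <- id; d2
  }))
  s <- study(base$images, base$ground_truth, copies)
  one <- fuse_ensemble(s, fusion_config("m1"))
  three <- fuse_ensemble(s, fusion_config(c("m1", "m2", "m3")))
  expect_equal(nrow(three), nrow(one))
  expect_equal(three[, c("x_min", "y_min", "confidence")],
               one[, c("x_min", "y_min", "confidence")])
})

test_that("disjoint member boxes are both retained", {
  s <- study(manifest_df("i"),
             gt_row("i", "L1", 0, 0, 10, 10),
             rbind(det_row("i", "m1", 0, 0, 10, 10, 0.6),
                   det_row("i", "m2", 40, 40, 50, 50, 0.5)))
  fused <- fuse_ensemble(s, fusion_config(c("m1", "m2")))
  expect_equal(nrow(fused), 2L)
  expect_identical(unique(fused$model_id), "ensemble:m1+m2")
})

test_that("every fused box is one of the members' original boxes", {
  s <- generate_study(paper_like_spec(n_images = 80, seed = 17))
  members <- study_models(s)
  fused <- fuse_ensemble(s, fusion_config(members))
  pool <- s$detections[s$detections$confidence >= 0.1, ]
  expect_lte(nrow(fused), nrow(pool))
  key <- function(d) paste(d$image_id, d$x_min, d$y_min, d$x_max, d$y_max,
                           d$confidence)
  expect_true(all(key(fused) %in% key(pool)))
})

test_that("fusion errors on unknown members and empty configs", {
  s <- generate_study(study_spec(list(detector_profile("m1", 0.9, 0.2)),
                                 n_images = 10, seed = 3))
  expect_error(fuse_ensemble(s, fusion_config(c("m1", "mystery"))),
               "mystery")
  expect_error(fusion_config(character(0)), "non-empty")
  expect_error(fusion_config(c("a", "a")), "unique")
  expect_error(fusion_config("a", iou_threshold = 0), "iou_threshold")
  expect_error(fusion_config("a", confidence_threshold = 1), "confidence_threshold")
})
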