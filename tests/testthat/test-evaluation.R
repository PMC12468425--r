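test_that("matching handles the trivial extremes", {
  gts <- rbind(gt_row("i", "L1", 0, 0, 10, 10),
               gt_row("i", "L2", 30, 30, 40, 40),
               gt_row("i", "L3", 60, 60, 70, 70))
  perfect <- det_row("i", "m", gts$x_min, gts$y_min, gts$x_max, gts$y_max, 0.9)
  m <- match_detections(perfect, gts, 0.3)
  expect_equal(c(m$TP, m$FP, m$FN), c(3L, 0L, 0L))
  expect_true(all(m$lesion_detected))

  none <- perfect[0, ]
  m0 <- match_detections(none, gts, 0.3)
  expect_equal(c(m0$TP, m0$FP, m0$FN), c(0L, 0L, 3L))
})

test_that("a duplicate detection of a matched lesion counts as FP", {
  gts <- gt_row("i", "L1", 0, 0, 10, 10)
  dets <- rbind(det_row("i", "m", 1, 1, 11, 11, 0.9),   # IoU ~ 0.681, matches
                det_row("i", "m", 0, 0, 10, 10, 0.5))   # duplicate -> FP
  m <- match_detections(dets, gts, 0.3)
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 1L, 0L))
  expect_identical(m$detection_label, c("TP", "FP"))
})

test_that("matched count equals exhaustive optimal matching on small instances", {
  set.seed(515)
  for (trial in 1:150) {
    inst <- random_match_instance()
    m <- match_detections(inst$dets, inst$gts, 0.3)
    expect_identical(m$TP, optimal_match_count(inst$dets, inst$gts, 0.3))
  }
})

test_that("counts are conserved on random multi-image instances", {
  set.seed(99)
  for (trial in 1:20) {
    s <- generate_study(study_spec(
      list(detector_profile("m", runif(1, 0.5, 1), runif(1, 0, 1))),
      n_images = 25, seed = trial))
    d <- model_detections(s, "m")
    m <- match_detections(d, s$ground_truth, 0.3)
    expect_equal(m$TP + m$FN, nrow(s$ground_truth))
    expect_equal(m$TP + m$FP, nrow(d))
    expect_equal(sum(m$detection_label == "TP"), m$TP)
    expect_equal(sum(m$lesion_detected), m$TP)
  }
})

test_that("precision, recall and F1 follow their defining ratios", {
  r <- compute_metrics(list(TP = 8, FP = 2, FN = 1))
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 8 / 9)
  expect_equal(r$f1, 16 / 19)  # harmonic mean, = 0.842 at 3 decimals
  expect_equal(r$f1_3, 0.842)
  expect_false(r$degenerate)

  z <- compute_metrics(list(TP = 0, FP = 0, FN = 0))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_true(z$degenerate)

  no_dets <- compute_metrics(list(TP = 0, FP = 0, FN = 5))
  expect_true(no_dets$degenerate)
  expect_equal(no_dets$recall, 0)
})

test_that("f1 lies between precision and recall when both are positive", {
  set.seed(4)
  for (i in 1:50) {
    tp <- sample(1:50, 1); fp <- sample(0:30, 1); fn <- sample(0:30, 1)
    r <- compute_metrics(list(TP = tp, FP = fp, FN = fn))
    if (r$precision > 0 && r$recall > 0) {
      expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
      expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
    }
  }
})

test_that("a perfect detector scores 1 across the board", {
  s <- generate_study(study_spec(
    list(detector_profile("perfect", 1, 0, jitter_sd = 0)),
    n_images = 10, seed = 8))
  r <- evaluate_model(s, "perfect")
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
})

test_that("an engineered detector reproduces its designed error profile", {
  # 20 lesions; the detector misses exactly lesions 19 and 20, no FPs
  s <- flagged_study(20, list(m = 1:18))
  r <- evaluate_model(s, "m")
  expect_equal(r$recall, 0.9)
  expect_equal(r$precision, 1)
  # deterministic: same evaluation twice
  expect_identical(r, evaluate_model(s, "m"))
})

test_that("recall and retained detections are monotone in the confidence floor", {
  s <- generate_study(study_spec(
    list(detector_profile("m", 0.9, 0.8, tp_conf = c(4, 2), fp_conf = c(2, 4))),
    n_images = 60, seed = 55))
  thresholds <- c(0, 0.1, 0.25, 0.5, 0.75, 0.9)
  recalls <- numeric(0); retained <- integer(0)
  for (ct in thresholds) {
    r <- evaluate_model(s, "m", confidence_threshold = ct)
    recalls <- c(recalls, r$recall)
    retained <- c(retained, r$TP + r$FP)
  }
  expect_true(all(diff(recalls) <= 1e-12))
  expect_true(all(diff(retained) <= 0))
})

test_that("lesion-free images contribute false positives only", {
  im <- rbind(manifest_df("pos"), manifest_df("neg", stratum = "lesion_free"))
  s <- study(im, gt_row("pos", "L1", 10, 10, 30, 30),
             rbind(det_row("pos", "m", 10, 10, 30, 30, 0.9),
                   det_row("neg", "m", 10, 10, 30, 30, 0.9)))
  r <- evaluate_model(s, "m")
  expect_equal(c(r$TP, r$FP, r$FN), c(1L, 1L, 0L))
})

test_that("image-level recall mode aggregates lesions per image", {
  # one image with 2 lesions (1 found), one with 1 lesion (found)
  im <- manifest_df(c("a", "b"))
  gts <- rbind(gt_row("a", "L1", 0, 0, 10, 10),
               gt_row("a", "L2", 40, 40, 60, 60),
               gt_row("b", "L3", 0, 0, 10, 10))
  dets <- rbind(det_row("a", "m", 0, 0, 10, 10, 0.9),
                det_row("b", "m", 0, 0, 10, 10, 0.9))
  s <- study(im, gts, dets)
  lesion_level <- evaluate_model(s, "m")
  image_level <- evaluate_model(s, "m", recall_unit = "image")
  expect_equal(lesion_level$recall, 2 / 3)
  expect_equal(image_level$recall, 1)
})

test_that("unknown models are rejected by name", {
  s <- flagged_study(3, list(m = 1:3))
  expect_error(evaluate_model(s, "nonexistent"), "nonexistent")
})
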