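#' Operating profile of a synthetic detector
#'
#' Describes one simulated detector: its per-lesion detection probability
#' (sensitivity), the expected number of spurious boxes per image
#' (Poisson mean), Gaussian localization jitter applied to true-positive
#' boxes, and Beta confidence distributions for true and false positives.
#' True-positive confidences should sit stochastically above
#' false-positive ones (warned when the means are not ordered that way),
#' which is how trained detectors behave and what makes confidence
#' thresholding trade recall against precision.
#'
#' @param model_id detector identifier.
#' @param sensitivity per-lesion detection probability in `[0, 1]`.
#' @param fp_rate expected false positives per image (Poisson mean, >= 0).
#' @param jitter_sd per-coordinate Gaussian jitter of TP boxes, pixels.
#' @param tp_conf,fp_conf length-2 Beta shape parameters for TP and FP
#'   confidence draws.
#' @return an object of class `detector_profile`.
#' @export
detector_profile <- function(model_id, sensitivity, fp_rate,
                             jitter_sd = 4, tp_conf = c(8, 2),
                             fp_conf = c(2, 8)) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_rate >= 0,
            jitter_sd >= 0, length(tp_conf) == 2, length(fp_conf) == 2,
            all(tp_conf > 0), all(fp_conf > 0))
  tp_mean <- tp_conf[1] / sum(tp_conf)
  fp_mean <- fp_conf[1] / sum(fp_conf)
  if (tp_mean <= fp_mean) {
    warning("tp_conf mean <= fp_conf mean: confidence thresholding will ",
            "behave unrealistically", call. = FALSE)
  }
  structure(list(model_id = model_id, sensitivity = sensitivity,
                 fp_rate = fp_rate, jitter_sd = jitter_sd,
                 tp_conf = tp_conf, fp_conf = fp_conf),
            class = "detector_profile")
}

#' Specification of a synthetic multi-detector study
#'
#' Defines the study-level conditions: how many images, what fraction
#' carry lesions, how many lesions a positive image carries, image and
#' lesion geometry, the detector profiles, and the cross-detector miss
#' correlation. The miss-correlation model: with probability `rho` a
#' lesion is "coupled" — a single shared uniform draw `V` decides every
#' detector at once (detector `j` detects iff `V <= sensitivity_j`, so
#' misses coincide); otherwise detectors decide independently. Marginal
#' sensitivities are unchanged by `rho`; only the complementarity of the
#' detectors' misses varies, which is exactly what determines how much an
#' ensemble can gain.
#'
#' @param profiles list of [detector_profile()] objects.
#' @param n_images total number of images.
#' @param frac_lesion_bearing fraction of images in the lesion-bearing
#'   stratum; the default mirrors a roughly 61/39 case/control split.
#' @param lesion_count_probs probabilities of 1, 2 or 3 lesions on a
#'   lesion-bearing image.
#' @param image_width,image_height image dimensions in pixels.
#' @param lesion_size_range min and max lesion box side length, pixels.
#' @param miss_correlation `rho` in `[0, 1]`.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return an object of class `study_spec`.
#' @export
study_spec <- function(profiles, n_images = 500,
                       frac_lesion_bearing = 2220 / 3620,
                       lesion_count_probs = c(`1` = 0.7, `2` = 0.2, `3` = 0.1),
                       image_width = 640, image_height = 512,
                       lesion_size_range = c(60, 200),
                       miss_correlation = 0.6, seed = 20250910) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "detector_profile")),
            n_images >= 1,
            frac_lesion_bearing >= 0, frac_lesion_bearing <= 1,
            length(lesion_count_probs) == 3,
            abs(sum(lesion_count_probs) - 1) < 1e-9,
            image_width >= 1, image_height >= 1,
            length(lesion_size_range) == 2,
            lesion_size_range[1] <= lesion_size_range[2],
            miss_correlation >= 0, miss_correlation <= 1)
  ids <- vapply(profiles, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) stop("duplicate detector model_id", call. = FALSE)
  if (lesion_size_range[2] > min(image_width, image_height)) {
    stop("lesion size range infeasible for image dimensions", call. = FALSE)
  }
  structure(list(profiles = profiles, n_images = n_images,
                 frac_lesion_bearing = frac_lesion_bearing,
                 lesion_count_probs = lesion_count_probs,
                 image_width = image_width, image_height = image_height,
                 lesion_size_range = lesion_size_range,
                 miss_correlation = miss_correlation, seed = seed),
            class = "study_spec")
}

#' False-positive rate reaching a target single-model precision
#'
#' Solves, in expectation, for the Poisson false-positive rate that lands
#' a detector at a target micro-averaged precision under a study spec:
#' expected TPs per image are
#' `frac_lesion_bearing * E[lesions per positive image] * sensitivity`
#' (times the fraction of TP confidences above the floor), and the
#' required effective FP rate is `TP * (1 - p) / p`, inflated for the
#' fraction of FP confidences that the floor removes.
#'
#' @param target_precision desired precision in `(0, 1)`.
#' @param sensitivity detector sensitivity.
#' @param spec_args list of study-spec level parameters
#'   (`frac_lesion_bearing`, `lesion_count_probs`).
#' @param tp_conf,fp_conf Beta confidence parameters of the profile.
#' @param confidence_threshold the evaluation confidence floor.
#' @return Poisson mean false positives per image.
#' @export
fp_rate_for_precision <- function(target_precision, sensitivity,
                                  spec_args = list(),
                                  tp_conf = c(8, 2), fp_conf = c(2, 8),
                                  confidence_threshold = 0.1) {
  stopifnot(target_precision > 0, target_precision < 1)
  frac <- spec_args$frac_lesion_bearing %||% (2220 / 3620)
  probs <- spec_args$lesion_count_probs %||% c(`1` = 0.7, `2` = 0.2, `3` = 0.1)
  mean_lesions <- sum(c(1, 2, 3) * probs)
  tp_keep <- 1 - stats::pbeta(confidence_threshold, tp_conf[1], tp_conf[2])
  fp_keep <- 1 - stats::pbeta(confidence_threshold, fp_conf[1], fp_conf[2])
  tp_per_image <- frac * mean_lesions * sensitivity * tp_keep
  fp_eff <- tp_per_image * (1 - target_precision) / target_precision
  fp_eff / fp_keep
}

#' The default five-detector study conditions
#'
#' A ready-made [study_spec()] emulating a five-variant YOLO screening
#' study: standalone sensitivities 0.922-0.946, false-positive rates
#' solved to put standalone precisions near 0.72-0.80, miss correlation
#' 0.6, 640x512 frames with 60-200 px lesions and 4 px localization
#' jitter.
#'
#' @param n_images total number of images (default 2400, giving roughly
#'   2000 lesions).
#' @param seed RNG seed.
#' @param ... further arguments passed to [study_spec()].
#' @return a `study_spec`.
#' @export
paper_like_spec <- function(n_images = 2400, seed = 20250910, ...) {
  ids <- c("yolov5n", "yolov9t", "yolov10n", "yolov11n", "yolov12n")
  sens <- c(0.926, 0.934, 0.923, 0.946, 0.922)
  prec <- c(0.796, 0.755, 0.760, 0.717, 0.782)
  profiles <- mapply(function(id, s, p) {
    detector_profile(id, sensitivity = s,
                     fp_rate = fp_rate_for_precision(p, s))
  }, ids, sens, prec, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  study_spec(profiles, n_images = n_images, seed = seed, ...)
}

place_lesions <- function(k, width, height, size_range, max_tries = 50) {
  boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0))
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      w <- stats::runif(1, size_range[1], size_range[2])
      h <- stats::runif(1, size_range[1], size_range[2])
      x <- stats::runif(1, 0, width - w)
      y <- stats::runif(1, 0, height - h)
      cand <- data.frame(x_min = x, y_min = y, x_max = x + w, y_max = y + h)
      # reject overlap at/above the usual matching threshold so the
      # assignment problem stays well-posed
      if (nrow(boxes) == 0L || all(iou_matrix(cand, boxes) < 0.3)) {
        boxes <- rbind(boxes, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place non-overlapping lesions; lesion size range ",
           "too large for image dimensions", call. = FALSE)
    }
  }
  boxes
}

#' Generate a synthetic multi-detector study
#'
#' Realizes a [study_spec()]: lesion-bearing images receive 1-3
#' ground-truth boxes (uniform position, side lengths uniform in the size
#' range, same-image overlap above IoU 0.3 rejected); each detector then
#' detects each lesion according to the coupled/independent miss model
#' (see [study_spec()]), emitting a jittered copy of the truth box with a
#' Beta TP confidence; and each detector scatters Poisson false-positive
#' boxes with Beta FP confidences across all images. Fully deterministic
#' given `spec$seed`; the caller's RNG state is restored on exit.
#'
#' @param spec a `study_spec`.
#' @return a `detfuse_study`.
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_images
  n_pos <- round(n * spec$frac_lesion_bearing)
  width <- spec$image_width; height <- spec$image_height
  ids <- sprintf("img%05d", seq_len(n))
  images <- data.frame(
    image_id = ids,
    width = width, height = height,
    stratum = rep(c("lesion_bearing", "lesion_free"), c(n_pos, n - n_pos)),
    modality = sample(c("WLI", "NBI"), n, replace = TRUE))

  # ground truth
  gt <- NULL
  if (n_pos > 0) {
    counts <- sample(1:3, n_pos, replace = TRUE, prob = spec$lesion_count_probs)
    gt_list <- lapply(seq_len(n_pos), function(i) {
      b <- place_lesions(counts[i], width, height, spec$lesion_size_range)
      cbind(data.frame(image_id = ids[i],
                       lesion_id = sprintf("%s_L%d", ids[i], seq_len(counts[i]))),
            b)
    })
    gt <- do.call(rbind, gt_list)
    rownames(gt) <- NULL
  }
  n_lesions <- if (is.null(gt)) 0L else nrow(gt)

  # shared miss-difficulty draws, one pair per lesion
  coupled <- stats::runif(n_lesions) < spec$miss_correlation
  shared_v <- stats::runif(n_lesions)

  det_list <- list()
  for (p in spec$profiles) {
    if (n_lesions > 0) {
      own <- stats::runif(n_lesions)
      detected <- ifelse(coupled, shared_v <= p$sensitivity,
                         own <= p$sensitivity)
      hit <- which(detected)
      if (length(hit)) {
        tb <- gt[hit, BOX_COLS]
        if (p$jitter_sd > 0) {
          jit <- matrix(stats::rnorm(4 * length(hit), 0, p$jitter_sd),
                        ncol = 4)
          tb <- tb + jit
          tb$x_min <- pmax(tb$x_min, 0); tb$y_min <- pmax(tb$y_min, 0)
          tb$x_max <- pmin(pmax(tb$x_max, tb$x_min + 1), width)
          tb$y_max <- pmin(pmax(tb$y_max, tb$y_min + 1), height)
        }
        det_list[[length(det_list) + 1L]] <- cbind(
          data.frame(image_id = gt$image_id[hit], model_id = p$model_id),
          tb,
          data.frame(confidence = stats::rbeta(length(hit), p$tp_conf[1],
                                               p$tp_conf[2])))
      }
    }
    if (p$fp_rate > 0) {
      fp_counts <- stats::rpois(n, p$fp_rate)
      total <- sum(fp_counts)
      if (total > 0) {
        w <- stats::runif(total, spec$lesion_size_range[1], spec$lesion_size_range[2])
        h <- stats::runif(total, spec$lesion_size_range[1], spec$lesion_size_range[2])
        x <- stats::runif(total) * (width - w)
        y <- stats::runif(total) * (height - h)
        det_list[[length(det_list) + 1L]] <- data.frame(
          image_id = rep(ids, fp_counts), model_id = p$model_id,
          x_min = x, y_min = y, x_max = x + w, y_max = y + h,
          confidence = stats::rbeta(total, p$fp_conf[1], p$fp_conf[2]))
      }
    }
  }
  dets <- if (length(det_list)) do.call(rbind, det_list) else NULL
  if (!is.null(dets)) rownames(dets) <- NULL
  study(images, gt, dets)
}

#' Expected fused recall of a detector union
#'
#' Closed form for the generator's miss model: a lesion is found by the
#' fused ensemble when any member detects it, so expected union recall is
#' `rho * max(s_j) + (1 - rho) * (1 - prod(1 - s_j))` — coupled lesions
#' are found exactly when the most sensitive member finds them (shared
#' draw), independent lesions by the usual union complement. With
#' `rho = 0` this reduces to `1 - prod(1 - s_j)`; with `rho = 1`, to the
#' best single sensitivity. Ignores jitter, confidence floors and false
#' positives, which perturb realized recall only marginally at the
#' default conditions.
#'
#' @param profiles list of [detector_profile()] objects, or a numeric
#'   vector of sensitivities.
#' @param rho miss correlation in `[0, 1]`.
#' @return expected union recall.
#' @examples
#' expected_ensemble_recall(c(0.9, 0.9), rho = 0) # 0.99
#' @export
expected_ensemble_recall <- function(profiles, rho = 0) {
  s <- if (is.numeric(profiles)) profiles
       else vapply(profiles, `[[`, numeric(1), "sensitivity")
  stopifnot(length(s) >= 1, all(s >= 0), all(s <= 1), rho >= 0, rho <= 1)
  rho * max(s) + (1 - rho) * (1 - prod(1 - s))
}
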