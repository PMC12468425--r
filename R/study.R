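#' Assemble a detection study
#'
#' A study bundles everything needed to evaluate and fuse detectors on one
#' test set: the image manifest, the expert ground-truth lesion boxes, and
#' per-model detections. Images are stratified into `lesion_bearing`
#' (patient images carrying annotated lesions) and `lesion_free` controls;
#' lesion-free images must have no ground-truth entries and contribute only
#' false positives during evaluation.
#'
#' @param images data frame with columns `image_id`, `width`, `height`,
#'   `stratum` (`"lesion_bearing"` or `"lesion_free"`) and optionally
#'   `modality` (`"WLI"` or `"NBI"`; metadata only).
#' @param ground_truth data frame with columns `image_id`, `lesion_id` and
#'   the box columns `x_min`, `y_min`, `x_max`, `y_max` (absolute pixels).
#' @param detections data frame with columns `image_id`, `model_id`, the
#'   box columns, and `confidence` in `[0, 1]`.
#' @return an object of class `detfuse_study`.
#' @seealso [read_study()], [write_study()], [generate_study()]
#' @export
study <- function(images, ground_truth = NULL, detections = NULL) {
  if (is.null(ground_truth)) {
    ground_truth <- data.frame(image_id = character(), lesion_id = character(),
                               x_min = numeric(), y_min = numeric(),
                               x_max = numeric(), y_max = numeric())
  }
  if (is.null(detections)) {
    detections <- data.frame(image_id = character(), model_id = character(),
                             x_min = numeric(), y_min = numeric(),
                             x_max = numeric(), y_max = numeric(),
                             confidence = numeric())
  }
  images <- as.data.frame(images)
  ground_truth <- as.data.frame(ground_truth)
  detections <- as.data.frame(detections)
  if (!"modality" %in% names(images)) images$modality <- NA_character_
  s <- structure(list(images = images, ground_truth = ground_truth,
                      detections = detections),
                 class = "detfuse_study")
  validate_study(s)
  s
}

validate_study <- function(s) {
  im <- s$images
  req <- c("image_id", "width", "height", "stratum")
  if (!all(req %in% names(im))) {
    stop("manifest missing columns: ",
         paste(setdiff(req, names(im)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(im$image_id)) {
    stop("duplicate image_id in manifest: ",
         paste(unique(im$image_id[duplicated(im$image_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(im$width < 1 | im$height < 1)) {
    stop("image dimensions must be >= 1 pixel", call. = FALSE)
  }
  bad_stratum <- setdiff(unique(im$stratum), c("lesion_bearing", "lesion_free"))
  if (length(bad_stratum)) {
    stop("unknown stratum value(s): ", paste(bad_stratum, collapse = ", "),
         call. = FALSE)
  }
  gt <- s$ground_truth
  if (nrow(gt)) {
    validate_boxes(gt, "ground_truth")
    unknown <- setdiff(gt$image_id, im$image_id)
    if (length(unknown)) {
      stop("ground truth references unknown image_id: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(gt$lesion_id)) {
      stop("duplicate lesion_id in ground truth", call. = FALSE)
    }
    free <- im$image_id[im$stratum == "lesion_free"]
    offending <- intersect(gt$image_id, free)
    if (length(offending)) {
      stop("lesion_free image(s) carry ground truth: ",
           paste(offending, collapse = ", "), call. = FALSE)
    }
  }
  dets <- s$detections
  if (nrow(dets)) {
    validate_boxes(dets, "detections")
    unknown <- setdiff(dets$image_id, im$image_id)
    if (length(unknown)) {
      stop("detections reference unknown image_id: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(dets$confidence < 0 | dets$confidence > 1)) {
      stop("detection confidence outside [0, 1]", call. = FALSE)
    }
  }
  invisible(s)
}

#' Model identifiers present in a study
#' @param s a `detfuse_study`.
#' @return character vector of model ids, sorted.
#' @export
study_models <- function(s) {
  sort(unique(s$detections$model_id))
}

#' Detections of one model
#' @param s a `detfuse_study`.
#' @param model_id model identifier.
#' @return data frame of that model's detections.
#' @export
model_detections <- function(s, model_id) {
  if (!model_id %in% s$detections$model_id) {
    stop("unknown model: ", model_id, call. = FALSE)
  }
  d <- s$detections[s$detections$model_id == model_id, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @export
print.detfuse_study <- function(x, ...) {
  n_pos <- sum(x$images$stratum == "lesion_bearing")
  cat("<detfuse_study>\n")
  cat(sprintf("  images:       %d (%d lesion-bearing, %d lesion-free)\n",
              nrow(x$images), n_pos, nrow(x$images) - n_pos))
  cat(sprintf("  lesions:      %d\n", nrow(x$ground_truth)))
  models <- study_models(x)
  cat(sprintf("  detections:   %d from %d model(s)%s\n",
              nrow(x$detections), length(models),
              if (length(models)) paste0(" [", paste(models, collapse = ", "), "]")
              else ""))
  invisible(x)
}

# Resolve a "system" argument: either a model_id string or a detections
# data frame (e.g. the output of fuse_ensemble()).
resolve_detections <- function(s, system) {
  if (is.character(system) && length(system) == 1L) {
    return(model_detections(s, system))
  }
  if (is.data.frame(system)) {
    validate_boxes(system, "detections")
    return(system)
  }
  stop("system must be a model_id string or a detections data frame",
       call. = FALSE)
}
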