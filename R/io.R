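#' Parse YOLO-format label lines
#'
#' The YOLO text dialect stores one box per line as
#' `class cx cy w h` (ground truth) or `class cx cy w h conf` (detections),
#' all values normalized to `[0, 1]` relative to the image size. This
#' toolkit is single-class: the class index must be 0 ("lesion").
#' Normalized centers/sizes are converted to absolute corner coordinates
#' (`x_min = (cx - w/2) * width`, etc.) and clipped to the image bounds.
#'
#' @param lines character vector of label lines (blank lines are skipped).
#' @param width,height image dimensions in pixels.
#' @param with_confidence if `TRUE`, expect 6 fields per line and attach a
#'   `confidence` column; otherwise expect 5.
#' @param file optional file name used in error messages.
#' @return data frame of boxes in absolute coordinates (plus `confidence`
#'   when requested).
#' @examples
#' parse_yolo_labels("0 0.5 0.5 0.2 0.2", 100, 100) # Box(40, 40, 60, 60)
#' @export
parse_yolo_labels <- function(lines, width, height, with_confidence = FALSE,
                              file = "<input>") {
  lines <- lines[nzchar(trimws(lines))]
  n_fields <- if (with_confidence) 6L else 5L
  empty <- data.frame(x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric())
  if (with_confidence) empty$confidence <- numeric()
  if (length(lines) == 0L) return(empty)

  parts <- strsplit(trimws(lines), "[[:space:]]+")
  lens <- lengths(parts)
  if (any(lens != n_fields)) {
    bad <- which(lens != n_fields)[1L]
    stop(sprintf("%s line %d: expected %d fields, found %d",
                 file, bad, n_fields, lens[bad]), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = n_fields, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1L]
    stop(sprintf("%s line %d: non-numeric field", file, bad), call. = FALSE)
  }
  if (any(m[, 1] != 0)) {
    bad <- which(m[, 1] != 0)[1L]
    stop(sprintf("%s line %d: class index %s (only class 0 supported)",
                 file, bad, format(m[bad, 1])), call. = FALSE)
  }
  vals <- m[, 2:5, drop = FALSE]
  if (any(vals < 0 | vals > 1)) {
    bad <- which(apply(vals, 1, function(v) any(v < 0 | v > 1)))[1L]
    stop(sprintf("%s line %d: normalized value outside [0, 1]", file, bad),
         call. = FALSE)
  }
  cx <- m[, 2] * width; cy <- m[, 3] * height
  bw <- m[, 4] * width; bh <- m[, 5] * height
  out <- data.frame(x_min = cx - bw / 2, y_min = cy - bh / 2,
                    x_max = cx + bw / 2, y_max = cy + bh / 2)
  if (with_confidence) {
    conf <- m[, 6]
    if (any(conf < 0 | conf > 1)) {
      bad <- which(conf < 0 | conf > 1)[1L]
      stop(sprintf("%s line %d: confidence outside [0, 1]", file, bad),
           call. = FALSE)
    }
    out$confidence <- conf
  }
  clip_boxes(out, width, height)
}

#' Serialize boxes to YOLO-format label lines
#'
#' Inverse of [parse_yolo_labels()]: absolute corner coordinates are
#' converted back to normalized center/size form, printed with six decimal
#' places (round-trips within 1e-6 pixel at usual image sizes).
#'
#' @param boxes data frame with box columns; a `confidence` column, if
#'   present, is appended as a sixth field.
#' @param width,height image dimensions in pixels.
#' @return character vector of label lines.
#' @export
format_yolo_labels <- function(boxes, width, height) {
  if (nrow(boxes) == 0L) return(character())
  cx <- (boxes$x_min + boxes$x_max) / 2 / width
  cy <- (boxes$y_min + boxes$y_max) / 2 / height
  bw <- (boxes$x_max - boxes$x_min) / width
  bh <- (boxes$y_max - boxes$y_min) / height
  if ("confidence" %in% names(boxes)) {
    sprintf("0 %.6f %.6f %.6f %.6f %.6f", cx, cy, bw, bh, boxes$confidence)
  } else {
    sprintf("0 %.6f %.6f %.6f %.6f", cx, cy, bw, bh)
  }
}

#' Read an image manifest
#'
#' @param path CSV file with columns `image_id,width,height,stratum` and
#'   optionally `modality`.
#' @return data frame sorted by `image_id`.
#' @export
read_manifest <- function(path) {
  im <- utils::read.csv(path, colClasses = c(image_id = "character"))
  req <- c("image_id", "width", "height", "stratum")
  missing <- setdiff(req, names(im))
  if (length(missing)) {
    stop("manifest ", path, " missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"modality" %in% names(im)) im$modality <- NA_character_
  im <- im[order(im$image_id), , drop = FALSE]
  rownames(im) <- NULL
  im
}

read_label_dir <- function(dir, images, with_confidence) {
  out <- vector("list", nrow(images))
  for (i in seq_len(nrow(images))) {
    id <- images$image_id[i]
    path <- file.path(dir, paste0(id, ".txt"))
    if (!file.exists(path)) next  # missing file = no boxes on that image
    b <- parse_yolo_labels(readLines(path, warn = FALSE),
                           images$width[i], images$height[i],
                           with_confidence = with_confidence, file = path)
    if (nrow(b)) {
      b <- cbind(data.frame(image_id = id), b)
      out[[i]] <- b
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a study from a directory tree
#'
#' Expects the layout written by [write_study()]: a manifest CSV, one
#' YOLO-format ground-truth label file per annotated image, and one label
#' directory per detector. A missing label file means the image has no
#' boxes from that source (legal: lesion-free controls). Reads are
#' order-deterministic: images sorted by `image_id`, boxes in file order;
#' lesion ids are assigned canonically as `<image_id>_L<k>`.
#'
#' @param manifest_path path to the manifest CSV.
#' @param gt_dir directory of ground-truth label files (or `NULL`).
#' @param det_dirs named character vector mapping `model_id` to a label
#'   directory (or `NULL`).
#' @return a `detfuse_study`.
#' @export
read_study <- function(manifest_path, gt_dir = NULL, det_dirs = NULL) {
  images <- read_manifest(manifest_path)
  gt <- NULL
  if (!is.null(gt_dir)) {
    gt <- read_label_dir(gt_dir, images, with_confidence = FALSE)
    if (!is.null(gt)) {
      k <- stats::ave(seq_len(nrow(gt)), gt$image_id, FUN = seq_along)
      gt <- cbind(data.frame(image_id = gt$image_id,
                             lesion_id = sprintf("%s_L%d", gt$image_id, k)),
                  gt[, BOX_COLS])
    }
  }
  dets <- NULL
  if (length(det_dirs)) {
    if (is.null(names(det_dirs)) || any(!nzchar(names(det_dirs)))) {
      stop("det_dirs must be a named vector: model_id -> directory",
           call. = FALSE)
    }
    parts <- lapply(names(det_dirs), function(mid) {
      d <- read_label_dir(det_dirs[[mid]], images, with_confidence = TRUE)
      if (is.null(d)) return(NULL)
      cbind(data.frame(image_id = d$image_id, model_id = mid),
            d[, c(BOX_COLS, "confidence")])
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts)) {
      dets <- do.call(rbind, parts)
      rownames(dets) <- NULL
    }
  }
  study(images, gt, dets)
}

#' Write a study to a directory tree
#'
#' Writes `manifest.csv`, ground-truth label files under `labels/`,
#' per-model detection label files under `detections/<model_id>/`, and a
#' COCO-style JSON mirror `study.json` (absolute `[x, y, w, h]` boxes).
#' `read_study()` on the result reproduces the study up to float
#' round-trip (1e-6 normalized precision).
#'
#' @param s a `detfuse_study`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(s, out_dir) {
  validate_study(s)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  im <- s$images[order(s$images$image_id), , drop = FALSE]
  utils::write.csv(im, file.path(out_dir, "manifest.csv"), row.names = FALSE)

  dims <- function(id) im[match(id, im$image_id), c("width", "height")]
  if (nrow(s$ground_truth)) {
    dir.create(file.path(out_dir, "labels"), showWarnings = FALSE)
    for (id in unique(s$ground_truth$image_id)) {
      g <- s$ground_truth[s$ground_truth$image_id == id, , drop = FALSE]
      d <- dims(id)
      writeLines(format_yolo_labels(g[, BOX_COLS], d$width, d$height),
                 file.path(out_dir, "labels", paste0(id, ".txt")))
    }
  }
  if (nrow(s$detections)) {
    for (mid in unique(s$detections$model_id)) {
      mdir <- file.path(out_dir, "detections", mid)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      dd <- s$detections[s$detections$model_id == mid, , drop = FALSE]
      for (id in unique(dd$image_id)) {
        g <- dd[dd$image_id == id, , drop = FALSE]
        d <- dims(id)
        writeLines(format_yolo_labels(g[, c(BOX_COLS, "confidence")],
                                      d$width, d$height),
                   file.path(mdir, paste0(id, ".txt")))
      }
    }
  }
  write_study_json(s, file.path(out_dir, "study.json"))
  invisible(out_dir)
}

to_xywh <- function(b) {
  lapply(seq_len(nrow(b)), function(i) {
    c(b$x_min[i], b$y_min[i], b$x_max[i] - b$x_min[i], b$y_max[i] - b$y_min[i])
  })
}

#' Write the COCO-style JSON mirror of a study
#'
#' A single JSON document with `images` (id, width, height, stratum,
#' modality), `annotations` (id, image_id, bbox as absolute
#' `[x, y, w, h]`) and `detections` (image_id, model_id, bbox, score).
#'
#' @param s a `detfuse_study`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_study_json <- function(s, path) {
  doc <- list(
    images = lapply(seq_len(nrow(s$images)), function(i) {
      r <- s$images[i, ]
      list(id = r$image_id, width = r$width, height = r$height,
           stratum = r$stratum,
           modality = if (is.na(r$modality)) NULL else r$modality)
    }),
    annotations = lapply(seq_len(nrow(s$ground_truth)), function(i) {
      r <- s$ground_truth[i, ]
      list(id = r$lesion_id, image_id = r$image_id,
           bbox = c(r$x_min, r$y_min, r$x_max - r$x_min, r$y_max - r$y_min))
    }),
    detections = lapply(seq_len(nrow(s$detections)), function(i) {
      r <- s$detections[i, ]
      list(image_id = r$image_id, model_id = r$model_id,
           bbox = c(r$x_min, r$y_min, r$x_max - r$x_min, r$y_max - r$y_min),
           score = r$confidence)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study from its COCO-style JSON mirror
#' @param path JSON file written by [write_study_json()].
#' @return a `detfuse_study`.
#' @export
read_study_json <- function(path) {
  doc <- jsonlite::read_json(path)
  images <- do.call(rbind, lapply(doc$images, function(r) {
    data.frame(image_id = r$id, width = as.integer(r$width),
               height = as.integer(r$height), stratum = r$stratum,
               modality = if (is.null(r$modality)) NA_character_ else r$modality)
  }))
  from_xywh <- function(bb) {
    bb <- as.numeric(unlist(bb))
    data.frame(x_min = bb[1], y_min = bb[2],
               x_max = bb[1] + bb[3], y_max = bb[2] + bb[4])
  }
  gt <- NULL
  if (length(doc$annotations)) {
    gt <- do.call(rbind, lapply(doc$annotations, function(r) {
      cbind(data.frame(image_id = r$image_id, lesion_id = r$id), from_xywh(r$bbox))
    }))
  }
  dets <- NULL
  if (length(doc$detections)) {
    dets <- do.call(rbind, lapply(doc$detections, function(r) {
      cbind(data.frame(image_id = r$image_id, model_id = r$model_id),
            from_xywh(r$bbox), data.frame(confidence = as.numeric(r$score)))
    }))
  }
  study(images, gt, dets)
}
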