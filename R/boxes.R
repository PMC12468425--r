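#' Axis-aligned bounding boxes
#'
#' Boxes are represented as data frames (or named rows) with continuous
#' pixel coordinates `x_min`, `y_min`, `x_max`, `y_max`, origin at the
#' top-left of the image. A valid box has strictly positive width and
#' height; area is the plain product `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param x_min,y_min,x_max,y_max numeric vectors of equal length.
#' @return `box_df()` returns a data frame with one row per box.
#' @examples
#' box_df(0, 0, 10, 10)
#' @export
box_df <- function(x_min, y_min, x_max, y_max) {
  b <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_boxes(b)
  b
}

BOX_COLS <- c("x_min", "y_min", "x_max", "y_max")

validate_boxes <- function(b, where = "box") {
  if (!all(BOX_COLS %in% names(b))) {
    stop(where, ": missing box columns ",
         paste(setdiff(BOX_COLS, names(b)), collapse = ", "), call. = FALSE)
  }
  if (nrow(b) == 0L) return(invisible(b))
  bad <- !(b$x_max > b$x_min & b$y_max > b$y_min)
  if (any(bad)) {
    stop(where, ": ", sum(bad), " box(es) with non-positive width or height",
         call. = FALSE)
  }
  invisible(b)
}

#' Box areas
#' @param b data frame with box columns.
#' @return numeric vector of areas.
#' @export
box_area <- function(b) {
  (b$x_max - b$x_min) * (b$y_max - b$y_min)
}

#' Clip boxes to image bounds
#'
#' Boxes are intersected with the image rectangle `[0, width] x [0, height]`.
#' Boxes that become degenerate (zero area) after clipping are dropped with
#' a warning rather than raising an error; edge annotations that merely
#' touch the border are a fact of life in endoscopic frames.
#'
#' @param b data frame with box columns (other columns are preserved).
#' @param width,height image dimensions in pixels.
#' @return the clipped data frame, possibly with fewer rows.
#' @export
clip_boxes <- function(b, width, height) {
  if (nrow(b) == 0L) return(b)
  b$x_min <- pmax(b$x_min, 0)
  b$y_min <- pmax(b$y_min, 0)
  b$x_max <- pmin(b$x_max, width)
  b$y_max <- pmin(b$y_max, height)
  degenerate <- !(b$x_max > b$x_min & b$y_max > b$y_min)
  if (any(degenerate)) {
    warning(sum(degenerate), " box(es) degenerate after clipping; dropped",
            call. = FALSE)
    b <- b[!degenerate, , drop = FALSE]
    rownames(b) <- NULL
  }
  b
}

#' Intersection over Union of two boxes
#'
#' The overlap criterion used both for non-maximum suppression and for
#' matching detections to ground-truth lesions: intersection area divided
#' by union area. Symmetric; 0 for disjoint boxes; 1 for identical boxes.
#'
#' @param a,b single boxes: one-row data frames or named numeric vectors
#'   with `x_min`, `y_min`, `x_max`, `y_max`.
#' @return a number in `[0, 1]`.
#' @examples
#' iou(box_df(0, 0, 2, 2), box_df(1, 0, 3, 2)) # 1/3
#' @export
iou <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

#' Pairwise IoU matrix
#'
#' @param a,b data frames of boxes with `n` and `m` rows.
#' @return an `n x m` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  ix_min <- outer(a$x_min, b$x_min, pmax)
  ix_max <- outer(a$x_max, b$x_max, pmin)
  iy_min <- outer(a$y_min, b$y_min, pmax)
  iy_max <- outer(a$y_max, b$y_max, pmin)
  iw <- pmax(ix_max - ix_min, 0)
  ih <- pmax(iy_max - iy_min, 0)
  inter <- iw * ih
  union <- outer(box_area(a), box_area(b), `+`) - inter
  inter / union
}
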