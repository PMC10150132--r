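as_box <- function(b) {
  if (is.data.frame(b)) b <- unlist(b[1, intersect(
    c("x_min", "y_min", "x_max", "y_max", "confidence"), names(b))])
  b <- as.numeric(b)
  if (length(b) < 4) abort("a box needs x_min, y_min, x_max, y_max")
  if (b[1] >= b[3] || b[2] >= b[4]) abort("degenerate box")
  b[1:4]
}

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b Boxes as `(x_min, y_min, x_max, y_max)` vectors or one-row
#'   data frames with those columns.
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)) # 1/3
box_iou <- function(a, b) {
  a <- as_box(a)
  b <- as_box(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Detect the shaft region in a grayscale scene
#'
#' Deterministic localization: global Otsu threshold on intensity,
#' morphological opening, connected components; every component whose
#' area clears a floor (a fraction of the image) yields one box with
#' confidence equal to its area relative to the largest component.
#' Boxes with confidence at or below `conf_floor` are discarded, which
#' suppresses secondary blobs while always keeping the dominant
#' component (confidence 1).
#'
#' @param image Numeric matrix in `[0, 1]` with the shaft brighter than
#'   the background.
#' @param conf_floor Confidence cutoff; detections must exceed it
#'   (default 0.75).
#' @param min_area_frac Minimum component area as a fraction of image
#'   pixels.
#' @param open_radius Radius (px) of the disc structuring element for
#'   the opening step.
#' @return Tibble of detections (`x_min`, `y_min`, `x_max`, `y_max`,
#'   `confidence`), sorted by descending confidence; zero rows when
#'   nothing passes the area floor.
#' @export
detect_shaft <- function(image, conf_floor = 0.75, min_area_frac = 0.001,
                         open_radius = 3) {
  img <- as_raster_matrix(image)
  empty <- tibble::tibble(x_min = numeric(), y_min = numeric(),
                          x_max = numeric(), y_max = numeric(),
                          confidence = numeric())
  if (diff(range(img)) < 1e-6) return(empty)
  thr <- EBImage::otsu(EBImage::Image(img), range = range(img))
  bw <- EBImage::Image((img > thr) + 0)
  if (open_radius > 0) {
    bw <- EBImage::opening(bw, EBImage::makeBrush(2 * open_radius + 1, "disc"))
  }
  lab <- EBImage::bwlabel(bw)
  labs <- EBImage::imageData(lab)
  n <- max(labs)
  if (n == 0) return(empty)
  areas <- tabulate(labs[labs > 0], nbins = n)
  floor_px <- min_area_frac * length(img)
  keep <- which(areas >= floor_px)
  if (length(keep) == 0) return(empty)
  conf <- areas[keep] / max(areas[keep])
  boxes <- purrr::map2(keep, conf, function(k, cf) {
    b <- mask_bbox((labs == k) + 0L)
    b$confidence <- cf
    b
  }) |> purrr::list_rbind()
  boxes <- boxes[boxes$confidence > conf_floor, , drop = FALSE]
  dplyr::arrange(boxes, dplyr::desc(.data$confidence))
}

#' Crop a detection box to a fixed-size square analysis window
#'
#' Expands the box by a margin, pads it to a square (letterbox: the
#' aspect ratio is preserved and out-of-box area is filled with a
#' background value), and resamples to `out_size x out_size` by bilinear
#' interpolation. The affine map used is attached to the result so
#' points can be transformed in both directions with
#' [transform_points()].
#'
#' @param image Numeric matrix.
#' @param box Box as in [box_iou()].
#' @param out_size Output side length in pixels (default 256).
#' @param margin Fractional expansion of the box on each side.
#' @param fill Fill intensity outside the image; default is the median
#'   border intensity.
#' @param binarize If `TRUE`, threshold the interpolated crop at 0.5
#'   (use when cropping a binary mask).
#' @return `out_size x out_size` matrix with attribute `"transform"`
#'   (class `crop_transform`).
#' @export
crop_to_window <- function(image, box, out_size = 256, margin = 0.05,
                           fill = NULL, binarize = FALSE) {
  img <- as_raster_matrix(image)
  b <- as_box(box)
  w <- b[3] - b[1]
  h <- b[4] - b[2]
  side <- max(w, h) * (1 + 2 * margin)
  cx <- (b[1] + b[3]) / 2 - 0.5
  cy <- (b[2] + b[4]) / 2 - 0.5
  tf <- structure(list(cx = cx, cy = cy, scale = out_size / side,
                       out_size = as.integer(out_size)),
                  class = "crop_transform")
  if (is.null(fill)) {
    border <- c(img[1, ], img[nrow(img), ], img[, 1], img[, ncol(img)])
    fill <- median(border)
  }
  j <- seq_len(out_size) - 1
  u <- cx + (j - (out_size - 1) / 2) / tf$scale
  v <- cy + (j - (out_size - 1) / 2) / tf$scale
  crop <- bilinear_sample(img, u, v, fill)
  if (binarize) crop <- (crop > 0.5) + 0L
  attr(crop, "transform") <- tf
  crop
}

# Re-apply an existing crop transform to another raster of the same
# source geometry (e.g. the ground-truth mask of a cropped image).
crop_apply <- function(image, transform, fill = 0, binarize = FALSE) {
  img <- as_raster_matrix(image)
  out_size <- transform$out_size
  j <- seq_len(out_size) - 1
  u <- transform$cx + (j - (out_size - 1) / 2) / transform$scale
  v <- transform$cy + (j - (out_size - 1) / 2) / transform$scale
  crop <- bilinear_sample(img, u, v, fill)
  if (binarize) crop <- (crop > 0.5) + 0L
  attr(crop, "transform") <- transform
  crop
}

# Bilinear interpolation of img at the grid (xs columns, ys rows) of
# center-based 0-based coordinates; positions outside get `fill`.
bilinear_sample <- function(img, xs, ys, fill) {
  nr <- nrow(img)
  nc <- ncol(img)
  gx <- matrix(rep(xs, each = length(ys)), length(ys), length(xs))
  gy <- matrix(rep(ys, times = length(xs)), length(ys), length(xs))
  x0 <- floor(gx)
  y0 <- floor(gy)
  fx <- gx - x0
  fy <- gy - y0
  inside <- gx >= 0 & gx <= nc - 1 & gy >= 0 & gy <= nr - 1
  cx0 <- pmin(pmax(x0, 0), nc - 1)
  cx1 <- pmin(cx0 + 1, nc - 1)
  cy0 <- pmin(pmax(y0, 0), nr - 1)
  cy1 <- pmin(cy0 + 1, nr - 1)
  at <- function(r, c) img[cbind(as.vector(r) + 1, as.vector(c) + 1)]
  val <- (1 - fx) * (1 - fy) * at(cy0, cx0) +
    fx * (1 - fy) * at(cy0, cx1) +
    (1 - fx) * fy * at(cy1, cx0) +
    fx * fy * at(cy1, cx1)
  val[!inside] <- fill
  matrix(val, length(ys), length(xs))
}

#' Map points through a crop transform
#'
#' @param points Data frame or matrix with `x`, `y` columns (original
#'   image coordinates, or crop coordinates when `inverse = TRUE`).
#' @param transform A `crop_transform` (the `"transform"` attribute of a
#'   [crop_to_window()] result, or the crop itself).
#' @param inverse Map from crop coordinates back to the original image.
#' @return Object of the same shape with transformed `x`, `y`.
#' @export
transform_points <- function(points, transform, inverse = FALSE) {
  if (!inherits(transform, "crop_transform")) {
    transform <- attr(transform, "transform")
  }
  stopifnot(inherits(transform, "crop_transform"))
  m <- if (is.data.frame(points)) cbind(points$x, points$y) else
    points[, 1:2, drop = FALSE]
  c0 <- (transform$out_size - 1) / 2
  if (inverse) {
    out <- cbind(transform$cx + (m[, 1] - c0) / transform$scale,
                 transform$cy + (m[, 2] - c0) / transform$scale)
  } else {
    out <- cbind((m[, 1] - transform$cx) * transform$scale + c0,
                 (m[, 2] - transform$cy) * transform$scale + c0)
  }
  if (is.data.frame(points)) {
    points$x <- out[, 1]
    points$y <- out[, 2]
    points
  } else {
    out
  }
}

#' Single-class mean average precision over IoU thresholds
#'
#' Confidence-ranked all-point precision-recall integration with greedy
#' matching: detections are processed in order of descending confidence
#' (ties by input order) and each ground truth can be matched at most
#' once, to the highest-IoU unmatched truth at or above the threshold.
#' AP is the area under the stepwise precision envelope.
#'
#' @param detections Tibble with `image_id`, box columns and
#'   `confidence`.
#' @param truths Tibble with `image_id` and box columns.
#' @param iou_thresholds IoU thresholds; the default sweep 0.5 to 0.95
#'   by 0.05 yields both mAP@0.5 and mAP@[.5:.95].
#' @return A `detection_result`: list with `ap` (tibble of threshold,
#'   AP), `map50`, `map5095`, counts; see [glance.detection_result()].
#' @export
mean_ap <- function(detections, truths,
                    iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (is.null(truths) || nrow(truths) == 0) {
    abort("AP is undefined without ground-truth boxes")
  }
  stopifnot("image_id" %in% names(truths))
  det <- tibble::as_tibble(detections)
  if (nrow(det) > 0) {
    det <- det[order(-det$confidence, seq_len(nrow(det))), , drop = FALSE]
  }
  n_truth <- nrow(truths)
  ap_one <- function(thr) {
    if (nrow(det) == 0) return(0)
    matched <- rep(FALSE, n_truth)
    tp <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
      cand <- which(truths$image_id == det$image_id[i] & !matched)
      if (length(cand) == 0) next
      ious <- vapply(cand, function(k) {
        box_iou(det[i, ], truths[k, ])
      }, numeric(1))
      best <- which.max(ious)
      if (ious[best] >= thr) {
        matched[cand[best]] <- TRUE
        tp[i] <- TRUE
      }
    }
    cum_tp <- cumsum(tp)
    prec <- cum_tp / seq_along(tp)
    rec <- cum_tp / n_truth
    prec_env <- rev(cummax(rev(prec)))
    drec <- diff(c(0, rec))
    sum(drec * prec_env)
  }
  ap <- vapply(iou_thresholds, ap_one, numeric(1))
  res <- tibble::tibble(iou_threshold = iou_thresholds, ap = ap)
  structure(list(ap = res,
                 map50 = if (any(iou_thresholds == 0.5))
                   ap[iou_thresholds == 0.5] else NA_real_,
                 map5095 = mean(ap),
                 n_detections = nrow(det),
                 n_truths = n_truth),
            class = "detection_result")
}

#' @describeIn mean_ap AP per IoU threshold as a tibble.
#' @param x A `detection_result`.
#' @param ... Unused.
#' @export
tidy.detection_result <- function(x, ...) x$ap

#' One-row summary of a detection result
#'
#' @param x A `detection_result`.
#' @param ... Unused.
#' @return Tibble with `map50`, `map5095`, `n_detections`, `n_truths`.
#' @export
glance.detection_result <- function(x, ...) {
  tibble::tibble(map50 = x$map50, map5095 = x$map5095,
                 n_detections = x$n_detections, n_truths = x$n_truths)
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> mAP@0.5 = %.4f, mAP@[.5:.95] = %.4f (%d detections, %d truths)\n",
              x$map50, x$map5095, x$n_detections, x$n_truths))
  invisible(x)
}
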