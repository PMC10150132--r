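#' Segment the shaft from a cropped grayscale image
#'
#' Deterministic mask extraction: global Otsu threshold on intensity,
#' morphological opening then closing with a disc element, keep the
#' largest connected component, and fill holes. Designed for crops where
#' the shaft is brighter than the background, as produced by
#' [render_scene()] and [crop_to_window()].
#'
#' @param crop Numeric matrix in `[0, 1]`.
#' @param open_radius Disc radius (px) for opening/closing (default 3).
#' @return 0/1 integer mask of the same shape.
#' @export
segment_shaft <- function(crop, open_radius = 3) {
  img <- as_raster_matrix(crop)
  if (diff(range(img)) < 1e-6) abort("empty foreground: constant crop")
  thr <- EBImage::otsu(EBImage::Image(img), range = range(img))
  bw <- EBImage::Image((img > thr) + 0)
  if (open_radius > 0) {
    brush <- EBImage::makeBrush(2 * open_radius + 1, "disc")
    bw <- EBImage::closing(EBImage::opening(bw, brush), brush)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  n <- max(lab)
  if (n == 0) abort("empty foreground after morphological cleanup")
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- which.max(areas)
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(
    (lab == keep) + 0)))
  storage.mode(mask) <- "integer"
  mask
}

#' Pixelwise confusion counts and overlap metrics
#'
#' Compares a predicted binary mask with ground truth and reports the
#' confusion counts together with `accuracy = (TP + TN) / total`,
#' foreground `iou = TP / (TP + FP + FN)`,
#' `dsc = 2 TP / (2 TP + FP + FN)`, and `weighted_iou`, the
#' class-frequency-weighted mean of foreground and background IoU
#' (weights are the ground-truth class frequencies). Both IoU variants
#' are reported because verbal descriptions of "IoU" in segmentation
#' tables are often the weighted two-class form while the printed
#' formula is the foreground form.
#'
#' @param pred,truth 0/1 matrices of identical shape.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `iou`, `weighted_iou`, `dsc`.
#' @export
#' @examples
#' a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
#' b <- matrix(0L, 4, 4); b[2:3, 1:2] <- 1L
#' pixel_metrics(b, a)
pixel_metrics <- function(pred, truth) {
  p <- as_mask_matrix(pred)
  g <- as_mask_matrix(truth)
  if (!all(dim(p) == dim(g))) abort("mask shape mismatch")
  tp <- sum(p == 1L & g == 1L)
  fp <- sum(p == 1L & g == 0L)
  fn <- sum(p == 0L & g == 1L)
  tn <- sum(p == 0L & g == 0L)
  iou_fg <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1
  iou_bg <- if (tn + fp + fn > 0) tn / (tn + fp + fn) else 1
  n_fg <- tp + fn
  n_bg <- tn + fp
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    iou = iou_fg,
    weighted_iou = (n_fg * iou_fg + n_bg * iou_bg) / (n_fg + n_bg),
    dsc = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1)
}
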