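#' Construct a four-landmark keypoint set
#'
#' The four mid-axis landmarks of a bent shaft, in the fixed order
#' DMD_top `(x1, y1)`, DMD_bottom `(x2, y2)`, PMD_top `(x3, y3)`,
#' PMD_bottom `(x4, y4)`: DMD_top is the distal-most point of the distal
#' mid-axis, DMD_bottom its curvature-adjacent end; PMD_top is the
#' curvature-adjacent end of the proximal mid-axis, PMD_bottom the
#' proximal-most point. Coordinates are continuous (sub-pixel), x
#' rightward and y downward, 0-based.
#'
#' @param x1,y1,x2,y2,x3,y3,x4,y4 Landmark coordinates in pixels.
#' @return A tibble of class `keypoint_set` with columns `point`, `x`,
#'   `y` (rows in the order above).
#' @export
#' @examples
#' kps <- keypoint_set(0, 0, 0, 10, 5, 12, 15, 15)
#' kp_angle(kps)
keypoint_set <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  out <- tibble::tibble(
    point = c("dmd_top", "dmd_bottom", "pmd_top", "pmd_bottom"),
    x = as.numeric(c(x1, x2, x3, x4)),
    y = as.numeric(c(y1, y2, y3, y4)))
  if (anyNA(out$x) || anyNA(out$y)) abort("keypoints must be finite")
  class(out) <- c("keypoint_set", class(tibble::tibble()))
  out
}

# Wide one-row representation (manifest / JSON field order x1..y4).
kp_wide <- function(kps) {
  setNames(as.list(c(rbind(kps$x, kps$y))),
           c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4"))
}

kp_from_wide <- function(row) {
  keypoint_set(row$x1, row$y1, row$x2, row$y2,
               row$x3, row$y3, row$x4, row$y4)
}

kp_matrix <- function(kps) cbind(kps$x, kps$y)

#' Normalized mean error between two keypoint sets
#'
#' The mean Euclidean distance between corresponding landmarks, divided
#' by a per-image reference distance: the ground-truth distance from the
#' top DMD point to the bottom PMD point. The normalizer always comes
#' from the ground truth, so NME is comparable across predictions and
#' invariant to joint scaling or rotation of both sets.
#'
#' @param predicted,truth [keypoint_set()] objects.
#' @return A single nonnegative number.
#' @export
nme <- function(predicted, truth) {
  p <- kp_matrix(predicted)
  g <- kp_matrix(truth)
  if (nrow(p) != 4 || nrow(g) != 4) abort("keypoint sets must have 4 points")
  d <- sqrt(sum((g[1, ] - g[4, ])^2))
  if (d <= 0) abort("degenerate reference distance (DMD_top == PMD_bottom)")
  mean(sqrt(rowSums((p - g)^2))) / d
}
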