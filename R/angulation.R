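#' Mid-axis vectors from a keypoint set
#'
#' The distal mid-axis vector `v1 = (x1 - x2, y1 - y2)` and proximal
#' mid-axis vector `v2 = (x3 - x4, y3 - y4)`, exact component-wise
#' differences with no normalization. With the package's keypoint
#' ordering both vectors point "backwards" along the shaft (toward the
#' tip side of their zone), so a straight shaft yields an angle of 0 and
#' the angle between them is the curvature angle itself.
#'
#' @param kps A [keypoint_set()].
#' @return An `axis_vectors` object: list with numeric `v1` and `v2`.
#' @export
axis_vectors <- function(kps) {
  m <- kp_matrix(kps)
  v1 <- m[1, ] - m[2, ]
  v2 <- m[3, ] - m[4, ]
  if (all(v1 == 0) || all(v2 == 0)) {
    abort("degenerate axis: coincident keypoint pair")
  }
  structure(list(v1 = v1, v2 = v2), class = "axis_vectors")
}

#' Angle between the two mid-axis vectors
#'
#' Computes `theta = acos(v1 . v2 / (|v1| |v2|))` in degrees, in
#' `[0, 180]`. The cosine argument is clamped to `[-1, 1]` before the
#' arccosine to absorb floating-point rounding. Unlike slope-based
#' formulas, the vector form stays finite and correct as the angle
#' approaches 90 degrees.
#'
#' @param v An `axis_vectors` object, or the first vector `v1` (length-2
#'   numeric) when `v2` is supplied.
#' @param v2 Optional second vector.
#' @return The angle in degrees.
#' @export
#' @examples
#' angle_between(c(1, 0), c(0, 1)) # 90
angle_between <- function(v, v2 = NULL) {
  if (inherits(v, "axis_vectors")) {
    v1 <- v$v1
    v2 <- v$v2
  } else {
    v1 <- as.numeric(v)
    v2 <- as.numeric(v2)
  }
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) abort("zero-length axis vector")
  cosv <- sum(v1 * v2) / (n1 * n2)
  rad2deg(acos(max(-1, min(1, cosv))))
}

#' Curvature angle from a keypoint set
#'
#' Convenience composition of [axis_vectors()] and [angle_between()].
#'
#' @param kps A [keypoint_set()].
#' @return The curvature angle in degrees.
#' @export
kp_angle <- function(kps) angle_between(axis_vectors(kps))

#' Per-model angle-error report (MAE)
#'
#' Scores per-image angle predictions against per-model ground-truth
#' angles. Two overall summaries are computed because the two textbook
#' readings of MAE differ: `mae_pooled` is the mean absolute per-image
#' error over all images pooled (the headline figure), and
#' `mae_model_mean` is the mean over models of the absolute error of the
#' per-model averaged prediction.
#'
#' @param predictions Data frame with columns `model` and `angle`
#'   (one row per image).
#' @param truths Data frame with columns `model` and `angle` (one row
#'   per model).
#' @return An `angle_report`: a tibble with one row per model (`model`,
#'   `truth`, `n`, `mean`, `sd`, `mae`), carrying the overall summaries
#'   as attributes; see [glance.angle_report()].
#' @export
#' @examples
#' preds <- tibble::tibble(model = "a", angle = c(30, 35))
#' mae_report(preds, tibble::tibble(model = "a", angle = 33))
mae_report <- function(predictions, truths) {
  stopifnot(all(c("model", "angle") %in% names(predictions)),
            all(c("model", "angle") %in% names(truths)))
  missing <- setdiff(unique(predictions$model), truths$model)
  if (length(missing) > 0) {
    abort(paste("models without ground truth:",
                paste(missing, collapse = ", ")))
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(predictions),
    dplyr::distinct(tibble::as_tibble(truths), .data$model,
                    truth = .data$angle),
    by = "model")
  per_model <- joined |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(truth = .data$truth[1],
                     n = dplyr::n(),
                     mean = mean(.data$angle),
                     sd = stats::sd(.data$angle),
                     mae = mean(abs(.data$angle - .data$truth)),
                     .groups = "drop")
  structure(per_model,
            class = c("angle_report", class(per_model)),
            mae_pooled = mean(abs(joined$angle - joined$truth)),
            mae_model_mean = mean(abs(per_model$mean - per_model$truth)),
            n_images = nrow(joined))
}

#' @describeIn mae_report Per-model rows as a tibble.
#' @param x An `angle_report`.
#' @param ... Unused.
#' @export
tidy.angle_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[seq_along(x)])
}

#' One-row summary of an angle report
#'
#' @param x An `angle_report`.
#' @param ... Unused.
#' @return Tibble with `n_models`, `n_images`, `mae_pooled` (mean
#'   absolute per-image error over all pooled images) and
#'   `mae_model_mean` (mean absolute error of per-model mean
#'   predictions).
#' @export
glance.angle_report <- function(x, ...) {
  tibble::tibble(n_models = nrow(x),
                 n_images = attr(x, "n_images"),
                 mae_pooled = attr(x, "mae_pooled"),
                 mae_model_mean = attr(x, "mae_model_mean"))
}

#' @export
print.angle_report <- function(x, ...) {
  cat(sprintf("<angle_report> %d models, %d images; pooled MAE %.3f deg (per-model-mean MAE %.3f deg)\n",
              nrow(x), attr(x, "n_images"), attr(x, "mae_pooled"),
              attr(x, "mae_model_mean")))
  print(tidy(x))
  invisible(x)
}
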