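#' Read and write binary masks as PNG
#'
#' Masks are stored as single-channel PNG with foreground 255 and
#' background 0.
#'
#' @param mask 0/1 integer matrix.
#' @param path File path.
#' @return `read_mask_png` returns a 0/1 integer matrix;
#'   `write_mask_png` returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask_matrix(mask) + 0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  as_mask_matrix(png::readPNG(path))
}

#' Read a grayscale image raster
#'
#' Reads a PNG and averages colour channels to a grayscale matrix in
#' `[0, 1]`.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_image_png <- function(path) {
  as_raster_matrix(png::readPNG(path))
}

#' Read and write keypoint records as JSON
#'
#' Records use the manifest field order: `image_id`, `x1`, `y1`, ...,
#' `x4`, `y4` (DMD_top, DMD_bottom, PMD_top, PMD_bottom).
#'
#' @param df Data frame with those columns (one row per image).
#' @param path File path.
#' @return `read_keypoints_json` returns a tibble.
#' @export
write_keypoints_json <- function(df, path) {
  cols <- c("image_id", "x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")
  stopifnot(all(cols %in% names(df)))
  jsonlite::write_json(df[, cols], path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_keypoints_json
#' @export
read_keypoints_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Read and write detection boxes as JSON
#'
#' Records `{image_id, x_min, y_min, x_max, y_max, confidence}`.
#'
#' @param df Data frame of detections.
#' @param path File path.
#' @return `read_detections_json` returns a tibble.
#' @export
write_detections_json <- function(df, path) {
  cols <- c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")
  stopifnot(all(cols %in% names(df)))
  jsonlite::write_json(df[, cols], path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_detections_json
#' @export
read_detections_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Import YOLO-format detection text files
#'
#' Reads the normalized `class cx cy w h [conf]` text dialect and
#' converts to absolute corner coordinates for the given image size.
#'
#' @param path Text file, one box per line.
#' @param image_size `(height, width)` in pixels.
#' @param image_id Id to attach to all rows.
#' @return Tibble of boxes in corner form.
#' @export
read_yolo_boxes <- function(path, image_size, image_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(image_id = character(), x_min = numeric(),
                          y_min = numeric(), x_max = numeric(),
                          y_max = numeric(), confidence = numeric()))
  }
  h <- image_size[1]
  w <- image_size[2]
  purrr::map(lines, function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    tibble::tibble(image_id = image_id,
                   x_min = (v[2] - v[4] / 2) * w,
                   y_min = (v[3] - v[5] / 2) * h,
                   x_max = (v[2] + v[4] / 2) * w,
                   y_max = (v[3] + v[5] / 2) * h,
                   confidence = if (length(v) >= 6) v[6] else 1)
  }) |> purrr::list_rbind()
}

#' Read a dataset manifest CSV
#'
#' @param path Path to a `manifest.csv` written by [make_dataset()].
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
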