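#' Pipeline configuration
#'
#' All tunable thresholds of the image-to-angle pipeline in one flat,
#' serializable record.
#'
#' @param crop_size Side of the square analysis window, px (default 256).
#' @param conf_floor Detection confidence floor (default 0.75;
#'   detections must exceed it).
#' @param margin Fractional box expansion before cropping.
#' @param open_radius Morphology disc radius, px, for detection and
#'   segmentation cleanup.
#' @param straightness_tol Zone-partition straightness tolerance,
#'   degrees.
#' @param distal Distal-end rule for [extract_midline()]: `"auto"`,
#'   `"top"`, `"bottom"`, `"left"`, `"right"` (per-image hints from a
#'   manifest override this).
#' @param seed Integer seed recorded with runs.
#' @param out_dir Optional output directory for masks and reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(crop_size = 256, conf_floor = 0.75,
                            margin = 0.05, open_radius = 3,
                            straightness_tol = 3, distal = "auto",
                            seed = 0L, out_dir = NULL) {
  cfg <- structure(
    list(crop_size = as.integer(crop_size),
         conf_floor = as.numeric(conf_floor),
         margin = as.numeric(margin),
         open_radius = as.integer(open_radius),
         straightness_tol = as.numeric(straightness_tol),
         distal = distal,
         seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$crop_size < 16) abort("crop_size must be >= 16")
  if (cfg$conf_floor < 0 || cfg$conf_floor > 1) {
    abort("conf_floor must be in [0, 1]")
  }
  if (cfg$margin < 0 || cfg$margin > 1) abort("margin must be in [0, 1]")
  if (cfg$open_radius < 0) abort("open_radius must be >= 0")
  if (cfg$straightness_tol <= 0 || cfg$straightness_tol > 45) {
    abort("straightness_tol must be in (0, 45] degrees")
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm,
                if (is.null(x[[nm]])) "<none>" else as.character(x[[nm]])))
  }
  invisible(x)
}

#' Write and read a pipeline configuration file
#'
#' Flat human-editable YAML; a read immediately after a write
#' reproduces the configuration exactly.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# Normalize run_pipeline input into a list of per-image work items.
pipeline_items <- function(x, input, manifest) {
  get_hint <- function(id, man) {
    if (!is.null(man) && all(c("x1", "y1") %in% names(man))) {
      r <- man[man$id == id, , drop = FALSE]
      if (nrow(r) == 1) return(c(r$x1[1], r$y1[1]))
    }
    NULL
  }
  if (inherits(x, "phantom_dataset")) {
    man <- if (is.null(manifest)) x else manifest
    return(purrr::map(seq_len(nrow(x)), function(i) {
      raster <- if (input == "mask") x$truth[[i]]$mask else x$image[[i]]
      list(id = x$id[i], raster = raster, hint = get_hint(x$id[i], man))
    }))
  }
  if (is.character(x)) {
    return(purrr::map(x, function(p) {
      raster <- if (input == "mask") read_mask_png(p) else read_image_png(p)
      id <- sub("\\.png$", "", basename(p))
      if (input == "mask") id <- sub("_mask$", "", id)
      list(id = id, raster = raster, hint = get_hint(id, manifest))
    }))
  }
  if (is.list(x)) {
    ids <- if (!is.null(names(x))) names(x) else
      sprintf("img_%04d", seq_along(x))
    return(purrr::map2(x, ids, function(r, id) {
      list(id = id, raster = r, hint = get_hint(id, manifest))
    }))
  }
  abort("unsupported input: expected a phantom_dataset, paths, or a list of rasters")
}

#' Run the full image-to-angle pipeline
#'
#' Image mode runs detect, crop, segment, midline, keypoints, angle per
#' image; mask mode skips the detection and segmentation stages entirely
#' and measures the supplied masks. Per-image failures at any stage are
#' recorded as warnings in the run record, not raised.
#'
#' @param x Input scenes: a [make_dataset()] tibble, a character vector
#'   of PNG paths, or a (optionally named) list of rasters.
#' @param config A [pipeline_config()].
#' @param input `"image"` or `"mask"`.
#' @param manifest Optional manifest (or the dataset itself) supplying
#'   per-image distal-end hints via its ground-truth `x1`, `y1` columns.
#' @return A `pipeline_run` tibble: one row per image with `id`,
#'   `status`, detection box (image mode), keypoints `x1..y4` in input
#'   coordinates, `angle` in degrees, a `warning` message for failures,
#'   and list-columns `pred_mask`/`crop_transform` for downstream
#'   evaluation.
#' @export
run_pipeline <- function(x, config = pipeline_config(),
                         input = c("image", "mask"), manifest = NULL) {
  input <- match.arg(input)
  validate_config(config)
  items <- pipeline_items(x, input, manifest)
  rows <- purrr::map(items, function(it) {
    run_one(it, config, input)
  }) |> purrr::list_rbind()
  if (all(rows$status != "ok")) {
    warn("no image yielded an angle")
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    flat <- rows[, setdiff(names(rows), c("pred_mask", "crop_transform"))]
    write.csv(flat, file.path(config$out_dir, "run_records.csv"),
              row.names = FALSE)
  }
  structure(rows, class = c("pipeline_run", class(rows)), config = config)
}

run_one <- function(it, config, input) {
  base <- tibble::tibble(
    id = it$id, status = "failed",
    x_min = NA_real_, y_min = NA_real_, x_max = NA_real_,
    y_max = NA_real_, confidence = NA_real_,
    x1 = NA_real_, y1 = NA_real_, x2 = NA_real_, y2 = NA_real_,
    x3 = NA_real_, y3 = NA_real_, x4 = NA_real_, y4 = NA_real_,
    angle = NA_real_, warning = NA_character_,
    pred_mask = list(NULL), crop_transform = list(NULL))
  out <- tryCatch({
    hint <- it$hint
    if (input == "image") {
      det <- detect_shaft(it$raster, conf_floor = config$conf_floor,
                          open_radius = config$open_radius)
      if (nrow(det) == 0) abort("no detection above the confidence floor")
      box <- det[1, ]
      crop <- crop_to_window(it$raster, box, out_size = config$crop_size,
                             margin = config$margin)
      tf <- attr(crop, "transform")
      mask <- segment_shaft(crop, open_radius = config$open_radius)
      hint_crop <- if (is.null(hint)) config$distal else
        as.numeric(transform_points(matrix(hint, 1), tf))
      ml <- extract_midline(mask, distal = hint_crop)
      kps <- derive_keypoints(ml, partition_zones(ml, config$straightness_tol))
      kps_orig <- transform_points(kps, tf, inverse = TRUE)
      row <- base
      row[, c("x_min", "y_min", "x_max", "y_max", "confidence")] <-
        box[, c("x_min", "y_min", "x_max", "y_max", "confidence")]
      row[, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")] <-
        kp_wide(kps_orig)
      row$angle <- kp_angle(kps)
      row$pred_mask <- list(mask)
      row$crop_transform <- list(tf)
      row$status <- "ok"
      row
    } else {
      mask <- as_mask_matrix(it$raster)
      ml <- extract_midline(mask,
                            distal = if (is.null(hint)) config$distal else hint)
      kps <- derive_keypoints(ml, partition_zones(ml, config$straightness_tol))
      row <- base
      row[, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")] <- kp_wide(kps)
      row$angle <- kp_angle(kps)
      row$pred_mask <- list(mask)
      row$status <- "ok"
      row
    }
  }, error = function(e) {
    row <- base
    row$warning <- conditionMessage(e)
    row
  })
  out
}

#' Evaluate a pipeline run against ground truth
#'
#' Computes the full metric set spanning all four families: detection
#' mAP, per-image pixel metrics (accuracy, IoU, weighted IoU, DSC),
#' per-image keypoint NME, and the per-model/overall angle MAE report.
#' Metric families whose inputs are absent from the run (e.g. boxes in
#' mask-input mode) are skipped.
#'
#' @param records A `pipeline_run`.
#' @param manifest Ground truth: a [make_dataset()] tibble or a manifest
#'   data frame with `id`, keypoints `x1..y4`, box columns, `model` and
#'   angle columns (`model_angle_deg` preferred, else `angle_deg`).
#'   Every record id must be present.
#' @return A `curvature_eval` list with elements `detection`
#'   (`detection_result` or `NULL`), `segmentation` (per-image tibble),
#'   `keypoints` (per-image NME tibble), `angles` (an `angle_report`);
#'   summarized by [glance.curvature_eval()].
#' @export
evaluate_run <- function(records, manifest) {
  man <- tibble::as_tibble(manifest)
  missing <- setdiff(records$id, man$id)
  if (length(missing) > 0) {
    abort(paste("id mismatch: records without manifest truth:",
                paste(head(missing, 5), collapse = ", ")))
  }
  ok <- records[records$status == "ok", , drop = FALSE]
  man_ok <- man[match(ok$id, man$id), , drop = FALSE]

  detection <- NULL
  if (any(!is.na(ok$x_min)) &&
      all(c("x_min", "y_min", "x_max", "y_max") %in% names(man))) {
    det <- ok[!is.na(ok$x_min),
              c("id", "x_min", "y_min", "x_max", "y_max", "confidence")]
    names(det)[1] <- "image_id"
    tru <- man[, c("id", "x_min", "y_min", "x_max", "y_max")]
    names(tru)[1] <- "image_id"
    detection <- mean_ap(det, tru)
  }

  segmentation <- NULL
  if ("truth" %in% names(man) && any(!purrr::map_lgl(ok$pred_mask, is.null))) {
    segmentation <- purrr::map(seq_len(nrow(ok)), function(i) {
      pred <- ok$pred_mask[[i]]
      if (is.null(pred)) return(NULL)
      tm <- man_ok$truth[[i]]$mask
      tf <- ok$crop_transform[[i]]
      if (!is.null(tf)) {
        tm <- crop_apply(tm, tf, fill = 0, binarize = TRUE)
      }
      dplyr::bind_cols(tibble::tibble(id = ok$id[i]), pixel_metrics(pred, tm))
    }) |> purrr::list_rbind()
  }

  keypoints <- NULL
  if (all(c("x1", "y1", "x4", "y4") %in% names(man))) {
    keypoints <- purrr::map(seq_len(nrow(ok)), function(i) {
      tibble::tibble(id = ok$id[i],
                     nme = nme(kp_from_wide(ok[i, ]),
                               kp_from_wide(man_ok[i, ])))
    }) |> purrr::list_rbind()
  }

  truth_col <- if ("model_angle_deg" %in% names(man)) "model_angle_deg"
    else "angle_deg"
  model_col <- if ("model" %in% names(man)) "model" else "id"
  preds <- tibble::tibble(model = man_ok[[model_col]], angle = ok$angle)
  truths <- dplyr::distinct(tibble::tibble(model = man[[model_col]],
                                           angle = man[[truth_col]]))
  angles <- mae_report(preds, truths)

  structure(list(detection = detection, segmentation = segmentation,
                 keypoints = keypoints, angles = angles,
                 n_ok = nrow(ok), n_failed = nrow(records) - nrow(ok)),
            class = "curvature_eval")
}

#' One-row summary of a full evaluation
#'
#' @param x A `curvature_eval`.
#' @param ... Unused.
#' @return Tibble with `map50`, `map5095`, mean `accuracy`, `iou`,
#'   `weighted_iou`, `dsc`, `mean_nme`, `mae_pooled`, `mae_model_mean`
#'   and counts (missing families are `NA`).
#' @export
glance.curvature_eval <- function(x, ...) {
  seg <- if (!is.null(x$segmentation)) {
    dplyr::summarise(x$segmentation,
                     accuracy = mean(.data$accuracy),
                     iou = mean(.data$iou),
                     weighted_iou = mean(.data$weighted_iou),
                     dsc = mean(.data$dsc))
  } else {
    tibble::tibble(accuracy = NA_real_, iou = NA_real_,
                   weighted_iou = NA_real_, dsc = NA_real_)
  }
  tibble::tibble(
    map50 = if (is.null(x$detection)) NA_real_ else x$detection$map50,
    map5095 = if (is.null(x$detection)) NA_real_ else x$detection$map5095,
    accuracy = seg$accuracy, iou = seg$iou,
    weighted_iou = seg$weighted_iou, dsc = seg$dsc,
    mean_nme = if (is.null(x$keypoints)) NA_real_ else mean(x$keypoints$nme),
    mae_pooled = attr(x$angles, "mae_pooled"),
    mae_model_mean = attr(x$angles, "mae_model_mean"),
    n_ok = x$n_ok, n_failed = x$n_failed)
}

#' @export
print.curvature_eval <- function(x, ...) {
  cat("<curvature_eval>\n")
  print(glance(x))
  invisible(x)
}

#' Write an evaluation to a machine-readable JSON file
#'
#' @param eval A `curvature_eval`.
#' @param path File path.
#' @export
write_eval <- function(eval, path) {
  out <- list(summary = glance(eval),
              per_model_angles = tidy(eval$angles))
  if (!is.null(eval$detection)) out$ap <- tidy(eval$detection)
  if (!is.null(eval$segmentation)) out$segmentation = eval$segmentation
  if (!is.null(eval$keypoints)) out$keypoints = eval$keypoints
  jsonlite::write_json(out, path, digits = NA, dataframe = "rows")
  invisible(path)
}
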