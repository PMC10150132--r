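#' Describe a synthetic bent-shaft phantom
#'
#' A phantom is a constant-width stroke swept along a piecewise midline:
#' a straight distal segment, a curvature zone, and a straight proximal
#' segment. Hinge-type phantoms concentrate the whole bend at a single
#' vertex (`curve_length = 0`); arc-type phantoms distribute it along a
#' circular arc whose total turning angle equals `curvature_angle`. The
#' defaults mimic a paediatric-scale shaft (about 1.5 cm wide, 5-6 cm
#' long) rendered into a 256 x 256 raster.
#'
#' @param curvature_angle Curvature angle in degrees, in `[0, 150)`.
#' @param curvature_type `"arc"` or `"hinge"`.
#' @param shaft_width Stroke width in pixels (> 0).
#' @param distal_length,proximal_length Straight-zone midline lengths in
#'   pixels (> 0).
#' @param curve_length Arclength of the curvature zone in pixels; must be
#'   0 for hinge phantoms and > 0 for arc phantoms with a nonzero angle.
#' @param global_rotation In-plane rotation of the whole phantom, degrees.
#' @param tip_style `"rounded"` (default) or `"flat"` distal tip cap.
#' @param image_size `(height, width)` of the target raster in pixels.
#' @param jitter List with `horizontal` and `vertical` camera-jitter
#'   ranges in degrees, used by [make_dataset()] when spawning jittered
#'   scenes. Defaults to `(-5, 5)` and `(0, 20)`, the two-axis ranges of
#'   the emulated photography protocol.
#'
#' @return An object of class `phantom_spec` (a named list).
#' @seealso [make_phantom()], [make_dataset()]
#' @export
#' @examples
#' spec <- phantom_spec(curvature_angle = 40, curvature_type = "hinge")
#' truth <- make_phantom(spec)
#' truth$angle
phantom_spec <- function(curvature_angle = 40,
                         curvature_type = c("arc", "hinge"),
                         shaft_width = 16,
                         distal_length = 60,
                         curve_length = NULL,
                         proximal_length = 66,
                         global_rotation = 0,
                         tip_style = c("rounded", "flat"),
                         image_size = c(256, 256),
                         jitter = list(horizontal = c(-5, 5),
                                       vertical = c(0, 20))) {
  curvature_type <- match.arg(curvature_type)
  tip_style <- match.arg(tip_style)
  if (is.null(curve_length)) {
    curve_length <- if (curvature_type == "hinge") 0 else 40
  }
  spec <- structure(
    list(curvature_angle = as.numeric(curvature_angle),
         curvature_type = curvature_type,
         shaft_width = as.numeric(shaft_width),
         distal_length = as.numeric(distal_length),
         curve_length = as.numeric(curve_length),
         proximal_length = as.numeric(proximal_length),
         global_rotation = as.numeric(global_rotation),
         tip_style = tip_style,
         image_size = as.integer(image_size),
         jitter = jitter),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$curvature_angle < 0 || spec$curvature_angle >= 150) {
    abort("curvature_angle must be in [0, 150) degrees")
  }
  if (spec$shaft_width <= 0) abort("shaft_width must be > 0")
  if (spec$distal_length <= 0 || spec$proximal_length <= 0) {
    abort("distal_length and proximal_length must be > 0")
  }
  if (spec$curvature_type == "hinge" && spec$curve_length != 0) {
    abort("hinge phantoms require curve_length = 0")
  }
  if (spec$curvature_type == "arc" && spec$curvature_angle > 0 &&
      spec$curve_length <= 0) {
    abort("arc phantoms with a nonzero angle require curve_length > 0")
  }
  if (spec$curve_length < 0) abort("curve_length must be >= 0")
  if (length(spec$image_size) != 2 || any(spec$image_size < 16)) {
    abort("image_size must be (height, width), both >= 16")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s, %.1f deg, width %.1f px, zones %g/%g/%g px, rot %.1f deg\n",
              x$curvature_type, x$curvature_angle, x$shaft_width,
              x$distal_length, x$curve_length, x$proximal_length,
              x$global_rotation))
  invisible(x)
}

# Analytic midline: distal segment -> (arc | hinge vertex) -> proximal
# segment, in the image coordinate frame (x rightward, y downward,
# 0-based pixel centers). Returns sample points including the exact zone
# break positions, plus their row indices.
phantom_midline_points <- function(spec, rotation_extra = 0, step = 0.25) {
  theta <- deg2rad(spec$curvature_angle)
  phi0 <- deg2rad(spec$global_rotation + rotation_extra)
  ld <- spec$distal_length
  lc <- spec$curve_length
  lp <- spec$proximal_length
  total <- ld + lc + lp
  breaks <- c(0, ld, ld + lc, total)
  tt <- sort(unique(c(seq(0, total, by = step), breaks, total)))
  u0 <- c(cos(phi0), sin(phi0))
  phi1 <- phi0 + theta
  u1 <- c(cos(phi1), sin(phi1))
  p_ld <- ld * u0
  if (lc > 0 && theta > 0) {
    k <- theta / lc
    arc_pt <- function(s) {
      cbind(p_ld[1] + (sin(phi0 + k * s) - sin(phi0)) / k,
            p_ld[2] - (cos(phi0 + k * s) - cos(phi0)) / k)
    }
  } else {
    arc_pt <- function(s) cbind(p_ld[1] + s * u0[1], p_ld[2] + s * u0[2])
  }
  p_lc <- as.numeric(arc_pt(lc))
  pt_at <- function(t) {
    out <- matrix(0, length(t), 2)
    i1 <- t <= ld
    i2 <- t > ld & t < ld + lc
    i3 <- t >= ld + lc
    if (any(i1)) out[i1, ] <- cbind(t[i1] * u0[1], t[i1] * u0[2])
    if (any(i2)) out[i2, ] <- arc_pt(t[i2] - ld)
    if (any(i3)) {
      s <- t[i3] - ld - lc
      out[i3, ] <- cbind(p_lc[1] + s * u1[1], p_lc[2] + s * u1[2])
    }
    out
  }
  pts <- pt_at(tt)
  list(points = pts, t = tt,
       break_idx = match(breaks, tt),
       break_points = pt_at(breaks),
       directions = c(phi0, phi1))
}

# Shared constructor for phantom ground truth, optionally with pose
# jitter: extra in-plane rotation (degrees) and a foreshortening tilt
# (degrees) that scales the geometry along image y by cos(tilt),
# emulating an out-of-plane camera angle.
build_phantom_truth <- function(spec, rotation_extra = 0, tilt = 0) {
  ml <- phantom_midline_points(spec, rotation_extra = rotation_extra)
  pts <- ml$points
  bpts <- ml$break_points
  if (tilt != 0) {
    cy <- mean(range(pts[, 2]))
    f <- cos(deg2rad(tilt))
    pts[, 2] <- cy + (pts[, 2] - cy) * f
    bpts[, 2] <- cy + (bpts[, 2] - cy) * f
  }
  r <- spec$shaft_width / 2
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  xr <- range(pts[, 1]) + c(-r, r)
  yr <- range(pts[, 2]) + c(-r, r)
  if (diff(xr) > w - 3 || diff(yr) > h - 3) {
    abort("rendered shaft would clip the image border")
  }
  shift <- c((w - 1) / 2 - mean(xr), (h - 1) / 2 - mean(yr))
  pts <- sweep(pts, 2, shift, "+")
  bpts <- sweep(bpts, 2, shift, "+")

  d <- cpp_polyline_distance(pts[, 1], pts[, 2], h, w, r + 2)
  mask <- (d <= r) + 0L
  if (spec$tip_style == "flat") {
    u0 <- c(cos(deg2rad(spec$global_rotation + rotation_extra)),
            sin(deg2rad(spec$global_rotation + rotation_extra)))
    xs <- matrix(rep(0:(w - 1), each = h), h, w)
    ys <- matrix(rep(0:(h - 1), times = w), h, w)
    ahead <- (xs - bpts[1, 1]) * u0[1] + (ys - bpts[1, 2]) * u0[2] >= 0
    mask <- mask * (ahead + 0L)
  }

  kps <- keypoint_set(bpts[1, 1], bpts[1, 2], bpts[2, 1], bpts[2, 2],
                      bpts[3, 1], bpts[3, 2], bpts[4, 1], bpts[4, 2])
  ang <- if (tilt == 0) spec$curvature_angle else kp_angle(kps)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  sb <- s[ml$break_idx]
  zones <- tibble::tibble(zone = c("distal", "curvature", "proximal"),
                          s_start = sb[1:3], s_end = sb[2:4])
  structure(
    list(mask = mask,
         keypoints = kps,
         bbox = mask_bbox(mask),
         angle = ang,
         midline = tibble::tibble(x = pts[, 1], y = pts[, 2], s = s),
         zones = zones,
         spec = spec),
    class = "phantom_truth")
}

#' Build a phantom silhouette with analytic ground truth
#'
#' Sweeps a constant-width stroke along the spec's midline (two straight
#' segments joined at a vertex for hinge type; straight-arc-straight for
#' arc type) and returns the rasterized binary mask together with exact
#' ground truth: the midline, the four mid-axis keypoints (DMD_top,
#' DMD_bottom, PMD_top, PMD_bottom), the tight bounding box, the zone
#' partition, and the curvature angle. The keypoints are the midline
#' endpoints and the two zone boundaries; because the midline ends at the
#' cap centers, each terminal keypoint sits one cap radius inside the
#' physical silhouette end.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed recorded for provenance; the construction
#'   itself is deterministic, so the result depends only on `spec`.
#' @return A `phantom_truth` object: list with elements `mask` (0/1
#'   integer matrix), `keypoints` (a [keypoint_set()]), `bbox` (one-row
#'   tibble), `angle` (degrees), `midline` (tibble `x`, `y`, `s`),
#'   `zones` (tibble of arclength intervals) and `spec`.
#' @export
make_phantom <- function(spec, seed = 0L) {
  validate_phantom_spec(spec)
  out <- build_phantom_truth(spec)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s, angle %.3f deg, mask %d x %d (%d fg px)\n",
              x$spec$curvature_type, x$angle, nrow(x$mask), ncol(x$mask),
              sum(x$mask)))
  invisible(x)
}

# Tight axis-aligned bounding box of a mask, 0-based edge coordinates:
# a pixel at (x, y) spans [x, x + 1) after the -1 shift, so width and
# height equal pixel counts.
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask has no foreground")
  tibble::tibble(x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
                 x_max = max(idx[, 2]), y_max = max(idx[, 1]),
                 confidence = 1)
}

#' Render a phantom into a grayscale scene
#'
#' Paints the phantom silhouette at a foreground intensity over a plain
#' or textured background, optionally adding Gaussian intensity noise.
#' Rendering is geometry-preserving: the scene's image stays aligned
#' with the phantom's ground-truth mask, keypoints and bounding box
#' (pose jitter is applied when scenes are spawned by [make_dataset()]).
#'
#' @param truth A `phantom_truth` from [make_phantom()].
#' @param background `"plain"` (flat) or `"textured"` (seeded smooth
#'   sinusoidal field, amplitude well below the foreground-background
#'   gap).
#' @param noise_sd Standard deviation of additive Gaussian intensity
#'   noise, in intensity units (images span `[0, 1]`).
#' @param fg,bg Foreground and background base intensities.
#' @param seed Integer seed; the rendering is byte-identical for a fixed
#'   `(truth, background, noise_sd, seed)`.
#' @return A `scene` object: list with `image` (numeric matrix in
#'   `[0, 1]`), `bbox` (tight box of the silhouette) and `truth`.
#' @export
render_scene <- function(truth, background = c("plain", "textured"),
                         noise_sd = 0, fg = 0.75, bg = 0.25, seed = 0L) {
  background <- match.arg(background)
  stopifnot(inherits(truth, "phantom_truth"))
  if (fg <= bg) abort("fg intensity must exceed bg")
  h <- nrow(truth$mask)
  w <- ncol(truth$mask)
  img <- with_seed(seed, {
    base <- matrix(bg, h, w)
    if (background == "textured") {
      fx <- runif(1, 1 / 60, 1 / 25)
      fy <- runif(1, 1 / 60, 1 / 25)
      ph <- runif(2, 0, 2 * pi)
      xs <- matrix(rep(0:(w - 1), each = h), h, w)
      ys <- matrix(rep(0:(h - 1), times = w), h, w)
      base <- base + 0.08 * sin(2 * pi * fx * xs + ph[1]) *
        sin(2 * pi * fy * ys + ph[2])
    }
    out <- base
    out[truth$mask == 1L] <- fg
    if (noise_sd > 0) out <- out + rnorm(h * w, 0, noise_sd)
    out
  })
  img[img < 0] <- 0
  img[img > 1] <- 1
  structure(list(image = img, bbox = truth$bbox, truth = truth),
            class = "scene")
}

#' Generate a jittered phantom dataset with a ground-truth manifest
#'
#' Emulates the study protocol behind the method: a small set of distinct
#' bent-shaft models with curvature angles spread over a range, each
#' photographed many times under camera jitter. Every scene gets its own
#' self-consistent analytic truth: the per-scene pose jitter (an in-plane
#' rotation drawn from the spec's horizontal range and a foreshortening
#' tilt drawn from the vertical range) is applied to the geometry before
#' rasterization, so the recorded per-image `angle_deg` is the projected
#' angle while `model_angle_deg` keeps the model's nominal angle.
#'
#' @param n_models Number of distinct phantom models (>= 1).
#' @param per_model Scenes per model (>= 1).
#' @param angle_range `(low, high)` nominal curvature angles in degrees;
#'   models are spread evenly over the range.
#' @param type_mix Fraction of models that are hinge-type (the rest are
#'   arc-type); hinge models are interleaved across the angle ladder.
#' @param seed Integer seed driving all stochastic choices.
#' @param render If `TRUE`, render a grayscale scene image for every
#'   mask; masks-only datasets are faster for landmark benchmarks.
#' @param background,noise_sd,fg,bg Passed to [render_scene()].
#' @param image_size `(height, width)` raster size for all scenes.
#' @param dir Optional directory; when given, masks (and images) are
#'   written as PNG and a `manifest.csv` is written with columns `id`,
#'   `image_path`, `mask_path`, `angle_deg`, keypoints `x1..y4` (order
#'   DMD_top, DMD_bottom, PMD_top, PMD_bottom) and bbox columns.
#' @return A tibble (class `phantom_dataset`) with one row per scene:
#'   ids, model metadata, nominal and projected angles, keypoints, bbox,
#'   and list-columns `truth` (the `phantom_truth`) and `image`.
#' @export
make_dataset <- function(n_models = 9, per_model = 100,
                         angle_range = c(18, 86), type_mix = 0.5,
                         seed = 0L, render = TRUE,
                         background = "plain", noise_sd = 0,
                         fg = 0.75, bg = 0.25,
                         image_size = c(256, 256), dir = NULL) {
  if (n_models < 1 || per_model < 1) {
    abort("n_models and per_model must both be >= 1")
  }
  if (length(angle_range) != 2 || !all(is.finite(angle_range)) ||
      angle_range[2] < angle_range[1]) {
    abort("angle_range must be a finite (low, high) pair")
  }
  angles <- if (n_models == 1) mean(angle_range) else
    seq(angle_range[1], angle_range[2], length.out = n_models)
  n_hinge <- min(n_models, ceiling(type_mix * n_models))
  types <- rep("arc", n_models)
  if (n_hinge > 0) {
    types[unique(round(seq(1, n_models, length.out = n_hinge)))] <- "hinge"
  }

  rows <- with_seed(seed, {
    purrr::map(seq_len(n_models), function(i) {
      distal <- runif(1, 50, 68)
      ratio <- runif(1, 0.8, 1.2)
      width <- 0.25 * distal
      curve <- if (types[i] == "hinge") 0 else
        runif(1, 0.25, 0.40) * distal * (1 + ratio)
      spec <- phantom_spec(curvature_angle = angles[i],
                           curvature_type = types[i],
                           shaft_width = width,
                           distal_length = distal,
                           curve_length = curve,
                           proximal_length = distal * ratio,
                           image_size = image_size)
      purrr::map(seq_len(per_model), function(j) {
        rot <- runif(1, 0, 360)
        hj <- runif(1, spec$jitter$horizontal[1], spec$jitter$horizontal[2])
        vj <- runif(1, spec$jitter$vertical[1], spec$jitter$vertical[2])
        scene_seed <- sample.int(.Machine$integer.max - 1L, 1)
        truth <- build_phantom_truth(spec, rotation_extra = rot + hj,
                                     tilt = vj)
        img <- if (render) {
          render_scene(truth, background = background, noise_sd = noise_sd,
                       fg = fg, bg = bg, seed = scene_seed)$image
        } else NULL
        kw <- kp_wide(truth$keypoints)
        tibble::tibble(
          id = sprintf("m%02d_s%03d", i, j),
          model = sprintf("model_%d", i),
          curvature_type = types[i],
          model_angle_deg = angles[i],
          angle_deg = truth$angle,
          !!!kw,
          x_min = truth$bbox$x_min, y_min = truth$bbox$y_min,
          x_max = truth$bbox$x_max, y_max = truth$bbox$y_max,
          jitter_h = hj, jitter_v = vj, scene_seed = scene_seed,
          truth = list(truth),
          image = list(img))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows$mask_path <- file.path(dir, paste0(rows$id, "_mask.png"))
    rows$image_path <- if (render) {
      file.path(dir, paste0(rows$id, ".png"))
    } else NA_character_
    for (k in seq_len(nrow(rows))) {
      write_mask_png(rows$truth[[k]]$mask, rows$mask_path[k])
      if (render) png::writePNG(rows$image[[k]], rows$image_path[k])
    }
    man <- rows[, c("id", "image_path", "mask_path", "angle_deg",
                    "x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4",
                    "x_min", "y_min", "x_max", "y_max",
                    "model", "model_angle_deg", "curvature_type")]
    man$seed <- as.integer(seed)
    write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(rows, class = c("phantom_dataset", class(rows)),
            seed = as.integer(seed), dir = dir)
}
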