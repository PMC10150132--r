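test_that("ground-truth angle and keypoints are analytically consistent", {
  grid <- expand.grid(angle = c(0, 18, 40, 86, 120),
                      type = c("hinge", "arc"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    spec <- phantom_spec(curvature_angle = grid$angle[i],
                         curvature_type = grid$type[i],
                         curve_length = if (grid$type[i] == "hinge") 0 else 40)
    tr <- make_phantom(spec)
    expect_identical(tr$angle, grid$angle[i])
    expect_lt(abs(kp_angle(tr$keypoints) - grid$angle[i]), 1e-9)
    # keypoints lie on the recorded midline
    km <- cbind(tr$keypoints$x, tr$keypoints$y)
    mlm <- cbind(tr$midline$x, tr$midline$y)
    for (k in 1:4) {
      expect_lt(min(sqrt(rowSums(sweep(mlm, 2, km[k, ])^2))), 0.3)
    }
  }
})

test_that("a zero-angle phantom has a straight midline", {
  tr <- make_phantom(phantom_spec(curvature_angle = 0,
                                  curvature_type = "hinge"))
  d <- prcomp(cbind(tr$midline$x, tr$midline$y))$sdev
  expect_lt(d[2], 1e-9)
  expect_identical(tr$angle, 0)
})

test_that("arc construction turns by exactly the requested angle", {
  spec <- phantom_spec(curvature_angle = 86, curvature_type = "arc",
                       curve_length = 45)
  tr <- make_phantom(spec)
  # tangent directions at the ends of the analytic midline
  ml <- tr$midline
  n <- nrow(ml)
  v_d <- c(ml$x[1] - ml$x[5], ml$y[1] - ml$y[5])
  v_p <- c(ml$x[n - 4] - ml$x[n], ml$y[n - 4] - ml$y[n])
  expect_lt(abs(angle_between(v_d, v_p) - 86), 1e-6)
})

test_that("global rotation changes neither angle nor mask area materially", {
  base <- make_phantom(phantom_spec(curvature_angle = 40,
                                    curvature_type = "arc",
                                    curve_length = 40))
  for (phi in c(33, 117, 250)) {
    rot <- make_phantom(phantom_spec(curvature_angle = 40,
                                     curvature_type = "arc",
                                     curve_length = 40,
                                     global_rotation = phi))
    expect_identical(rot$angle, base$angle)
    expect_lt(abs(sum(rot$mask) - sum(base$mask)) / sum(base$mask), 0.02)
  }
})

test_that("mask area matches the swept-stroke construction", {
  for (tr in list(hinge40(), arc60())) {
    expected <- tr$spec$shaft_width * max(tr$midline$s) +
      pi * (tr$spec$shaft_width / 2)^2 # straight sweep plus two end caps
    expect_lt(abs(sum(tr$mask) - expected) / expected, 0.10)
  }
})

test_that("a shaft too large for the image is rejected", {
  expect_error(
    make_phantom(phantom_spec(distal_length = 150, proximal_length = 150,
                              curvature_angle = 0, curvature_type = "hinge")),
    "clip")
})

test_that("phantoms and rendered scenes are deterministic under a seed", {
  a <- make_phantom(phantom_spec(curvature_angle = 35))
  b <- make_phantom(phantom_spec(curvature_angle = 35))
  expect_identical(a$mask, b$mask)
  s1 <- render_scene(a, noise_sd = 0.02, seed = 7)
  s2 <- render_scene(a, noise_sd = 0.02, seed = 7)
  expect_identical(s1$image, s2$image)
  s3 <- render_scene(a, noise_sd = 0.02, seed = 8)
  expect_false(identical(s1$image, s3$image))
})

test_that("noiseless rendering thresholds back to the exact mask", {
  tr <- hinge40()
  sc <- render_scene(tr, background = "plain", noise_sd = 0)
  expect_identical((sc$image > 0.5) + 0L, tr$mask)
  expect_identical(sc$bbox, tr$bbox)
})

test_that("make_dataset produces the requested layout and honest truth", {
  ds <- make_dataset(n_models = 9, per_model = 2, angle_range = c(18, 86),
                     seed = 5, render = FALSE)
  expect_equal(nrow(ds), 18)
  expect_equal(length(unique(ds$model_angle_deg)), 9)
  expect_true(all(ds$model_angle_deg >= 18 & ds$model_angle_deg <= 86))
  expect_setequal(unique(ds$curvature_type), c("hinge", "arc"))
  # pose jitter stays inside the protocol ranges
  expect_true(all(ds$jitter_h >= -5 & ds$jitter_h <= 5))
  expect_true(all(ds$jitter_v >= 0 & ds$jitter_v <= 20))
  # per-scene truth is self-consistent even under foreshortening
  for (i in c(1, 10, 18)) {
    expect_lt(abs(kp_angle(ds$truth[[i]]$keypoints) - ds$angle_deg[i]), 1e-9)
  }
  # a single-scene dataset works
  one <- make_dataset(n_models = 1, per_model = 1, seed = 1, render = FALSE)
  expect_equal(nrow(one), 1)
  expect_error(make_dataset(n_models = 0, per_model = 1), "n_models")
})

test_that("dataset regeneration with the same seed is identical", {
  a <- make_dataset(n_models = 2, per_model = 2, seed = 11, render = TRUE,
                    noise_sd = 0.01)
  b <- make_dataset(n_models = 2, per_model = 2, seed = 11, render = TRUE,
                    noise_sd = 0.01)
  expect_identical(a$truth[[3]]$mask, b$truth[[3]]$mask)
  expect_identical(a$image[[4]], b$image[[4]])
  expect_identical(a$angle_deg, b$angle_deg)
})

test_that("written datasets round-trip through the manifest", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(n_models = 2, per_model = 1, seed = 3, render = TRUE,
                     dir = dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  expect_true(all(c("id", "image_path", "mask_path", "angle_deg",
                    "x1", "y1", "x4", "y4", "x_min", "y_max") %in% names(man)))
  m <- read_mask_png(man$mask_path[1])
  expect_identical(m, ds$truth[[1]]$mask)
})
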