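test_that("a straight rectangle yields its long axis as midline", {
  mask <- matrix(0L, 64, 160)
  mask[25:40, 21:140] <- 1L # long axis at y = 31.5
  ml <- extract_midline(mask, distal = "left")
  mid_y <- ml$y[ml$x > 30 & ml$x < 130]
  expect_lt(max(abs(mid_y - 31.5)), 1)
  pz <- partition_zones(ml)
  cz <- pz[pz$zone == "curvature", ]
  expect_equal(cz$s_start, cz$s_end) # empty curvature zone
  kps <- derive_keypoints(ml, pz)
  # all four points collinear
  res <- prcomp(cbind(kps$x, kps$y))$sdev[2]
  expect_lt(res, 1e-6)
})

test_that("a disk has no dominant axis", {
  mask <- matrix(0L, 64, 64)
  xs <- matrix(rep(0:63, each = 64), 64, 64)
  ys <- matrix(rep(0:63, times = 64), 64, 64)
  mask[(xs - 32)^2 + (ys - 32)^2 <= 20^2] <- 1L
  expect_error(extract_midline(mask), "dominant|endpoints|short")
})

test_that("masks thinner than 3 px and multi-component masks are rejected", {
  thin <- matrix(0L, 32, 32)
  thin[10, 5:25] <- 1L
  expect_error(extract_midline(thin), "interior")
  two <- matrix(0L, 64, 64)
  two[10:20, 10:40] <- 1L
  two[40:50, 10:40] <- 1L
  expect_error(extract_midline(two), "single")
})

test_that("the extracted midline tracks the constructed one closely", {
  tr <- hinge40()
  ml <- extract_midline(tr$mask, distal = distal_hint(tr))
  expect_gte(nrow(ml), 10)
  expect_true(all(diff(ml$s) > 0))
  expect_lt(hausdorff(midline_matrix(ml), midline_matrix(tr$midline)), 1.5)
})

test_that("zone partition recovers hinge and arc curvature zones", {
  # hinge: the curvature interval collapses to (near) the vertex
  tr <- hinge40()
  ml <- extract_midline(tr$mask, distal = distal_hint(tr))
  pz <- partition_zones(ml)
  cz <- pz[pz$zone == "curvature", ]
  expect_lte((cz$s_end - cz$s_start) / max(ml$s), 0.05)
  vertex_true <- tr$zones$s_start[2] / max(tr$midline$s)
  vertex_rec <- cz$s_start / max(ml$s)
  expect_lt(abs(vertex_rec - vertex_true), 0.05)

  # arc: recovered interval overlaps the true one with Jaccard >= 0.8
  tra <- arc60()
  mla <- extract_midline(tra$mask, distal = distal_hint(tra))
  pza <- partition_zones(mla)
  cza <- pza[pza$zone == "curvature", ]
  tz <- tra$zones[tra$zones$zone == "curvature", ]
  # compare as fractions of total arclength
  rec <- c(cza$s_start, cza$s_end) / max(mla$s)
  tru <- c(tz$s_start, tz$s_end) / max(tra$midline$s)
  inter <- max(0, min(rec[2], tru[2]) - max(rec[1], tru[1]))
  union <- max(rec[2], tru[2]) - min(rec[1], tru[1])
  expect_gte(inter / union, 0.8)
})

test_that("derived keypoints from ground-truth midline match ground truth", {
  for (tr in list(hinge40(), arc60())) {
    kps <- derive_keypoints(tr$midline, as_partition(tr$zones))
    err <- sqrt((kps$x - tr$keypoints$x)^2 + (kps$y - tr$keypoints$y)^2)
    expect_lt(max(err), 2)
  }
})

test_that("reversing the midline orientation swaps the keypoint pairs", {
  tr <- arc60()
  ml <- tr$midline
  rev_ml <- tibble::tibble(x = rev(ml$x), y = rev(ml$y),
                           s = max(ml$s) - rev(ml$s))
  total <- max(ml$s)
  z <- tr$zones
  rev_zones <- tibble::tibble(
    zone = c("distal", "curvature", "proximal"),
    s_start = total - c(z$s_end[3], z$s_end[2], z$s_end[1]),
    s_end = total - c(z$s_start[3], z$s_start[2], z$s_start[1]))
  kf <- derive_keypoints(ml, as_partition(z))
  kr <- derive_keypoints(rev_ml, as_partition(rev_zones))
  expect_equal(cbind(kr$x, kr$y), cbind(kf$x, kf$y)[4:1, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("NME matches its definition and invariances", {
  truth <- keypoint_set(0, 0, 0, 40, 10, 50, 10, 100)
  expect_equal(nme(truth, truth), 0)
  d <- sqrt(10^2 + 100^2)
  shifted <- keypoint_set(0 + d / 10, 0, 0 + d / 10, 40,
                          10 + d / 10, 50, 10 + d / 10, 100)
  expect_equal(nme(shifted, truth), 0.1, tolerance = 1e-12)
  # scale invariance
  double <- function(k) keypoint_set(2 * k$x[1], 2 * k$y[1], 2 * k$x[2],
                                     2 * k$y[2], 2 * k$x[3], 2 * k$y[3],
                                     2 * k$x[4], 2 * k$y[4])
  expect_equal(nme(double(shifted), double(truth)), nme(shifted, truth),
               tolerance = 1e-12)
  # rotation invariance
  expect_equal(nme(rotate_kps(shifted, 73), rotate_kps(truth, 73)),
               nme(shifted, truth), tolerance = 1e-9)
  degenerate <- keypoint_set(0, 0, 1, 1, 2, 2, 0, 0)
  expect_error(nme(shifted, degenerate), "reference")
})

test_that("rotating a mask leaves the keypoint NME unchanged", {
  angle_spec <- function(rot) {
    phantom_spec(curvature_angle = 50, curvature_type = "arc",
                 curve_length = 40, global_rotation = rot)
  }
  nmes <- vapply(c(0, 68, 141), function(rot) {
    tr <- make_phantom(angle_spec(rot))
    kps <- mask_keypoints(tr$mask, distal = distal_hint(tr))
    nme(kps, tr$keypoints)
  }, numeric(1))
  expect_lt(max(nmes), 0.05)
  expect_lt(diff(range(nmes)), 0.02)
})

test_that("the full landmark stage stays within NME 0.05 across the family", {
  grid <- expand.grid(angle = c(10, 40, 100),
                      width = c(10, 16),
                      type = c("hinge", "arc"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    spec <- phantom_spec(
      curvature_angle = grid$angle[i], curvature_type = grid$type[i],
      shaft_width = grid$width[i],
      curve_length = if (grid$type[i] == "hinge") 0 else 40)
    tr <- make_phantom(spec)
    kps <- mask_keypoints(tr$mask, distal = distal_hint(tr))
    expect_lt(nme(kps, tr$keypoints), 0.05)
  }
})

test_that("the landmark stage is deterministic", {
  tr <- arc60()
  k1 <- mask_keypoints(tr$mask, distal = distal_hint(tr))
  k2 <- mask_keypoints(tr$mask, distal = distal_hint(tr))
  expect_identical(k1, k2)
})

test_that("keypoints round-trip through JSON records", {
  df <- tibble::tibble(image_id = "a", x1 = 1.5, y1 = 2, x2 = 3, y2 = 4,
                       x3 = 5, y3 = 6, x4 = 7, y4 = 8.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_keypoints_json(df, path)
  expect_equal(as.data.frame(read_keypoints_json(path)), as.data.frame(df))
})
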