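test_that("box_iou matches hand-computed overlaps", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1.0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0.0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150)
})

test_that("box_iou is symmetric and translation invariant", {
  set.seed(42)
  for (i in 1:25) {
    a <- c(runif(2, 0, 50), 0, 0)
    a[3:4] <- a[1:2] + runif(2, 1, 40)
    b <- c(runif(2, 0, 50), 0, 0)
    b[3:4] <- b[1:2] + runif(2, 1, 40)
    expect_equal(box_iou(a, b), box_iou(b, a))
    shift <- runif(2, -20, 20)
    expect_equal(box_iou(a + shift[c(1, 2, 1, 2)], b + shift[c(1, 2, 1, 2)]),
                 box_iou(a, b), tolerance = 1e-12)
  }
})

test_that("detect_shaft recovers the exact box on a noiseless scene", {
  tr <- hinge40()
  sc <- render_scene(tr)
  det <- detect_shaft(sc$image)
  expect_equal(nrow(det), 1)
  expect_equal(det$confidence, 1)
  expect_equal(unlist(det[1, 1:4]), unlist(tr$bbox[1, 1:4]),
               tolerance = 1.01, ignore_attr = TRUE)
})

test_that("a blank image yields no detections", {
  expect_equal(nrow(detect_shaft(matrix(0.3, 64, 64))), 0)
})

test_that("secondary blobs below the confidence floor are suppressed", {
  img <- matrix(0.2, 128, 128)
  img[20:59, 20:39] <- 0.8   # 800 px component
  img[90:109, 90:109] <- 0.8 # 400 px component -> confidence 0.5
  det <- detect_shaft(img, open_radius = 0)
  expect_equal(nrow(det), 1)
  expect_lt(det$x_max[1], 80)
  # with the floor lowered, both components are reported
  det2 <- detect_shaft(img, conf_floor = 0.25, open_radius = 0)
  expect_equal(nrow(det2), 2)
  expect_equal(det2$confidence, c(1, 0.5))
})

test_that("crop_to_window emits the requested window and exact transform", {
  tr <- arc60()
  sc <- render_scene(tr)
  crop <- crop_to_window(sc$image, sc$bbox, out_size = 256, margin = 0.05)
  expect_equal(dim(crop), c(256L, 256L))
  tf <- attr(crop, "transform")
  pts <- cbind(runif(20, 0, 255), runif(20, 0, 255))
  back <- transform_points(transform_points(pts, tf), tf, inverse = TRUE)
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("a square box with zero margin is a pure rescale", {
  img <- matrix(runif(100 * 100), 100, 100)
  crop <- crop_to_window(img, c(10, 20, 50, 60), out_size = 80, margin = 0)
  tf <- attr(crop, "transform")
  expect_equal(tf$scale, 2) # 40 px box -> 80 px window
  # the box corners land on the window corners
  corners <- transform_points(rbind(c(9.5, 19.5), c(49.5, 59.5)), tf)
  expect_equal(corners, rbind(c(-0.5, -0.5), c(79.5, 79.5)),
               tolerance = 1e-9)
})

test_that("degenerate boxes are rejected", {
  img <- matrix(0, 10, 10)
  expect_error(crop_to_window(img, c(5, 5, 5, 9)), "degenerate")
  expect_error(box_iou(c(0, 0, 0, 5), c(0, 0, 1, 1)), "degenerate")
})

test_that("mean_ap reproduces enumerated precision-recall areas", {
  truths <- tibble::tibble(image_id = "a",
                           x_min = c(0, 20), y_min = c(0, 20),
                           x_max = c(10, 30), y_max = c(10, 30))
  hit1 <- c(0, 0, 10, 10)
  hit2 <- c(20, 20, 30, 30)
  miss <- c(40, 40, 50, 50)
  det <- tibble::tibble(image_id = "a",
                        x_min = c(hit1[1], miss[1], hit2[1]),
                        y_min = c(hit1[2], miss[2], hit2[2]),
                        x_max = c(hit1[3], miss[3], hit2[3]),
                        y_max = c(hit1[4], miss[4], hit2[4]),
                        confidence = c(0.9, 0.8, 0.7))
  res <- mean_ap(det, truths, iou_thresholds = 0.5)
  # ranked [hit, miss, hit]: precision at the recall steps is 1/1, 2/3
  expect_equal(res$ap$ap, (1 + 2 / 3) / 2, tolerance = 1e-12)

  perfect <- det[c(1, 3), ]
  expect_equal(mean_ap(perfect, truths, 0.5)$ap$ap, 1.0)
  none <- dplyr::mutate(det, x_min = x_min + 100, x_max = x_max + 100)
  expect_equal(mean_ap(none, truths, 0.5)$ap$ap, 0.0)
})

test_that("mAP@0.5 bounds mAP@[.5:.95] and empty truth errors", {
  set.seed(7)
  truths <- tibble::tibble(image_id = rep("a", 4),
                           x_min = c(0, 30, 60, 0), y_min = c(0, 0, 0, 40),
                           x_max = c(20, 50, 80, 20), y_max = c(20, 20, 20, 60))
  det <- dplyr::mutate(truths,
                       x_min = x_min + runif(4, -4, 4),
                       y_min = y_min + runif(4, -4, 4),
                       x_max = x_max + runif(4, -4, 4),
                       y_max = y_max + runif(4, -4, 4),
                       confidence = runif(4, 0.8, 1))
  res <- mean_ap(det, truths)
  expect_gte(res$map50, res$map5095)
  expect_true(all(res$ap$ap >= 0 & res$ap$ap <= 1))
  expect_error(mean_ap(det, truths[0, ]), "undefined")
})

test_that("detection JSON and YOLO text round-trip", {
  df <- tibble::tibble(image_id = c("a", "b"),
                       x_min = c(1, 2), y_min = c(3, 4),
                       x_max = c(11, 12), y_max = c(13, 14),
                       confidence = c(0.9, 0.8))
  path <- withr::local_tempfile(fileext = ".json")
  write_detections_json(df, path)
  expect_equal(as.data.frame(read_detections_json(path)), as.data.frame(df))
  ypath <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.25 0.25", ypath)
  yb <- read_yolo_boxes(ypath, image_size = c(100, 200))
  expect_equal(unlist(yb[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 75, y_min = 37.5, x_max = 125, y_max = 62.5))
})
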