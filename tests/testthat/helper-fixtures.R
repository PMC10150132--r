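# fixtures are generated in code and cached per test run
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

hinge40 <- function() cached("hinge40", {
  make_phantom(phantom_spec(curvature_angle = 40, curvature_type = "hinge"))
})

arc60 <- function() cached("arc60", {
  make_phantom(phantom_spec(curvature_angle = 60, curvature_type = "arc",
                            curve_length = 51, distal_length = 60,
                            proximal_length = 59))
})

# symmetric Hausdorff distance between two point sets (n x 2 matrices)
hausdorff <- function(a, b) {
  one_way <- function(p, q) {
    max(vapply(seq_len(nrow(p)), function(i) {
      min(sqrt((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2))
    }, numeric(1)))
  }
  max(one_way(a, b), one_way(b, a))
}

midline_matrix <- function(ml) cbind(ml$x, ml$y)

# distal-end hint for a phantom: its ground-truth DMD_top location
distal_hint <- function(truth) c(truth$keypoints$x[1], truth$keypoints$y[1])

as_partition <- function(df) {
  structure(tibble::as_tibble(df),
            class = c("zone_partition", class(tibble::tibble())))
}

# slope-based two-line angle formula (the classical alternative that
# breaks down at 90 degrees); defined only for non-vertical axes
slope_angle <- function(kps) {
  m1 <- (kps$y[1] - kps$y[2]) / (kps$x[1] - kps$x[2])
  m2 <- (kps$y[3] - kps$y[4]) / (kps$x[3] - kps$x[4])
  abs(atan((m1 - m2) / (1 + m1 * m2))) * 180 / pi
}

rotate_kps <- function(kps, phi_deg, center = c(0, 0)) {
  phi <- phi_deg * pi / 180
  xr <- center[1] + (kps$x - center[1]) * cos(phi) -
    (kps$y - center[2]) * sin(phi)
  yr <- center[2] + (kps$x - center[1]) * sin(phi) +
    (kps$y - center[2]) * cos(phi)
  keypoint_set(xr[1], yr[1], xr[2], yr[2], xr[3], yr[3], xr[4], yr[4])
}
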