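#' Extract the mid-axis (midline) of a shaft mask
#'
#' Morphological (Zhang-Suen) skeletonization, followed by the longest
#' geodesic path between skeleton endpoints on the 8-connected pixel
#' graph, pruning of short side branches, moving-average smoothing over
#' a 5-point window, and orientation fixing so the path runs distal tip
#' first.
#'
#' Side branches longer than `spur_frac` of the main path mean there is
#' no dominant axis and raise an error, as do masks with no interior
#' (thinner than about 3 px) or blob-like masks whose main path is not
#' clearly longer than the local half-width (e.g. a disk).
#'
#' @param mask Single-component, hole-free 0/1 matrix.
#' @param distal Which end of the path is the distal tip: `"auto"`
#'   (the end with the smaller local width, i.e. tip taper, with a
#'   deterministic top-left tie-break), one of `"top"`, `"bottom"`,
#'   `"left"`, `"right"`, or a numeric `(x, y)` hint (the end nearer the
#'   hint is distal).
#' @param spur_frac Maximum tolerated side-branch length as a fraction
#'   of the main path (default 0.10).
#' @param smooth_window Moving-average window in points (default 5).
#' @return A `midline_path`: tibble with columns `x`, `y` and arclength
#'   `s`, ordered from distal tip to proximal base.
#' @export
extract_midline <- function(mask, distal = "auto", spur_frac = 0.10,
                            smooth_window = 5) {
  m <- as_mask_matrix(mask)
  if (sum(m) == 0) abort("mask has no foreground")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m + 0)))
  if (max(lab) > 1) abort("mask must be a single connected component")
  m <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m + 0)))
  storage.mode(m) <- "integer"
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(m + 0)))
  max_r <- max(dm)
  if (max_r < 1.5) abort("mask has no interior (width < 3 px)")

  skel <- cpp_thin(m)
  px <- which(skel == 1L, arr.ind = TRUE) # [row, col]
  if (nrow(px) < 10) abort("skeleton too short for a midline")

  # 8-neighbour graph over skeleton pixels
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(nrow(px))
  edges <- NULL
  wts <- NULL
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (o in offs) {
    r2 <- px[, 1] + o[1]
    c2 <- px[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nrow(skel) & c2 >= 1 & c2 <= ncol(skel)
    nb <- integer(nrow(px))
    nb[ok] <- id[cbind(r2[ok], c2[ok])]
    hit <- which(nb > 0)
    if (length(hit) > 0) {
      edges <- c(edges, rbind(hit, nb[hit]))
      wts <- c(wts, rep(sqrt(sum(o^2)), length(hit)))
    }
  }
  if (is.null(edges)) abort("skeleton is disconnected")
  g <- igraph::make_graph(edges, n = nrow(px), directed = FALSE)
  igraph::E(g)$weight <- wts
  deg <- igraph::degree(g)
  ends <- which(deg == 1)
  if (length(ends) < 2) abort("no dominant axis: skeleton has no endpoints")
  dmat <- igraph::distances(g, v = ends, to = ends)
  best <- which(dmat == max(dmat[is.finite(dmat)]), arr.ind = TRUE)[1, ]
  main_len <- dmat[best[1], best[2]]
  if (!is.finite(main_len)) abort("skeleton is disconnected")
  if (main_len < 3 * max_r) abort("no dominant axis (blob-like mask)")
  path <- igraph::shortest_paths(g, from = ends[best[1]],
                                 to = ends[best[2]])$vpath[[1]]
  path <- as.integer(path)

  # spur check: remaining endpoints must hang off the main path by less
  # than spur_frac of its length
  others <- setdiff(ends, c(ends[best[1]], ends[best[2]]))
  if (length(others) > 0) {
    dspur <- igraph::distances(g, v = others, to = path)
    spur_len <- apply(dspur, 1, min)
    if (any(spur_len > spur_frac * main_len)) {
      abort("no dominant path: skeleton branches too long to prune")
    }
  }

  xy <- cbind(px[path, 2] - 1, px[path, 1] - 1) # x = col - 1, y = row - 1
  xy <- smooth_path(xy, smooth_window)
  xy <- refine_path_ends(xy, dm)

  # orientation: distal end first
  n <- nrow(xy)
  k <- min(5, n)
  w_head <- mean(bilinear_at(dm, xy[1:k, 1], xy[1:k, 2]))
  w_tail <- mean(bilinear_at(dm, xy[(n - k + 1):n, 1], xy[(n - k + 1):n, 2]))
  flip <- if (is.numeric(distal) && length(distal) == 2) {
    sum((xy[n, ] - distal)^2) < sum((xy[1, ] - distal)^2)
  } else {
    switch(as.character(distal),
      auto = if (abs(w_head - w_tail) > 0.05 * max(w_head, w_tail)) {
        w_tail < w_head
      } else {
        (xy[n, 2] < xy[1, 2]) ||
          (xy[n, 2] == xy[1, 2] && xy[n, 1] < xy[1, 1])
      },
      top = xy[n, 2] < xy[1, 2],
      bottom = xy[n, 2] > xy[1, 2],
      left = xy[n, 1] < xy[1, 1],
      right = xy[n, 1] > xy[1, 1],
      abort("unknown distal rule"))
  }
  if (flip) xy <- xy[n:1, , drop = FALSE]

  s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  out <- tibble::tibble(x = xy[, 1], y = xy[, 2], s = s)
  class(out) <- c("midline_path", class(tibble::tibble()))
  attr(out, "max_radius") <- max_r
  out
}

# bilinear lookup of a matrix at continuous (x, y) center coordinates
bilinear_at <- function(m, x, y) {
  nr <- nrow(m)
  nc <- ncol(m)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2)
  y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0
  fy <- y - y0
  at <- function(r, c) m[cbind(r + 1, c + 1)]
  (1 - fx) * (1 - fy) * at(y0, x0) + fx * (1 - fy) * at(y0, x0 + 1) +
    (1 - fx) * fy * at(y0 + 1, x0) + fx * fy * at(y0 + 1, x0 + 1)
}

# Thinning retracts and sometimes hooks the skeleton near a rounded end
# cap. Trim about half a cap radius from each path end, then extend the
# end along its local tangent to the cap center, located where the
# distance transform starts to fall off (inside the cap, distance to
# background drops linearly toward the silhouette end).
refine_path_ends <- function(xy, dm) {
  for (pass in 1:2) {
    xy <- xy[nrow(xy):1, , drop = FALSE]
    r0 <- bilinear_at(dm, xy[1, 1], xy[1, 2])
    s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
    keep <- which(s >= r0 / 2)
    if (length(keep) >= 10) xy <- xy[keep, , drop = FALSE]
    k <- min(6, nrow(xy))
    u <- xy[1, ] - xy[k, ]
    un <- sqrt(sum(u^2))
    if (un == 0) next
    u <- u / un
    r1 <- bilinear_at(dm, xy[1, 1], xy[1, 2])
    tt <- 0
    est <- NULL
    while (tt < 3 * r1) {
      tt <- tt + 0.25
      p <- xy[1, ] + tt * u
      v <- bilinear_at(dm, p[1], p[2])
      if (v < r1 - 0.5) {
        est <- p - (r1 - v) * u
        break
      }
    }
    if (!is.null(est)) {
      len <- sqrt(sum((est - xy[1, ])^2))
      if (len > 0.3) {
        steps <- seq(len, len / ceiling(len), length.out = ceiling(len))
        add <- cbind(xy[1, 1] + steps * (est[1] - xy[1, 1]) / len,
                     xy[1, 2] + steps * (est[2] - xy[1, 2]) / len)
        xy <- rbind(add, xy)
      }
    }
  }
  xy
}

# centered moving average with shrinking windows at the ends
smooth_path <- function(xy, window) {
  if (window <= 1) return(xy)
  half <- floor(window / 2)
  n <- nrow(xy)
  out <- xy
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    out[i, ] <- colMeans(xy[j, , drop = FALSE])
  }
  out
}

# local tangent direction (radians, unwrapped) from chords over +/- span
path_tangents <- function(xy, span = 2) {
  n <- nrow(xy)
  i0 <- pmax(1, seq_len(n) - span)
  i1 <- pmin(n, seq_len(n) + span)
  th <- atan2(xy[i1, 2] - xy[i0, 2], xy[i1, 1] - xy[i0, 1])
  # unwrap
  dth <- diff(th)
  dth <- dth - 2 * pi * round(dth / (2 * pi))
  c(th[1], th[1] + cumsum(dth))
}

#' Partition a midline into distal, curvature and proximal zones
#'
#' Uses the structure of the shape family: along a
#' straight-bend-straight shaft the tangent angle is a piecewise-linear
#' function of arclength (flat over the distal zone, ramping at constant
#' curvature over an arc - or stepping at a hinge vertex - then flat
#' over the proximal zone). The two zone boundaries are located by a
#' least-squares change-point fit of that flat-ramp-flat profile, with
#' each straight run constrained to at least `min_run_frac` of the total
#' arclength. When the whole tangent profile stays within
#' `straightness_tol` of flat (a near-straight shaft) the midline is
#' split at its midpoint and the curvature zone is empty. A fitted
#' straight run whose tangents still deviate grossly from flat is
#' rejected (the straight zone is effectively shorter than the minimum
#' run).
#'
#' @param midline A `midline_path` from [extract_midline()].
#' @param straightness_tol Maximum tangent deviation counted as
#'   straight, degrees (default 3).
#' @param min_run_frac Minimum straight-run length as a fraction of
#'   total arclength (default 0.15).
#' @return A `zone_partition`: tibble with rows `distal`, `curvature`,
#'   `proximal` and columns `zone`, `s_start`, `s_end` (curvature may be
#'   empty: `s_start == s_end`).
#' @export
partition_zones <- function(midline, straightness_tol = 3,
                            min_run_frac = 0.15) {
  xy <- cbind(midline$x, midline$y)
  n <- nrow(xy)
  if (n < 10) abort("midline too short to partition")
  s <- midline$s
  total <- s[n]
  tol <- deg2rad(straightness_tol)
  th <- path_tangents(xy)

  if (max(th) - min(th) <= 2 * tol) {
    # near-straight: the straight runs from both ends overlap
    mid <- total / 2
    s_d <- mid
    s_p <- mid
  } else {
    # moving-average the tangent profile so that raster quantization
    # noise does not swamp the model comparison below
    th_f <- smooth_path(cbind(th, th), 5)[, 1]
    free <- fit_three_zone(s, th_f, min_run_frac)
    # Hinge-vs-arc model selection. Path smoothing, chord tangents and
    # the skeleton's corner rounding smear a hinge's step profile into a
    # short ramp whose width scales with the stroke half-width, and
    # tangent noise can stretch a shallow step even further. Refit with
    # the ramp constrained to that smear width; if the constrained
    # (hinge) model explains the profile almost as well, the bend is a
    # point vertex and the zone collapses to the narrow ramp's midpoint.
    spacing <- total / (n - 1)
    blur <- max(7 * spacing, 1.1 * (attr(midline, "max_radius") %||% 0))
    hinge <- fit_three_zone(s, th_f, min_run_frac,
                            max_width = max(1, round(2 * blur / spacing)))
    if (hinge$sse <= 1.1 * free$sse + 1e-12) {
      # confident hinge: collapse to the narrow ramp's midpoint
      mid <- (s[hinge$i] + s[hinge$j]) / 2
      s_d <- mid
      s_p <- mid
      cp <- c(hinge$i, hinge$j)
    } else if (hinge$sse <= 1.5 * free$sse) {
      # ambiguous (shallow bend): a wrong hard choice would misplace the
      # inner keypoints by half the ramp; shrinking the free ramp by the
      # smear width bounds the error under either true shape
      mid <- (s[free$i] + s[free$j]) / 2
      s_d <- min(s[free$i] + blur, mid)
      s_p <- max(s[free$j] - blur, mid)
      cp <- c(free$i, free$j)
    } else {
      s_d <- s[free$i]
      s_p <- s[free$j]
      cp <- c(free$i, free$j)
    }
    rms <- function(v) sqrt(mean((v - mean(v))^2))
    if (max(rms(th[seq_len(cp[1])]), rms(th[cp[2]:n])) > 3 * tol) {
      abort("straight zone shorter than the minimum run fraction")
    }
  }
  out <- tibble::tibble(zone = c("distal", "curvature", "proximal"),
                        s_start = c(0, s_d, s_p),
                        s_end = c(s_d, s_p, total))
  class(out) <- c("zone_partition", class(tibble::tibble()))
  attr(out, "straightness_tol") <- straightness_tol
  out
}

# Least-squares change-point fit of a flat-ramp-flat profile to the
# tangent angles th(s): left mean over 1..i, right mean over j..n, and a
# connecting line between (s_i, left mean) and (s_j, right mean) for the
# points in between. All range sums come from prefix sums, so the sweep
# over candidate pairs is O(n) per left index.
fit_three_zone <- function(s, th, min_frac = 0.15, max_width = Inf) {
  n <- length(th)
  c1 <- cumsum(th)
  c2 <- cumsum(th^2)
  cs <- cumsum(s)
  css <- cumsum(s^2)
  cts <- cumsum(th * s)
  lo <- max(3, which(s >= min_frac * s[n])[1])
  hi <- min(n - 2, max(which(s <= (1 - min_frac) * s[n])))
  if (lo > hi) abort("midline too short for the minimum run fraction")
  best_sse <- Inf
  best <- c(lo, hi)
  for (i in lo:hi) {
    j <- i:min(hi, i + max_width)
    th0 <- c1[i] / i
    sse_l <- c2[i] - c1[i]^2 / i
    m_r <- n - j + 1
    sum_r <- c1[n] - c1[j - 1]
    th1 <- sum_r / m_r
    sse_r <- (c2[n] - c2[j - 1]) - sum_r^2 / m_r
    # middle points i+1 .. j-1 against the connecting line a + b*s
    b <- ifelse(s[j] > s[i], (th1 - th0) / (s[j] - s[i]), 0)
    a <- th0 - b * s[i]
    m_m <- pmax(0, j - 1 - i)
    jm <- pmax(i, j - 1)
    sum_t <- c1[jm] - c1[i]
    sum_t2 <- c2[jm] - c2[i]
    sum_s <- cs[jm] - cs[i]
    sum_s2 <- css[jm] - css[i]
    sum_ts <- cts[jm] - cts[i]
    sse_m <- sum_t2 - 2 * a * sum_t - 2 * b * sum_ts +
      a^2 * m_m + 2 * a * b * sum_s + b^2 * sum_s2
    sse <- sse_l + sse_r + sse_m
    k <- which.min(sse)
    if (sse[k] < best_sse) {
      best_sse <- sse[k]
      best <- c(i, j[k])
    }
  }
  list(i = best[1], j = best[2], sse = best_sse)
}

# position on the path at arclength s0 (linear interpolation)
path_point_at <- function(midline, s0) {
  cbind(stats::approx(midline$s, midline$x, xout = s0, rule = 2)$y,
        stats::approx(midline$s, midline$y, xout = s0, rule = 2)$y)
}

#' Derive the four mid-axis keypoints from a partitioned midline
#'
#' Fits a total-least-squares line to the midline points of each
#' straight zone and projects the zone's arclength endpoints
#' perpendicularly onto the fitted line. The projections are returned in
#' the fixed ordering DMD_top (distal-most), DMD_bottom
#' (curvature-adjacent), PMD_top (curvature-adjacent), PMD_bottom
#' (proximal-most).
#'
#' @param midline A `midline_path`.
#' @param partition A `zone_partition` for that midline.
#' @return A [keypoint_set()].
#' @export
derive_keypoints <- function(midline, partition) {
  stopifnot(is.data.frame(partition),
            all(c("zone", "s_start", "s_end") %in% names(partition)))
  fit_zone <- function(s0, s1, trim_end) {
    # the curvature-adjacent 15% of the zone can be contaminated by the
    # skeleton's corner rounding, so it is excluded from the line fit
    # (the zone endpoints are still the points projected)
    len <- s1 - s0
    f0 <- if (trim_end == "start") s0 + 0.15 * len else s0
    f1 <- if (trim_end == "end") s1 - 0.15 * len else s1
    idx <- which(midline$s >= f0 - 1e-9 & midline$s <= f1 + 1e-9)
    if (length(idx) < 3) {
      idx <- which(midline$s >= s0 - 1e-9 & midline$s <= s1 + 1e-9)
    }
    if (length(idx) < 3) abort("straight zone has fewer than 3 points")
    pts <- cbind(midline$x[idx], midline$y[idx])
    ctr <- colMeans(pts)
    dir <- prcomp(pts, center = TRUE)$rotation[, 1]
    project <- function(p) {
      as.numeric(ctr + sum((p - ctr) * dir) * dir)
    }
    ends <- path_point_at(midline, c(s0, s1))
    list(a = project(ends[1, ]), b = project(ends[2, ]))
  }
  d <- partition[partition$zone == "distal", ]
  p <- partition[partition$zone == "proximal", ]
  dz <- fit_zone(d$s_start, d$s_end, trim_end = "end")
  pz <- fit_zone(p$s_start, p$s_end, trim_end = "start")
  keypoint_set(dz$a[1], dz$a[2], dz$b[1], dz$b[2],
               pz$a[1], pz$a[2], pz$b[1], pz$b[2])
}

#' Mask-to-keypoints convenience wrapper
#'
#' Runs [extract_midline()], [partition_zones()] and
#' [derive_keypoints()] in sequence on a binary mask.
#'
#' @inheritParams extract_midline
#' @inheritParams partition_zones
#' @return A [keypoint_set()].
#' @export
mask_keypoints <- function(mask, distal = "auto", straightness_tol = 3) {
  ml <- extract_midline(mask, distal = distal)
  derive_keypoints(ml, partition_zones(ml, straightness_tol))
}
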