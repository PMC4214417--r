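# Morphological shape descriptors of a binary plant silhouette.
#
# The descriptor catalogue is a frozen contract of 25 named statistics
# (see `morph_feature_names`).  Conventions:
#   * pixels are unit squares; the convex hull is taken over pixel corner
#     points, so a filled w x h rectangle has hull area exactly w*h;
#   * perimeter uses the weighted boundary-configuration estimator
#     (Gray/ skimage-style weights 1, sqrt(2), (1+sqrt(2))/2), accurate to
#     well under 2% on rasterized discs;
#   * row 0 at the image top, so "height" is the vertical bbox extent.

#' Frozen catalogue of the 25 morphological descriptor names
#' @export
morph_feature_names <- c(
  "plant_height_px", "plant_width_px", "height_width_ratio", "bbox_area_px",
  "extent", "compactness", "solidity", "convexity", "circularity",
  "eccentricity", "major_axis_px", "minor_axis_px", "orientation_rad",
  "equivalent_diameter_px", "perimeter_px", "hull_area_px2",
  "hull_perimeter_px", "centroid_height_frac", "top_half_area_frac",
  "radial_spread_px", "hole_count", "skeleton_length_px", "branch_count",
  "caliper_diameter_px", "hull_bbox_fill")

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Crofton perimeter estimator (4 directions): each 2x2 pixel
# configuration contributes a fixed length increment; accurate to well
# under 1% on rasterized discs.
mask_perimeter <- function(bits) {
  H <- nrow(bits); W <- ncol(bits)
  m <- matrix(0, H + 2, W + 2)
  m[2:(H + 1), 2:(W + 1)] <- as.numeric(bits)
  code <- m + 4 * shift_mat(m, 0, 1) + 2 * shift_mat(m, 1, 0) +
    8 * shift_mat(m, 1, 1)
  h <- tabulate(code + 1, nbins = 16)
  coefs <- c(0, pi / 4 * (1 + 1 / sqrt(2)), pi / (4 * sqrt(2)),
             pi / (2 * sqrt(2)), 0, pi / 4 * (1 + 1 / sqrt(2)), 0,
             pi / (4 * sqrt(2)), pi / 4, pi / 2, pi / (4 * sqrt(2)),
             pi / (4 * sqrt(2)), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

# Convex hull over pixel corner points; returns closed polygon (rows r, c).
corner_hull <- function(r, co) {
  pts <- cbind(
    r = c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
    c = c(co - 0.5, co + 0.5, co - 0.5, co + 0.5))
  pts <- unique(pts)
  h <- grDevices::chull(pts[, 2], pts[, 1])  # x = col, y = row
  pts[h, , drop = FALSE]
}

shoelace_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

poly_perimeter <- function(poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  sum(sqrt((poly[, 1] - poly[j, 1])^2 + (poly[, 2] - poly[j, 2])^2))
}

# points-in-polygon by ray crossing (boundary-inclusive), vectorised
points_in_polygon <- function(pr, pc, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(pr))
  on_edge <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    cross <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    # distance from point to the segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx^2 + dy^2
    t <- if (L2 > 0) pmin(pmax(((pc - xi) * dx + (pr - yi) * dy) / L2, 0), 1)
         else 0
    d2 <- (pc - (xi + t * dx))^2 + (pr - (yi + t * dy))^2
    on_edge <- on_edge | d2 < eps
    j <- i
  }
  inside | on_edge
}

# Zhang-Suen thinning; returns logical skeleton matrix.
zhang_suen_skeleton <- function(bits) {
  m <- matrix(as.integer(bits), nrow(bits), ncol(bits))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

count_holes <- function(bits) {
  bg <- !bits
  cc <- label_components(bg, connectivity = 4L)
  if (length(cc$sizes) == 0L) return(0L)
  border_labels <- unique(c(cc$labels[1, ], cc$labels[nrow(bits), ],
                            cc$labels[, 1], cc$labels[, ncol(bits)]))
  sum(!seq_along(cc$sizes) %in% border_labels[border_labels > 0])
}

#' Morphological features of a plant mask
#'
#' Computes the frozen 25-descriptor catalogue (`morph_feature_names`).
#' Key definitions: `compactness = projected area / rasterized convex-hull
#' area` (pixel centres inside-or-on the hull of the pixel centres), so
#' compactness equals 1 exactly when the mask equals its own rasterized
#' hull -- true for every digitally convex shape, rectangles and discs
#' alike.  `solidity = projected area / continuous hull area` over pixel
#' corner points (a w x h rectangle has corner-hull area exactly w*h);
#' `circularity = 4*pi*A / P^2` with a Crofton perimeter;
#' `convexity = hull perimeter / perimeter`.
#'
#' @param mask A [plant_mask()] with at least one foreground pixel.
#' @return Named numeric vector of length 25 with attribute `degenerate`
#'   set when the mask has fewer than 4 pixels (ratio conventions apply).
#' @export
morphological_features <- function(mask) {
  bits <- unclass(mask)
  idx <- which(bits)
  A <- length(idx)
  if (A == 0L) stop("empty mask")
  H <- nrow(bits); W <- ncol(bits)
  r <- ((idx - 1L) %% H) + 1L
  co <- ((idx - 1L) %/% H) + 1L
  degenerate <- A < 4L

  h_px <- max(r) - min(r) + 1L
  w_px <- max(co) - min(co) + 1L
  bbox <- h_px * w_px

  hull <- corner_hull(r, co)
  hull_area <- shoelace_area(hull)
  hull_perim <- poly_perimeter(hull)

  # rasterized hull for compactness: pixel centres inside-or-on the hull
  # of the pixel centres
  hull_c <- if (A >= 3) {
    hc <- grDevices::chull(co, r)
    cbind(r[hc], co[hc])
  } else cbind(r, co)
  rr <- rep(min(r):max(r), times = w_px)
  cc <- rep(min(co):max(co), each = h_px)
  conv_px <- if (nrow(unique(hull_c)) < 3) A else
    max(sum(points_in_polygon(rr, cc, hull_c)), A)

  P <- mask_perimeter(bits)
  if (P <= 0) P <- 4 * sqrt(A)   # degenerate tiny blobs

  # central moments of pixel centres
  mr <- mean(r); mc <- mean(co)
  mu20 <- mean((co - mc)^2); mu02 <- mean((r - mr)^2)
  mu11 <- mean((co - mc) * (r - mr))
  common <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  if (l1 <= 0) { major <- 1; minor <- 1; ecc <- 0; orient <- 0 } else {
    major <- 4 * sqrt(l1)
    minor <- 4 * sqrt(pmax(l2, 0))
    ecc <- sqrt(pmax(1 - l2 / l1, 0))
    orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  }

  skel <- zhang_suen_skeleton(bits)
  sk <- matrix(as.numeric(skel), H, W)
  n4 <- (sum(sk * shift_mat(sk, 0, 1)) + sum(sk * shift_mat(sk, 1, 0)))
  nd <- (sum(sk * shift_mat(sk, 1, 1)) + sum(sk * shift_mat(sk, 1, -1)))
  skel_len <- n4 + sqrt(2) * nd
  nb8 <- shift_mat(sk, -1, 0) + shift_mat(sk, 1, 0) + shift_mat(sk, 0, -1) +
    shift_mat(sk, 0, 1) + shift_mat(sk, 1, 1) + shift_mat(sk, 1, -1) +
    shift_mat(sk, -1, 1) + shift_mat(sk, -1, -1)
  branches <- sum(sk == 1 & nb8 >= 3)

  hv <- hull[, 1]; hc <- hull[, 2]
  caliper <- if (nrow(hull) < 2) 1 else
    max(dist(cbind(hv, hc)))

  out <- c(
    plant_height_px = as.numeric(h_px),
    plant_width_px = as.numeric(w_px),
    height_width_ratio = h_px / w_px,
    bbox_area_px = as.numeric(bbox),
    extent = A / bbox,
    compactness = A / conv_px,
    solidity = min(A / hull_area, 1),
    convexity = min(hull_perim / P, 1),
    circularity = 4 * pi * A / P^2,
    eccentricity = ecc,
    major_axis_px = major,
    minor_axis_px = minor,
    orientation_rad = orient,
    equivalent_diameter_px = sqrt(4 * A / pi),
    perimeter_px = P,
    hull_area_px2 = hull_area,
    hull_perimeter_px = hull_perim,
    centroid_height_frac = if (h_px > 1) (max(r) - mr) / (h_px - 1) else 0.5,
    top_half_area_frac = mean(r < min(r) + h_px / 2),
    radial_spread_px = sqrt(mean((r - mr)^2 + (co - mc)^2)),
    hole_count = as.numeric(count_holes(bits)),
    skeleton_length_px = skel_len,
    branch_count = as.numeric(branches),
    caliper_diameter_px = caliper,
    hull_bbox_fill = hull_area / bbox)
  attr(out, "degenerate") <- degenerate
  out
}
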