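# Procedural scene generators with exact pixel-level ground truth.
#
# The plant renderer emulates what the side-view camera sees: a green
# shoot (vertical stem plus arcing leaves) on a uniform bright background.
# Truth masks are recorded at draw time, never re-segmented, so
# segmentation and feature contracts can be tested against exact values.

# stroke a polyline with a given thickness onto a logical canvas
stroke_mask <- function(H, W, xs, ys, thickness) {
  bits <- matrix(FALSE, H, W)
  rad <- thickness / 2
  # dense samples along the curve, then mark pixels within `rad`
  for (i in seq_along(xs)) {
    r0 <- max(1L, floor(ys[i] - rad)); r1 <- min(H, ceiling(ys[i] + rad))
    c0 <- max(1L, floor(xs[i] - rad)); c1 <- min(W, ceiling(xs[i] + rad))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - ys[i])^2, (cc - xs[i])^2, `+`)
    sub <- d2 <= rad^2
    bits[rr, cc] <- bits[rr, cc] | sub
  }
  bits
}

#' Render a synthetic side-view plant scene
#'
#' Draws a vertical stem plus `n_leaves` arcing leaf strokes in green hues
#' on a uniform background, and records the exact composite mask,
#' projected area, vertical extent and per-leaf pre-overlap pixel areas.
#' Deterministic for a given seed.
#'
#' @param n_leaves Number of leaves (0 allowed: bare stem).
#' @param stem_height_px Stem height in pixels.
#' @param leaf_thickness_px Leaf stroke thickness.
#' @param background RGB triple of the background, default near-white.
#' @param seed Integer seed.
#' @param canvas `c(H, W)`; default scales with the stem.
#' @return `plant_scene_truth`: list with `image` ([rgb_image()]), `mask`
#'   ([plant_mask()]), `area_px`, `height_px`, `leaf_count`,
#'   `leaf_areas_px` (pre-overlap), `stem_area_px`.
#' @export
render_plant <- function(n_leaves = 6L, stem_height_px = 160L,
                         leaf_thickness_px = 5L,
                         background = c(245, 245, 240), seed = 1L,
                         canvas = NULL) {
  stopifnot(n_leaves >= 0, stem_height_px > 0, leaf_thickness_px > 0)
  set.seed(seed)
  if (is.null(canvas))
    canvas <- c(round(stem_height_px * 1.5), round(stem_height_px * 1.6))
  H <- canvas[1]; W <- canvas[2]
  if (stem_height_px > H - 4) stop("stem exceeds canvas")
  cx <- round(W / 2)
  base_r <- H - 2L
  top_r <- base_r - stem_height_px + 1L
  stem_w <- 3L
  mask <- matrix(FALSE, H, W)
  mask[top_r:base_r, (cx - (stem_w %/% 2)):(cx + (stem_w %/% 2))] <- TRUE
  stem_area <- sum(mask)
  leaf_areas <- numeric(0)
  if (n_leaves > 0) {
    for (l in seq_len(n_leaves)) {
      side <- if (l %% 2 == 0) 1 else -1
      attach_r <- round(stats::runif(1, top_r + 2,
                                     base_r - stem_height_px * 0.25))
      len <- stats::runif(1, 0.35, 0.65) * stem_height_px
      droop <- stats::runif(1, 0.3, 1.1)
      t <- seq(0, 1, length.out = max(40L, round(2 * len)))
      xs <- cx + side * len * t
      ys <- attach_r - len * 0.8 * t + droop * len * t^2
      keep <- xs >= 2 & xs <= W - 1 & ys >= 2 & ys <= H - 1
      leaf <- stroke_mask(H, W, xs[keep], ys[keep], leaf_thickness_px)
      leaf_areas <- c(leaf_areas, sum(leaf))
      mask <- mask | leaf
    }
  }
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- background[ch]
  # plant-green hue with mild per-pixel jitter so texture is non-trivial
  idx <- which(mask)
  jit <- stats::runif(length(idx), -18, 18)
  img[, , 1][idx] <- pmin(pmax(62 + jit, 0), 255)
  img[, , 2][idx] <- pmin(pmax(150 + jit, 0), 255)
  img[, , 3][idx] <- pmin(pmax(58 + jit, 0), 255)
  rows <- which(rowSums(mask) > 0)
  structure(list(image = rgb_image(img), mask = plant_mask(mask),
                 area_px = sum(mask),
                 height_px = max(rows) - min(rows) + 1L,
                 leaf_count = n_leaves, leaf_areas_px = leaf_areas,
                 stem_area_px = stem_area, seed = seed),
            class = "plant_scene_truth")
}

# rasterize a rotated ellipse: pixel centres strictly inside
ellipse_pixels <- function(cr, cc, a, b, theta, H, W) {
  ext <- ceiling(max(a, b)) + 1L
  rr <- max(1L, floor(cr - ext)):min(H, ceiling(cr + ext))
  cc2 <- max(1L, floor(cc - ext)):min(W, ceiling(cc + ext))
  gr <- rep(rr, times = length(cc2))
  gc <- rep(cc2, each = length(rr))
  dx <- gc - cc; dy <- gr - cr
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 < 1
  cbind(r = gr[keep], c = gc[keep])
}

#' Render a synthetic grain scatter scene
#'
#' Places `n` bright elliptical grains on a dark background by rejection
#' sampling.  A `touching_fraction` of the grains are laid down as
#' edge-adjacent pairs (masks touch but do not overlap), emulating grains
#' the feeder failed to separate.  Deterministic for a given seed.
#'
#' @param n Number of grains.
#' @param axis_ranges List with `major` and `minor` semi-axis ranges (px).
#' @param touching_fraction Fraction of grains placed in touching pairs
#'   (rounded down to an even count).
#' @param seed Integer seed.
#' @param canvas `c(H, W)`; default sized to hold `n` grains sparsely.
#' @return `grain_scene_truth`: list with `image` (grey matrix), `count`,
#'   `grains` (data frame of centroid/semi-axes/orientation),
#'   `touching_pairs`.
#' @export
render_grains <- function(n = 40L, axis_ranges = list(major = c(26, 34),
                                                      minor = c(10, 13)),
                          touching_fraction = 0, seed = 1L, canvas = NULL) {
  stopifnot(n >= 0, touching_fraction >= 0, touching_fraction < 1)
  set.seed(seed)
  if (is.null(canvas)) {
    side <- ceiling(sqrt(max(n, 1) * 9000))
    canvas <- c(side, side)
  }
  H <- canvas[1]; W <- canvas[2]
  img <- matrix(25, H, W) + matrix(stats::runif(H * W, 0, 8), H, W)
  occupied <- matrix(FALSE, H, W)
  grains <- data.frame(r = numeric(0), c = numeric(0), a = numeric(0),
                       b = numeric(0), theta = numeric(0))
  n_pairs <- floor(n * touching_fraction / 2)
  n_single <- n - 2L * n_pairs
  margin <- max(axis_ranges$major) + 3

  draw_grain <- function(px) {
    img[px] <<- pmin(205 + stats::runif(nrow(px), -10, 10), 255)
    occupied[px] <<- TRUE
  }
  sep_ok <- function(px) {
    # require a 1-px clear ring so isolated grains never touch
    for (dr in -1:1) for (dc in -1:1) {
      rr <- px[, 1] + dr; cc <- px[, 2] + dc
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      if (any(occupied[cbind(rr[ok], cc[ok])])) return(FALSE)
    }
    TRUE
  }
  rand_axes <- function() c(stats::runif(1, axis_ranges$major[1],
                                         axis_ranges$major[2]),
                            stats::runif(1, axis_ranges$minor[1],
                                         axis_ranges$minor[2]))

  placed <- 0L; tries <- 0L
  while (placed < n_single) {
    if ((tries <- tries + 1L) > 4000L * max(n, 1))
      stop("canvas too small to place the requested grains")
    ax <- rand_axes(); th <- stats::runif(1, 0, pi)
    cr <- stats::runif(1, margin, H - margin)
    cc <- stats::runif(1, margin, W - margin)
    px <- ellipse_pixels(cr, cc, ax[1], ax[2], th, H, W)
    if (nrow(px) < 4L || !sep_ok(px)) next
    draw_grain(px)
    grains[nrow(grains) + 1L, ] <- c(cr, cc, ax[1], ax[2], th)
    placed <- placed + 1L
  }
  pairs_placed <- 0L
  while (pairs_placed < n_pairs) {
    if ((tries <- tries + 1L) > 8000L * max(n, 1))
      stop("canvas too small to place the requested touching pairs")
    ax1 <- rand_axes(); ax2 <- rand_axes()
    th <- stats::runif(1, 0, pi)
    cr <- stats::runif(1, margin * 1.5, H - margin * 1.5)
    cc <- stats::runif(1, margin * 1.5, W - margin * 1.5)
    px1 <- ellipse_pixels(cr, cc, ax1[1], ax1[2], th, H, W)
    if (nrow(px1) < 4L || !sep_ok(px1)) next
    # slide the partner outward along the major axis from an overlapping
    # start; accept the first non-overlapping position if it is 8-adjacent
    dir <- c(sin(th), cos(th))            # (dr, dc) unit along major axis
    key1 <- (px1[, 2] - 1) * H + px1[, 1]
    adj8 <- function(pxm) {
      for (dr in -1:1) for (dc in -1:1) {
        if (any(((pxm[, 2] + dc - 1) * H + pxm[, 1] + dr) %in% key1))
          return(TRUE)
      }
      FALSE
    }
    found <- FALSE; px2 <- NULL; cr2 <- cc2 <- NA
    for (gap in seq(floor(0.8 * (ax1[1] + ax2[1])),
                    ceiling(ax1[1] + ax2[1]) + 3)) {
      cr2 <- cr + dir[1] * gap; cc2 <- cc + dir[2] * gap
      if (cr2 < margin || cr2 > H - margin ||
          cc2 < margin || cc2 > W - margin) break
      cand <- ellipse_pixels(cr2, cc2, ax2[1], ax2[2], th, H, W)
      if (nrow(cand) < 4L) break
      if (any(((cand[, 2] - 1) * H + cand[, 1]) %in% key1)) next  # overlap
      if (adj8(cand)) { found <- TRUE; px2 <- cand }
      break                                # first non-overlapping position
    }
    if (!found) next
    # the partner may touch px1 but nothing previously placed
    ok2 <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- px2[, 1] + dr; cc3 <- px2[, 2] + dc
      okb <- rr >= 1 & rr <= H & cc3 >= 1 & cc3 <= W
      if (any(occupied[cbind(rr[okb], cc3[okb])])) ok2 <- FALSE
    }
    if (!ok2) next
    draw_grain(px1); draw_grain(px2)
    grains[nrow(grains) + 1L, ] <- c(cr, cc, ax1[1], ax1[2], th)
    grains[nrow(grains) + 1L, ] <- c(cr2, cc2, ax2[1], ax2[2], th)
    pairs_placed <- pairs_placed + 1L
  }
  structure(list(image = img, count = nrow(grains), grains = grains,
                 touching_pairs = n_pairs, seed = seed),
            class = "grain_scene_truth")
}
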