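# Grain counting and grain-shape measurement (yield-traits scorer).
#
# Scenes are bright grains on a dark belt; foreground comes from an Otsu
# threshold, debris is removed by a minimum-area filter, and components
# much larger than the typical grain (possible touching grains) are
# re-split by a distance-transform watershed.

# Euclidean distance of each foreground pixel to the nearest background
# pixel adjacent to the component (includes hole boundaries).
region_distance_transform <- function(r, co, H, W) {
  bits <- matrix(FALSE, H, W)
  bits[cbind(r, co)] <- TRUE
  ring <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- co + dc
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    ring[cbind(rr[ok], cc[ok])] <- TRUE
  }
  # pixels off the canvas edge also bound the region
  ring <- ring & !bits
  br <- row(ring)[ring]; bc <- col(ring)[ring]
  edge_r <- pmin(r - 0, H + 1 - r)   # distance to canvas border + 1
  edge_c <- pmin(co - 0, W + 1 - co)
  if (length(br) == 0L) return(pmin(edge_r, edge_c))
  d2 <- outer(r, br, function(a, b) (a - b)^2) +
    outer(co, bc, function(a, b) (a - b)^2)
  pmin(sqrt(apply(d2, 1, min)), edge_r, edge_c)
}

# Split one connected component into k watershed basins seeded at distance
# maxima.  Returns a list of pixel-index subsets (possibly length 1).
watershed_split <- function(r, co, merge_radius) {
  H <- max(r) + 1L; W <- max(co) + 1L
  dt <- region_distance_transform(r, co, H, W)
  n <- length(r)
  key <- (co - 1L) * H + r
  pos <- integer(H * W); pos[key] <- seq_len(n)
  # 8-neighbour local maxima of the distance transform
  nb_off <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  is_max <- rep(TRUE, n)
  for (o in nb_off) {
    p <- pos[pmax(pmin(key + o, H * W), 1L)]
    has <- p > 0L
    is_max[has] <- is_max[has] & dt[has] >= dt[p[has]]
  }
  cand <- which(is_max & dt >= 0.45 * max(dt))
  if (length(cand) < 2L) return(list(seq_len(n)))
  # merge candidate maxima closer than merge_radius; one marker per group
  d <- as.matrix(dist(cbind(r[cand], co[cand])))
  g <- igraph::graph_from_adjacency_matrix(d < merge_radius, mode = "undirected")
  grp <- igraph::components(g)$membership
  if (max(grp) < 2L) return(list(seq_len(n)))
  label <- integer(n)
  for (k in seq_len(max(grp))) {
    members <- cand[grp == k]
    label[members[which.max(dt[members])]] <- k
  }
  # ordered flood: descending distance, attach to an already-labelled
  # neighbour (the one with the deepest distance)
  ord <- order(-dt)
  repeat {
    changed <- FALSE
    for (i in ord) {
      if (label[i] > 0L) next
      best <- 0L; bestd <- -1
      for (o in nb_off) {
        kk <- key[i] + o
        if (kk < 1L || kk > H * W) next
        p <- pos[kk]
        if (p > 0L && label[p] > 0L && dt[p] > bestd) {
          bestd <- dt[p]; best <- label[p]
        }
      }
      if (best > 0L) { label[i] <- best; changed <- TRUE }
    }
    if (all(label > 0L) || !changed) break
  }
  label[label == 0L] <- 1L
  split(seq_len(n), label)
}

#' Segment grains in a scatter image
#'
#' Otsu-thresholds a bright-on-dark grain image, removes components below
#' `min_area_px`, and optionally re-splits components larger than 1.6x the
#' median accepted area with a distance-transform watershed.
#'
#' @param image Grey matrix or [rgb_image()].
#' @param min_area_px Minimum region area kept (debris filter).
#' @param split_touching Attempt watershed splitting of oversized regions.
#' @param split_factor Area multiple of the median that triggers a split.
#' @param min_contrast Minimum grey dynamic range for the scene to be
#'   considered non-empty; below it Otsu would split background noise.
#' @return Object of class `grain_regions`: list with `labels` (integer
#'   matrix) and `regions` (list of pixel-index matrices `cbind(r, c)`).
#' @export
segment_grains <- function(image, min_area_px = 40L, split_touching = TRUE,
                           split_factor = 1.6, min_contrast = 50) {
  grey <- to_grey(image)
  H <- nrow(grey); W <- ncol(grey)
  empty <- function() structure(list(labels = matrix(0L, H, W),
                                     regions = list()),
                                class = "grain_regions")
  if (max(grey) - min(grey) < min_contrast) return(empty())
  q <- floor(grey)                      # threshold on the histogram bins
  thr <- otsu_threshold(q)
  fg <- q > thr
  if (!any(fg)) return(empty())
  cc <- label_components(fg, connectivity = 8L)
  keep <- which(cc$sizes >= min_area_px)
  if (length(keep) == 0L) return(empty())
  idx_by_lab <- split(which(cc$labels %in% keep),
                      cc$labels[cc$labels %in% keep])
  regions <- lapply(idx_by_lab, function(idx)
    cbind(r = ((idx - 1L) %% H) + 1L, c = ((idx - 1L) %/% H) + 1L))
  if (split_touching && length(regions) >= 2L) {
    areas <- vapply(regions, nrow, 0L)
    med <- stats::median(areas)
    merge_radius <- 0.9 * sqrt(med / pi)
    out <- list()
    for (reg in regions) {
      if (nrow(reg) > split_factor * med) {
        parts <- watershed_split(reg[, 1], reg[, 2], merge_radius)
        for (p in parts) out[[length(out) + 1L]] <- reg[p, , drop = FALSE]
      } else out[[length(out) + 1L]] <- reg
    }
    regions <- out
  }
  labels <- matrix(0L, H, W)
  for (i in seq_along(regions)) labels[regions[[i]]] <- i
  structure(list(labels = labels, regions = regions), class = "grain_regions")
}

#' Count accepted grain regions
#'
#' @param regions A `grain_regions` object from [segment_grains()].
#' @return Integer count.
#' @export
count_grains <- function(regions) {
  length(regions$regions)
}

# Minimum-area rotated bounding rectangle over pixel centres.  Each side
# extent is the centre-projection span plus half the lattice gap observed
# at either extreme (capped at half a pixel): for grid-aligned sides the
# gap is 1 so the extent is span + 1, exact for rectangles; for oblique
# sides the staircase extremes already hug the continuous boundary and
# the measured gap shrinks the correction, keeping rotation bias under
# ~2% on rasterized ellipses.  Returns c(long, short) in pixels.
min_area_rect <- function(r, co) {
  h <- grDevices::chull(co, r)
  hx <- co[h]; hy <- r[h]
  n <- length(hx)
  j <- c(2:n, 1)
  ex <- hx[j] - hx; ey <- hy[j] - hy
  len <- sqrt(ex^2 + ey^2)
  proj_span <- function(p) {
    u <- sort(unique(round(p, 8)))
    k <- length(u)
    g_hi <- if (k > 1) u[k] - u[k - 1] else 1
    g_lo <- if (k > 1) u[2] - u[1] else 1
    (u[k] - u[1]) + min(g_hi, 1) / 2 + min(g_lo, 1) / 2
  }
  best <- c(Inf, NA, NA)
  for (e in which(len > 0)) {
    ux <- ex[e] / len[e]; uy <- ey[e] / len[e]
    # project all pixels (not only hull vertices): the gap correction
    # needs the second-extreme lattice values
    p1 <- co * ux + r * uy
    p2 <- -co * uy + r * ux
    w1 <- proj_span(p1); w2 <- proj_span(p2)
    if (w1 * w2 < best[1]) best <- c(w1 * w2, w1, w2)
  }
  sort(best[2:3], decreasing = TRUE)
}

#' Shape metrics of one grain region
#'
#' Length and width are the long and short sides of the minimum-area
#' rotated bounding rectangle (over pixel corners), scaled by the
#' calibration; projected area is the pixel count times `mm_per_px^2`.
#'
#' @param region Two-column matrix `cbind(r, c)` of pixel coordinates.
#' @param cal A [calibration()].
#' @return List of class `grain_region` with `area_px`, `length_mm`,
#'   `width_mm`, `lw_ratio`, `projected_area_mm2`, `centroid`, and a
#'   `degenerate` flag for 1-px-wide slivers.
#' @export
grain_shape_metrics <- function(region, cal) {
  if (nrow(region) < 4L) stop("region area must be >= 4 px")
  sides <- min_area_rect(region[, 1], region[, 2])
  degenerate <- sides[2] <= 1
  structure(list(
    area_px = nrow(region),
    length_mm = sides[1] * cal$mm_per_px,
    width_mm = sides[2] * cal$mm_per_px,
    lw_ratio = sides[1] / sides[2],
    projected_area_mm2 = nrow(region) * cal$mm_per_px^2,
    centroid = c(r = mean(region[, 1]), c = mean(region[, 2])),
    degenerate = degenerate), class = "grain_region")
}

#' Derive yield traits from batch counts and filled-grain weight
#'
#' Spikelet fertility = filled / total; yield per plant = the weighed
#' filled-grain mass; 1,000-grain weight = `1000 * weight / filled`.
#'
#' @param total Total spikelet count (>= filled).
#' @param filled Filled spikelet count.
#' @param filled_weight_g Mass of the filled spikelets in grams.
#' @param per_grain Optional list of [grain_shape_metrics()] results.
#' @return List of class `grain_batch_result` with `fertility`,
#'   `yield_per_plant_g`, `tgw_g` (NA with `tgw_undefined = TRUE` when
#'   `filled == 0`) and the inputs echoed.
#' @export
derive_yield_traits <- function(total, filled, filled_weight_g,
                                per_grain = list()) {
  if (filled > total) stop("filled spikelets cannot exceed total")
  if (filled < 0 || total < 0 || filled_weight_g < 0)
    stop("counts and weight must be non-negative")
  fert_flag <- total == 0
  structure(list(
    total_spikelets = as.integer(total),
    filled_spikelets = as.integer(filled),
    fertility = if (total > 0) filled / total else 0,
    fertility_undefined = fert_flag,
    filled_weight_g = filled_weight_g,
    yield_per_plant_g = filled_weight_g,
    tgw_g = if (filled > 0) 1000 * filled_weight_g / filled else NA_real_,
    tgw_undefined = filled == 0,
    per_grain = per_grain), class = "grain_batch_result")
}

#' Score a grain batch from two images
#'
#' Mirrors the two-conveyor design: one image of all spikelets (count
#' only) and one of the filled spikelets (count + shape), plus the weighed
#' filled-grain mass.
#'
#' @param total_image,filled_image Grain scatter images.
#' @param filled_weight_g Filled-grain mass in grams.
#' @param cal A [calibration()].
#' @param ... Passed to [segment_grains()].
#' @return A `grain_batch_result` with per-grain shape metrics from the
#'   filled image.
#' @export
score_grain_batch <- function(total_image, filled_image, filled_weight_g,
                              cal, ...) {
  tot <- count_grains(segment_grains(total_image, ...))
  seg_f <- segment_grains(filled_image, ...)
  fil <- count_grains(seg_f)
  per <- lapply(seg_f$regions[vapply(seg_f$regions, nrow, 0L) >= 4L],
                grain_shape_metrics, cal = cal)
  derive_yield_traits(tot, fil, filled_weight_g, per_grain = per)
}

#' Per-grain table from a batch result
#'
#' @param batch A `grain_batch_result`.
#' @return Data frame with one row per measured grain.
#' @export
grain_table <- function(batch) {
  if (length(batch$per_grain) == 0L)
    return(data.frame(area_px = integer(), length_mm = numeric(),
                      width_mm = numeric(), lw_ratio = numeric(),
                      projected_area_mm2 = numeric()))
  do.call(rbind, lapply(batch$per_grain, function(g)
    data.frame(area_px = g$area_px, length_mm = g$length_mm,
               width_mm = g$width_mm, lw_ratio = g$lw_ratio,
               projected_area_mm2 = g$projected_area_mm2)))
}
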