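# Core raster containers and small image utilities.
#
# Images are plain R arrays: an RGB image is an H x W x 3 numeric array of
# 8-bit intensities (row 1 = top of the image), a grey image is an H x W
# matrix, and a mask is an H x W logical matrix.  Keeping the containers
# base-R makes every downstream operator testable without an image stack.

#' Construct an RGB image
#'
#' Wraps an `H x W x 3` array of 8-bit intensities (values in `[0, 255]`,
#' row 1 is the top of the image) after validating its shape and value
#' range.
#'
#' @param pixels Numeric array of dimension `H x W x 3`.
#' @return An object of class `rgb_image` (the validated array).
#' @export
rgb_image <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (d[1] < 8L || d[2] < 8L)
    stop("image must be at least 8 x 8 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  structure(pixels, class = "rgb_image")
}

#' @export
dim.rgb_image <- function(x) dim(unclass(x))

#' Construct a plant mask
#'
#' A binary foreground raster tied to the dimensions of its source image.
#'
#' @param bits Logical matrix (`TRUE` = foreground).
#' @return An object of class `plant_mask`.
#' @export
plant_mask <- function(bits) {
  if (!is.matrix(bits)) stop("`bits` must be a matrix")
  storage.mode(bits) <- "logical"
  if (anyNA(bits)) stop("mask may not contain NA")
  structure(bits, class = "plant_mask")
}

#' Length calibration
#'
#' @param mm_per_px Millimetres per pixel; must be positive.
#' @return An object of class `calibration`.
#' @export
calibration <- function(mm_per_px) {
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L || mm_per_px <= 0)
    stop("`mm_per_px` must be a single positive number")
  structure(list(mm_per_px = as.numeric(mm_per_px)), class = "calibration")
}

# Luma-style grey conversion used for texture; plain channel mean keeps the
# constant-region invariants exact.
to_grey <- function(image) {
  a <- unclass(image)
  if (length(dim(a)) == 2L) return(a)
  (a[, , 1] + a[, , 2] + a[, , 3]) / 3
}

#' Otsu threshold of a grey image
#'
#' Maximises between-class variance over the 256-bin intensity histogram.
#' Returns the threshold `t` such that pixels with value `> t` fall in the
#' upper class.
#'
#' @param grey Numeric matrix of intensities in `[0, 255]`.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(grey) {
  v <- as.vector(grey)
  v <- v[is.finite(v)]
  h <- tabulate(pmin(pmax(floor(v), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  which.max(sigma_b) - 1L  # threshold level; foreground is strictly above
}

# Connected-component labelling of a logical matrix via a pixel adjacency
# graph (igraph does the union-find).  Returns an integer matrix with 0 for
# background and labels 1..k, plus component sizes.
label_components <- function(bits, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  H <- nrow(bits); W <- ncol(bits)
  idx <- which(bits)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0L)
    return(list(labels = lab, sizes = integer(0)))
  pos <- matrix(0L, H, W)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  co <- ((idx - 1L) %/% H) + 1L
  edge_pairs <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= H & co + dc >= 1L & co + dc <= W
    from <- idx[ok]
    to <- (co[ok] + dc - 1L) * H + (r[ok] + dr)
    keep <- bits[to]
    cbind(pos[from[keep]], pos[to[keep]])
  }
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  ed <- do.call(rbind, lapply(shifts, function(s) edge_pairs(s[1], s[2])))
  g <- igraph::graph_from_edgelist(
    rbind(ed, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  list(labels = lab, sizes = as.integer(comp$csize))
}

# ---- plain-text portable anymap I/O (P2/P3) ---------------------------------
# PNG/TIFF decoding is unavailable in this toolchain, so images travel as
# text PGM/PPM; any converter can turn PNG into these losslessly.

#' Write an image as a plain-text portable pixmap/greymap
#'
#' RGB images are written as ASCII PPM (`P3`), grey matrices and masks as
#' ASCII PGM (`P2`).  The format is lossless for 8-bit data.
#'
#' @param image `rgb_image`, grey matrix, or `plant_mask`.
#' @param path Output file path (conventionally `.ppm` / `.pgm`).
#' @export
write_pnm <- function(image, path) {
  if (inherits(image, "plant_mask")) {
    m <- matrix(as.integer(unclass(image)) * 255L, nrow(image), ncol(image))
    return(write_pnm(m, path))
  }
  a <- unclass(image)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(dim(a)) == 2L) {
    writeLines(c("P2", paste(ncol(a), nrow(a)), "255"), con)
    write(t(round(a)), con, ncolumns = ncol(a))
  } else {
    writeLines(c("P3", paste(dim(a)[2], dim(a)[1]), "255"), con)
    # interleave channels pixel by pixel, row-major
    flat <- aperm(round(a), c(3, 2, 1))
    write(as.integer(flat), con, ncolumns = 12L)
  }
  invisible(path)
}

#' Read a plain-text portable pixmap/greymap
#'
#' @param path A `P2` (grey) or `P3` (RGB) file written by [write_pnm()] or
#'   any standard converter.
#' @return An `rgb_image` for P3, a grey matrix for P2.
#' @export
read_pnm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  magic <- toks[1]
  if (!magic %in% c("P2", "P3")) stop("only ASCII P2/P3 PNM is supported")
  W <- as.integer(toks[2]); H <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (magic == "P2") {
    m <- matrix(vals, nrow = H, ncol = W, byrow = TRUE)
    return(m)
  }
  flat <- array(vals, dim = c(3, W, H))
  rgb_image(aperm(flat, c(3, 2, 1)))
}
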