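# Grey-level co-occurrence texture statistics inside a mask.

#' Grey-level co-occurrence matrix
#'
#' Quantizes the grey intensities of the masked region into `levels` equal
#' bins over `[0, 255]`, accumulates co-occurrences of pixel pairs at the
#' given offset where both ends lie inside the mask, symmetrizes and
#' normalizes to sum 1.
#'
#' @param grey Numeric intensity matrix.
#' @param bits Logical mask of the same dimensions.
#' @param levels Number of grey levels (>= 2).
#' @param offset Integer `c(dy, dx)` displacement.
#' @return `levels x levels` matrix summing to 1, or `NULL` when no valid
#'   pair exists at this offset.
#' @export
glcm <- function(grey, bits, levels = 32L, offset = c(0L, 1L)) {
  q <- pmin(floor(grey / 256 * levels), levels - 1L)  # 0-based level index
  H <- nrow(grey); W <- ncol(grey)
  dr <- offset[1]; dc <- offset[2]
  rs <- max(1, 1 - dr):min(H, H - dr)
  cs <- max(1, 1 - dc):min(W, W - dc)
  if (length(rs) == 0L || length(cs) == 0L) return(NULL)
  a_bits <- bits[rs, cs, drop = FALSE]
  b_bits <- bits[rs + dr, cs + dc, drop = FALSE]
  ok <- a_bits & b_bits
  if (!any(ok)) return(NULL)
  ia <- q[rs, cs, drop = FALSE][ok]
  ib <- q[rs + dr, cs + dc, drop = FALSE][ok]
  counts <- tabulate(ia * levels + ib + 1L, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)                       # symmetric
  P / sum(P)
}

#' Frozen catalogue of the 7 texture descriptor names
#' @export
texture_feature_names <- c(
  "glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity", "glcm_energy",
  "glcm_correlation", "glcm_entropy", "glcm_variance")

glcm_stats <- function(P) {
  L <- nrow(P)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  d <- i - j
  mu_i <- sum(i * P)
  mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P)
  var_j <- sum((j - mu_j)^2 * P)
  corr <- if (var_i > 0 && var_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j) else 1
  pz <- P[P > 0]
  c(glcm_contrast = sum(d^2 * P),
    glcm_dissimilarity = sum(abs(d) * P),
    glcm_homogeneity = sum(P / (1 + d^2)),
    glcm_energy = sum(P^2),
    glcm_correlation = corr,
    glcm_entropy = -sum(pz * log(pz)),
    glcm_variance = var_i)
}

#' Texture features of the masked plant region
#'
#' Computes one normalized symmetric GLCM per offset (default: the four
#' directions at distance 1) and averages the seven Haralick-style
#' statistics over offsets.  A constant-intensity region gives
#' contrast = 0, entropy = 0 and energy = 1.
#'
#' @param image An [rgb_image()] (or grey matrix).
#' @param mask A [plant_mask()].
#' @param levels Grey quantization levels, default 32.
#' @param offsets List of `c(dy, dx)` offsets; default the four unit
#'   directions.
#' @return Named numeric vector of length 7 (`texture_feature_names`).
#' @export
texture_features <- function(image, mask, levels = 32L,
                             offsets = list(c(0L, 1L), c(1L, 0L),
                                            c(1L, 1L), c(1L, -1L))) {
  if (levels < 2L) stop("`levels` must be >= 2")
  bits <- unclass(mask)
  if (sum(bits) < 2L) stop("masked region smaller than 2 px")
  grey <- to_grey(image)
  if (!all(dim(grey) == dim(bits))) stop("mask/image dimension mismatch")
  mats <- Filter(Negate(is.null),
                 lapply(offsets, function(o) glcm(grey, bits, levels, o)))
  if (length(mats) == 0L) stop("no co-occurring pixel pair in the mask")
  stats <- vapply(mats, glcm_stats, numeric(7))
  out <- rowMeans(stats)
  names(out) <- texture_feature_names
  out
}
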