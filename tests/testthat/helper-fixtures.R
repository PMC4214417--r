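# Shared fixture builders (all generated in code, no stored data).

# filled disc mask of radius r centred in a square canvas
disc_mask <- function(r, pad = 11L) {
  side <- 2L * r + 2L * pad + 1L
  ctr <- pad + r + 1L
  g <- expand.grid(rr = seq_len(side), cc = seq_len(side))
  plant_mask(matrix((g$rr - ctr)^2 + (g$cc - ctr)^2 <= r^2, side, side))
}

# plus/cross polyomino: 3-wide arms on a 15x15 canvas, arm span 11
plus_mask <- function() {
  m <- matrix(FALSE, 15, 15)
  m[7:9, 3:13] <- TRUE
  m[3:13, 7:9] <- TRUE
  plant_mask(m)
}

# Sylvester Hadamard matrix of order 2^k
hadamard <- function(k) {
  h <- matrix(1, 1, 1)
  for (i in seq_len(k)) h <- rbind(cbind(h, h), cbind(h, -h))
  h
}

# exactly orthogonal 0/2 dosage fixture: n = 2^k rows, m columns
orthogonal_genotypes <- function(k = 5L, m = 20L) {
  h <- hadamard(k)
  stopifnot(m <= ncol(h) - 1)
  genotype_matrix(h[, 2:(m + 1)] + 1)
}

# flat RGB image of a single colour
flat_image <- function(H, W, rgb) {
  a <- array(0, c(H, W, 3))
  for (ch in 1:3) a[, , ch] <- rgb[ch]
  rgb_image(a)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
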