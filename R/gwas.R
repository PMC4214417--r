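# Mixed-model association chain: MAF/MAC filter -> identity-proportion
# kinship -> spectral LMM likelihood-ratio scan -> effective-marker
# Bonferroni thresholds -> LD-r2 clumping and optional peak filtering.
#
# The LMM is y = mu + x b + g + e with g ~ N(0, sg2 K), e ~ N(0, se2 I).
# K is eigendecomposed once; with delta = se2/sg2 the covariance is
# sg2 (K + delta I), so after rotation by the eigenvectors every fit is a
# weighted least squares with weights 1/(lambda_i + delta).  Maximum
# likelihood (not REML) is used throughout so likelihood-ratio tests are
# valid; p-values come from chi-squared with 1 df.

#' Construct a genotype matrix
#'
#' @param dosages `n x m` matrix of dosages in `{0, 1, 2, NA}`; rows are
#'   accessions, columns SNPs.
#' @param chrom Chromosome per SNP.
#' @param pos 1-based position per SNP (strictly increasing within a
#'   chromosome).
#' @param ref,alt Alleles per SNP (defaults `"A"`/`"T"`).
#' @param ids Accession identifiers.
#' @return `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, chrom = rep(1L, ncol(dosages)),
                            pos = seq_len(ncol(dosages)),
                            ref = NULL, alt = NULL, ids = NULL) {
  dosages <- as.matrix(dosages)
  if (!all(dosages %in% c(0, 1, 2) | is.na(dosages)))
    stop("dosages must be 0, 1, 2 or NA")
  m <- ncol(dosages)
  stopifnot(length(chrom) == m, length(pos) == m)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within a chromosome")
  }
  if (is.null(ids)) ids <- paste0("acc", seq_len(nrow(dosages)))
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  if (is.null(colnames(dosages)) && m > 0)
    colnames(dosages) <- paste0(chrom, "_", pos)
  rownames(dosages) <- ids
  structure(list(dosages = dosages, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, ids = ids), class = "genotype_matrix")
}

#' Number of accessions / SNPs
#' @param x A `genotype_matrix`.
#' @return Integer `c(n, m)`.
#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

subset_snps <- function(G, keep) {
  genotype_matrix(G$dosages[, keep, drop = FALSE], G$chrom[keep],
                  G$pos[keep], G$ref[keep], G$alt[keep], G$ids)
}

#' Minor-allele frequency and carrier-count filter
#'
#' Retains SNPs with MAF >= `maf_min` (computed over non-missing calls)
#' AND at least `mac_accessions_min` accessions carrying one or more
#' copies of the minor allele.
#'
#' @param G A [genotype_matrix()].
#' @param maf_min MAF cut, default 0.05.
#' @param mac_accessions_min Minimum minor-allele carriers, default 6.
#' @return Filtered `genotype_matrix`.
#' @export
maf_filter <- function(G, maf_min = 0.05, mac_accessions_min = 6L) {
  D <- G$dosages
  nn <- colSums(!is.na(D))
  af <- colSums(D, na.rm = TRUE) / (2 * nn)
  maf <- pmin(af, 1 - af)
  minor_is_alt <- af <= 0.5
  carriers <- ifelse(minor_is_alt, colSums(D > 0, na.rm = TRUE),
                     colSums(D < 2, na.rm = TRUE))
  keep <- which(nn > 0 & maf >= maf_min & carriers >= mac_accessions_min)
  if (length(keep) == 0L) warning("all SNPs removed by the MAF/MAC filter")
  subset_snps(G, keep)
}

#' Identity-proportion kinship
#'
#' `K[i, j]` is the fraction of an evenly distributed SNP subset at which
#' accessions i and j carry identical non-missing genotype calls.  The
#' subset takes `subset_size` indices on an even stride with a seeded
#' random phase.  Because identity proportions need not form a PSD
#' matrix, a PSD repair (eigenvalue clipping at 0 followed by rescaling
#' back to unit diagonal) is applied for mixed-model use; the raw matrix
#' is retained.
#'
#' @param G A [genotype_matrix()].
#' @param subset_size Number of SNPs used (clamped to m).
#' @param seed Seed for the random phase.
#' @return `kinship_matrix`: list with `K` (PSD-repaired), `raw`,
#'   `subset_size`, `repaired` flag.
#' @export
kinship_identity_proportion <- function(G, subset_size = ncol(G$dosages),
                                        seed = 1L) {
  D <- G$dosages
  m <- ncol(D)
  k <- min(subset_size, m)
  idx <- local({
    set.seed(seed)
    stride <- m / k
    phase <- stats::runif(1, 0, stride)
    unique(pmin(m, pmax(1L, floor(phase + stride * (0:(k - 1))) + 1L)))
  })
  X <- D[, idx, drop = FALSE]
  obs <- !is.na(X)
  denom <- tcrossprod(obs * 1)
  if (any(denom == 0))
    stop("a pair of accessions has no overlapping non-missing SNPs")
  M <- matrix(0, nrow(X), nrow(X))
  for (g in c(0, 1, 2)) {
    A <- (X == g) & obs
    M <- M + tcrossprod(A * 1)
  }
  raw <- M / denom
  ev <- eigen(raw, symmetric = TRUE)
  repaired <- any(ev$values < -1e-10)
  if (repaired) {
    warning("identity-proportion kinship was not PSD; eigenvalues clipped")
    vals <- pmax(ev$values, 0)
    K <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(pmax(diag(K), .Machine$double.eps))
    K <- K / tcrossprod(d)
  } else K <- raw
  dimnames(K) <- dimnames(raw) <- list(G$ids, G$ids)
  structure(list(K = K, raw = raw, subset_size = length(idx),
                 repaired = repaired), class = "kinship_matrix")
}

#' Phenotype outlier removal
#'
#' Single-pass rule: values farther than `z_max` standard deviations from
#' the mean are dropped (a documented stand-in for the usual pre-GWAS
#' outlier cleaning).  A zero-SD vector is returned unchanged.
#'
#' @param y Named numeric vector (names = accession ids); NAs allowed.
#' @param z_max SD multiple, default 3.
#' @return Numeric vector of retained values with attribute `dropped`
#'   (names of removed accessions).
#' @export
phenotype_preprocess <- function(y, z_max = 3.0) {
  obs <- y[!is.na(y)]
  if (length(obs) < 10L) stop("need at least 10 non-missing values")
  s <- stats::sd(obs)
  if (s == 0) { attr(obs, "dropped") <- character(0); return(obs) }
  bad <- abs(obs - mean(obs)) > z_max * s
  out <- obs[!bad]
  attr(out, "dropped") <- names(obs)[bad]
  out
}

wls_fit <- function(yt, Xt, w) {
  XtW <- Xt * w
  XX <- crossprod(Xt, XtW)
  Xy <- crossprod(XtW, yt)
  beta <- solve(XX, Xy)
  r <- yt - Xt %*% beta
  list(beta = drop(beta), rss = sum(w * drop(r)^2))
}

loglik_at_delta <- function(delta, yt, Xt, lam) {
  w <- 1 / (lam + delta)
  fit <- wls_fit(yt, Xt, w)
  n <- length(yt)
  list(ll = -0.5 * (n * log(2 * pi * fit$rss / n) + n + sum(log(lam + delta))),
       beta = fit$beta, rss = fit$rss)
}

optimize_delta <- function(yt, Xt, lam, grid_points = 100L) {
  lg <- seq(-5, 5, length.out = grid_points) * log(10)
  ll <- vapply(lg, function(l) loglik_at_delta(exp(l), yt, Xt, lam)$ll, 0)
  i <- which.max(ll)
  lo <- lg[max(1L, i - 1L)]; hi <- lg[min(length(lg), i + 1L)]
  opt <- stats::optimize(function(l) loglik_at_delta(exp(l), yt, Xt, lam)$ll,
                         c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  c(loglik_at_delta(delta, yt, Xt, lam), delta = delta)
}

#' Spectral linear mixed-model association scan
#'
#' Fits `y = mu + x b + g + e`, `g ~ N(0, sg2 K)`, `e ~ N(0, se2 I)` by
#' maximum likelihood after one eigendecomposition of K, and tests each
#' SNP with a likelihood-ratio statistic against chi-squared(1).  Under
#' the default `null_delta` mode the variance ratio `delta = se2/sg2` is
#' estimated once under the no-SNP null (grid over `log10 delta` in
#' `[-5, 5]` plus local refinement) and held fixed per SNP;
#' `per_snp_delta` re-optimizes delta for every alternative model.
#' Missing dosages are mean-imputed in the design column; monomorphic
#' SNPs get `p = NA`.
#'
#' @param G A [genotype_matrix()].
#' @param y Phenotype vector named by accession id (or aligned to
#'   `G$ids`).
#' @param K A [kinship_identity_proportion()] result, or an `n x n`
#'   matrix.
#' @param mode `"null_delta"` (default) or `"per_snp_delta"`.
#' @return `association_result`: data frame (`snp`, `chrom`, `pos`,
#'   `beta`, `lr`, `p`) with null-model variance components as
#'   attributes.
#' @export
lmm_scan <- function(G, y, K, mode = c("null_delta", "per_snp_delta")) {
  mode <- match.arg(mode)
  Km <- if (inherits(K, "kinship_matrix")) K$K else as.matrix(K)
  if (!is.null(names(y))) {
    common <- intersect(G$ids, names(y))
    ix <- match(common, G$ids)
    y <- y[common]
    D <- G$dosages[ix, , drop = FALSE]
    Km <- Km[ix, ix]
  } else D <- G$dosages
  n <- length(y)
  if (n < 30L) stop("need at least 30 accessions")
  ev <- eigen(Km, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    warning("kinship not PSD; clipping eigenvalues for the scan")
    ev$values <- pmax(ev$values, 0)
  }
  U <- ev$vectors
  lam <- pmax(ev$values, 0)
  yt <- drop(crossprod(U, y))
  ones_t <- drop(crossprod(U, rep(1, n)))
  null <- optimize_delta(yt, ones_t, lam)
  delta0 <- null$delta
  ll0 <- null$ll
  sg2 <- null$rss / n

  # rotate all SNP columns at once (mean-imputed)
  Dimp <- D
  if (anyNA(Dimp)) {
    mu <- colMeans(Dimp, na.rm = TRUE)
    nas <- which(is.na(Dimp), arr.ind = TRUE)
    Dimp[nas] <- mu[nas[, 2]]
  }
  mono <- apply(Dimp, 2, function(x) max(x) == min(x))
  Xt_all <- crossprod(U, Dimp)

  m <- ncol(D)
  beta <- lr <- pvec <- rep(NA_real_, m)
  if (mode == "null_delta") {
    w <- 1 / (lam + delta0)
    # FWL: residualize y and each SNP on the rotated intercept under w
    sw1 <- sum(w * ones_t^2)
    a_y <- sum(w * ones_t * yt) / sw1
    ry <- yt - ones_t * a_y
    rss0 <- sum(w * ry^2)
    a_x <- colSums(w * ones_t * Xt_all) / sw1
    RX <- Xt_all - outer(drop(ones_t), a_x)
    sxx <- colSums(w * RX^2)
    sxy <- colSums(w * RX * ry)
    ok <- !mono & sxx > 1e-12
    b <- sxy[ok] / sxx[ok]
    rss1 <- rss0 - sxy[ok]^2 / sxx[ok]
    beta[ok] <- b
    lr[ok] <- n * log(rss0 / rss1)
    pvec[ok] <- stats::pchisq(lr[ok], df = 1, lower.tail = FALSE)
  } else {
    for (j in seq_len(m)) {
      if (mono[j]) next
      Xt <- cbind(ones_t, Xt_all[, j])
      alt <- optimize_delta(yt, Xt, lam)
      beta[j] <- alt$beta[2]
      lr[j] <- max(0, 2 * (alt$ll - ll0))
      pvec[j] <- stats::pchisq(lr[j], df = 1, lower.tail = FALSE)
    }
  }
  lr <- pmax(lr, 0)
  res <- data.frame(snp = colnames(D), chrom = G$chrom, pos = G$pos,
                    beta = beta, lr = lr, p = pvec,
                    stringsAsFactors = FALSE)
  structure(res, delta = delta0, sigma_g2 = sg2,
            sigma_e2 = sg2 * delta0, loglik_null = ll0,
            class = c("association_result", "data.frame"))
}

#' Naive (no-kinship) regression scan
#'
#' Per-SNP ordinary regression likelihood-ratio tests, used as the
#' uncorrected baseline when demonstrating stratification control.
#'
#' @param G A [genotype_matrix()].
#' @param y Phenotype vector aligned to `G$ids`.
#' @return `association_result` data frame.
#' @export
ols_scan <- function(G, y) {
  lmm_scan(G, y, diag(length(y)), mode = "null_delta")
}

#' Genomic inflation factor
#'
#' Median observed association chi-squared over the null median.
#'
#' @param p Vector of p-values (NAs dropped).
#' @return `lambda_GC`.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Effective number of independent markers
#'
#' Block-wise eigenvalue estimator: per chromosome the SNPs are cut into
#' consecutive blocks of at most `block_size`; each block contributes
#' `sum(lambda >= 1) + sum(lambda - floor(lambda))` where `lambda` are the
#' eigenvalues of the block's SNP Pearson-correlation matrix; N is the sum
#' over blocks.  Mutually uncorrelated SNPs give N = m; a block of k
#' identical columns contributes exactly 1.
#'
#' @param G A [genotype_matrix()].
#' @param block_size Maximum SNPs per block, default 200.
#' @return Effective marker number N.
#' @export
effective_marker_number <- function(G, block_size = 200L) {
  D <- G$dosages
  if (ncol(D) < 2L) stop("need at least 2 SNPs")
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    nas <- which(is.na(D), arr.ind = TRUE)
    D[nas] <- mu[nas[, 2]]
  }
  sds <- apply(D, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant SNP columns excluded from the effective-marker count")
  }
  total <- 0
  for (ch in unique(G$chrom)) {
    cols <- which(G$chrom == ch & sds > 0)
    if (length(cols) == 0L) next
    starts <- seq(1L, length(cols), by = block_size)
    for (s in starts) {
      blk <- cols[s:min(s + block_size - 1L, length(cols))]
      if (length(blk) == 1L) { total <- total + 1; next }
      R <- stats::cor(D[, blk, drop = FALSE])
      lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      lam <- pmax(lam, 0)
      total <- total + sum(lam >= 1) + sum(lam - floor(lam))
    }
  }
  total
}

#' Suggestive and significant association thresholds
#'
#' `suggestive = 1/N`, `significant = alpha/N` for the effective marker
#' number N, so `significant = alpha * suggestive` exactly.
#'
#' @param effective_n Effective marker number (>= 1).
#' @param alpha Genome-wide type-1 error, default 0.05.
#' @return List with `suggestive`, `significant`, `effective_n`.
#' @export
significance_thresholds <- function(effective_n, alpha = 0.05) {
  if (effective_n < 1) stop("effective_n must be >= 1")
  suggestive <- 1 / effective_n
  list(suggestive = suggestive,
       significant = alpha * suggestive,   # = alpha/N, ratio exact
       effective_n = effective_n)
}

#' Haplotype-frequency LD r-squared
#'
#' Treats homozygous diploid calls of an inbred panel as observed
#' haplotypes: with allele frequencies `pA`, `pB` and haplotype frequency
#' `pAB`, `r2 = (pAB - pA pB)^2 / (pA (1-pA) pB (1-pB))`.  Heterozygous
#' or missing calls are excluded pairwise.
#'
#' @param x,z Dosage vectors in `{0, 1, 2, NA}`.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(x, z) {
  ok <- !is.na(x) & !is.na(z) & x != 1 & z != 1
  a <- x[ok] / 2; b <- z[ok] / 2
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic column after exclusions")
  pAB <- mean(a * b)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Greedy LD clumping of association results
#'
#' Repeatedly takes the unassigned SNP with smallest p-value below
#' `p_threshold` as a lead, and assigns to its clump every unassigned
#' passing SNP on the same chromosome within `window_kb` of the lead with
#' `r2 > r2_threshold`.
#'
#' @param results An `association_result`.
#' @param G The matching [genotype_matrix()].
#' @param p_threshold Inclusion p-value threshold.
#' @param r2_threshold LD cut, default 0.25.
#' @param window_kb Window half-width in kb, default 250.
#' @return List of `clumped_locus` entries (lead snp/chrom/pos/p, member
#'   data frame, span), sorted by lead p.
#' @export
clump_loci <- function(results, G, p_threshold, r2_threshold = 0.25,
                       window_kb = 250L) {
  pass <- which(!is.na(results$p) & results$p < p_threshold)
  loci <- list()
  assigned <- rep(FALSE, length(pass))
  ord <- order(results$p[pass])
  for (i in ord) {
    if (assigned[i]) next
    lead <- pass[i]
    assigned[i] <- TRUE
    cand <- which(!assigned &
                    results$chrom[pass] == results$chrom[lead] &
                    abs(results$pos[pass] - results$pos[lead]) <=
                      window_kb * 1000)
    members <- lead
    for (j in cand) {
      r2 <- tryCatch(ld_r2(G$dosages[, lead], G$dosages[, pass[j]]),
                     error = function(e) 0)
      if (r2 > r2_threshold) { assigned[j] <- TRUE
        members <- c(members, pass[j]) }
    }
    loci[[length(loci) + 1L]] <- structure(list(
      lead_snp = results$snp[lead], chrom = results$chrom[lead],
      pos = results$pos[lead], lead_p = results$p[lead],
      members = results[members, c("snp", "chrom", "pos", "p")],
      span = range(results$pos[members])), class = "clumped_locus")
  }
  loci[order(vapply(loci, `[[`, 0, "lead_p"))]
}

#' Filter clumped loci for peak-like support
#'
#' Keeps loci whose lead has at least `min_support` additional SNPs within
#' the window at `p < support_p` (default 100x the lead threshold), a
#' configurable stand-in for requiring "clear peak-like" association
#' signals.
#'
#' @param loci Output of [clump_loci()].
#' @param results The `association_result` the loci came from.
#' @param min_support Minimum supporting SNPs, default 2.
#' @param support_p Support p-value cut.
#' @param window_kb Window half-width in kb, default 250.
#' @return Filtered list of loci.
#' @export
peak_filter <- function(loci, results, min_support = 2L,
                        support_p, window_kb = 250L) {
  Filter(function(loc) {
    nearby <- !is.na(results$p) &
      results$chrom == loc$chrom &
      abs(results$pos - loc$pos) <= window_kb * 1000 &
      results$snp != loc$lead_snp &
      results$p < support_p
    sum(nearby) >= min_support
  }, loci)
}
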