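# Genotype and phenotype simulation with stated LD, structure and
# heritability, emulating the statistical structure of an inbred rice
# diversity panel: diploid-coded but homozygous genotypes, block LD from
# a first-order copying chain, Balding-Nichols population structure.

#' Simulate an inbred genotype panel
#'
#' Ancestral allele frequencies are drawn uniformly from `maf_range`;
#' subpopulation frequencies follow the Balding-Nichols construction
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)`.  One haplotype per accession is built
#' by a first-order copying chain (allele copied from the previous SNP
#' with probability `ld_rho`, else drawn fresh), restarted at chromosome
#' boundaries, and doubled into a homozygous genotype; an optional
#' `het_rate` converts random calls to heterozygous.
#'
#' @param n Accessions.
#' @param m SNPs.
#' @param ld_rho Adjacent-SNP copying probability in `[0, 1)`.
#' @param n_subpops Number of subpopulations (1 = unstructured).
#' @param fst Balding-Nichols differentiation in `[0, 1)`.
#' @param seed Integer seed.
#' @param n_chrom Chromosomes the SNPs are split over, default 5.
#' @param spacing_bp Base-pair spacing of consecutive SNPs, default 1000.
#' @param maf_range Ancestral frequency range, default `c(0.05, 0.5)`.
#' @param het_rate Fraction of calls made heterozygous, default 0.
#' @return `sim_population`: list with the [genotype_matrix()], `subpop`
#'   labels, `freqs` and the seed.
#' @export
simulate_genotypes <- function(n, m, ld_rho = 0, n_subpops = 1L, fst = 0,
                               seed = 1L, n_chrom = 5L, spacing_bp = 1000L,
                               maf_range = c(0.05, 0.5), het_rate = 0) {
  stopifnot(n >= 2, m >= 2, ld_rho >= 0, ld_rho < 1, fst >= 0, fst < 1)
  set.seed(seed)
  chrom <- rep(seq_len(n_chrom), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(table(chrom), function(k) seq_len(k) * spacing_bp))
  p_anc <- stats::runif(m, maf_range[1], maf_range[2])
  subpop <- sort(rep_len(seq_len(n_subpops), n))
  freqs <- matrix(p_anc, nrow = n_subpops, ncol = m, byrow = TRUE)
  if (fst > 0 && n_subpops > 1) {
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    for (s in seq_len(n_subpops))
      freqs[s, ] <- stats::rbeta(m, a, b)
  }
  hap <- matrix(0L, n, m)
  pf <- freqs[subpop, , drop = FALSE]    # n x m per-individual frequencies
  hap[, 1] <- stats::rbinom(n, 1, pf[, 1])
  for (j in 2:m) {
    fresh <- stats::rbinom(n, 1, pf[, j])
    if (ld_rho > 0 && chrom[j] == chrom[j - 1]) {
      copy <- stats::runif(n) < ld_rho
      hap[, j] <- ifelse(copy, hap[, j - 1], fresh)
    } else hap[, j] <- fresh
  }
  D <- 2L * hap
  if (het_rate > 0) {
    flip <- which(stats::runif(n * m) < het_rate)
    D[flip] <- 1L
  }
  G <- genotype_matrix(D, chrom = chrom, pos = pos)
  structure(list(G = G, subpop = subpop, freqs = freqs, seed = seed),
            class = "sim_population")
}

#' Simulate a phenotype on a genotype panel
#'
#' `y` is the sum of a causal component (the named SNPs with effects
#' `beta`), a polygenic component (genome-wide small effects so kinship
#' estimated from the same SNPs is internally consistent) and Gaussian
#' noise; the three components are rescaled so the realized sample
#' variance fractions equal `h2_causal`, `h2_polygenic` and the
#' remainder.  Total phenotypic variance is 1.
#'
#' @param pop A [simulate_genotypes()] result (or a `genotype_matrix`).
#' @param causal_idx SNP column indices of causal variants (may be empty).
#' @param h2_causal Variance fraction of the causal component.
#' @param h2_polygenic Variance fraction of the polygenic component.
#' @param seed Integer seed.
#' @param beta Relative causal effects (recycled), default 1.
#' @return Named numeric phenotype vector with attribute `truth`: list of
#'   realized per-SNP effects (`beta_realized`, on the dosage scale) and
#'   component variance fractions.
#' @export
simulate_phenotype <- function(pop, causal_idx = integer(0),
                               h2_causal = 0, h2_polygenic = 0, seed = 1L,
                               beta = 1) {
  G <- if (inherits(pop, "sim_population")) pop$G else pop
  if (h2_causal + h2_polygenic >= 1)
    stop("h2_causal + h2_polygenic must be < 1")
  if (length(causal_idx) > 0 && max(causal_idx) > ncol(G$dosages))
    stop("causal index out of range")
  set.seed(seed)
  D <- G$dosages
  n <- nrow(D); m <- ncol(D)
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    nas <- which(is.na(D), arr.ind = TRUE)
    D[nas] <- mu[nas[, 2]]
  }
  beta <- rep_len(beta, length(causal_idx))
  causal <- if (length(causal_idx) > 0)
    drop(D[, causal_idx, drop = FALSE] %*% beta) else rep(0, n)
  u <- stats::rnorm(m, 0, 1 / sqrt(m))
  poly <- drop(scale(D) %*% u)
  poly[is.na(poly)] <- 0
  eps <- stats::rnorm(n)
  scale_to <- function(x, v) {
    s <- stats::sd(x)
    if (s == 0 || v == 0) return(list(x = rep(0, n), f = 0))
    list(x = x * sqrt(v) / s, f = sqrt(v) / s)
  }
  sc_c <- scale_to(causal, h2_causal)
  sc_p <- scale_to(poly, h2_polygenic)
  sc_e <- scale_to(eps, 1 - h2_causal - h2_polygenic)
  y <- sc_c$x + sc_p$x + sc_e$x
  names(y) <- G$ids
  attr(y, "truth") <- list(
    causal_idx = causal_idx,
    beta_realized = beta * sc_c$f,
    h2_causal = h2_causal, h2_polygenic = h2_polygenic,
    var_frac_causal = if (stats::var(y) > 0)
      stats::var(sc_c$x) / stats::var(y) else 0)
  y
}

#' Simulate a feature/trait table for model selection
#'
#' Draws a projected-area column plus morphological and texture feature
#' pools correlated with area, then builds the trait from the stated
#' generating family (`A`, `AM`, `AT` or `ATM`) and standardized effect
#' sizes, plus Gaussian noise.  `noise_sd = NULL` with `target_r2` set
#' calibrates the noise so the population signal R-squared equals the
#' target.
#'
#' @param n Rows (>= 20).
#' @param generating_family `"A"`, `"AM"`, `"AT"` or `"ATM"`.
#' @param coefficients Standardized effects: `area` always used; `morph`
#'   and `texture` used by the matching families.
#' @param noise_sd Noise SD on the trait scale, or `NULL` to use
#'   `target_r2`.
#' @param seed Integer seed.
#' @param n_morph,n_texture Pool sizes, default 8 and 4.
#' @param target_r2 Signal R-squared used when `noise_sd` is `NULL`.
#' @param which_morph,which_texture Index of the causal pool member.
#' @return A [trait_table()] with attribute `truth` (generating family,
#'   causal columns, noise SD).
#' @export
simulate_feature_trait_table <- function(
    n = 200L, generating_family = c("A", "AM", "AT", "ATM"),
    coefficients = c(area = 1, morph = 0.6, texture = 0.6),
    noise_sd = NULL, seed = 1L, n_morph = 8L, n_texture = 4L,
    target_r2 = 0.9, which_morph = 3L, which_texture = 2L) {
  generating_family <- match.arg(generating_family)
  if (n < 20L) stop("need n >= 20")
  set.seed(seed)
  area <- stats::rnorm(n, 500, 120)
  area <- pmax(area, 50)
  az <- as.numeric(scale(area))
  morph_names <- paste0("morph_", seq_len(n_morph))
  tex_names <- paste0("glcm_tex", seq_len(n_texture))
  morph <- sapply(seq_len(n_morph), function(i)
    0.4 * az + sqrt(1 - 0.4^2) * stats::rnorm(n))
  tex <- sapply(seq_len(n_texture), function(i)
    0.3 * az + sqrt(1 - 0.3^2) * stats::rnorm(n))
  colnames(morph) <- morph_names
  colnames(tex) <- tex_names
  use_m <- generating_family %in% c("AM", "ATM")
  use_t <- generating_family %in% c("AT", "ATM")
  signal <- coefficients[["area"]] * az +
    (if (use_m) coefficients[["morph"]] * morph[, which_morph] else 0) +
    (if (use_t) coefficients[["texture"]] * tex[, which_texture] else 0)
  if (is.null(noise_sd))
    noise_sd <- stats::sd(signal) * sqrt(1 / target_r2 - 1)
  trait <- 200 + 10 * (signal + stats::rnorm(n, 0, noise_sd))
  df <- data.frame(projected_area_px = area, morph, tex, trait = trait,
                   check.names = FALSE)
  tt <- trait_table(df, trait_col = "trait",
                    morph_cols = morph_names, texture_cols = tex_names)
  attr(tt, "truth") <- list(family = generating_family,
                            morph_col = morph_names[which_morph],
                            texture_col = tex_names[which_texture],
                            noise_sd = noise_sd, seed = seed)
  tt
}
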