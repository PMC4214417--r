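# MAF filtering, kinship, LMM scan, thresholds, LD and clumping.

test_that("MAF/MAC filter applies both rules over non-missing calls", {
  # 529 homozygous accessions, minor allele in 27: retained
  D <- matrix(0, 529, 3)
  D[1:27, 1] <- 2            # maf 27/529 ~ 0.051, carriers 27
  D[1:5, 2] <- 2             # maf ~ 0.0095, carriers 5: fails both
  D[1:100, 3] <- 2           # comfortably retained
  G <- maf_filter(genotype_matrix(D))
  expect_equal(ncol(G$dosages), 2)
  expect_true(all(colnames(G$dosages) %in% c("1_1", "1_3")))

  # n = 100, minor allele in 5: MAF = 0.05 passes, 5 < 6 carriers fails
  D2 <- matrix(0, 100, 2)
  D2[1:5, 1] <- 2
  D2[1:6, 2] <- 2
  G2 <- maf_filter(genotype_matrix(D2))
  expect_equal(colnames(G2$dosages), "1_2")
  expect_warning(maf_filter(genotype_matrix(matrix(0, 50, 2) +
                                              c(rep(2, 2), rep(0, 98)))),
                 "all SNPs removed")
})

test_that("identity-proportion kinship matches brute-force pair counts", {
  D <- matrix(c(0, 2, 2, 0, 0, 2, 0, 2,
                0, 2, 2, 0, 0, 2, 0, 2,
                2, 0, 2, 0, 2, 2, 0, 0,
                0, 0, 0, 0, 2, 2, 2, 2,
                2, 2, 2, 2, 0, 0, 0, 0), 5, 8, byrow = TRUE)
  K <- kinship_identity_proportion(genotype_matrix(D), seed = 1)
  hand <- outer(seq_len(5), seq_len(5),
                Vectorize(function(i, j) mean(D[i, ] == D[j, ])))
  expect_equal(unname(K$raw), hand)
  expect_equal(unname(K$raw[1, 2]), 1)          # identical accessions
  expect_equal(unname(K$raw[4, 5]), 0)          # fully opposite
  expect_equal(K$raw, t(K$raw))
  expect_true(all(diag(K$raw) == 1))

  # accessions differing at exactly half the SNPs
  D3 <- rbind(rep(c(0, 2), 4), c(0, 2, 0, 2, 2, 0, 2, 0), rep(0, 8))
  K3 <- kinship_identity_proportion(genotype_matrix(D3), seed = 1)
  expect_equal(unname(K3$raw[1, 2]), 0.5)

  # missing calls are excluded pairwise (repair warning expected: the
  # raw identity matrix need not be PSD once denominators differ)
  Dm <- D; Dm[1, 1] <- NA
  expect_warning(kinship_identity_proportion(genotype_matrix(Dm), seed = 1),
                 "PSD")
  Km <- suppressWarnings(kinship_identity_proportion(genotype_matrix(Dm),
                                                     seed = 1))
  expect_equal(unname(Km$raw[1, 2]), mean(Dm[1, -1] == Dm[2, -1]))
})

test_that("phenotype outlier rule drops only extreme values", {
  set.seed(4)
  y <- stats::setNames(rnorm(50), paste0("a", 1:50))
  y <- pmin(pmax(y, -2.8), 2.8)            # keep the base sample inside 3 SD
  clean <- phenotype_preprocess(y)
  expect_length(clean, 50)
  y2 <- c(y, out = 10)
  clean2 <- phenotype_preprocess(y2)
  expect_length(clean2, 50)
  expect_identical(attr(clean2, "dropped"), "out")
  y3 <- stats::setNames(rep(3, 12), paste0("b", 1:12))
  expect_length(phenotype_preprocess(y3), 12)   # SD = 0 guard
  expect_error(phenotype_preprocess(rnorm(5)), "at least 10")
})

test_that("LMM with identity kinship reproduces OLS likelihood-ratio tests", {
  set.seed(1)
  pop <- simulate_genotypes(n = 80, m = 120, ld_rho = 0, seed = 3)
  y <- simulate_phenotype(pop, causal_idx = 7, h2_causal = 0.25, seed = 4)
  scan <- lmm_scan(pop$G, y, diag(80))
  p_oracle <- vapply(seq_len(120), function(j) {
    x <- pop$G$dosages[, j]
    if (max(x) == min(x)) return(NA_real_)
    lr <- 2 * (as.numeric(stats::logLik(stats::lm(y ~ x))) -
                 as.numeric(stats::logLik(stats::lm(y ~ 1))))
    stats::pchisq(lr, 1, lower.tail = FALSE)
  }, 0)
  expect_lt(max(abs(scan$p - p_oracle), na.rm = TRUE), 1e-6)
  expect_true(all(scan$lr >= 0, na.rm = TRUE))
  expect_true(all(scan$p > 0 & scan$p <= 1, na.rm = TRUE))
  expect_true(is.na(scan$p[which(apply(pop$G$dosages, 2,
                                       function(x) max(x) == min(x)))[1]]) ||
                all(apply(pop$G$dosages, 2, function(x) max(x) > min(x))))
})

test_that("spectral log-likelihood matches a direct dense-matrix oracle", {
  set.seed(9)
  n <- 8
  pop <- simulate_genotypes(n = 40, m = 60, ld_rho = 0.4, seed = 5)
  K <- kinship_identity_proportion(pop$G, seed = 2)$K[1:n, 1:n]
  y <- rnorm(n) + seq_len(n) * 0.1
  ev <- eigen(K, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  yt <- drop(crossprod(ev$vectors, y))
  ones_t <- drop(crossprod(ev$vectors, rep(1, n)))
  direct_ll <- function(delta) {
    # profile mu and sg2 out of the dense MVN likelihood
    V <- K + delta * diag(n)
    Vi <- solve(V)
    mu <- sum(Vi %*% y) / sum(Vi)
    r <- y - mu
    q <- drop(t(r) %*% Vi %*% r)
    sg2 <- q / n
    -0.5 * (n * log(2 * pi * sg2) + n +
              determinant(V, logarithm = TRUE)$modulus)
  }
  for (delta in c(0.05, 0.3, 1, 5)) {
    mine <- phenokit:::loglik_at_delta(delta, yt, ones_t, lam)$ll
    expect_equal(mine, as.numeric(direct_ll(delta)), tolerance = 1e-8)
  }
  # the maximized value agrees with an independent optimizer on the oracle
  opt <- stats::optimize(function(ld) direct_ll(exp(ld)), c(-10, 10),
                         maximum = TRUE, tol = 1e-9)
  mine_opt <- phenokit:::optimize_delta(yt, ones_t, lam)
  expect_equal(mine_opt$ll, as.numeric(opt$objective), tolerance = 1e-4)
})

test_that("per-SNP delta mode agrees with null-delta mode on easy data", {
  set.seed(12)
  pop <- simulate_genotypes(n = 60, m = 25, ld_rho = 0, seed = 13)
  y <- simulate_phenotype(pop, causal_idx = 5, h2_causal = 0.3,
                          h2_polygenic = 0.2, seed = 14)
  K <- kinship_identity_proportion(pop$G, seed = 1)
  s1 <- lmm_scan(pop$G, y, K, mode = "null_delta")
  s2 <- lmm_scan(pop$G, y, K, mode = "per_snp_delta")
  expect_equal(s1$beta, s2$beta, tolerance = 0.05)
  expect_lt(s2$p[5], 1e-3)
  # per-SNP refit can only raise the alternative likelihood
  expect_true(all(s2$lr >= s1$lr - 1e-6, na.rm = TRUE))
})

test_that("permuted phenotypes give uniform p-values", {
  pop <- simulate_genotypes(n = 200, m = 5000, ld_rho = 0.5,
                            n_subpops = 2, fst = 0.1, seed = 21)
  y <- simulate_phenotype(pop, h2_polygenic = 0.4, seed = 22)
  set.seed(23)
  yp <- stats::setNames(sample(as.numeric(y)), names(y))  # break structure
  K <- kinship_identity_proportion(pop$G, seed = 3)
  scan <- lmm_scan(pop$G, yp, K)
  ks <- stats::ks.test(scan$p[!is.na(scan$p)], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("effective marker number has the stated eigen properties", {
  Go <- orthogonal_genotypes(5, 20)
  expect_equal(effective_marker_number(Go), 20)      # N = m exactly

  base <- c(0, 2, 0, 2, 2, 0, 2, 0, 0, 2)
  Gi <- genotype_matrix(matrix(rep(base, 10), 10, 10))
  expect_equal(effective_marker_number(Gi), 1)       # k identical columns

  # 20 duplicated blocks of 10 identical SNPs each: N = 20
  set.seed(31)
  cols <- do.call(cbind, lapply(1:20, function(b) {
    v <- sample(c(0, 2), 40, replace = TRUE)
    matrix(rep(v, 10), 40, 10)
  }))
  G20 <- genotype_matrix(cols, chrom = rep(1:4, each = 50),
                         pos = rep(seq_len(50) * 100, 4))
  expect_equal(effective_marker_number(G20, block_size = 10), 20)

  # invariant to duplicating an already perfectly-correlated SNP
  G21 <- genotype_matrix(cbind(cols, cols[, 1]),
                         chrom = c(rep(1:4, each = 50), 9),
                         pos = c(rep(seq_len(50) * 100, 4), 100))
  # the duplicate sits alone on its own chromosome-block, adding 1
  expect_equal(effective_marker_number(G21, block_size = 10), 21)

  expect_warning(
    effective_marker_number(genotype_matrix(cbind(rep(0, 10),
                                                  rep(c(0, 2), 5)))),
    "constant")
})

test_that("thresholds implement 1/N and alpha/N exactly", {
  thr <- significance_thresholds(1e6)
  expect_identical(thr$suggestive, 1e-6)
  expect_equal(thr$significant, 5e-8)
  for (N in c(1, 3.7, 829517.2)) {
    t2 <- significance_thresholds(N, alpha = 0.05)
    expect_equal(t2$significant / t2$suggestive, 0.05)
  }
  expect_error(significance_thresholds(0.5), ">= 1")
})

test_that("LD r2 matches haplotype-frequency arithmetic and dosage cor", {
  x <- rep(c(2, 0), c(5, 5))
  expect_equal(ld_r2(x, x), 1)
  # haplotype counts AB=4, Ab=1, aB=1, ab=4 -> r2 = 0.0225/0.0625
  a <- c(rep(2, 4), 2, 0, rep(0, 4))
  b <- c(rep(2, 4), 0, 2, rep(0, 4))
  expect_equal(ld_r2(a, b), 0.36)
  set.seed(41)
  for (i in 1:20) {
    u <- sample(c(0, 2), 30, replace = TRUE)
    v <- ifelse(runif(30) < 0.3, u, sample(c(0, 2), 30, replace = TRUE))
    if (sd(u) == 0 || sd(v) == 0) next
    expect_equal(ld_r2(u, v), cor(u, v)^2, tolerance = 1e-12)
  }
  expect_error(ld_r2(rep(2, 10), x), "monomorphic")
})

test_that("greedy clumping equals a brute-force oracle on 50-SNP fixtures", {
  for (seed in 1:5) {
    pop <- simulate_genotypes(n = 120, m = 50, ld_rho = 0.9, n_chrom = 2,
                              seed = 50 + seed)
    y <- simulate_phenotype(pop, causal_idx = c(10, 40), h2_causal = 0.3,
                            seed = 60 + seed)
    K <- kinship_identity_proportion(pop$G, seed = 1)
    scan <- lmm_scan(pop$G, y, K)
    thr <- 1e-3
    loci <- clump_loci(scan, pop$G, p_threshold = thr, r2_threshold = 0.25,
                       window_kb = 10)
    # independent greedy re-implementation
    pass <- which(!is.na(scan$p) & scan$p < thr)
    taken <- logical(length(pass))
    oracle <- list()
    while (any(!taken)) {
      rem <- pass[!taken]
      lead <- rem[which.min(scan$p[rem])]
      mem <- lead
      taken[match(lead, pass)] <- TRUE
      for (s in pass[!taken]) {
        if (scan$chrom[s] == scan$chrom[lead] &&
            abs(scan$pos[s] - scan$pos[lead]) <= 10 * 1000) {
          r2 <- tryCatch(ld_r2(pop$G$dosages[, lead], pop$G$dosages[, s]),
                         error = function(e) 0)
          if (r2 > 0.25) { mem <- c(mem, s); taken[match(s, pass)] <- TRUE }
        }
      }
      oracle[[length(oracle) + 1]] <- list(lead = lead, members = sort(mem))
    }
    oracle <- oracle[order(vapply(oracle, function(l) scan$p[l$lead], 0))]
    expect_equal(length(loci), length(oracle))
    for (i in seq_along(loci)) {
      expect_equal(loci[[i]]$lead_snp, scan$snp[oracle[[i]]$lead])
      expect_equal(sort(loci[[i]]$members$snp),
                   sort(scan$snp[oracle[[i]]$members]))
      expect_true(all(loci[[i]]$lead_p <= loci[[i]]$members$p))
    }
  }
  # degenerate cases
  pop <- simulate_genotypes(n = 60, m = 10, seed = 99)
  y <- simulate_phenotype(pop, h2_polygenic = 0.1, seed = 98)
  scan <- lmm_scan(pop$G, y, kinship_identity_proportion(pop$G, seed = 1))
  expect_length(clump_loci(scan, pop$G, p_threshold = 1e-300), 0)
})

test_that("peak filter keeps supported loci and drops singletons", {
  res <- data.frame(snp = paste0("s", 1:6), chrom = rep(1L, 6),
                    pos = c(100, 200, 300, 400, 50000, 90000) * 10L,
                    beta = 0, lr = 1,
                    p = c(1e-9, 1e-6, 1e-6, 1e-5, 1e-9, 0.5))
  class(res) <- c("association_result", "data.frame")
  lead1 <- structure(list(lead_snp = "s1", chrom = 1L, pos = 1000L,
                          lead_p = 1e-9,
                          members = res[1, c("snp", "chrom", "pos", "p")],
                          span = c(1000L, 1000L)), class = "clumped_locus")
  lead5 <- structure(list(lead_snp = "s5", chrom = 1L, pos = 500000L,
                          lead_p = 1e-9,
                          members = res[5, c("snp", "chrom", "pos", "p")],
                          span = c(500000L, 500000L)), class = "clumped_locus")
  kept <- peak_filter(list(lead1, lead5), res, min_support = 2,
                      support_p = 1e-4, window_kb = 250)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$lead_snp, "s1")
})
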