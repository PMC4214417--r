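# Readers/writers, run configuration and the umbrella pipeline tying the
# stages together: images -> features -> trait model -> phenotype -> GWAS
# -> loci.  All randomness flows through explicit seeds in the config;
# every output directory carries a provenance file with the config and
# its hash.

#' Read genotypes from a minimal VCF or a dosage matrix
#'
#' The VCF path parses biallelic SNP records only (others are skipped and
#' counted), reads the GT field tolerant of `/` and `|` separators, and
#' maps `./.` to a missing dosage.  The matrix path expects a TSV with
#' columns `snp`, `chrom`, `pos`, `ref`, `alt` followed by one column per
#' accession.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"matrix"`.
#' @return A [genotype_matrix()]; attribute `skipped` counts non-biallelic
#'   VCF records.
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix") {
    df <- utils::read.delim(path, check.names = FALSE)
    meta <- df[, 1:5]
    D <- t(as.matrix(df[, -(1:5), drop = FALSE]))
    colnames(D) <- df$snp
    G <- genotype_matrix(D, chrom = meta$chrom, pos = meta$pos,
                         ref = meta$ref, alt = meta$alt,
                         ids = colnames(df)[-(1:5)])
    attr(G, "skipped") <- 0L
    return(G)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("malformed VCF: missing #CHROM header")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  skipped <- 0L
  rows <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    ref <- f[4]; alt <- f[5]
    if (nchar(ref) != 1L || nchar(alt) != 1L || grepl(",", alt)) {
      skipped <- skipped + 1L
      next
    }
    gt <- sub(":.*", "", f[-(1:9)])
    gt <- gsub("\\|", "/", gt)
    dose <- vapply(strsplit(gt, "/"), function(a) {
      if (any(a == ".")) NA_real_ else sum(as.numeric(a))
    }, 0)
    rows[[length(rows) + 1L]] <-
      list(chrom = f[1], pos = as.integer(f[2]), id = f[3],
           ref = ref, alt = alt, dose = dose)
  }
  if (length(rows) == 0L) stop("zero usable records in VCF")
  D <- do.call(cbind, lapply(rows, `[[`, "dose"))
  colnames(D) <- vapply(rows, `[[`, "", "id")
  G <- genotype_matrix(D,
                       chrom = vapply(rows, `[[`, "", "chrom"),
                       pos = vapply(rows, `[[`, 0L, "pos"),
                       ref = vapply(rows, `[[`, "", "ref"),
                       alt = vapply(rows, `[[`, "", "alt"),
                       ids = ids)
  attr(G, "skipped") <- skipped
  G
}

#' Write a genotype matrix as a minimal VCF
#'
#' @param G A [genotype_matrix()].
#' @param path Output file.
#' @export
write_genotypes_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=phenokit",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", G$ids), collapse = "\t")),
             con)
  D <- G$dosages
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(D))) {
    gt <- ifelse(is.na(D[, j]), "./.", gt_of[D[, j] + 1L])
    writeLines(paste(c(G$chrom[j], G$pos[j], colnames(D)[j], G$ref[j],
                       G$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Default run configuration
#'
#' Every stage parameter of the pipeline with its documented default;
#' pass overrides as named arguments.
#'
#' @param ... Named overrides of the defaults.
#' @return `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # imaging
    min_object_px = 64L, threshold_mode = "otsu", glcm_levels = 32L,
    mm_per_px = 1.0, view_aggregation = "mean",
    # grains
    grain_min_area_px = 40L, split_touching = TRUE, split_factor = 1.6,
    # trait models
    train_fraction = 0.5, cv_folds = 10L, rel_press = 0.05, abs_adj = 0.01,
    # gwas
    maf_min = 0.05, mac_accessions_min = 6L, kinship_subset = Inf,
    z_max = 3.0, lmm_mode = "null_delta", block_size = 200L, alpha = 0.05,
    r2_threshold = 0.25, window_kb = 250L,
    peak_filter = FALSE, min_support = 2L,
    # synthetic inputs
    sim = list(n_plants = 12L, n_views = 3L, n = 200L, m = 1000L,
               ld_rho = 0.6, n_subpops = 2L, fst = 0.1,
               h2_causal = 0.15, h2_polygenic = 0.3))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 10),
             tmp)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(cfg, out_dir) {
  jsonlite::write_json(
    list(config = unclass(cfg), config_hash = config_hash(cfg)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = 10,
    pretty = TRUE)
}

#' Write an association result bundle
#'
#' Deterministic column order and fixed float formatting: an association
#' TSV, a loci TSV (valid empty table with header when nothing passes),
#' a thresholds JSON and a provenance JSON with the config hash.
#'
#' @param results An `association_result`.
#' @param loci List from [clump_loci()].
#' @param thresholds List from [significance_thresholds()].
#' @param cfg The `run_config` used.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, loci, thresholds, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assoc <- data.frame(snp = results$snp, chrom = results$chrom,
                      pos = results$pos,
                      beta = sprintf("%.6g", results$beta),
                      lr = sprintf("%.6g", results$lr),
                      p = sprintf("%.6g", results$p))
  utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ldf <- if (length(loci) == 0)
    data.frame(lead_snp = character(), chrom = character(), pos = integer(),
               lead_p = character(), n_members = integer(),
               span_start = integer(), span_end = integer())
  else do.call(rbind, lapply(loci, function(l)
    data.frame(lead_snp = l$lead_snp, chrom = l$chrom, pos = l$pos,
               lead_p = sprintf("%.6g", l$lead_p),
               n_members = nrow(l$members),
               span_start = l$span[1], span_end = l$span[2])))
  utils::write.table(ldf, file.path(out_dir, "loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(thresholds, file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = 12)
  write_provenance(cfg, out_dir)
  invisible(out_dir)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Simulates plants, extracts image features, trains and selects a trait
#' model, simulates a structured genotype panel and phenotype, and runs
#' the association chain (filter, kinship, LMM scan, thresholds,
#' clumping), writing the bundle to `out_dir`.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return List with the feature table, selection report, association
#'   result, thresholds and loci.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = tempfile("phenokit_")) {
  required <- c("seed", "min_object_px", "glcm_levels", "train_fraction",
                "rel_press", "abs_adj", "maf_min", "mac_accessions_min",
                "z_max", "lmm_mode", "block_size", "alpha", "r2_threshold",
                "window_kb", "sim")
  for (f in required)
    if (is.null(cfg[[f]])) stop("config field missing: ", f)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  # stage 1: plant imaging
  vectors <- lapply(seq_len(cfg$sim$n_plants), function(i) {
    views <- lapply(seq_len(cfg$sim$n_views), function(v) {
      sc <- render_plant(seed = seed * 1000L + i * 10L + v)
      view_features(sc$image, levels = cfg$glcm_levels)
    })
    aggregate_views(views, plant_id = sprintf("plant_%03d", i),
                    method = cfg$view_aggregation)
  })
  features <- write_feature_table(vectors,
                                  file.path(out_dir, "features.csv"))
  # stage 2: trait model on a simulated feature/trait table
  tt <- simulate_feature_trait_table(n = cfg$sim$n, generating_family = "AM",
                                     seed = seed)
  sp <- split_train_test(tt, fraction = cfg$train_fraction, seed = seed)
  report <- select_best_model(sp$train, rel_press = cfg$rel_press,
                              abs_adj = cfg$abs_adj)
  eval_m <- evaluate_predictions(report$chosen, sp$test)
  jsonlite::write_json(
    list(chosen = list(family = report$chosen$family,
                       predictors = report$chosen$predictors,
                       coefficients = as.list(report$chosen$coefficients)),
         criteria = report$criteria, test = eval_m),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = 10,
    pretty = TRUE)
  # stage 3: association chain on a simulated panel
  pop <- simulate_genotypes(cfg$sim$n, cfg$sim$m, ld_rho = cfg$sim$ld_rho,
                            n_subpops = cfg$sim$n_subpops,
                            fst = cfg$sim$fst, seed = seed + 1L)
  causal <- max(1L, round(cfg$sim$m * 0.4))
  y <- simulate_phenotype(pop, causal_idx = causal,
                          h2_causal = cfg$sim$h2_causal,
                          h2_polygenic = cfg$sim$h2_polygenic,
                          seed = seed + 2L)
  y <- phenotype_preprocess(y, z_max = cfg$z_max)
  G <- maf_filter(pop$G, cfg$maf_min, cfg$mac_accessions_min)
  K <- kinship_identity_proportion(
    G, subset_size = min(cfg$kinship_subset, ncol(G$dosages)), seed = seed)
  scan <- lmm_scan(G, y, K, mode = cfg$lmm_mode)
  N <- effective_marker_number(G, block_size = cfg$block_size)
  thr <- significance_thresholds(N, alpha = cfg$alpha)
  loci <- clump_loci(scan, G, p_threshold = thr$suggestive,
                     r2_threshold = cfg$r2_threshold,
                     window_kb = cfg$window_kb)
  if (isTRUE(cfg$peak_filter))
    loci <- peak_filter(loci, scan, min_support = cfg$min_support,
                        support_p = 100 * thr$suggestive,
                        window_kb = cfg$window_kb)
  write_results(scan, loci, thr, cfg, out_dir)
  list(features = features, report = report, eval = eval_m, scan = scan,
       thresholds = thr, loci = loci, out_dir = out_dir)
}
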