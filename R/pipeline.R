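# End-to-end orchestration: data (VCF or simulation) -> F-statistics ->
# calibrated hierarchical-island null -> outlier z-scores -> HMM islands ->
# parallel classification -> genomic context, diversity and QTL stages.
# A single global seed fans out to per-stage seeds via derive_seed(), so any
# stage can be rerun in isolation.

#' Per-population inbreeding coefficients from genotypes
#'
#' Weighted F_IS per population from the within-population levels of the
#' genotypic AMOVA (ratio of summed variance components over loci).
#'
#' @param gm a [genotype_matrix()].
#' @return named numeric vector of F_IS per population.
#' @export
estimate_fis_per_pop <- function(gm) {
  pops <- unique(gm$populations)
  out <- stats::setNames(numeric(length(pops)), pops)
  for (p in pops) {
    g <- gm$genotypes[gm$populations == p, , drop = FALSE]
    np <- colSums(!is.na(g))
    n1 <- colSums(g == 1L, na.rm = TRUE)
    a <- colSums(g, na.rm = TRUE)
    xp <- ifelse(np > 0, a / (2 * np), NA_real_)
    sxi2 <- colSums(g == 2L, na.rm = TRUE) + 0.25 * n1
    ss_wi <- 0.5 * n1
    ss_ai <- 2 * (sxi2 - np * xp^2)
    ok <- np >= 2
    ms_wi <- ss_wi / np
    ms_ai <- ss_ai / (np - 1)
    sig_w <- ms_wi
    sig_i <- (ms_ai - ms_wi) / 2
    out[p] <- sum(sig_i[ok]) / sum((sig_i + sig_w)[ok])
  }
  out
}

#' Default configuration for the bundled synthetic demo
#'
#' A down-scaled end-to-end run: ~5,000 SNPs on 20 chromosomes, ten planted
#' islands (six parallel, four group-specific), realistic inbreeding, a
#' two-regime recombination profile and a synthetic QTL table.
#'
#' @param n_snps total SNPs.
#' @param seed global seed.
#' @return a pipeline configuration list for [run_pipeline()].
#' @export
demo_config <- function(n_snps = 5000, seed = 42) {
  chroms <- setdiff(as.character(utils::as.roman(1:25)), "XIX")[1:20]
  islands <- data.frame(
    chrom = c("VII", "VII", "VII", "I", "IV", "XII", "II", "IX", "XV", "III"),
    start = c(2e6, 8e6, 14e6, 5e6, 9e6, 3e6, 11e6, 6e6, 1e6, 15e6),
    end   = c(2e6, 8e6, 14e6, 5e6, 9e6, 3e6, 11e6, 6e6, 1e6, 15e6) + 6e5,
    strength = 0.8,
    parallel = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  recomb <- do.call(rbind, lapply(chroms, function(ch) data.frame(
    chrom = ch, start = c(0, 1e7), end = c(1e7, 2e7),
    rate_cm_per_mb = if (ch == "VII") c(0.5, 4) else c(2, 4))))
  list(
    simulate = sim_config(n_snps = n_snps, island_spec = islands,
                          recomb_profile = recomb, seed = seed),
    maf = 0.01,
    contrasts = list(c("L1", "S1"), c("L2", "S2")),
    null = list(n_sims = 20000, n_groups = 10, demes_per_group = 100,
                n_bins = 20, min_per_bin = 500, calib_reps = 2000),
    hmm = list(fdr = 0.001, n_restarts = 5, decode = "posterior",
               alpha_parallel = 0.05, n_perm_parallel = 499),
    ripley = list(n_null = 2000, alpha = 0.05),
    diversity = list(min_sites = 2500),
    qtl = list(n_perm = 10000, buffer_bp = 10000, n_traits = 16,
               frac_overlapping = 0.4, n_per_trait = 3),
    seed = seed)
}

#' Run the full island-detection pipeline
#'
#' Executes, in dependency order: data acquisition (synthetic simulation or
#' VCF ingest with the full filter cascade), MAF filtering, hierarchical
#' F-statistics, migration calibration and the hierarchical-island null,
#' outlier p-values and z-scores, HMM segmentation and island calling,
#' parallel classification, Ripley's K clustering of outliers,
#' recombination-rate association tests, windowed nucleotide diversity
#' contrasts, and the QTL overlap permutation test. All stage outputs are
#' written as TSV under `out_dir` together with a provenance manifest;
#' reruns with the same configuration are bit-identical.
#'
#' @param config configuration list (see [demo_config()]); alternatively the
#'   path to a YAML file holding the same structure.
#' @param out_dir output directory (created).
#' @param seed optional override of `config$seed`.
#' @return (invisibly) a list with all stage results, including `islands`
#'   (classified), `fst_hier`, `outliers`, `qtl` and, for simulated data,
#'   `recovery` (planted-island recovery and label agreement).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- seed
  seed0 <- config$seed
  if (!is.null(config$paths)) {
    for (f in unlist(config$paths))
      if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)

  # -- data ------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    gm <- sim$gm; map <- sim$map; truth <- sim$truth
    rad_loci <- sim$rad_loci
    qtls <- simulate_qtl_intervals(config$simulate, sim$islands,
                                   n_traits = config$qtl$n_traits,
                                   frac_overlapping = config$qtl$frac_overlapping,
                                   n_per_trait = config$qtl$n_per_trait,
                                   seed = derive_seed(seed0, "qtl_sim"))
    res$sim <- sim
  } else {
    gm <- read_vcf(config$paths$vcf, config$paths$popmap, config$paths$hierarchy)
    if (!is.null(gm$gq) || !is.null(gm$dp)) gm <- apply_genotype_filters(gm)
    else message("VCF carries no GQ/DP annotations; genotype filter skipped")
    gm <- apply_site_filters(gm)
    gm <- hwe_excess_homozygote_filter(gm)
    if (nrow(gm$loci) == 0) stop("no SNPs survive the filters")
    map <- utils::read.table(config$paths$map, header = TRUE, sep = "\t")
    qtls <- utils::read.table(config$paths$qtl, header = TRUE, sep = "\t")
    rad_loci <- derive_rad_loci(gm$loci, 90)
  }
  res$gm <- gm

  # -- F-statistics (all SNPs) and MAF-filtered scan set ----------------
  gm_maf <- maf_filter(gm, threshold = config$maf)
  fst_h <- hierarchical_fst(gm_maf)
  res$fst_hier <- fst_h

  # -- null model: calibrate migration, simulate, p-values --------------
  fis_hat <- pmax(estimate_fis_per_pop(gm), 0)
  pops <- unique(gm$populations)
  scfg <- sample_config(pop = pops, group = gm$hierarchy[pops],
                        n_dip = vapply(pops, function(p) sum(gm$populations == p),
                                       integer(1)),
                        fis = fis_hat[pops])
  set.seed(derive_seed(seed0, "calibrate"))
  mig <- calibrate_migration(max(fst_h$fct_wt, 0), max(fst_h$fsc_wt, 0), scfg,
                             n_groups = config$null$n_groups,
                             demes_per_group = config$null$demes_per_group,
                             n_reps = config$null$calib_reps)
  null_tab <- simulate_null(scfg, n_sims = config$null$n_sims,
                            n_groups = config$null$n_groups,
                            demes_per_group = config$null$demes_per_group,
                            migration = mig,
                            n_bins = config$null$n_bins,
                            min_per_bin = config$null$min_per_bin,
                            seed = derive_seed(seed0, "null"))
  pv <- outlier_pvalues(fst_h$per_snp, null_tab)
  res$null_table <- null_tab
  res$outliers <- cbind(fst_h$per_snp, pv)

  # -- HMM segmentation and island classification -----------------------
  model <- fit_hmm(pv$z, gm_maf$loci$chrom, n_restarts = config$hmm$n_restarts,
                   seed = derive_seed(seed0, "hmm"))
  decoded <- decode_states(model, pv$z, gm_maf$loci$chrom,
                           method = config$hmm$decode)
  islands <- call_islands(decoded, gm_maf$loci, fdr = config$hmm$fdr,
                          state = "high")
  low_regions <- call_islands(decoded, gm_maf$loci, fdr = config$hmm$fdr,
                              state = "low")
  member_idx <- unlist(islands$snps)
  snp_flags <- if (length(member_idx) > 0)
    classify_parallel_snps(gm_maf, member_idx, contrasts = config$contrasts,
                           alpha = config$hmm$alpha_parallel,
                           n_perm = config$hmm$n_perm_parallel,
                           seed = derive_seed(seed0, "parallel"))
  else NULL
  islands <- classify_islands(islands, snp_flags, alpha = config$hmm$alpha_parallel)
  res$hmm_model <- model
  res$decoded <- decoded
  res$islands <- islands
  res$low_regions <- low_regions
  res$snp_flags <- snp_flags
  res$outliers$state <- decoded$state
  res$outliers$p_high <- decoded$p_high

  # -- genomic context ---------------------------------------------------
  cm <- interpolate_genetic_position(map, gm_maf$loci)
  loci_cm <- gm_maf$loci; loci_cm$cm <- cm
  rate <- estimate_recombination_rate(map, gm_maf$loci)
  set.seed(derive_seed(seed0, "ripley"))
  ripley <- ripley_k_test(pv$p_out < config$ripley$alpha, loci_cm,
                          n_null = config$ripley$n_null)
  island_class <- rep("background", nrow(gm_maf$loci))
  for (k in seq_len(nrow(islands)))
    island_class[islands$snps[[k]]] <- islands$class[k]
  assoc <- recomb_association_tests(rate, island_class,
                                    list(hierarchical = fst_h$per_snp$fst),
                                    gm_maf$loci$chrom)
  res$recomb_rate <- rate
  res$ripley <- ripley
  res$assoc <- assoc

  # -- diversity windows -------------------------------------------------
  am <- sample_allele_dataset(gm, seed = derive_seed(seed0, "alleles"))
  win <- build_windows(rad_loci, min_sites = config$diversity$min_sites)
  wpi <- window_pi(am, win)
  div <- label_and_test(wpi, islands)
  res$diversity <- div

  # -- QTL overlap: physical and genetic coordinates ---------------------
  ipd <- islands[islands$class == "IPD", , drop = FALSE]
  if (nrow(ipd) > 0) {
    chrom_len <- if (!is.null(config$simulate))
      stats::setNames(rep(config$simulate$chrom_length_bp,
                          length(config$simulate$chroms)),
                      config$simulate$chroms)
    else vapply(split(map$bp, map$chrom), max, numeric(1))
    res$qtl <- permutation_test(ipd, qtls, chrom_len,
                                n_perm = config$qtl$n_perm,
                                buffer_bp = config$qtl$buffer_bp,
                                seed = derive_seed(seed0, "qtl_perm"))
    # genetic-map coordinates control for recombination-rate variation
    # inflating physical confidence intervals
    to_cm <- function(d) {
      d2 <- d
      d2$start <- interpolate_genetic_position(map, data.frame(
        chrom = d$chrom, pos = d$start))
      d2$end <- interpolate_genetic_position(map, data.frame(
        chrom = d$chrom, pos = d$end))
      d2$end <- pmax(d2$end, d2$start + 1e-9)
      d2
    }
    chrom_len_cm <- vapply(split(map$cm, map$chrom), max, numeric(1))
    buffer_cm <- config$qtl$buffer_bp * mean(chrom_len_cm) /
      mean(chrom_len[names(chrom_len_cm)])
    res$qtl_genetic <- suppressWarnings(
      permutation_test(to_cm(ipd), to_cm(qtls), chrom_len_cm,
                       n_perm = config$qtl$n_perm, buffer_bp = buffer_cm,
                       seed = derive_seed(seed0, "qtl_perm_cm")))
  }
  res$qtls <- qtls

  # -- truth recovery (synthetic runs) ----------------------------------
  if (!is.null(truth) && nrow(res$sim$islands) > 0)
    res$recovery <- evaluate_island_recovery(islands, res$sim$islands)

  write_pipeline_outputs(res, out_dir)
  invisible(res)
}

#' Match called islands against planted truth
#'
#' A planted island is recovered when a called island overlaps it (bp
#' overlap of the called extent with the planted interval); its label
#' agrees when the overlapping called island's IPD/IND class matches the
#' planted parallel flag.
#'
#' @param called classified islands ([classify_islands()]).
#' @param planted island spec with `chrom`, `start`, `end`, `parallel`.
#' @return list: per-planted-island table, `frac_recovered`,
#'   `frac_correct` (recovered AND correctly labelled, over all planted).
#' @export
evaluate_island_recovery <- function(called, planted) {
  recovered <- logical(nrow(planted))
  label_ok <- logical(nrow(planted))
  for (k in seq_len(nrow(planted))) {
    hit <- which(called$chrom == planted$chrom[k] &
                   called$start <= planted$end[k] &
                   called$end >= planted$start[k])
    recovered[k] <- length(hit) > 0
    if (recovered[k]) {
      want <- if (planted$parallel[k]) "IPD" else "IND"
      label_ok[k] <- any(called$class[hit] == want)
    }
  }
  list(table = data.frame(planted[, c("chrom", "start", "end", "parallel")],
                          recovered = recovered, label_ok = label_ok),
       frac_recovered = mean(recovered),
       frac_correct = mean(recovered & label_ok))
}

write_pipeline_outputs <- function(res, out_dir) {
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$outliers, "per_snp_outliers.tsv")
  isl <- res$islands
  if (nrow(isl) > 0) {
    bed <- data.frame(chrom = isl$chrom, start = isl$start - 1, end = isl$end,
                      id = isl$id, class = isl$class)
    wt(bed, "islands.bed")
    wt(isl[, setdiff(names(isl), "snps")], "islands.tsv")
  }
  wt(res$diversity$windows, "diversity_windows.tsv")
  wt(res$diversity$tests, "diversity_tests.tsv")
  wt(res$assoc, "recomb_associations.tsv")
  if (!is.null(res$qtl)) wt(res$qtl, "qtl_overlap.tsv")
  if (!is.null(res$qtl_genetic)) wt(res$qtl_genetic, "qtl_overlap_genetic.tsv")
  manifest <- list(
    seed = res$config$seed,
    n_samples = length(res$gm$samples),
    n_snps_total = nrow(res$gm$loci),
    n_snps_maf = nrow(res$fst_hier$per_snp),
    fst_weighted = res$fst_hier$fst_wt,
    fct_weighted = res$fst_hier$fct_wt,
    migration = as.list(res$null_table$sim_config$migration),
    n_islands = nrow(res$islands),
    n_ipd = sum(res$islands$class == "IPD"),
    n_low_regions = nrow(res$low_regions),
    hmm_means = res$hmm_model$mean)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Write a genotype matrix as a VCF file with popmap and hierarchy TSVs
#'
#' @param gm a [genotype_matrix()].
#' @param dir output directory; writes `data.vcf`, `popmap.tsv`,
#'   `hierarchy.tsv`.
#' @return (invisibly) the VCF path.
#' @export
write_dataset_vcf <- function(gm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "data.vcf")
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(gm$loci))) {
    g <- gm$genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(gm$loci$chrom[j], gm$loci$pos[j], ".",
                       gm$loci$ref[j], gm$loci$alt[j],
                       format(gm$loci$qual[j]), "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  close(con)
  utils::write.table(data.frame(names(gm$populations), gm$populations),
                     file.path(dir, "popmap.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(names(gm$hierarchy), gm$hierarchy),
                     file.path(dir, "hierarchy.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
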