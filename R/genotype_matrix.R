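#' Genotype matrix with population labels and a population-group hierarchy
#'
#' Container for diploid biallelic genotypes: an individuals x SNPs integer
#' matrix counting copies of the alternate allele (0, 1, 2 or `NA` for
#' missing), sample-to-population labels, a population-to-group hierarchy and
#' a locus table. Loci are stored sorted by (chromosome, position), with
#' chromosomes kept in their order of first appearance.
#'
#' @param genotypes integer matrix, samples x loci, values in {0,1,2,NA}.
#' @param loci data.frame with at least `chrom` and `pos` (1-based bp);
#'   optional columns `ref`, `alt`, `qual`, `is_indel`, `multiallelic`.
#' @param populations named character vector mapping sample id to population.
#' @param hierarchy named character vector mapping population to group.
#' @param gq,dp optional numeric matrices of per-genotype quality and depth,
#'   same dimensions as `genotypes`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, loci, populations, hierarchy,
                            gq = NULL, dp = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- rownames(genotypes)
  if (is.null(samples)) stop("genotypes must have sample ids as rownames")
  bad <- setdiff(samples, names(populations))
  if (length(bad) > 0)
    stop("sample(s) missing from population map: ", paste(bad, collapse = ", "))
  populations <- populations[samples]
  badp <- setdiff(unique(populations), names(hierarchy))
  if (length(badp) > 0)
    stop("population(s) missing from hierarchy: ", paste(badp, collapse = ", "))
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) > 0 && (min(vals) < 0L || max(vals) > 2L))
    stop("genotype values must be in {0, 1, 2, NA}")
  loci <- as.data.frame(loci)
  stopifnot(all(c("chrom", "pos") %in% names(loci)), nrow(loci) == ncol(genotypes))
  if (any(loci$pos < 1)) stop("positions must be >= 1")
  for (col in c("is_indel", "multiallelic"))
    if (is.null(loci[[col]])) loci[[col]] <- FALSE
  if (is.null(loci$maf)) loci$maf <- NA_real_
  if (is.null(loci$cm)) loci$cm <- NA_real_
  chrom_lv <- unique(as.character(loci$chrom))
  ord <- order(match(as.character(loci$chrom), chrom_lv), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  genotypes <- genotypes[, ord, drop = FALSE]
  if (!is.null(gq)) gq <- gq[, ord, drop = FALSE]
  if (!is.null(dp)) dp <- dp[, ord, drop = FALSE]
  structure(list(genotypes = genotypes, loci = loci, samples = samples,
                 populations = populations, hierarchy = hierarchy,
                 gq = gq, dp = dp, filter_log = numeric(0)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x", nrow(x$loci),
      "SNPs;", length(unique(x$populations)), "populations in",
      length(unique(x$hierarchy)), "groups\n")
  if (length(x$filter_log) > 0) {
    cat("filter log:\n")
    for (nm in names(x$filter_log)) cat("  ", nm, ":", x$filter_log[[nm]], "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

# subset loci by index, keeping metadata and filter log in step
subset_loci <- function(gm, keep) {
  gm$genotypes <- gm$genotypes[, keep, drop = FALSE]
  gm$loci <- gm$loci[keep, , drop = FALSE]
  rownames(gm$loci) <- NULL
  if (!is.null(gm$gq)) gm$gq <- gm$gq[, keep, drop = FALSE]
  if (!is.null(gm$dp)) gm$dp <- gm$dp[, keep, drop = FALSE]
  gm
}

log_filter <- function(gm, rule, n) {
  gm$filter_log[rule] <- unname(n)
  gm
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file with `vcfR`, attaches the sample-to-population map
#' and population-to-group hierarchy, and returns a [genotype_matrix()].
#' Multi-allelic records are retained but flagged in `loci$multiallelic` for
#' removal by [apply_site_filters()]; gene copies of a third or higher allele
#' are coded missing so genotype values stay in {0,1,2,NA}. Indel records are
#' flagged in `loci$is_indel`.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param popmap two-column data.frame (sample, population) or path to a
#'   headerless two-column TSV.
#' @param hierarchy two-column data.frame (population, group) or TSV path.
#' @return a [genotype_matrix()] with per-genotype GQ and DP matrices when the
#'   VCF provides them.
#' @export
read_vcf <- function(path, popmap, hierarchy) {
  if (is.character(popmap))
    popmap <- utils::read.table(popmap, header = FALSE, sep = "\t",
                                col.names = c("sample", "population"),
                                stringsAsFactors = FALSE)
  if (is.character(hierarchy))
    hierarchy <- utils::read.table(hierarchy, header = FALSE, sep = "\t",
                                   col.names = c("population", "group"),
                                   stringsAsFactors = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  # require coordinate order within chromosome
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) stop("VCF is not coordinate-sorted on chromosome ", ch)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  multiallelic <- grepl(",", alt, fixed = TRUE)
  alt1 <- sub(",.*$", "", alt)
  is_indel <- nchar(ref) != 1L | (nchar(alt1) != 1L & !multiallelic) |
    (multiallelic & vapply(strsplit(alt, ",", fixed = TRUE),
                           function(a) any(nchar(a) != 1L), logical(1)))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  popv <- stats::setNames(as.character(popmap[[2]]), as.character(popmap[[1]]))
  bad <- setdiff(samples, names(popv))
  if (length(bad) > 0)
    stop("sample(s) missing from population map: ", paste(bad, collapse = ", "))
  hier <- stats::setNames(as.character(hierarchy[[2]]), as.character(hierarchy[[1]]))

  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  a1[a1 > 1L] <- NA_integer_
  a2[a2 > 1L] <- NA_integer_
  g <- a1 + a2
  g <- matrix(g, nrow = nrow(gt), dimnames = dimnames(gt))
  geno <- t(g) # samples x loci

  has_gq <- grepl("(^|:)GQ(:|$)", unique(vcf@gt[, "FORMAT"]))
  has_dp <- grepl("(^|:)DP(:|$)", unique(vcf@gt[, "FORMAT"]))
  gq <- if (any(has_gq))
    t(matrix(suppressWarnings(as.numeric(vcfR::extract.gt(vcf, "GQ"))),
             nrow = nrow(gt), dimnames = dimnames(gt))) else NULL
  dp <- if (any(has_dp))
    t(matrix(suppressWarnings(as.numeric(vcfR::extract.gt(vcf, "DP"))),
             nrow = nrow(gt), dimnames = dimnames(gt))) else NULL

  loci <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     qual = qual, is_indel = is_indel,
                     multiallelic = multiallelic, stringsAsFactors = FALSE)
  genotype_matrix(geno, loci, popv, hier, gq = gq, dp = dp)
}

#' Mask low-confidence genotypes
#'
#' Sets to missing every genotype whose quality or depth falls below the
#' thresholds (strict `<`, so GQ 30 / DP 10 are retained). Genotypes lacking
#' a GQ or DP annotation are treated as failing.
#'
#' @param gm a [genotype_matrix()].
#' @param min_gq,min_dp genotype quality and depth thresholds.
#' @return the matrix with failing genotypes set to `NA`; the count of masked
#'   genotypes is recorded in `filter_log`.
#' @export
apply_genotype_filters <- function(gm, min_gq = 30, min_dp = 10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  called <- !is.na(gm$genotypes)
  fail_gq <- if (is.null(gm$gq)) called else (is.na(gm$gq) | gm$gq < min_gq)
  fail_dp <- if (is.null(gm$dp)) called else (is.na(gm$dp) | gm$dp < min_dp)
  fail <- called & (fail_gq | fail_dp)
  gm$genotypes[fail] <- NA_integer_
  log_filter(gm, "genotypes_masked", sum(fail))
}

pop_missing_fraction <- function(gm) {
  pops <- unique(gm$populations)
  miss <- vapply(pops, function(p) {
    rows <- gm$populations == p
    colMeans(is.na(gm$genotypes[rows, , drop = FALSE]))
  }, numeric(nrow(gm$loci)))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = 1)
  apply(miss, 1, max)
}

is_monomorphic <- function(gm) {
  ac <- colSums(gm$genotypes, na.rm = TRUE)
  n <- colSums(!is.na(gm$genotypes))
  n == 0L | ac == 0L | ac == 2L * n
}

#' Site-level filters
#'
#' Removes, in order: sites with QUAL below `min_qual`; sites with more than
#' `max_missing_per_pop` missing genotypes in any single population;
#' multi-allelic records (>2 alleles); indels and SNPs within
#' `indel_buffer_bp` of an indel; all sites on excluded chromosomes; and
#' monomorphic sites (including sites made monomorphic by genotype masking).
#' Each removed site is counted once, under the first rule that removes it.
#'
#' @param gm a [genotype_matrix()].
#' @param min_qual site QUAL threshold (strict `<` removes).
#' @param max_missing_per_pop maximum tolerated missing-genotype fraction per
#'   population (strict `>` removes).
#' @param indel_buffer_bp SNPs within this many bp of an indel are removed.
#' @param excluded_chroms chromosomes dropped entirely (default the sex
#'   chromosome XIX).
#' @return the filtered matrix with per-rule removal counts in `filter_log`.
#' @export
apply_site_filters <- function(gm, min_qual = 30, max_missing_per_pop = 0.5,
                               indel_buffer_bp = 10,
                               excluded_chroms = "XIX") {
  stopifnot(inherits(gm, "genotype_matrix"))
  L <- nrow(gm$loci)
  removed <- rep(NA_character_, L)
  qual <- gm$loci$qual
  if (!is.null(qual)) {
    bad <- !is.na(qual) & qual < min_qual
    removed[is.na(removed) & bad] <- "site_qual"
  }
  bad <- pop_missing_fraction(gm) > max_missing_per_pop
  removed[is.na(removed) & bad] <- "missingness"
  removed[is.na(removed) & gm$loci$multiallelic] <- "multiallelic"
  # indels and SNPs within the buffer of an indel
  indel <- gm$loci$is_indel
  near <- rep(FALSE, L)
  if (any(indel)) {
    for (ch in unique(gm$loci$chrom[indel])) {
      on_ch <- gm$loci$chrom == ch
      ip <- gm$loci$pos[on_ch & indel]
      sp <- gm$loci$pos[on_ch]
      idx <- findInterval(sp, sort(ip))
      lo <- sort(ip)[pmax(idx, 1L)]
      hi <- sort(ip)[pmin(idx + 1L, length(ip))]
      near[on_ch] <- pmin(abs(sp - lo), abs(sp - hi)) <= indel_buffer_bp
    }
  }
  removed[is.na(removed) & (indel | near)] <- "indel_proximity"
  removed[is.na(removed) & gm$loci$chrom %in% excluded_chroms] <- "excluded_chrom"
  removed[is.na(removed) & is_monomorphic(gm)] <- "monomorphic"

  keep <- is.na(removed)
  counts <- table(removed[!keep])
  out <- subset_loci(gm, which(keep))
  out$filter_log <- gm$filter_log
  for (nm in c("site_qual", "missingness", "multiallelic", "indel_proximity",
               "excluded_chrom", "monomorphic"))
    out$filter_log[nm] <- unname(ifelse(nm %in% names(counts), counts[[nm]], 0L))
  out
}

# exact conditional distribution of heterozygote count given sample size n
# (diploids) and minor-allele copy count, after Levene; returns probabilities
# over feasible heterozygote counts (same parity as the allele count)
hwe_exact_probs <- function(n, n_alt) {
  n_ref <- 2L * n - n_alt
  hmax <- min(n_alt, n_ref)
  h <- seq.int(n_alt %% 2L, hmax, by = 2L)
  logp <- h * log(2) + lfactorial(n) + lfactorial(n_alt) + lfactorial(n_ref) -
    lfactorial((n_alt - h) / 2) - lfactorial(h) - lfactorial((n_ref - h) / 2) -
    lfactorial(2L * n)
  p <- exp(logp - max(logp))
  stats::setNames(p / sum(p), h)
}

# one-sided (heterozygote-deficit) and two-sided exact HWE p for observed
# heterozygote count
hwe_exact_p <- function(n, n_alt, n_het, two_sided = FALSE) {
  pr <- hwe_exact_probs(n, n_alt)
  h <- as.integer(names(pr))
  if (two_sided) sum(pr[pr <= pr[h == n_het] * (1 + 1e-12)])
  else sum(pr[h <= n_het])
}

#' Remove sites with an excess of homozygotes
#'
#' Drops every site at which, within any single population, an exact
#' Hardy-Weinberg test detects a deficit of heterozygotes at `p < alpha`.
#' The test is one-sided towards heterozygote deficit by default, matching
#' the targeted artifact (PCR-duplicate-driven apparent homozygosity);
#' `two_sided = TRUE` removes on significant deviation in either direction.
#' Populations with fewer than two non-missing genotypes at a site are
#' skipped for that site.
#'
#' @param gm a [genotype_matrix()].
#' @param alpha significance level of the exact test.
#' @param two_sided use the two-sided exact deviation test instead.
#' @return the filtered matrix; removals logged under `hwe_homozygote_excess`.
#' @export
hwe_excess_homozygote_filter <- function(gm, alpha = 0.01, two_sided = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$populations)
  L <- nrow(gm$loci)
  bad <- rep(FALSE, L)
  cache <- new.env(parent = emptyenv())
  for (p in pops) {
    g <- gm$genotypes[gm$populations == p, , drop = FALSE]
    n <- colSums(!is.na(g))
    nh <- colSums(g == 1L, na.rm = TRUE)
    na_ <- colSums(g, na.rm = TRUE)
    for (j in seq_len(L)) {
      if (bad[j] || n[j] < 2L) next
      if (na_[j] == 0L || na_[j] == 2L * n[j]) next
      key <- paste(n[j], na_[j], nh[j], two_sided, sep = "_")
      pv <- cache[[key]]
      if (is.null(pv)) {
        pv <- hwe_exact_p(n[j], na_[j], nh[j], two_sided)
        cache[[key]] <- pv
      }
      if (pv < alpha) bad[j] <- TRUE
    }
  }
  out <- subset_loci(gm, which(!bad))
  out$filter_log <- gm$filter_log
  out$filter_log["hwe_homozygote_excess"] <- sum(bad)
  out
}

# reproducible per-SNP seed: depends on the locus identity, not its index,
# so subsetting SNPs leaves the draws of the remaining SNPs unchanged
snp_seed <- function(seed, chrom, pos) {
  h <- vapply(chrom, function(ch) sum(utf8ToInt(ch)), numeric(1))
  as.integer((as.numeric(seed) + h * 1000003 + as.numeric(pos) * 31) %% 2147483647)
}

#' Sample one allele per genotype (random-allele dataset)
#'
#' For every non-missing genotype, draws one of the two gene copies uniformly
#' at random: homozygotes always yield their allele, heterozygotes yield 0 or
#' 1 with equal probability. Used to sidestep the homozygote-excess bias of
#' PCR duplicates in analyses that cannot model inbreeding.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param seed integer seed; draws are keyed per SNP so that subsetting SNPs
#'   does not change the draws at the remaining SNPs.
#' @return an `allele_matrix`: one allele in {0,1,NA} per (sample, SNP).
#' @export
sample_allele_dataset <- function(gm, seed) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes
  al <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  al[g == 0L] <- 0L
  al[g == 2L] <- 1L
  seeds <- snp_seed(seed, gm$loci$chrom, gm$loci$pos)
  ns <- nrow(g)
  for (j in seq_len(ncol(g))) {
    het <- which(g[, j] == 1L)
    if (length(het) == 0L) next
    set.seed(seeds[j])
    u <- stats::runif(ns)
    al[het, j] <- as.integer(u[het] < 0.5)
  }
  structure(list(alleles = al, loci = gm$loci, samples = gm$samples,
                 populations = gm$populations, hierarchy = gm$hierarchy,
                 seed = seed),
            class = "allele_matrix")
}

#' Minor allele frequency over pooled non-missing calls
#'
#' @param x a [genotype_matrix()] or `allele_matrix`.
#' @return numeric vector of per-SNP minor allele frequencies in \[0, 0.5\].
#' @export
compute_maf <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    ac <- colSums(x$genotypes, na.rm = TRUE)
    n <- 2 * colSums(!is.na(x$genotypes))
  } else if (inherits(x, "allele_matrix")) {
    ac <- colSums(x$alleles, na.rm = TRUE)
    n <- colSums(!is.na(x$alleles))
  } else stop("unsupported input")
  f <- ifelse(n > 0, ac / n, NA_real_)
  pmin(f, 1 - f)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains SNPs whose minor allele frequency, computed over all non-missing
#' calls pooled across populations of the object passed in, is strictly
#' greater than `threshold`.
#'
#' @param x a [genotype_matrix()] or `allele_matrix`.
#' @param threshold MAF cutoff (strict `>` retains).
#' @return the filtered object with `loci$maf` filled in.
#' @export
maf_filter <- function(x, threshold = 0.01) {
  maf <- compute_maf(x)
  keep <- which(!is.na(maf) & maf > threshold)
  if (inherits(x, "genotype_matrix")) {
    x$loci$maf <- maf
    out <- subset_loci(x, keep)
    out$filter_log <- x$filter_log
    out$filter_log["maf"] <- nrow(x$loci) - length(keep)
    return(out)
  }
  x$loci$maf <- maf
  x$alleles <- x$alleles[, keep, drop = FALSE]
  x$loci <- x$loci[keep, , drop = FALSE]
  rownames(x$loci) <- NULL
  x
}
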