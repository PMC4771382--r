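# VCF ingest, genotype/site filters, HWE homozygote-excess filter, the
# random-allele dataset and the MAF filter.

basic_vcf <- function(path) {
  gt <- matrix(c("0/0", "0/1", "1/1",
                 "0/1", "./.", "0/0"), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  gq <- matrix(99L, 2, 3); dp <- matrix(50L, 2, 3)
  write_test_vcf(path, chrom = c("I", "I"), pos = c(100L, 200L),
                 ref = c("A", "C"), alt = c("T", "G"), qual = c(60, 60),
                 gt = gt, gq = gq, dp = dp)
}

popmap3 <- data.frame(sample = c("s1", "s2", "s3"),
                      population = c("A", "A", "B"))
hier3 <- data.frame(population = c("A", "B"), group = c("g1", "g2"))

test_that("read_vcf parses genotypes, missing cells and metadata", {
  f <- withr::local_tempfile(fileext = ".vcf")
  basic_vcf(f)
  gm <- read_vcf(f, popmap3, hier3)
  expect_equal(dim(gm), c(3L, 2L))
  expect_equal(unname(gm$genotypes[, 1]), c(0L, 1L, 2L))
  expect_true(is.na(gm$genotypes["s2", 2]))
  expect_equal(unname(gm$populations["s3"]), "B")
  expect_equal(gm$loci$pos, c(100L, 200L))
})

test_that("read_vcf errors name the offending sample and reject unsorted input", {
  f <- withr::local_tempfile(fileext = ".vcf")
  basic_vcf(f)
  expect_error(read_vcf(f, popmap3[1:2, ], hier3), "s3")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix("0/0", 2, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  write_test_vcf(f2, chrom = c("I", "I"), pos = c(200L, 100L),
                 ref = c("A", "C"), alt = c("T", "G"), qual = c(60, 60),
                 gt = gt)
  expect_error(read_vcf(f2, popmap3, hier3), "sorted")
})

test_that("multi-allelic records are retained but flagged", {
  f <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix(c("0/0", "0/2", "1/1"), nrow = 1,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  write_test_vcf(f, "I", 100L, "A", "T,G", 60, gt)
  gm <- read_vcf(f, popmap3, hier3)
  expect_true(gm$loci$multiallelic)
  expect_true(is.na(gm$genotypes["s2", 1])) # third allele not representable
  gm2 <- apply_site_filters(gm)
  expect_equal(nrow(gm2$loci), 0L)
})

test_that("genotype filter masks on strict thresholds and treats missing annotations as failing", {
  f <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix(c("0/1", "0/1", "0/1",
                 "0/1", "0/1", "0/1"), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  gq <- matrix(c(29L, 30L, 99L, 31L, 45L, 99L), 2, 3, byrow = TRUE)
  dp <- matrix(c(50L, 10L, 9L, 10L, 50L, 50L), 2, 3, byrow = TRUE)
  write_test_vcf(f, c("I", "I"), c(100L, 200L), c("A", "C"), c("T", "G"),
                 c(60, 60), gt, gq, dp)
  gm <- apply_genotype_filters(read_vcf(f, popmap3, hier3))
  expect_true(is.na(gm$genotypes["s1", 1]))   # GQ 29 < 30
  expect_equal(gm$genotypes["s2", 1], 1L)     # GQ 30, DP 10 kept (strict <)
  expect_true(is.na(gm$genotypes["s3", 1]))   # DP 9
  expect_false(anyNA(gm$genotypes[, 2]))
  expect_equal(unname(gm$filter_log["genotypes_masked"]), 2)

  # identity when everything passes
  f2 <- withr::local_tempfile(fileext = ".vcf")
  basic_vcf(f2)
  gm2 <- read_vcf(f2, popmap3, hier3)
  gm3 <- apply_genotype_filters(gm2)
  expect_identical(gm3$genotypes, gm2$genotypes)

  # missing annotations fail the filter
  f3 <- withr::local_tempfile(fileext = ".vcf")
  gt3 <- matrix("0/1", 1, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  write_test_vcf(f3, "I", 100L, "A", "T", 60, gt3) # GT only, no GQ/DP
  gm4 <- apply_genotype_filters(read_vcf(f3, popmap3, hier3))
  expect_true(all(is.na(gm4$genotypes)))
})

test_that("site filters remove by QUAL, missingness, indel proximity and chromosome", {
  n <- 10
  ids <- paste0("i", 1:n)
  geno <- matrix(1L, n, 7, dimnames = list(ids, NULL))
  geno[, 2] <- c(rep(NA_integer_, 6), 1L, 0L, 2L, 1L)   # 6/10 missing in pop A
  geno[, 6] <- 0L                                        # monomorphic
  loci <- data.frame(chrom = c("I", "I", "I", "I", "XIX", "I", "I"),
                     pos = c(100L, 300L, 500L, 507L, 200L, 900L, 700L),
                     qual = c(10, 60, 60, 60, 60, 60, 60),
                     is_indel = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
                     multiallelic = FALSE)
  gm <- genotype_matrix(geno, loci, stats::setNames(rep("A", n), ids),
                        c(A = "g"))
  out <- apply_site_filters(gm, max_missing_per_pop = 0.5)
  # QUAL 10, >50% missing, the indel, the SNP 7 bp from it, the XIX site and
  # the monomorphic site all go; only the clean SNP at 700 survives
  expect_equal(out$loci$pos, 700L)
})

test_that("site filter accounting: every removal counted once, totals add up", {
  n <- 10
  ids <- paste0("i", 1:n)
  geno <- matrix(rep(c(0L, 1L), length.out = n), n, 7,
                 dimnames = list(ids, NULL))
  geno[, 3] <- 2L # monomorphic alt
  loci <- data.frame(chrom = c("I", "I", "I", "I", "I", "XIX", "II"),
                     pos = c(100L, 300L, 400L, 500L, 508L, 200L, 50L),
                     qual = c(10, 60, 60, 60, 60, 60, 60),
                     is_indel = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                     multiallelic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  gm <- genotype_matrix(geno, loci, stats::setNames(rep("A", n), ids), c(A = "g"))
  out <- apply_site_filters(gm)
  removed <- nrow(gm$loci) - nrow(out$loci)
  expect_equal(removed,
               sum(out$filter_log[c("site_qual", "missingness", "multiallelic",
                                    "indel_proximity", "excluded_chrom",
                                    "monomorphic")]))
  expect_equal(unname(out$filter_log["site_qual"]), 1)
  expect_equal(unname(out$filter_log["indel_proximity"]), 2) # indel + 8bp SNP
  expect_equal(unname(out$filter_log["excluded_chrom"]), 1)
  expect_equal(unname(out$filter_log["multiallelic"]), 1)
  expect_equal(unname(out$filter_log["monomorphic"]), 1)
  # idempotence
  out2 <- apply_site_filters(out)
  expect_identical(out2$loci$pos, out$loci$pos)
  expect_identical(out2$genotypes, out$genotypes)
})

test_that("HWE filter removes homozygote excess, one-sided by default", {
  n <- 20
  ids <- paste0("i", 1:n)
  geno <- cbind(rep(c(0L, 2L), each = 10),            # extreme hom excess
                rep(c(0L, 1L, 2L), c(5, 10, 5)),      # exact HW proportions
                rep(c(0L, 1L), c(1, 19)))             # heterozygote excess
  rownames(geno) <- ids
  gm <- make_gm(geno, rep("A", n))
  # oracle agreement for the exact test itself
  expect_equal(islandscan:::hwe_exact_p(10, 10, 0), hwe_oracle_p(10, 10, 0),
               tolerance = 1e-12)
  expect_equal(islandscan:::hwe_exact_p(12, 7, 5, two_sided = TRUE),
               hwe_oracle_p(12, 7, 5, two_sided = TRUE), tolerance = 1e-12)
  out <- hwe_excess_homozygote_filter(gm)
  expect_equal(out$loci$pos, c(2L, 3L))  # hom-excess site removed
  expect_equal(unname(out$filter_log["hwe_homozygote_excess"]), 1)
  # two-sided removes the heterozygote-excess site as well
  out2 <- hwe_excess_homozygote_filter(gm, two_sided = TRUE)
  expect_equal(out2$loci$pos, 2L)
  # idempotence
  out3 <- hwe_excess_homozygote_filter(out)
  expect_identical(out3$loci$pos, out$loci$pos)
})

test_that("random-allele sampling forces homozygotes and is fair and stable for heterozygotes", {
  geno <- cbind(c(0L, 2L, 1L), c(2L, 0L, 1L))
  rownames(geno) <- paste0("i", 1:3)
  gm <- make_gm(geno, rep("A", 3))
  am <- sample_allele_dataset(gm, seed = 7)
  expect_equal(unname(am$alleles[1, 1]), 0L)
  expect_equal(unname(am$alleles[2, 1]), 1L)
  expect_true(am$alleles[3, 1] %in% c(0L, 1L))
  expect_true(is.na(sample_allele_dataset(
    make_gm(matrix(NA_integer_, 1, 1, dimnames = list("i1", NULL)), "A"),
    seed = 1)$alleles[1, 1]))

  # heterozygote draws are Bernoulli(1/2): frequency over many seeds
  geno2 <- matrix(1L, 1, 1, dimnames = list("i1", NULL))
  gm2 <- make_gm(geno2, "A")
  draws <- vapply(1:4000, function(s)
    sample_allele_dataset(gm2, seed = s)$alleles[1, 1], integer(1))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 4000) + 1e-9)

  # per-SNP keying: subsetting SNPs leaves remaining draws unchanged
  geno3 <- matrix(1L, 4, 5, dimnames = list(paste0("i", 1:4), NULL))
  gm3 <- make_gm(geno3, rep("A", 4))
  full <- sample_allele_dataset(gm3, seed = 42)
  sub <- sample_allele_dataset(islandscan:::subset_loci(gm3, c(2, 4)), seed = 42)
  expect_identical(full$alleles[, c(2, 4)], sub$alleles)
})

test_that("allele sampling preserves expected allele frequencies", {
  set.seed(5)
  geno <- matrix(sample(0:2, 40 * 30, replace = TRUE), 40, 30,
                 dimnames = list(paste0("i", 1:40), NULL))
  gm <- make_gm(geno, rep("A", 40))
  freq_g <- colMeans(geno) / 2
  reps <- 60
  acc <- matrix(0, reps, 30)
  for (r in seq_len(reps))
    acc[r, ] <- colMeans(sample_allele_dataset(gm, seed = r)$alleles)
  mc_se <- apply(acc, 2, sd) / sqrt(reps)
  # allow the occasional 3-sigma excursion among 30 simultaneous checks
  n_beyond <- sum(abs(colMeans(acc) - freq_g) > 3 * mc_se + 1e-9)
  expect_lte(n_beyond, 2)
})

test_that("MAF is pooled and the filter threshold is strict", {
  # singleton alternate allele in 91 diploids: maf = 1/182
  geno <- matrix(0L, 91, 3, dimnames = list(paste0("i", 1:91), NULL))
  geno[1, 1] <- 1L
  geno[, 2] <- rep(c(0L, 1L), length.out = 91)  # common
  geno[1:2, 3] <- 1L                            # maf = 2/182 = 0.011
  gm <- make_gm(geno, rep("A", 91))
  maf <- compute_maf(gm)
  expect_equal(maf[1], 1 / 182)
  out <- maf_filter(gm, threshold = 0.01)
  expect_equal(out$loci$pos, c(2L, 3L))
  # exact boundary: maf == threshold is removed
  geno2 <- matrix(0L, 50, 1, dimnames = list(paste0("i", 1:50), NULL))
  geno2[1, 1] <- 1L  # maf = 1/100 = 0.01
  expect_equal(nrow(maf_filter(make_gm(geno2, rep("A", 50)),
                               threshold = 0.01)$loci), 0L)
})
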