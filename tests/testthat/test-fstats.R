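# Locus-by-locus AMOVA F-statistics: exact oracle agreement, limiting cases,
# robustness to inbreeding, windows, CV and LD.

test_that("fixed allelic difference gives F_ST exactly 1", {
  geno <- rbind(matrix(0L, 5, 3), matrix(2L, 5, 3))
  gm <- make_gm(geno, rep(c("A", "B"), each = 5))
  r <- pairwise_fst(gm, "A", "B")
  expect_identical(unname(r$per_snp$fst), rep(1, 3))
  expect_identical(r$fst_wt, 1)
})

test_that("AMOVA components match the brute-force oracle on small fixtures", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    pops <- sample(c("A", "B"), n, replace = TRUE)
    while (min(table(pops)) < 2) pops <- sample(c("A", "B"), n, replace = TRUE)
    geno <- matrix(sample(c(0:2, NA), n * 4, replace = TRUE,
                          prob = c(0.3, 0.3, 0.3, 0.1)), n, 4)
    gm <- make_gm(geno, pops)
    r <- pairwise_fst(gm, "A", "B")
    for (j in 1:4) {
      g <- gm$genotypes[, j]
      byp <- split(g, pops)
      if (any(vapply(byp, function(v) sum(!is.na(v)), 0) < 2)) {
        expect_true(is.na(r$per_snp$fst[j]))
        next
      }
      o <- amova_oracle(g, pops)
      if (!is.finite(o$fst)) next
      expect_equal(r$per_snp$fst[j], o$fst, tolerance = 1e-10)
      expect_equal(r$per_snp$fis[j], o$fis, tolerance = 1e-10)
    }
  }
})

test_that("hierarchical AMOVA matches the nested brute-force oracle", {
  set.seed(202)
  groups <- c(A = "g1", B = "g1", C = "g2", D = "g3")
  for (rep in 1:6) {
    pops <- rep(c("A", "B", "C", "D"), times = sample(2:3, 4, replace = TRUE))
    n <- length(pops)
    geno <- matrix(sample(0:2, n * 3, replace = TRUE), n, 3)
    gm <- make_gm(geno, pops, groups = groups)
    r <- hierarchical_fst(gm)
    for (j in 1:3) {
      o <- amova_oracle(gm$genotypes[, j], pops, groups)
      if (!is.finite(o$fst)) next
      expect_equal(r$per_snp$fst[j], o$fst, tolerance = 1e-10)
      expect_equal(r$per_snp$fct[j], o$fct, tolerance = 1e-10)
      expect_equal(r$per_snp$fsc[j], o$fsc, tolerance = 1e-10)
    }
  }
})

test_that("hierarchical saturation and degenerate hierarchy behave as documented", {
  # groups fixed for alternate alleles, pops within groups identical
  geno <- rbind(matrix(0L, 6, 2), matrix(2L, 6, 2))
  pops <- rep(c("A", "B", "C", "D"), each = 3)
  gm <- make_gm(geno, pops, groups = c(A = "g1", B = "g1", C = "g2", D = "g2"))
  r <- hierarchical_fst(gm)
  expect_equal(unname(r$per_snp$fst), rep(1, 2))
  expect_equal(unname(r$per_snp$fct), rep(1, 2))   # all variance among groups
  # identical frequencies everywhere -> F_ST near 0
  set.seed(3)
  geno2 <- matrix(rbinom(40 * 200, 2, 0.4), 40, 200)
  gm2 <- make_gm(geno2, rep(c("A", "B", "C", "D"), each = 10),
                 groups = c(A = "g1", B = "g1", C = "g2", D = "g2"))
  expect_lt(abs(hierarchical_fst(gm2)$fst_wt), 0.01)
  # one group -> warning and pairwise fallback
  gm3 <- make_gm(geno2[1:20, ], rep(c("A", "B"), each = 10),
                 groups = c(A = "g1", B = "g1"))
  expect_warning(r3 <- hierarchical_fst(gm3), "single group")
  expect_equal(r3$model, "pairwise")
})

test_that("panmictic samples give weighted F_ST near zero", {
  set.seed(7)
  L <- 5000
  p <- runif(L, 0.1, 0.9)
  geno <- matrix(rbinom(100 * L, 2, rep(p, each = 100)), 100, L)
  gm <- make_gm(geno, rep(c("A", "B"), each = 50))
  expect_lt(abs(pairwise_fst(gm, "A", "B")$fst_wt), 0.005)
})

test_that("pairwise F_ST is robust to inbreeding while F_IS tracks it", {
  set.seed(11)
  L <- 4000
  p1 <- runif(L, 0.2, 0.8)
  p2 <- pmin(pmax(p1 + rnorm(L, 0, 0.15), 0.01), 0.99)
  sim_pop <- function(p, n, fis) {
    a1 <- matrix(rbinom(n * L, 1, rep(p, each = n)), n, L)
    a2 <- matrix(rbinom(n * L, 1, rep(p, each = n)), n, L)
    ibd <- matrix(runif(n * L) < fis, n, L)
    a2[ibd] <- a1[ibd]
    a1 + a2
  }
  fst_at <- function(fis) {
    geno <- rbind(sim_pop(p1, 30, fis), sim_pop(p2, 30, fis))
    gm <- make_gm(geno, rep(c("A", "B"), each = 30))
    r <- pairwise_fst(gm, "A", "B")
    c(fst = r$fst_wt, fis = r$fis_wt)
  }
  res <- vapply(c(0, 0.3, 0.6), fst_at, numeric(2))
  expect_lt(max(res["fst", ]) - min(res["fst", ]), 0.02)
  expect_true(all(abs(res["fis", ] - c(0, 0.3, 0.6)) < 0.03))
})

test_that("permutation test: maximal statistic, and power on structured data", {
  geno <- rbind(matrix(0L, 8, 20), matrix(2L, 8, 20))
  gm <- make_gm(geno, rep(c("A", "B"), each = 8))
  r <- permutation_significance(gm, "A", "B", n_perm = 199, seed = 1)
  expect_equal(r$p_value, 1 / 200)
  # planted differentiation is detected
  set.seed(21)
  L <- 800
  p <- runif(L, 0.2, 0.8)
  pa <- islandscan:::bn_draw(p, 0.05)
  pb <- islandscan:::bn_draw(p, 0.05)
  geno2 <- rbind(matrix(rbinom(20 * L, 2, rep(pa, each = 20)), 20, L),
                 matrix(rbinom(20 * L, 2, rep(pb, each = 20)), 20, L))
  gm2 <- make_gm(geno2, rep(c("A", "B"), each = 20))
  r2 <- permutation_significance(gm2, "A", "B", n_perm = 999, seed = 2)
  expect_lt(r2$p_value, 0.001 + 1e-9)
})

test_that("permutation p-values are well calibrated under the null", {
  set.seed(31)
  L <- 150
  p <- runif(L, 0.2, 0.8)
  pvals <- vapply(1:60, function(r) {
    geno <- matrix(rbinom(16 * L, 2, rep(p, each = 16)), 16, L)
    gm <- make_gm(geno, rep(c("A", "B"), each = 8))
    permutation_significance(gm, "A", "B", n_perm = 99)$p_value
  }, numeric(1))
  # super-uniform or uniform: not concentrated low
  expect_gt(suppressWarnings(ks.test(pvals, "punif", alternative = "greater")$p.value),
            0.01)
})

test_that("window summaries follow the 20-SNP rule and direct arithmetic", {
  set.seed(4)
  fst <- c(runif(40), runif(19))
  loci <- data.frame(chrom = c(rep("I", 40), rep("II", 19)),
                     pos = c(sort(sample.int(2e6, 40)),
                             sort(sample.int(2e6, 19))))
  w <- window_fst(fst, loci, window_bp = 2e6, min_snps = 20)
  expect_equal(nrow(w), 1L)           # 19-SNP window omitted
  expect_equal(w$chrom, "I")
  expect_equal(w$n_snps, 40L)
  expect_equal(w$mean_fst, mean(fst[1:40]))
  expect_equal(w$sd_fst, sd(fst[1:40]))
  expect_equal(w$q95_fst, unname(quantile(fst[1:40], 0.95)))
  # constant values
  w2 <- window_fst(rep(0.3, 25), data.frame(chrom = "I", pos = 1:25))
  expect_equal(c(w2$mean_fst, w2$sd_fst, w2$q95_fst), c(0.3, 0, 0.3))
})

test_that("heterogeneity CV matches direct computation and is sign-invariant", {
  w <- data.frame(chrom = c("I", "I", "I"), start = c(0, 2e6, 4e6),
                  end = c(2e6, 4e6, 6e6), n_snps = 30,
                  mean_fst = c(0.1, 0.2, 0.3))
  cv <- heterogeneity_cv(w)
  expect_equal(cv$cv_genome, 0.5)
  w$mean_fst <- -w$mean_fst
  expect_equal(heterogeneity_cv(w)$cv_genome, 0.5)
  w$mean_fst <- rep(0.2, 3)
  expect_equal(heterogeneity_cv(w)$cv_genome, 0)
})

test_that("LD |r| handles self-pairs, perfect correlation and the null level", {
  geno <- cbind(c(0L, 0L, 2L, 2L), c(2L, 2L, 0L, 0L), c(0L, 2L, 0L, 2L))
  gm <- make_gm(geno, rep("A", 4))
  ld <- pairwise_ld(gm, 1:3, "A")
  expect_equal(ld[1, 1], 1)
  expect_equal(ld[1, 2], 1)    # perfect negative correlation -> |r| = 1
  # zero-variance locus yields NA
  geno2 <- cbind(c(0L, 1L, 2L, 1L), rep(1L, 4))
  ld2 <- pairwise_ld(make_gm(geno2, rep("A", 4)), 1:2, "A")
  expect_true(is.na(ld2[1, 2]))
  # independent loci at n = 200: mean |r| near E|r| = sqrt(2/(pi*n))
  set.seed(17)
  geno3 <- matrix(rbinom(200 * 120, 2, 0.5), 200, 120)
  ld3 <- pairwise_ld(make_gm(geno3, rep("A", 200)), 1:120, "A")
  off <- ld3[upper.tri(ld3)]
  expect_lt(abs(mean(off) - sqrt(2 / (pi * 200))), 0.01)
})
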