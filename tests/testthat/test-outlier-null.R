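# Hierarchical-island-model null: engine cross-validation, island-model
# expectations, inbreeding handling, migration calibration and the
# heterozygosity-conditioned p-values.

small_cfg <- sample_config(pop = c("p1", "p2", "p3"),
                           group = c("a", "b", "b"),
                           n_dip = c(10, 10, 10), fis = 0)

test_that("null simulation is deterministic under a seed", {
  a <- simulate_null(small_cfg, n_sims = 500, migration = c(among = 2, within = 5),
                     min_per_bin = 50, seed = 99)
  b <- simulate_null(small_cfg, n_sims = 500, migration = c(among = 2, within = 5),
                     min_per_bin = 50, seed = 99)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$edges, b$edges)
})

test_that("lumped and naive coalescent engines draw from the same distribution", {
  set.seed(41)
  a <- islandscan:::sim_null_replicates(2500, small_cfg, 3, 5, 3, 1.5,
                                        engine = "naive")
  b <- islandscan:::sim_null_replicates(2500, small_cfg, 3, 5, 3, 1.5,
                                        engine = "lumped")
  ks_fst <- suppressWarnings(ks.test(a$cmp$fst, b$cmp$fst))
  ks_h <- suppressWarnings(ks.test(a$cmp$h_bp, b$cmp$h_bp))
  expect_gt(ks_fst$p.value, 0.01)
  expect_gt(ks_h$p.value, 0.01)
  # and with inbreeding switched on
  cfgf <- small_cfg; cfgf$fis <- c(0.4, 0.4, 0.4)
  set.seed(42)
  af <- islandscan:::sim_null_replicates(2000, cfgf, 3, 5, 3, 1.5, engine = "naive")
  bf <- islandscan:::sim_null_replicates(2000, cfgf, 3, 5, 3, 1.5, engine = "lumped")
  expect_gt(suppressWarnings(ks.test(af$cmp$fst, bf$cmp$fst))$p.value, 0.01)
})

test_that("fis = 1 makes every simulated individual homozygous", {
  cfgf <- small_cfg; cfgf$fis <- c(1, 1, 1)
  set.seed(5)
  s <- islandscan:::sim_null_replicates(300, cfgf, 10, 100, 5, 1)
  expect_true(all(s$counts$n1 == 0L))
})

test_that("mean simulated F_ST follows the island-model expectation in a single group", {
  # one group of d demes is a plain finite island model:
  # F_ST ~ 1/(1 + M (d/(d-1))^2) for scaled migration M = 4Nm
  cfg1 <- sample_config(pop = c("p1", "p2"), group = c("a", "a"),
                        n_dip = c(20, 20), fis = 0)
  set.seed(55)
  for (M in c(2, 8)) {
    s <- islandscan:::sim_null_replicates(4000, cfg1, 1, 10, M, 0)
    cmp <- s$cmp
    fst_hat <- sum(cmp$sig_b, na.rm = TRUE) /
      sum(cmp$sig_b + cmp$sig_i + cmp$sig_w, na.rm = TRUE)
    expected <- 1 / (1 + M * (10 / 9)^2)
    expect_lt(abs(fst_hat - expected) / expected, 0.2)
  }
  # very high migration: mean F_ST collapses towards zero
  s0 <- islandscan:::sim_null_replicates(1500, cfg1, 1, 10, 250, 0)
  expect_lt(mean(s0$cmp$fst, na.rm = TRUE), 0.01)
})

test_that("inbreeding acts as a reduction of the effective number of gene copies", {
  # with IBD probability f, an n-diploid deme contributes 2n(1 - f/2)
  # independent gene copies in expectation; the F_ST and H_BP summaries
  # should therefore agree in mean with an outbred sample of that many
  # copies (the match is in expectation, not in distribution: the genotype
  # configurations remain those of n partially inbred diploids)
  cfg_f <- sample_config(pop = c("p1", "p2"), group = c("a", "b"),
                         n_dip = c(20, 20), fis = 0.5)
  cfg_n <- sample_config(pop = c("p1", "p2"), group = c("a", "b"),
                         n_dip = c(15, 15), fis = 0)   # 2*20*(1-0.25) = 30 copies
  set.seed(77)
  a <- islandscan:::sim_null_replicates(6000, cfg_f, 5, 10, 4, 1)
  b <- islandscan:::sim_null_replicates(6000, cfg_n, 5, 10, 4, 1)
  se <- function(v) sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  d_fst <- abs(mean(a$cmp$fst, na.rm = TRUE) - mean(b$cmp$fst, na.rm = TRUE))
  expect_lt(d_fst, 3 * sqrt(se(a$cmp$fst)^2 + se(b$cmp$fst)^2) + 0.01)
  d_h <- abs(mean(a$cmp$h_bp, na.rm = TRUE) - mean(b$cmp$h_bp, na.rm = TRUE))
  expect_lt(d_h, 3 * sqrt(se(a$cmp$h_bp)^2 + se(b$cmp$h_bp)^2) + 0.01)
  # and the genotype-level signature is as expected: heterozygosity halved
  het_f <- sum(a$counts$n1) / sum(a$counts$n0 + a$counts$n1 + a$counts$n2)
  set.seed(78)
  o <- islandscan:::sim_null_replicates(6000, {
    c0 <- cfg_f; c0$fis <- c(0, 0); c0
  }, 5, 10, 4, 1)
  het_o <- sum(o$counts$n1) / sum(o$counts$n0 + o$counts$n1 + o$counts$n2)
  expect_lt(abs(het_f / het_o - 0.5), 0.05)
})

test_that("migration calibration closes the loop and flags infeasible targets", {
  mig <- calibrate_migration(0.05, 0.08, small_cfg, n_groups = 6,
                             demes_per_group = 20, n_reps = 2000, seed = 6)
  ach <- attr(mig, "achieved")
  se <- attr(mig, "achieved_se")
  expect_lt(abs(ach[["fct"]] - 0.05), 0.005 + 3 * se[["fct"]] + 1e-9)
  expect_lt(abs(ach[["fsc"]] - 0.08), 0.008 + 3 * se[["fsc"]] + 1e-9)
  # near-zero target lands at the high-migration boundary
  mig0 <- calibrate_migration(0.002, 0.002, small_cfg, n_groups = 5,
                              demes_per_group = 10, n_reps = 800, seed = 7)
  expect_equal(unname(mig0[["among"]]), 150)
  set.seed(8)
  s <- islandscan:::sim_null_replicates(800, small_cfg, 5, 10,
                                        mig0[["within"]], mig0[["among"]])
  expect_lt(abs(mean(s$cmp$fst, na.rm = TRUE)), 0.005)
  # a target above the island-model maximum cannot converge
  expect_error(calibrate_migration(0.995, 0.1, small_cfg, n_reps = 400,
                                   seed = 9),
               "maximum")
})

test_that("outlier p-values follow the rank formula and map to signed z", {
  set.seed(3)
  nt <- structure(list(
    replicates = data.frame(h_bp = runif(999), fst = runif(999)),
    edges = c(-Inf, Inf),
    fst_by_bin = list(sort(runif(999)))), class = "null_table")
  v <- nt$fst_by_bin[[1]]
  obs <- data.frame(h_bp = c(0.5, 0.5, 0.5),
                    fst = c(max(v) + 1, stats::median(v), min(v) - 1))
  pv <- outlier_pvalues(obs, nt)
  expect_lte(pv$p_out[1], 0.001)                 # above every null value
  expect_gt(pv$p_out[1], 0)
  expect_equal(pv$p_out[2], 0.5, tolerance = 0.01)
  expect_gte(pv$p_out[3], 0.999)                 # below every null value
  expect_gt(pv$z[1], 3)
  expect_lt(pv$z[3], -3)
  expect_true(all(pv$p_out > 0 & pv$p_out < 1))
  expect_true(all(is.finite(pv$z)))
  # the deterministic mid-rank option reproduces the classic formula
  pvm <- outlier_pvalues(obs, nt, ties = "midrank")
  expect_equal(pvm$p_out[1], 0.5 / 1000)
  # heterozygosity outside the binned range warns and uses the nearest bin
  nt2 <- nt; nt2$edges <- c(0.2, 0.8)
  expect_warning(outlier_pvalues(data.frame(h_bp = 0.9, fst = 0.5), nt2),
                 "outside")
})

test_that("p-values are calibrated against a matched null (reduced scale)", {
  set.seed(13)
  mig <- c(among = 1, within = 8)
  nt <- simulate_null(small_cfg, n_sims = 12000, n_groups = 5,
                      demes_per_group = 10, migration = mig,
                      min_per_bin = 400)
  test <- simulate_test_snps(small_cfg, 5000, migration = mig, n_groups = 5,
                             demes_per_group = 10)
  pv <- outlier_pvalues(test, nt)
  expect_lt(abs(mean(pv$p_out < 0.05) - 0.05), 0.015)
  expect_lt(abs(mean(pv$p_out < 0.2) - 0.2), 0.025)
})

test_that("p-values are stable against the size of the null table", {
  set.seed(14)
  mig <- c(among = 1, within = 8)
  test <- simulate_test_snps(small_cfg, 1500, migration = mig, n_groups = 5,
                             demes_per_group = 10)
  nt_small <- simulate_null(small_cfg, n_sims = 6000, n_groups = 5,
                            demes_per_group = 10, migration = mig,
                            min_per_bin = 300, seed = 15)
  nt_big <- simulate_null(small_cfg, n_sims = 24000, n_groups = 5,
                          demes_per_group = 10, migration = mig,
                          min_per_bin = 1200, seed = 16)
  # mid-rank ties isolate the deterministic part of the estimate; the
  # randomized tie-break component is independent noise by construction and
  # would deflate the correlation at tied atoms without being instability
  p1 <- outlier_pvalues(test, nt_small, ties = "midrank")$p_out
  p2 <- outlier_pvalues(test, nt_big, ties = "midrank")$p_out
  expect_gt(cor(p1, p2, method = "spearman"), 0.98)
})
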