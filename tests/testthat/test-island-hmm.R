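# Three-state Gaussian HMM: fitting, decoding, island calling at a region
# FDR, and parallel-differentiation classification.

sim_z <- function(n_bg = 4000, n_chrom = 8, islands = list(), seed = 1) {
  # islands: list of c(chrom_index, start_offset, length, shift)
  set.seed(seed)
  chrom <- rep(sprintf("c%02d", seq_len(n_chrom)), each = ceiling(n_bg / n_chrom))
  chrom <- chrom[seq_len(n_bg)]
  z <- rnorm(n_bg)
  truth <- list()
  for (isl in islands) {
    idx <- which(chrom == sprintf("c%02d", isl[1]))
    s <- idx[isl[2]]
    span <- s:(s + isl[3] - 1)
    z[span] <- rnorm(isl[3], isl[4], 1)
    truth[[length(truth) + 1]] <- c(s, s + isl[3] - 1)
  }
  list(z = z, chrom = chrom, truth = truth,
       loci = data.frame(chrom = chrom, pos = seq_along(z)))
}

test_that("pure-noise data yields no islands and no confident extreme states", {
  # on N(0,1) noise the EM may still split the Gaussian across states (a
  # plain mixture-likelihood gain), but no SNP should be a confident member
  # of an extreme state and nothing should survive island calling
  d <- sim_z(4000, 4, seed = 2)
  m <- suppressWarnings(fit_hmm(d$z, d$chrom, n_restarts = 3))
  dec <- decode_states(m, d$z, d$chrom)
  expect_equal(nrow(call_islands(dec, d$loci, fdr = 0.001, state = "high")), 0L)
  expect_equal(nrow(call_islands(dec, d$loci, fdr = 0.001, state = "low")), 0L)
  expect_lt(max(pmax(dec$p_high, dec$p_low)), 0.999)
})

test_that("planted high blocks are recovered with a sensible emission mean", {
  d <- sim_z(4000, 8, islands = list(c(1, 50, 30, 4), c(3, 100, 30, 4),
                                     c(5, 200, 30, 4)), seed = 3)
  m <- fit_hmm(d$z, d$chrom, n_restarts = 5)
  expect_gt(m$mean[3], 3)
  expect_lt(m$mean[3], 5)
  expect_true(all(diff(m$mean) > 0))          # ordering constraint
  expect_true(all(abs(rowSums(m$trans) - 1) < 1e-8))
  dec <- decode_states(m, d$z, d$chrom)
  for (tr in d$truth)
    expect_gt(mean(dec$state[tr[1]:tr[2]] == "high"), 0.8)
  # any island that is actually called coincides with a planted block
  isl <- call_islands(dec, d$loci, fdr = 0.001)
  truth_idx <- unlist(lapply(d$truth, function(t) t[1]:t[2]))
  for (k in seq_len(nrow(isl)))
    expect_true(all(abs(range(isl$snps[[k]]) -
                          range(intersect(isl$snps[[k]], truth_idx))) <= 2))
})

test_that("chromosome order does not change the fitted parameters", {
  d <- sim_z(3000, 6, islands = list(c(2, 30, 25, 4)), seed = 4)
  m1 <- suppressWarnings(fit_hmm(d$z, d$chrom, n_restarts = 3, seed = 9))
  ord <- order(match(d$chrom, rev(unique(d$chrom))))
  m2 <- suppressWarnings(fit_hmm(d$z[ord], d$chrom[ord], n_restarts = 3, seed = 9))
  expect_equal(m1$mean, m2$mean, tolerance = 1e-5)
  expect_equal(m1$sd, m2$sd, tolerance = 1e-5)
  expect_equal(m1$loglik, m2$loglik, tolerance = 1e-6)
})

test_that("decoding limiting cases", {
  model <- structure(list(mean = c(-4, 0, 4), sd = c(1, 1, 1),
                          trans = matrix(c(0.99, 0.005, 0.005,
                                           0.005, 0.99, 0.005,
                                           0.005, 0.005, 0.99), 3, 3, byrow = TRUE),
                          init = c(0.005, 0.99, 0.005),
                          states = c("low", "background", "high")),
                     class = "hmm_model")
  one <- decode_states(model, 0, "I")
  expect_equal(as.character(one$state), "background")
  all_high <- decode_states(model, rep(4, 50), rep("I", 50))
  expect_true(all(all_high$state == "high"))
  # viterbi agrees on clean data
  vit <- decode_states(model, c(rep(0, 20), rep(4, 20)), rep("I", 40),
                       method = "viterbi")
  expect_true(all(vit$state[31:40] == "high"))
})

test_that("island calling applies the running-mean local FDR rule", {
  loci <- data.frame(chrom = rep("I", 6), pos = 1:6)
  mk_dec <- function(p_high) {
    data.frame(state = factor(ifelse(p_high > 0.5, "high", "background"),
                              levels = c("low", "background", "high")),
               p_low = 0, p_background = 1 - p_high, p_high = p_high)
  }
  # single isolated SNP above / below the threshold
  expect_equal(nrow(call_islands(mk_dec(c(0, 0.9994, 0, 0, 0, 0)), loci,
                                 fdr = 0.001)), 1L)
  expect_equal(nrow(call_islands(mk_dec(c(0, 0.99, 0, 0, 0, 0)), loci,
                                 fdr = 0.001)), 0L)
  # nothing decoded high
  expect_equal(nrow(call_islands(mk_dec(rep(0, 6)), loci)), 0L)
  # running mean: a clean candidate carries a borderline one
  dec2 <- mk_dec(c(0.99995, 0.99995, 0, 0.9986, 0, 0))
  out2 <- call_islands(dec2, loci, fdr = 0.001)
  expect_equal(nrow(out2), 2L)   # mean local fdr (0.00005+0.0014)/2 < 0.001
  # islands never span chromosomes
  loci2 <- data.frame(chrom = c("I", "I", "II", "II"), pos = c(1, 2, 1, 2))
  dec3 <- mk_dec(rep(0.9999, 4))
  out3 <- call_islands(dec3, loci2, fdr = 0.01)
  expect_equal(nrow(out3), 2L)
  expect_equal(out3$id, c("I.1", "II.1"))
})

test_that("planted islands are recovered and neutral data yields no calls", {
  d <- sim_z(10000, 20,
             islands = lapply(1:10, function(k) c(k, 40 + 13 * k, 15, 5)),
             seed = 6)
  m <- fit_hmm(d$z, d$chrom)
  dec <- decode_states(m, d$z, d$chrom)
  isl <- call_islands(dec, d$loci, fdr = 0.001)
  hits <- vapply(d$truth, function(tr)
    any(abs(isl$start - tr[1]) <= 2 & abs(isl$end - tr[2]) <= 2), logical(1))
  expect_gte(sum(hits), 9)
})

test_that("island recovery improves with shift and with island size", {
  grid_rec <- matrix(NA_real_, 3, 3)
  shifts <- c(1, 3, 6); lens <- c(3, 8, 15)
  for (i in 1:3) for (j in 1:3) {
    d <- sim_z(6000, 12,
               islands = lapply(1:10, function(k) c(k, 30 + 11 * k, lens[j],
                                                    shifts[i])),
               seed = 100 + 10 * i + j)
    m <- suppressWarnings(fit_hmm(d$z, d$chrom, n_restarts = 3))
    dec <- decode_states(m, d$z, d$chrom)
    isl <- call_islands(dec, d$loci, fdr = 0.001)
    grid_rec[i, j] <- mean(vapply(d$truth, function(tr)
      any(isl$start <= tr[2] & isl$end >= tr[1]), logical(1)))
  }
  # recovery at the strongest setting is high, at the weakest negligible,
  # and the marginal trend over shift is non-decreasing at the largest size
  expect_gt(grid_rec[3, 3], 0.8)
  expect_lt(grid_rec[1, 1], 0.3)
  expect_true(all(diff(grid_rec[, 3]) >= -0.10))
  expect_true(all(diff(grid_rec[3, ]) >= -0.10))
})

test_that("parallel-SNP classification follows direction and significance", {
  # build genotypes with known per-population frequencies
  set.seed(8)
  freqs <- list(
    parallel   = c(L1 = 0.9, S1 = 0.15, L2 = 0.85, S2 = 0.1),
    conflicting = c(L1 = 0.1, S1 = 0.9, L2 = 0.9, S2 = 0.1),
    one_sided  = c(L1 = 0.1, S1 = 0.9, L2 = 0.5, S2 = 0.5),
    tied       = c(L1 = 0.5, S1 = 0.5, L2 = 0.2, S2 = 0.8))
  n <- 25
  geno <- do.call(cbind, lapply(freqs, function(f)
    unlist(lapply(f, function(p) rbinom(n, 2, p)))))
  pops <- rep(c("L1", "S1", "L2", "S2"), each = n)
  gm <- make_gm(geno, pops)
  fl <- classify_parallel_snps(gm, 1:4, contrasts = list(c("L1", "S1"),
                                                         c("L2", "S2")),
                               n_perm = 499, seed = 11)
  expect_true(fl$parallel[1])
  expect_false(fl$parallel[2])   # direction conflict
  expect_false(fl$parallel[3])   # not significant in the second contrast
  # exact frequency tie in a contrast fails the strict inequality
  geno_tie <- cbind(c(rep(1L, n), rep(1L, n), rbinom(n, 2, 0.2), rbinom(n, 2, 0.8)))
  gm_tie <- make_gm(geno_tie, pops)
  fl_tie <- classify_parallel_snps(gm_tie, 1, n_perm = 199, seed = 12)
  expect_false(fl_tie$parallel[1])
})

test_that("islands are classified IPD with >= 1 parallel member SNP", {
  islands <- data.frame(id = c("I.1", "II.1"), chrom = c("I", "II"),
                        start = c(1, 1), end = c(3, 2), n_snps = c(3L, 2L),
                        local_fdr = 1e-4)
  islands$snps <- list(1:3, 4:5)
  flags <- data.frame(snp = 1:5, parallel = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                      p1 = c(0.01, 0.01, 0.2, 0.6, 0.01),
                      p2 = c(0.03, 0.01, 0.3, 0.9, 0.2))
  out <- classify_islands(islands, flags)
  expect_equal(out$class, c("IPD", "IND"))
  expect_equal(out$n_sig_sympatry, c(2L, 1L))
  expect_equal(out$n_sig_parapatry, c(2L, 0L))
  empty <- call_islands(
    data.frame(state = factor("background", levels = c("low", "background", "high")),
               p_low = 0, p_background = 1, p_high = 0),
    data.frame(chrom = "I", pos = 1))
  expect_equal(nrow(classify_islands(empty, flags)), 0L)
})

test_that("refits from random initialisations reach the generating likelihood", {
  set.seed(15)
  # generate from a known sticky 3-state model with well-separated means
  n <- 4000
  A <- matrix(c(0.98, 0.01, 0.01, 0.01, 0.98, 0.01, 0.01, 0.01, 0.98), 3, 3,
              byrow = TRUE)
  mu <- c(-4, 0, 4)
  s <- integer(n); s[1] <- 2
  for (t in 2:n) s[t] <- sample(1:3, 1, prob = A[s[t - 1], ])
  z <- rnorm(n, mu[s], 1)
  chrom <- rep("I", n)
  m <- fit_hmm(z, chrom, n_restarts = 10, seed = 16)
  # likelihood of the generating parameters
  gen_ll <- islandscan:::cpp_hmm_posterior(z, n, mu, rep(1, 3), A,
                                           c(0.01, 0.98, 0.01))$loglik
  expect_gt(m$loglik, gen_ll - 1e-3)
  dec <- decode_states(m, z, chrom)
  expect_gt(mean(as.integer(dec$state) == s), 0.95)
})
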