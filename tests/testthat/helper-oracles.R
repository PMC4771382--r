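# Independent oracles and fixture builders. The oracles are deliberately
# coded as plain loops from first principles, independent of the package's
# vectorized implementations.

# build a genotype_matrix from a genotype matrix and a population vector
make_gm <- function(geno, pops, groups = NULL, chrom = NULL, pos = NULL) {
  n <- nrow(geno); L <- ncol(geno)
  ids <- paste0("ind", seq_len(n))
  rownames(geno) <- ids
  if (is.null(groups)) {
    u <- unique(pops)
    groups <- stats::setNames(paste0("grp_", u), u)
  }
  if (is.null(chrom)) chrom <- rep("I", L)
  if (is.null(pos)) pos <- seq_len(L)
  genotype_matrix(geno, data.frame(chrom = chrom, pos = pos),
                  stats::setNames(pops, ids), groups)
}

# brute-force nested AMOVA on gene copies: explicit loops over individuals
# and copies, sums of squares by direct deviation from group means, variance
# components by solving the expected-mean-square equations
amova_oracle <- function(geno, pops, groups = NULL) {
  # geno: integer vector of per-individual genotypes at one locus
  if (is.null(groups)) groups <- stats::setNames(unique(pops), unique(pops))
  grp <- groups[pops]
  # expand each individual to its two gene copies; a heterozygote is (1, 0)
  # (which copy carries the alternate allele is irrelevant for the sums)
  x <- list()
  for (i in seq_along(geno)) {
    if (is.na(geno[i])) next
    g <- geno[i]
    x[[length(x) + 1]] <- list(pop = pops[i], grp = grp[[pops[i]]],
                               copies = if (g == 0) c(0, 0)
                               else if (g == 1) c(1, 0) else c(1, 1))
  }
  npop <- table(vapply(x, function(e) e$pop, character(1)))
  P <- length(npop)
  G <- length(unique(vapply(x, function(e) e$grp, character(1))))
  all_copies <- unlist(lapply(x, function(e) e$copies))
  grand <- mean(all_copies)

  pop_mean <- sapply(names(npop), function(p)
    mean(unlist(lapply(x, function(e) if (e$pop == p) e$copies))))
  grp_names <- unique(vapply(x, function(e) e$grp, character(1)))
  grp_mean <- sapply(grp_names, function(g)
    mean(unlist(lapply(x, function(e) if (e$grp == g) e$copies))))
  cp <- sapply(names(npop), function(p)
    length(unlist(lapply(x, function(e) if (e$pop == p) e$copies))))
  cg <- sapply(grp_names, function(g)
    length(unlist(lapply(x, function(e) if (e$grp == g) e$copies))))
  C <- sum(cp)

  ss_wi <- 0; ss_ai <- 0; ss_ap <- 0; ss_ag <- 0
  for (e in x) {
    m <- mean(e$copies)
    ss_wi <- ss_wi + sum((e$copies - m)^2)
    ss_ai <- ss_ai + 2 * (m - pop_mean[[e$pop]])^2
  }
  for (p in names(npop))
    ss_ap <- ss_ap + cp[[p]] *
      (pop_mean[[p]] - grp_mean[[grp[[p]]]])^2
  for (g in grp_names)
    ss_ag <- ss_ag + cg[[g]] * (grp_mean[[g]] - grand)^2

  Nind <- length(x)
  ms_wi <- ss_wi / Nind
  ms_ai <- ss_ai / (Nind - P)
  sig_w <- ms_wi
  sig_i <- (ms_ai - ms_wi) / 2
  if (G == 1 || G == P) {
    # single-level among-population analysis (or one pop per group)
    ss_among <- 0
    for (p in names(npop))
      ss_among <- ss_among + cp[[p]] * (pop_mean[[p]] - grand)^2
    nc <- (C - sum(cp^2) / C) / (P - 1)
    ms_ap <- ss_among / (P - 1)
    sig_b <- (ms_ap - ms_ai) / nc
    return(list(sig_b = sig_b, sig_i = sig_i, sig_w = sig_w,
                fst = sig_b / (sig_b + sig_i + sig_w),
                fis = sig_i / (sig_i + sig_w)))
  }
  ms_ap <- ss_ap / (P - G)
  ms_ag <- ss_ag / (G - 1)
  s_c2_cg <- 0
  for (g in grp_names)
    s_c2_cg <- s_c2_cg + sum(cp[grp[names(npop)] == g]^2) / cg[[g]]
  n1 <- (C - s_c2_cg) / (P - G)
  n2 <- (s_c2_cg - sum(cp^2) / C) / (G - 1)
  n3 <- (C - sum(cg^2) / C) / (G - 1)
  sig_b <- (ms_ap - ms_ai) / n1
  sig_a <- (ms_ag - ms_ai - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_i + sig_w
  list(sig_a = sig_a, sig_b = sig_b, sig_i = sig_i, sig_w = sig_w,
       fst = (sig_a + sig_b) / tot, fct = sig_a / tot,
       fsc = sig_b / (sig_b + sig_i + sig_w),
       fis = sig_i / (sig_i + sig_w))
}

# brute-force Ripley's K: double loop over ordered pairs
ripley_oracle <- function(cm, L, t_grid) {
  n <- length(cm)
  K <- numeric(length(t_grid))
  for (k in seq_along(t_grid)) {
    cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j && abs(cm[i] - cm[j]) <= t_grid[k]) cnt <- cnt + 1
    K[k] <- L / n^2 * cnt
  }
  K
}

# exact Hardy-Weinberg p by full enumeration of genotype configurations
# (n0, n1, n2) with n individuals and n_alt alternate copies; probability of
# a configuration under random union of gametes conditional on allele count
# is proportional to n! / (n0! n1! n2!) * 2^n1
hwe_oracle_p <- function(n, n_alt, n_het_obs, two_sided = FALSE) {
  configs <- list()
  for (n2 in 0:min(n, n_alt %/% 2)) {
    n1 <- n_alt - 2 * n2
    n0 <- n - n1 - n2
    if (n1 < 0 || n0 < 0) next
    lw <- lfactorial(n) - lfactorial(n0) - lfactorial(n1) - lfactorial(n2) +
      n1 * log(2)
    configs[[length(configs) + 1]] <- c(n1 = n1, lw = lw)
  }
  m <- do.call(rbind, configs)
  w <- exp(m[, "lw"] - max(m[, "lw"]))
  w <- w / sum(w)
  if (two_sided) {
    p_obs <- w[m[, "n1"] == n_het_obs]
    sum(w[w <= p_obs * (1 + 1e-12)])
  } else sum(w[m[, "n1"] <= n_het_obs])
}

# write a small VCF with GT:GQ:DP fields
write_test_vcf <- function(path, chrom, pos, ref, alt, qual, gt, gq = NULL,
                           dp = NULL, samples = colnames(gt)) {
  con <- file(path, "w")
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">", con)
  writeLines("##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">", con)
  writeLines("##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  fmt <- if (is.null(gq)) "GT" else "GT:GQ:DP"
  for (j in seq_along(pos)) {
    cells <- vapply(seq_along(samples), function(s) {
      if (is.null(gq)) gt[j, s]
      else paste(gt[j, s], gq[j, s], dp[j, s], sep = ":")
    }, character(1))
    writeLines(paste(c(chrom[j], pos[j], ".", ref[j], alt[j], qual[j], "PASS",
                       ".", fmt, cells), collapse = "\t"), con)
  }
  close(con)
  path
}
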