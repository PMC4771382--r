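# Locus-by-locus AMOVA F-statistics on diploid genotypes, with an
# among-individual level so that homozygote excess (inbreeding or PCR
# duplicates) loads on F_IS rather than inflating F_ST.
#
# All estimators work from per-population genotype counts (n0, n1, n2 per
# locus), which makes them shareable between observed data and the coalescent
# null simulator. Sums of squares on gene copies:
#   within individuals     SS = 0.5 * n_het           df = N_ind
#   among ind. within pops SS = 2 * sum_i (xbar_i - xbar_p)^2   df = N_ind - P
#   among pops (and groups) from population/group means of copies
# Expected mean squares (each individual contributes exactly 2 copies, so the
# among-individual coefficient is exactly 2; unbalanced population and group
# coefficients follow the standard nested-ANOVA formulas).

# counts: list of L x P matrices n0, n1, n2. Returns per-locus variance
# components and F-statistics for a single-level (populations only) AMOVA.
amova_components_pairwise <- function(n0, n1, n2) {
  n0 <- as.matrix(n0); n1 <- as.matrix(n1); n2 <- as.matrix(n2)
  np <- n0 + n1 + n2                      # individuals per pop per locus
  cp <- 2 * np                            # gene copies
  ap <- n1 + 2 * n2                       # alt copies
  P <- ncol(np)
  C <- rowSums(cp)
  A <- rowSums(ap)
  xbar <- A / C
  xp <- ifelse(cp > 0, ap / cp, NA_real_)
  Nind <- rowSums(np)

  ss_wi <- 0.5 * rowSums(n1)
  ss_ai <- 2 * rowSums(n2 + 0.25 * n1 - np * ifelse(np > 0, xp^2, 0), na.rm = TRUE)
  ss_ap <- rowSums(cp * (xp - xbar)^2, na.rm = TRUE)

  df_wi <- Nind
  df_ai <- Nind - P
  df_ap <- P - 1
  ms_wi <- ss_wi / df_wi
  ms_ai <- ss_ai / df_ai
  ms_ap <- ss_ap / df_ap
  nc <- (C - rowSums(cp^2) / C) / (P - 1)

  sig_w <- ms_wi
  sig_i <- (ms_ai - ms_wi) / 2
  sig_b <- (ms_ap - ms_ai) / nc
  tot <- sig_b + sig_i + sig_w

  ok <- apply(np >= 2, 1, all)
  bad <- !ok | !is.finite(tot) | tot == 0
  fst <- ifelse(bad, NA_real_, sig_b / tot)
  fis <- ifelse(bad, NA_real_, sig_i / (sig_i + sig_w))
  fit <- ifelse(bad, NA_real_, (sig_b + sig_i) / tot)
  pbar <- rowMeans(xp, na.rm = TRUE)
  h_bp <- 2 * pbar * (1 - pbar)
  list(sig_a = NULL, sig_b = sig_b, sig_i = sig_i, sig_w = sig_w,
       fst = fst, fis = fis, fit = fit, h_bp = h_bp, ok = ok)
}

# counts as above; group: integer vector (length P) assigning populations to
# groups. Four-level nested AMOVA: among groups / among pops within groups /
# among individuals within pops / within individuals.
amova_components_hier <- function(n0, n1, n2, group) {
  n0 <- as.matrix(n0); n1 <- as.matrix(n1); n2 <- as.matrix(n2)
  P <- ncol(n0)
  G <- length(unique(group))
  if (G == 1) {
    # degenerate hierarchy: single-level among-population analysis
    cmp <- amova_components_pairwise(n0, n1, n2)
    cmp$sig_a <- rep(0, nrow(as.matrix(n0)))
    cmp$fct <- rep(0, length(cmp$fst))
    cmp$fsc <- cmp$fst
    return(cmp)
  }
  np <- n0 + n1 + n2
  cp <- 2 * np
  ap <- n1 + 2 * n2
  C <- rowSums(cp)
  A <- rowSums(ap)
  xbar <- A / C
  xp <- ifelse(cp > 0, ap / cp, NA_real_)
  Nind <- rowSums(np)

  cg <- ag <- matrix(0, nrow(np), G)
  for (g in seq_len(G)) {
    cols <- which(group == sort(unique(group))[g])
    cg[, g] <- rowSums(cp[, cols, drop = FALSE])
    ag[, g] <- rowSums(ap[, cols, drop = FALSE])
  }
  xg <- ag / cg
  gidx <- match(group, sort(unique(group)))

  ss_wi <- 0.5 * rowSums(n1)
  ss_ai <- 2 * rowSums(n2 + 0.25 * n1 - np * ifelse(np > 0, xp^2, 0), na.rm = TRUE)
  ss_ap <- rowSums(cp * (xp - xg[, gidx, drop = FALSE])^2, na.rm = TRUE)
  ss_ag <- rowSums(cg * (xg - xbar)^2, na.rm = TRUE)

  df_wi <- Nind
  df_ai <- Nind - P
  df_ap <- P - G
  df_ag <- G - 1
  ms_wi <- ss_wi / df_wi
  ms_ai <- ss_ai / df_ai
  ms_ap <- ss_ap / df_ap
  ms_ag <- ss_ag / df_ag

  # unbalanced nested coefficients on gene-copy counts
  sum_c2_over_cg <- numeric(nrow(np))
  for (g in seq_len(G)) {
    cols <- which(gidx == g)
    sum_c2_over_cg <- sum_c2_over_cg +
      rowSums(cp[, cols, drop = FALSE]^2) / cg[, g]
  }
  sum_c2_over_C <- rowSums(cp^2) / C
  n1c <- (C - sum_c2_over_cg) / df_ap
  n2c <- (sum_c2_over_cg - sum_c2_over_C) / df_ag
  n3c <- (C - rowSums(cg^2) / C) / df_ag

  sig_w <- ms_wi
  sig_i <- (ms_ai - ms_wi) / 2
  if (P == G) {
    # one population per group: the among-populations-within-groups level
    # is empty (zero df); its component is structurally zero
    sig_b <- rep(0, nrow(np))
    sig_a <- (ms_ag - ms_ai) / n3c
  } else {
    sig_b <- (ms_ap - ms_ai) / n1c
    sig_a <- (ms_ag - ms_ai - n2c * sig_b) / n3c
  }
  tot <- sig_a + sig_b + sig_i + sig_w

  ok <- apply(np >= 2, 1, all)
  bad <- !ok | !is.finite(tot) | tot == 0
  fst <- ifelse(bad, NA_real_, (sig_a + sig_b) / tot)
  fct <- ifelse(bad, NA_real_, sig_a / tot)
  fsc <- ifelse(bad, NA_real_, sig_b / (sig_b + sig_i + sig_w))
  fis <- ifelse(bad, NA_real_, sig_i / (sig_i + sig_w))
  fit <- ifelse(bad, NA_real_, (sig_a + sig_b + sig_i) / tot)
  pbar <- rowMeans(xp, na.rm = TRUE)
  h_bp <- 2 * pbar * (1 - pbar)
  list(sig_a = drop(sig_a), sig_b = sig_b, sig_i = sig_i, sig_w = sig_w,
       fst = fst, fct = fct, fsc = fsc, fis = fis, fit = fit,
       h_bp = h_bp, ok = ok)
}

genotype_counts_by_pop <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- unique(gm$populations)
  L <- nrow(gm$loci)
  n0 <- n1 <- n2 <- matrix(0L, L, length(pops),
                           dimnames = list(NULL, pops))
  for (k in seq_along(pops)) {
    g <- gm$genotypes[gm$populations == pops[k], , drop = FALSE]
    n0[, k] <- colSums(g == 0L, na.rm = TRUE)
    n1[, k] <- colSums(g == 1L, na.rm = TRUE)
    n2[, k] <- colSums(g == 2L, na.rm = TRUE)
  }
  list(n0 = n0, n1 = n1, n2 = n2)
}

weighted_ratio <- function(num, den, ok) {
  s <- ok & is.finite(num) & is.finite(den)
  sum(num[s]) / sum(den[s])
}

#' Pairwise locus-by-locus F-statistics between two populations
#'
#' Genotypic AMOVA with an among-individual level, so Hardy-Weinberg
#' equilibrium within populations is not assumed: homozygote excess loads on
#' the within-population (F_IS) component, not on F_ST. Loci with fewer than
#' two non-missing genotypes in either population are skipped (`NA`).
#' Multi-locus weighted means are ratios of summed variance components, with
#' negative per-locus components retained in the sums.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population labels.
#' @return object of class `fst_result`: per-SNP `fst`, `fis`, `fit`, `h_bp`
#'   and weighted multi-locus `fst_wt`, `fis_wt`, `fit_wt`.
#' @export
pairwise_fst <- function(gm, popA, popB) {
  stopifnot(inherits(gm, "genotype_matrix"))
  for (p in c(popA, popB))
    if (!any(gm$populations == p)) stop("empty or unknown population: ", p)
  cn <- genotype_counts_by_pop(gm, c(popA, popB))
  cmp <- amova_components_pairwise(cn$n0, cn$n1, cn$n2)
  structure(list(
    per_snp = data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
                         fst = cmp$fst, fis = cmp$fis, fit = cmp$fit,
                         h_bp = cmp$h_bp),
    fst_wt = weighted_ratio(cmp$sig_b, cmp$sig_b + cmp$sig_i + cmp$sig_w, cmp$ok),
    fis_wt = weighted_ratio(cmp$sig_i, cmp$sig_i + cmp$sig_w, cmp$ok),
    fit_wt = weighted_ratio(cmp$sig_b + cmp$sig_i,
                            cmp$sig_b + cmp$sig_i + cmp$sig_w, cmp$ok),
    pops = c(popA, popB), model = "pairwise"),
    class = "fst_result")
}

#' Hierarchical locus-by-locus F-statistics
#'
#' Four-level nested AMOVA: among groups, among populations within groups,
#' among individuals within populations, within individuals. Returns per-SNP
#' total F_ST (among populations relative to total, i.e. among-group plus
#' among-population components) and the between-population expected
#' heterozygosity H_BP (from the unweighted mean of per-population allele
#' frequencies), the conditioning axis of the outlier test.
#'
#' @param gm a [genotype_matrix()]; its `hierarchy` supplies the grouping.
#' @return an `fst_result` with per-SNP `fst`, `fct`, `fsc`, `fis`, `fit`,
#'   `h_bp` and weighted multi-locus counterparts.
#' @export
hierarchical_fst <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$populations)
  grp <- gm$hierarchy[pops]
  if (length(unique(grp)) < 2) {
    warning("hierarchy has a single group; falling back to one-level AMOVA")
    cn <- genotype_counts_by_pop(gm, pops)
    cmp <- amova_components_pairwise(cn$n0, cn$n1, cn$n2)
    return(structure(list(
      per_snp = data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
                           fst = cmp$fst, fis = cmp$fis, fit = cmp$fit,
                           h_bp = cmp$h_bp),
      fst_wt = weighted_ratio(cmp$sig_b, cmp$sig_b + cmp$sig_i + cmp$sig_w, cmp$ok),
      fis_wt = weighted_ratio(cmp$sig_i, cmp$sig_i + cmp$sig_w, cmp$ok),
      pops = pops, model = "pairwise"), class = "fst_result"))
  }
  cn <- genotype_counts_by_pop(gm, pops)
  cmp <- amova_components_hier(cn$n0, cn$n1, cn$n2, grp)
  tot <- function(c_) c_$sig_a + c_$sig_b + c_$sig_i + c_$sig_w
  structure(list(
    per_snp = data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
                         fst = cmp$fst, fct = cmp$fct, fsc = cmp$fsc,
                         fis = cmp$fis, fit = cmp$fit, h_bp = cmp$h_bp),
    fst_wt = weighted_ratio(cmp$sig_a + cmp$sig_b, tot(cmp), cmp$ok),
    fct_wt = weighted_ratio(cmp$sig_a, tot(cmp), cmp$ok),
    fsc_wt = weighted_ratio(cmp$sig_b, cmp$sig_b + cmp$sig_i + cmp$sig_w, cmp$ok),
    fis_wt = weighted_ratio(cmp$sig_i, cmp$sig_i + cmp$sig_w, cmp$ok),
    fit_wt = weighted_ratio(cmp$sig_a + cmp$sig_b + cmp$sig_i, tot(cmp), cmp$ok),
    pops = pops, groups = grp, model = "hierarchical"),
    class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("fst_result (", x$model, "): ", nrow(x$per_snp), " SNPs; weighted F_ST = ",
      signif(x$fst_wt, 4), "\n", sep = "")
  invisible(x)
}

#' Permutation test of the multi-locus weighted pairwise F_ST
#'
#' Shuffles individuals between the two populations and recomputes the
#' weighted multi-locus F_ST each time;
#' p = (1 + #\{permuted >= observed\}) / (n_perm + 1).
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population labels.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `observed`, `p_value`, `n_perm`.
#' @export
permutation_significance <- function(gm, popA, popB, n_perm = 16000,
                                     seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  rows <- gm$populations %in% c(popA, popB)
  g <- gm$genotypes[rows, , drop = FALSE]
  labA <- gm$populations[rows] == popA
  nA <- sum(labA)
  I0 <- (g == 0L); I0[is.na(I0)] <- FALSE; storage.mode(I0) <- "double"
  I1 <- (g == 1L); I1[is.na(I1)] <- FALSE; storage.mode(I1) <- "double"
  I2 <- (g == 2L); I2[is.na(I2)] <- FALSE; storage.mode(I2) <- "double"
  tot0 <- colSums(I0); tot1 <- colSums(I1); tot2 <- colSums(I2)

  stat_from_assign <- function(idxA) {
    a0 <- colSums(I0[idxA, , drop = FALSE])
    a1 <- colSums(I1[idxA, , drop = FALSE])
    a2 <- colSums(I2[idxA, , drop = FALSE])
    cmp <- amova_components_pairwise(cbind(a0, tot0 - a0),
                                     cbind(a1, tot1 - a1),
                                     cbind(a2, tot2 - a2))
    weighted_ratio(cmp$sig_b, cmp$sig_b + cmp$sig_i + cmp$sig_w, cmp$ok)
  }
  obs <- stat_from_assign(which(labA))
  perm <- vapply(seq_len(n_perm), function(i)
    stat_from_assign(sample.int(nrow(g), nA)), numeric(1))
  list(observed = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm, permuted = perm)
}

#' Windowed summaries of per-SNP F_ST
#'
#' Non-overlapping adjacent windows anchored at coordinate 0 on each
#' chromosome; windows with fewer than `min_snps` SNPs are omitted.
#'
#' @param fst numeric vector of per-SNP F_ST.
#' @param loci data.frame with `chrom` and `pos` aligned to `fst`.
#' @param window_bp window width in bp.
#' @param min_snps minimum SNPs for a window to be reported.
#' @return data.frame: chrom, start, end (half-open), n_snps, mean_fst,
#'   q95_fst, sd_fst.
#' @export
window_fst <- function(fst, loci, window_bp = 2e6, min_snps = 20) {
  stopifnot(length(fst) == nrow(loci))
  win <- (loci$pos - 1) %/% window_bp
  key <- paste(loci$chrom, win, sep = "\r")
  keep <- !is.na(fst)
  sp <- split(fst[keep], key[keep])
  info <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  out <- data.frame(chrom = info[, 1],
                    start = as.numeric(info[, 2]) * window_bp,
                    stringsAsFactors = FALSE)
  out$end <- out$start + window_bp
  out$n_snps <- lengths(sp)
  out$mean_fst <- vapply(sp, mean, numeric(1))
  out$q95_fst <- vapply(sp, function(v) unname(stats::quantile(v, 0.95)), numeric(1))
  out$sd_fst <- vapply(sp, stats::sd, numeric(1))
  out <- out[out$n_snps >= min_snps, , drop = FALSE]
  chrom_lv <- unique(as.character(loci$chrom))
  out <- out[order(match(out$chrom, chrom_lv), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Heterogeneity of differentiation: coefficient of variation of window means
#'
#' The absolute coefficient of variation |sd/mean| of window mean F_ST,
#' genome-wide and per chromosome, plus the median of the per-chromosome
#' values.
#'
#' @param windows output of [window_fst()].
#' @return list with `cv_genome`, `cv_by_chrom`, `cv_median_chrom`.
#' @export
heterogeneity_cv <- function(windows) {
  stopifnot(nrow(windows) >= 2)
  cv <- function(v) {
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) { warning("window mean F_ST is zero; CV undefined"); return(NA_real_) }
    abs(stats::sd(v) / m)
  }
  by_chrom <- vapply(split(windows$mean_fst, windows$chrom), cv, numeric(1))
  list(cv_genome = cv(windows$mean_fst),
       cv_by_chrom = by_chrom,
       cv_median_chrom = stats::median(by_chrom, na.rm = TRUE))
}

#' Pairwise linkage disequilibrium |r| from genotype dosages
#'
#' Absolute Pearson correlation between genotype dosages (0/1/2) at pairs of
#' SNPs, computed within one population with pairwise-complete observations.
#' SNPs with zero dosage variance yield `NA` for their pairs.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_idx integer indices of the SNPs to correlate.
#' @param pop population label.
#' @return symmetric matrix of |r| values.
#' @export
pairwise_ld <- function(gm, snp_idx, pop) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes[gm$populations == pop, snp_idx, drop = FALSE]
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  abs(r)
}
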