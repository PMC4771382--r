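# Joint null distribution of (H_BP, F_ST) under a finite hierarchical island
# model with per-population inbreeding, and heterozygosity-conditioned
# per-SNP outlier p-values.

#' Sampling configuration for the null simulator
#'
#' @param pop population labels of the sampled demes.
#' @param group group label per sampled deme (mirrors the observed grouping).
#' @param n_dip diploids sampled per deme.
#' @param fis per-deme probability that an individual's two gene copies are
#'   identical by descent (inbreeding / PCR-duplicate coefficient).
#' @return data.frame used by [simulate_null()] and [calibrate_migration()].
#' @export
sample_config <- function(pop, group, n_dip, fis = 0) {
  data.frame(pop = pop, group = group, n_dip = as.integer(n_dip),
             fis = rep_len(fis, length(pop)), stringsAsFactors = FALSE)
}

# run the coalescent engine and return per-replicate (h_bp, fst) computed
# with the same inbreeding-aware AMOVA estimator used on observed data
sim_null_replicates <- function(n_sims, scfg, n_groups, demes_per_group,
                                m_within, m_among, engine = "lumped") {
  grp <- match(scfg$group, unique(scfg$group))
  fun <- if (engine == "naive") cpp_sim_hier_island_naive else cpp_sim_hier_island
  sim <- fun(n_sims, grp, scfg$n_dip, scfg$fis,
             n_groups, demes_per_group, m_within, m_among)
  cmp <- amova_components_hier(sim$n0, sim$n1, sim$n2, scfg$group)
  list(cmp = cmp, counts = sim)
}

# pooled minor-allele frequency of each simulated replicate
replicate_maf <- function(counts) {
  ac <- rowSums(counts$n1) + 2 * rowSums(counts$n2)
  n <- 2 * rowSums(counts$n0 + counts$n1 + counts$n2)
  pmin(ac / n, 1 - ac / n)
}

#' Simulate the hierarchical-island-model null table
#'
#' Each replicate simulates the genealogy of one SNP's sampled gene copies
#' under a finite hierarchical island model (structured coalescent: demes
#' nested in groups, migration more frequent within than between groups),
#' places a single infinite-sites mutation uniformly on the tree, forms
#' diploid genotypes with the per-deme inbreeding coefficient (each
#' individual's second gene copy identical by descent with probability
#' `fis`), and records the replicate's between-population heterozygosity and
#' hierarchical F_ST computed with the same AMOVA estimator used for
#' observed data. Replicates with an undefined F_ST are dropped and counted.
#'
#' @param scfg a [sample_config()]: sampled demes, their groups, sizes, fis.
#' @param n_sims number of replicates.
#' @param n_groups,demes_per_group size of the simulated metapopulation
#'   (should exceed the sampled numbers; defaults 10 and 100).
#' @param migration length-2 numeric: scaled migration rates
#'   `c(among = 4*N*m_among, within = 4*N*m_within)` (see
#'   [calibrate_migration()]).
#' @param n_bins target number of equal-count heterozygosity bins.
#' @param min_per_bin bins are merged until each holds at least this many
#'   replicates.
#' @param maf_min replicates with pooled minor allele frequency at or below
#'   this value are excluded from the table, mirroring the SNP class the
#'   scan is run on (use 0 to keep every replicate). Low-frequency variants
#'   have nearly degenerate F_ST given their heterozygosity, so including
#'   them mis-calibrates the conditional ranks for the SNPs actually tested.
#' @param seed RNG seed.
#' @return a `null_table`: replicates (h_bp, fst), bin edges, per-bin sorted
#'   F_ST values, and the simulation configuration.
#' @export
simulate_null <- function(scfg, n_sims = 50000, n_groups = 10,
                          demes_per_group = 100,
                          migration = c(among = 1, within = 10),
                          n_bins = 20, min_per_bin = 500, maf_min = 0.01,
                          seed = NULL) {
  stopifnot(n_groups >= length(unique(scfg$group)))
  if (!is.null(seed)) set.seed(seed)
  rep_ <- sim_null_replicates(n_sims, scfg, n_groups, demes_per_group,
                              m_within = migration[["within"]],
                              m_among = migration[["among"]])
  cmp <- rep_$cmp
  keep <- is.finite(cmp$fst) & is.finite(cmp$h_bp) &
    replicate_maf(rep_$counts) > maf_min
  tab <- data.frame(h_bp = cmp$h_bp[keep], fst = cmp$fst[keep])
  n_dropped <- sum(!keep)

  # equal-count bins with adaptive merging
  n_bins_eff <- max(1L, min(n_bins, floor(nrow(tab) / min_per_bin)))
  edges <- unique(stats::quantile(tab$h_bp, probs = seq(0, 1, length.out = n_bins_eff + 1),
                                  names = FALSE))
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  bin <- findInterval(tab$h_bp, edges, rightmost.closed = TRUE)
  # merge small bins into their left neighbour
  repeat {
    cnt <- tabulate(bin, nbins = length(edges) - 1)
    small <- which(cnt > 0 & cnt < min_per_bin)
    if (length(small) == 0 || length(edges) <= 2) break
    k <- small[1]
    drop_edge <- if (k == 1) 2L else k
    edges <- edges[-drop_edge]
    bin <- findInterval(tab$h_bp, edges, rightmost.closed = TRUE)
  }
  by_bin <- lapply(seq_len(length(edges) - 1),
                   function(b) sort(tab$fst[bin == b]))
  structure(list(replicates = tab, edges = edges, fst_by_bin = by_bin,
                 n_dropped = n_dropped,
                 sim_config = list(n_groups = n_groups,
                                   demes_per_group = demes_per_group,
                                   n_sims = n_sims, migration = migration,
                                   maf_min = maf_min,
                                   sample_config = scfg)),
            class = "null_table")
}

#' @export
print.null_table <- function(x, ...) {
  cat("null_table:", nrow(x$replicates), "replicates,",
      length(x$fst_by_bin), "heterozygosity bins; mean F_ST =",
      signif(mean(x$replicates$fst), 4), "\n")
  invisible(x)
}

#' Simulate test SNPs from the hierarchical island model
#'
#' Draws SNPs from the identical model used for the null table and returns
#' their (h_bp, fst) pairs, e.g. for self-calibration checks of the outlier
#' p-values. Replicates are drawn in batches until `n_snps` pass the minor
#' allele frequency restriction.
#'
#' @inheritParams simulate_null
#' @param n_snps number of test SNPs to return.
#' @return data.frame with `h_bp`, `fst`, `maf` (`n_snps` rows).
#' @export
simulate_test_snps <- function(scfg, n_snps, migration, n_groups = 10,
                               demes_per_group = 100, maf_min = 0.01,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  got <- 0L
  while (got < n_snps) {
    draw <- max(2000L, ceiling((n_snps - got) * 1.25))
    rep_ <- sim_null_replicates(draw, scfg, n_groups, demes_per_group,
                                m_within = migration[["within"]],
                                m_among = migration[["among"]])
    maf <- replicate_maf(rep_$counts)
    keep <- is.finite(rep_$cmp$fst) & maf > maf_min
    out[[length(out) + 1]] <- data.frame(h_bp = rep_$cmp$h_bp[keep],
                                         fst = rep_$cmp$fst[keep],
                                         maf = maf[keep])
    got <- got + sum(keep)
  }
  utils::head(do.call(rbind, out), n_snps)
}

#' Calibrate migration rates to observed differentiation
#'
#' Chooses the among-group and within-group scaled migration rates of the
#' hierarchical island model so that the simulated mean among-group (F_CT)
#' and among-population-within-group (F_SC) differentiation match the
#' observed values. Uses alternating log-scale bisections (among-group rate
#' against F_CT, then within-group rate against F_SC), each mean estimated
#' from `n_reps` coalescent replicates.
#'
#' @param target_fct,target_fsc observed multi-locus F_CT and F_SC.
#' @param scfg a [sample_config()].
#' @param n_groups,demes_per_group metapopulation size.
#' @param n_reps replicates per bisection evaluation.
#' @param tol relative tolerance on each matched component.
#' @param max_steps bisection steps per 1-D search.
#' @param seed RNG seed.
#' @return named numeric `c(among=, within=)` of scaled migration rates,
#'   with the achieved (F_CT, F_SC) as attribute `achieved`.
#' @export
calibrate_migration <- function(target_fct, target_fsc, scfg,
                                n_groups = 10, demes_per_group = 100,
                                n_reps = 2000, tol = 0.1, max_steps = 50,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(target_fct >= 0, target_fsc >= 0)
  # migration-rate bracket (log scale); at the upper bound differentiation is
  # already indistinguishable from zero, so targets below it are returned as
  # the high-migration boundary
  lo <- 1e-3; hi <- 150
  eval_fs <- function(m_a, m_w) {
    cmp <- sim_null_replicates(n_reps, scfg, n_groups, demes_per_group,
                               m_within = m_w, m_among = m_a)$cmp
    ok <- cmp$ok & is.finite(cmp$fst)
    tot <- cmp$sig_a + cmp$sig_b + cmp$sig_i + cmp$sig_w
    c(fct = sum(cmp$sig_a[ok]) / sum(tot[ok]),
      fsc = sum(cmp$sig_b[ok]) / sum((cmp$sig_b + cmp$sig_i + cmp$sig_w)[ok]))
  }
  bisect <- function(target, which, m_fixed, steps, bracket = c(lo, hi),
                     check_max = TRUE) {
    # differentiation decreases with migration rate
    if (target <= 0.003) return(hi)   # indistinguishable from zero
    if (check_max) {
      f_lo <- if (which == "fct") eval_fs(bracket[1], m_fixed)[["fct"]]
              else eval_fs(m_fixed, bracket[1])[["fsc"]]
      if (target > f_lo * 1.05)
        stop("migration calibration: target ", which, " = ", target,
             " exceeds island-model maximum ~", signif(f_lo, 3))
    }
    a <- log(bracket[1]); b <- log(bracket[2])
    m <- exp((a + b) / 2)
    for (s in seq_len(steps)) {
      m <- exp((a + b) / 2)
      f <- if (which == "fct") eval_fs(m, m_fixed)[["fct"]]
           else eval_fs(m_fixed, m)[["fsc"]]
      if (abs(f - target) < 0.4 * tol * target) break
      if (f > target) a <- log(m) else b <- log(m)
    }
    m
  }
  m_w <- 10; m_a <- 1
  for (round in 1:2) {
    shrink <- function(m) c(max(lo, m / 6), min(hi, m * 6))
    m_a <- bisect(target_fct, "fct", m_w, steps = min(9, max_steps),
                  bracket = if (round == 1) c(lo, hi) else shrink(m_a),
                  check_max = round == 1)
    m_w <- bisect(target_fsc, "fsc", m_a, steps = min(9, max_steps),
                  bracket = if (round == 1) c(lo, hi) else shrink(m_w),
                  check_max = round == 1)
  }
  # polish with tighter brackets and lower Monte-Carlo noise: single noisy
  # comparisons during bisection can strand the bracket on the wrong side
  n_reps <- 2 * n_reps
  polish <- function(m) c(max(lo, m / 2.5), min(hi, m * 2.5))
  if (target_fct > 0.003)
    m_a <- bisect(target_fct, "fct", m_w, steps = 6, bracket = polish(m_a),
                  check_max = FALSE)
  if (target_fsc > 0.003)
    m_w <- bisect(target_fsc, "fsc", m_a, steps = 6, bracket = polish(m_w),
                  check_max = FALSE)
  # final evaluation with a block standard error, so the convergence check
  # is held to the achievable Monte-Carlo precision
  cmp <- sim_null_replicates(n_reps, scfg, n_groups, demes_per_group,
                             m_within = m_w, m_among = m_a)$cmp
  ok <- cmp$ok & is.finite(cmp$fst)
  ratio <- function(sel) {
    tot <- cmp$sig_a + cmp$sig_b + cmp$sig_i + cmp$sig_w
    c(fct = sum(cmp$sig_a[sel]) / sum(tot[sel]),
      fsc = sum(cmp$sig_b[sel]) / sum((cmp$sig_b + cmp$sig_i + cmp$sig_w)[sel]))
  }
  ach <- ratio(ok)
  blocks <- split(which(ok), rep(1:10, length.out = sum(ok)))
  bvals <- vapply(blocks, ratio, numeric(2))
  ach_se <- apply(bvals, 1, stats::sd) / sqrt(10)
  off <- function(a, t, se) abs(a - t) > pmax(tol * t, 0.004) + 3 * se
  if (off(ach[["fct"]], target_fct, ach_se[["fct"]]))
    stop("migration calibration did not converge: achieved F_CT ",
         signif(ach[["fct"]], 3), " vs target ", target_fct)
  if (off(ach[["fsc"]], target_fsc, ach_se[["fsc"]]))
    stop("migration calibration did not converge: achieved F_SC ",
         signif(ach[["fsc"]], 3), " vs target ", target_fsc)
  out <- c(among = m_a, within = m_w)
  attr(out, "achieved") <- ach
  attr(out, "achieved_se") <- ach_se
  out
}

#' Heterozygosity-conditioned outlier p-values and z-scores
#'
#' For each observed SNP, the p-value is the upper-tail rank of its F_ST
#' among the null replicates in its heterozygosity bin, with ties between
#' the observed and null values broken uniformly at random:
#' p = (#\{null > obs\} + U (1 + #\{null = obs\})) / (n_bin + 1), U ~ U(0,1).
#' The tie treatment matters because a finite-sample coalescent null is
#' discrete: low-frequency variants produce large F_ST atoms, under which a
#' plain exceedance rank is strongly conservative and the nominal alpha
#' levels mis-calibrate (rejection at well under half the nominal rate in
#' the low-heterozygosity bins). The randomized rank is exactly uniform for
#' test SNPs exchangeable with the null, whatever the atom structure; with
#' `ties = "midrank"` a deterministic mid-rank p is returned instead
#' (slightly conservative at atoms). The z-score is `qnorm(1 - p)`, so
#' exceptionally high differentiation maps to large positive z and
#' exceptionally low differentiation to large negative z. SNPs with
#' heterozygosity outside the binned range are assigned to the nearest bin
#' with a warning.
#'
#' @param observed data.frame with columns `h_bp` and `fst` (e.g. the
#'   `per_snp` table of [hierarchical_fst()]).
#' @param null a `null_table` from [simulate_null()].
#' @param ties "randomized" (default; draws from the RNG, so set a seed for
#'   reproducibility) or "midrank".
#' @return data.frame with `p_out` in (0,1) and finite `z`, row-aligned to
#'   `observed`.
#' @export
outlier_pvalues <- function(observed, null, ties = c("randomized", "midrank")) {
  ties <- match.arg(ties)
  stopifnot(inherits(null, "null_table"),
            all(c("h_bp", "fst") %in% names(observed)))
  nb <- length(null$fst_by_bin)
  bin <- findInterval(observed$h_bp, null$edges, rightmost.closed = TRUE)
  out_of_range <- bin < 1 | bin > nb
  if (any(out_of_range, na.rm = TRUE))
    warning(sum(out_of_range, na.rm = TRUE),
            " SNP(s) outside the null heterozygosity range; nearest bin used")
  bin <- pmin(pmax(bin, 1L), nb)
  p <- rep(NA_real_, nrow(observed))
  for (b in seq_len(nb)) {
    idx <- which(bin == b & is.finite(observed$fst))
    if (length(idx) == 0) next
    v <- null$fst_by_bin[[b]]
    n_gt <- length(v) - findInterval(observed$fst[idx], v)
    n_lt <- findInterval(observed$fst[idx], v, left.open = TRUE)
    n_eq <- length(v) - n_gt - n_lt
    u <- if (ties == "randomized") stats::runif(length(idx)) else 0.5
    p[idx] <- (n_gt + u * (1 + n_eq)) / (length(v) + 1)
  }
  data.frame(p_out = p, z = stats::qnorm(1 - p))
}
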