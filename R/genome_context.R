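# Genetic-map interpolation, recombination-rate estimation from a smoothed
# map, Ripley's K clustering test for outlier SNPs on the genetic map, and
# recombination-differentiation association tests.

#' Interpolate genetic-map positions for SNPs
#'
#' Linear interpolation of cM against bp between flanking map markers, per
#' chromosome. SNPs outside the marker range are clamped to the terminal
#' marker's cM with a warning.
#'
#' @param map data.frame with columns `chrom`, `bp`, `cm` (bp strictly
#'   increasing and cm non-decreasing within chromosome).
#' @param loci data.frame with `chrom` and `pos`.
#' @return numeric vector of cM positions aligned to `loci`.
#' @export
interpolate_genetic_position <- function(map, loci) {
  missing_ch <- setdiff(unique(loci$chrom), unique(map$chrom))
  if (length(missing_ch) > 0)
    stop("chromosome(s) absent from genetic map: ",
         paste(missing_ch, collapse = ", "), " (",
         sum(loci$chrom %in% missing_ch), " SNPs affected)")
  cm <- rep(NA_real_, nrow(loci))
  clamped <- 0L
  for (ch in unique(loci$chrom)) {
    m <- map[map$chrom == ch, , drop = FALSE]
    m <- m[order(m$bp), , drop = FALSE]
    if (any(diff(m$cm) < 0)) stop("genetic map not monotone on ", ch)
    sel <- loci$chrom == ch
    p <- loci$pos[sel]
    clamped <- clamped + sum(p < min(m$bp) | p > max(m$bp))
    cm[sel] <- stats::approx(m$bp, m$cm, xout = p, rule = 2, ties = "ordered")$y
  }
  if (clamped > 0)
    warning(clamped, " SNP(s) outside the marker range; clamped to terminal cM")
  cm
}

#' Local recombination rate from a smoothed genetic map
#'
#' Fits a smoothing spline of cM against bp per chromosome
#' ([stats::smooth.spline()] with its `spar` smoothing parameter) and
#' evaluates the first derivative at each SNP, clamped at zero, in cM/Mb.
#' Chromosomes with fewer than four markers fall back to piecewise-linear
#' slopes with a warning.
#'
#' @param map genetic map as in [interpolate_genetic_position()].
#' @param loci data.frame with `chrom`, `pos`.
#' @param spar smoothing parameter passed to [stats::smooth.spline()].
#' @return numeric vector of per-SNP rates (cM/Mb), >= 0.
#' @export
estimate_recombination_rate <- function(map, loci, spar = 0.7) {
  rate <- rep(NA_real_, nrow(loci))
  for (ch in unique(loci$chrom)) {
    m <- map[map$chrom == ch, , drop = FALSE]
    m <- m[order(m$bp), , drop = FALSE]
    sel <- loci$chrom == ch
    p <- loci$pos[sel]
    if (nrow(m) >= 4) {
      fit <- stats::smooth.spline(m$bp, m$cm, spar = spar)
      r <- stats::predict(fit, x = p, deriv = 1)$y
    } else {
      warning("chromosome ", ch, " has < 4 markers; using piecewise-linear slopes")
      slopes <- diff(m$cm) / diff(m$bp)
      seg <- pmin(pmax(findInterval(p, m$bp), 1L), length(slopes))
      r <- slopes[seg]
    }
    rate[sel] <- pmax(r, 0) * 1e6
  }
  rate
}

#' One-dimensional Ripley's K on a genetic map
#'
#' K(t) = (L / n^2) * #\{ordered pairs (i,j), i != j, |cm_i - cm_j| <= t\},
#' with `L` the chromosome's genetic length. No edge correction is applied:
#' observed and null curves are computed identically, so the envelope
#' comparison is internally consistent.
#'
#' @param cm numeric positions (cM).
#' @param L chromosome genetic length (cM).
#' @param t_grid distances at which to evaluate K.
#' @return numeric vector K(t) over `t_grid`.
#' @export
ripley_k <- function(cm, L, t_grid) {
  n <- length(cm)
  if (n < 2) return(rep(0, length(t_grid)))
  dv <- sort(as.vector(stats::dist(cm)))
  (L / n^2) * 2 * findInterval(t_grid, dv)
}

# null K curves: B resamples of n positions without replacement, each pushed
# through ripley_k() so observed and null share one counting convention
ripley_null_curves <- function(positions, n, L, t_grid, B) {
  t(vapply(seq_len(B), function(b)
    ripley_k(sample(positions, n), L, t_grid), numeric(length(t_grid))))
}

#' Ripley's K clustering test for outlier SNPs
#'
#' Tests, per chromosome with more than two outlier SNPs, whether outliers
#' cluster on the genetic map beyond what recombination-rate variation
#' explains. The null resamples `n` SNP positions without replacement from
#' the chromosome's own SNP cM positions `n_null` times; envelopes are the
#' pointwise median, 95% and 99% quantiles over a grid of 50 distances from
#' 0 to half the chromosome's genetic length. A chromosome is "clustered"
#' when the observed K exceeds the 95% envelope at any grid distance.
#'
#' @param is_outlier logical per SNP.
#' @param loci data.frame with `chrom` and `cm` per SNP.
#' @param n_null number of null resamples.
#' @param n_grid number of grid distances.
#' @return list per chromosome: `t`, `K_obs`, `median`, `q95`, `q99`,
#'   `clustered`, `n_outliers`; chromosomes with <= 2 outliers are skipped.
#' @export
ripley_k_test <- function(is_outlier, loci, n_null = 10000, n_grid = 50) {
  stopifnot(length(is_outlier) == nrow(loci), !is.null(loci$cm))
  out <- list()
  for (ch in unique(loci$chrom)) {
    sel <- loci$chrom == ch
    cm_all <- loci$cm[sel]
    cm_out <- cm_all[is_outlier[sel]]
    n <- length(cm_out)
    if (n <= 2) next
    L <- max(cm_all) - min(cm_all)
    if (L <= 0) next
    t_grid <- seq(L / (2 * n_grid), L / 2, length.out = n_grid)
    K_obs <- ripley_k(cm_out, L, t_grid)
    if (n == length(cm_all)) {
      # every SNP is an outlier: resampling reproduces the observed set and
      # the test is vacuous
      message("chromosome ", ch, ": outlier set equals the SNP set; ",
              "clustering test is vacuous")
      out[[ch]] <- list(t = t_grid, K_obs = K_obs, median = K_obs,
                        q95 = K_obs, q99 = K_obs, p = NA_real_,
                        clustered = FALSE, n_outliers = n)
      next
    }
    Knull <- ripley_null_curves(cm_all, n, L, t_grid, n_null)
    med <- apply(Knull, 2, stats::median)
    q95 <- global_envelope(Knull, 0.95)
    q99 <- global_envelope(Knull, 0.99)
    p_global <- global_rank_p(K_obs, Knull)
    out[[ch]] <- list(t = t_grid, K_obs = K_obs, median = med, q95 = q95,
                      q99 = q99, p = p_global,
                      clustered = p_global < 0.05,
                      n_outliers = n)
  }
  out
}

# Simultaneous envelopes and the clustering decision. A pointwise 95%
# envelope would be exceeded somewhere along ~50 correlated grid distances
# by far more than 5% of null curves, so deciding "clustered" on any-t
# exceedance of pointwise envelopes over-rejects badly. Instead the decision
# uses a global rank test on the most extreme pointwise mid-rank of the
# curve (K values are heavily tied for small outlier counts, so ranks use
# mid-rank tie handling to stay calibrated), and the reported envelopes are
# simultaneous order-statistic envelopes at the matching family-wise level.

# worst (largest) pointwise mid-rank of each curve in `X` relative to the
# null curves; sorted_null is a list of sorted columns
worst_midrank <- function(X, sorted_null) {
  nt <- length(sorted_null)
  W <- rep(-Inf, nrow(X))
  for (j in seq_len(nt)) {
    v <- sorted_null[[j]]
    lt <- findInterval(X[, j], v, left.open = TRUE)   # #{null < x}
    le <- findInterval(X[, j], v)                      # #{null <= x}
    W <- pmax(W, lt + 0.5 * (le - lt))
  }
  W
}

# Monte-Carlo p for the observed worst rank among the null worst ranks.
# K takes few distinct values when outlier counts are small, so worst ranks
# carry large atoms; ties are broken uniformly at random, which makes the
# test exactly sized in expectation despite the discreteness.
global_rank_p <- function(K_obs, Knull) {
  sorted_null <- lapply(seq_len(ncol(Knull)), function(j) sort(Knull[, j]))
  W_null <- worst_midrank(Knull, sorted_null)
  W_obs <- worst_midrank(matrix(K_obs, nrow = 1), sorted_null)
  B <- nrow(Knull)
  (sum(W_null > W_obs) + stats::runif(1) * (1 + sum(W_null == W_obs))) / (B + 1)
}

global_envelope <- function(Knull, level = 0.95) {
  B <- nrow(Knull)
  mx <- apply(Knull, 2, rank, ties.method = "max")
  worst <- apply(mx, 1, max)
  r_star <- unname(stats::quantile(worst, level, type = 1))
  apply(Knull, 2, function(col) sort(col)[min(r_star, B)])
}

#' Association between recombination rate and differentiation
#'
#' Kruskal-Wallis test of local recombination rate across island classes
#' (background / IND / IPD; classes with fewer than two SNPs are dropped
#' with a message), and Spearman rank correlations of rate against each
#' supplied F_ST vector, genome-wide and per chromosome. All decisions use a
#' Bonferroni-corrected alpha.
#'
#' @param rate per-SNP recombination rate (cM/Mb).
#' @param island_class per-SNP factor/character: "background", "IND", "IPD".
#' @param fst_list named list of per-SNP F_ST vectors (e.g. hierarchical and
#'   pairwise estimates).
#' @param chrom chromosome per SNP.
#' @param alpha family-wise alpha before Bonferroni correction.
#' @return data.frame of tests: test, scope, statistic, estimate, p,
#'   p_bonferroni, significant.
#' @export
recomb_association_tests <- function(rate, island_class, fst_list, chrom,
                                     alpha = 0.05) {
  rows <- list()
  cls <- factor(island_class)
  keep_cls <- names(which(table(cls) >= 2))
  if (length(keep_cls) < length(levels(cls)))
    message("dropping island class(es) with < 2 SNPs: ",
            paste(setdiff(levels(cls), keep_cls), collapse = ", "))
  sel <- cls %in% keep_cls & !is.na(rate)
  if (length(keep_cls) >= 2) {
    kw <- stats::kruskal.test(rate[sel], droplevels(cls[sel]))
    rows[[length(rows) + 1]] <- data.frame(
      test = "kruskal_rate_by_class", scope = "genome",
      statistic = unname(kw$statistic), estimate = NA_real_,
      p = kw$p.value)
  }
  spearman <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  }
  for (nm in names(fst_list)) {
    s <- spearman(rate, fst_list[[nm]])
    rows[[length(rows) + 1]] <- data.frame(
      test = paste0("spearman_rate_vs_", nm), scope = "genome",
      statistic = NA_real_, estimate = s[1], p = s[2])
    for (ch in unique(chrom)) {
      on <- chrom == ch
      s <- spearman(rate[on], fst_list[[nm]][on])
      rows[[length(rows) + 1]] <- data.frame(
        test = paste0("spearman_rate_vs_", nm), scope = ch,
        statistic = NA_real_, estimate = s[1], p = s[2])
    }
  }
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(out$p * m, 1)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}
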