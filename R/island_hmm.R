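# Segmentation of genome-ordered outlier z-scores into three differentiation
# states (exceptionally low / background / exceptionally high) with a
# univariate Gaussian hidden Markov model, island calling under a region-level
# false discovery rate, and classification of parallel lake-stream
# differentiation.

#' Fit the three-state Gaussian HMM to genome-ordered z-scores
#'
#' Baum-Welch EM on the concatenated SNP dataset, with chromosomes treated as
#' independent chains sharing one parameter set (so parameter estimation uses
#' all SNPs but no state run can span a chromosome boundary). State
#' identifiability is enforced by ordering emission means after every M-step;
#' emission standard deviations are floored at `sd_floor` (with a warning) to
#' prevent state collapse. Initialisation: emission means at the 0.1/0.5/0.9
#' z quantiles, sticky transitions (0.99 self-transition), and `n_restarts`
#' jittered restarts keeping the best likelihood.
#'
#' @param z numeric vector of z-scores, genome-ordered, finite.
#' @param chrom chromosome label per SNP (defines chain boundaries).
#' @param n_restarts number of EM restarts.
#' @param max_iter,tol EM stopping rule (log-likelihood change).
#' @param sd_floor lower bound on emission standard deviations.
#' @param seed RNG seed for restart jitter.
#' @return `hmm_model`: `mean`, `sd`, `trans` (3x3), `init`, `loglik`,
#'   states ordered low < background < high.
#' @export
fit_hmm <- function(z, chrom, n_restarts = 10, max_iter = 500, tol = 1e-6,
                    sd_floor = 0.05, seed = 1) {
  stopifnot(all(is.finite(z)), length(z) == length(chrom))
  seq_len_ <- rle(as.character(chrom))$lengths
  set.seed(seed)
  mu0 <- unname(stats::quantile(z, c(0.1, 0.5, 0.9)))
  s0 <- stats::sd(z)
  trans0 <- matrix(0.005, 3, 3); diag(trans0) <- 0.99
  init0 <- c(0.005, 0.99, 0.005)
  best <- NULL        # best fit whose middle state is stationary-dominant
  best_any <- NULL    # best fit regardless
  for (r in seq_len(n_restarts)) {
    mu_r <- if (r == 1) mu0 else sort(mu0 + stats::rnorm(3, 0, 0.5 * s0))
    fit <- cpp_hmm_em(z, seq_len_, mu_r, rep(s0, 3), trans0, init0,
                      max_iter, tol, sd_floor)
    if (is.null(best_any) || fit$loglik > best_any$loglik) best_any <- fit
    if (which.max(fit$init) == 2L &&
        (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  # The three states are semantic: "background" must be the dominant state
  # of the chain, with "low"/"high" exceptional minorities. On weak data the
  # global likelihood optimum sometimes models the bulk with an extreme-
  # ranked state (mean ordering alone cannot identify the labels); restarts
  # whose stationary distribution is dominated by the middle state are
  # preferred, and if none exists the best fit is relabelled so that the
  # dominant state sits in the background position.
  if (is.null(best)) {
    best <- best_any
    ord <- label_by_dominance(best$init, best$mean)
    best$mean <- best$mean[ord]
    best$sd <- best$sd[ord]
    best$init <- best$init[ord]
    best$trans <- best$trans[ord, ord, drop = FALSE]
  }
  if (isTRUE(best$sd_floored))
    warning("an emission standard deviation was floored at ", sd_floor)
  structure(list(mean = best$mean, sd = best$sd, trans = best$trans,
                 init = best$init, loglik = best$loglik,
                 n_iter = best$n_iter, states = c("low", "background", "high")),
            class = "hmm_model")
}

# permutation placing the stationary-dominant state in the background slot,
# the smaller-mean remaining state in "low" and the larger in "high"
label_by_dominance <- function(weight, mean_) {
  bg <- which.max(weight)
  rest <- setdiff(1:3, bg)
  rest <- rest[order(mean_[rest])]
  c(rest[1], bg, rest[2])
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("hmm_model: emission means", paste(signif(x$mean, 4), collapse = " / "),
      "(low/background/high); loglik", signif(x$loglik, 8), "\n")
  invisible(x)
}

#' Decode per-SNP differentiation states
#'
#' Posterior (forward-backward) decoding by default: the reported state is
#' the per-SNP maximum-posterior state, matching a SNP-wise notion of the
#' most likely state. Viterbi (path-wise) decoding is available as an
#' alternative.
#'
#' @param model an `hmm_model` from [fit_hmm()].
#' @param z,chrom as in [fit_hmm()].
#' @param method "posterior" (default) or "viterbi".
#' @return data.frame: `state` (low/background/high), `p_low`,
#'   `p_background`, `p_high`.
#' @export
decode_states <- function(model, z, chrom, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  seq_len_ <- rle(as.character(chrom))$lengths
  post <- cpp_hmm_posterior(z, seq_len_, model$mean, model$sd, model$trans,
                            model$init)$posterior
  state_idx <- if (method == "posterior") max.col(post, ties.method = "first")
  else cpp_hmm_viterbi(z, seq_len_, model$mean, model$sd, model$trans, model$init)
  data.frame(state = factor(model$states[state_idx], levels = model$states),
             p_low = post[, 1], p_background = post[, 2], p_high = post[, 3])
}

#' Call islands of differentiation at a region-level FDR
#'
#' Maximal runs of consecutive SNPs decoded in the target state become
#' candidate regions. Each candidate's local false discovery rate is the
#' mean posterior probability of NOT being in the target state over its
#' member SNPs; candidates are ranked by local FDR and retained while the
#' running mean over accepted candidates stays at or below `fdr`.
#'
#' @param decoded output of [decode_states()].
#' @param loci data.frame with `chrom`, `pos` aligned to `decoded`.
#' @param fdr region-level false discovery rate (default 0.001).
#' @param state "high" for islands of differentiation, "low" for regions of
#'   exceptionally low differentiation.
#' @return data.frame of islands: `id` (chromosome.index), `chrom`, `start`,
#'   `end` (first to last member SNP), `n_snps`, `local_fdr`, and a
#'   list-column `snps` of member SNP indices.
#' @export
call_islands <- function(decoded, loci, fdr = 0.001, state = "high") {
  stopifnot(nrow(decoded) == nrow(loci))
  p_state <- switch(state, high = decoded$p_high, low = decoded$p_low,
                    stop("state must be 'high' or 'low'"))
  in_state <- decoded$state == state
  r <- rle(paste(loci$chrom, in_state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand_i <- which(grepl(" TRUE$", r$values))
  if (length(cand_i) == 0) return(empty_island_df())
  cand <- data.frame(first = starts[cand_i], last = ends[cand_i])
  cand$chrom <- loci$chrom[cand$first]
  cand$local_fdr <- vapply(seq_len(nrow(cand)), function(k)
    mean(1 - p_state[cand$first[k]:cand$last[k]]), numeric(1))
  ord <- order(cand$local_fdr)
  run_mean <- cumsum(cand$local_fdr[ord]) / seq_along(ord)
  n_keep <- max(0, which(run_mean <= fdr))
  if (n_keep == 0) return(empty_island_df())
  keep <- sort(ord[seq_len(n_keep)])
  isl <- cand[keep, , drop = FALSE]
  # chromosome.index ids in positional order per chromosome
  idx_on_chrom <- stats::ave(seq_len(nrow(isl)), isl$chrom, FUN = seq_along)
  out <- data.frame(id = paste0(isl$chrom, ".", idx_on_chrom),
                    chrom = isl$chrom,
                    start = loci$pos[isl$first], end = loci$pos[isl$last],
                    n_snps = isl$last - isl$first + 1L,
                    local_fdr = isl$local_fdr, stringsAsFactors = FALSE)
  out$snps <- lapply(seq_len(nrow(isl)), function(k) isl$first[k]:isl$last[k])
  rownames(out) <- NULL
  out
}

empty_island_df <- function() {
  out <- data.frame(id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    n_snps = integer(0), local_fdr = numeric(0),
                    stringsAsFactors = FALSE)
  out$snps <- list()
  out
}

# per-SNP pairwise F_ST and permutation p between two populations, for a
# subset of SNPs; permutations draw the focal population's genotype counts
# from the pooled counts (equivalent to shuffling individuals between the
# two populations, per SNP)
snp_pairwise_perm <- function(gm, snp_idx, popA, popB, n_perm = 999) {
  cn <- genotype_counts_by_pop(gm, c(popA, popB))
  res <- data.frame(fst = rep(NA_real_, length(snp_idx)),
                    p = NA_real_,
                    freqA = NA_real_, freqB = NA_real_)
  for (k in seq_along(snp_idx)) {
    j <- snp_idx[k]
    a <- c(cn$n0[j, 1], cn$n1[j, 1], cn$n2[j, 1])
    b <- c(cn$n0[j, 2], cn$n1[j, 2], cn$n2[j, 2])
    tot <- a + b
    nA <- sum(a)
    if (nA < 2 || sum(b) < 2) next
    obs <- amova_components_pairwise(matrix(c(a[1], b[1]), 1),
                                     matrix(c(a[2], b[2]), 1),
                                     matrix(c(a[3], b[3]), 1))
    res$fst[k] <- obs$fst
    res$freqA[k] <- (a[2] + 2 * a[3]) / (2 * nA)
    res$freqB[k] <- (b[2] + 2 * b[3]) / (2 * sum(b))
    if (is.na(obs$fst)) next
    # multivariate hypergeometric draw of popA genotype counts
    a0 <- stats::rhyper(n_perm, tot[1], tot[2] + tot[3], nA)
    a1 <- stats::rhyper(n_perm, tot[2], tot[3], nA - a0)
    a2 <- nA - a0 - a1
    cmp <- amova_components_pairwise(cbind(a0, tot[1] - a0),
                                     cbind(a1, tot[2] - a1),
                                     cbind(a2, tot[3] - a2))
    res$p[k] <- (1 + sum(cmp$fst >= obs$fst, na.rm = TRUE)) / (n_perm + 1)
  }
  res
}

#' Flag SNPs with parallel habitat-associated differentiation
#'
#' A SNP shows parallel differentiation when (a) the same allele is at
#' strictly higher frequency in the same habitat in both lake-stream
#' contrasts and (b) its pairwise F_ST is significant (permutation p <
#' `alpha`) in both contrasts. Frequency ties fail the strict inequality and
#' are therefore not parallel.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_idx SNP indices to classify (typically island members).
#' @param contrasts list of two character pairs, each `c(lake_pop,
#'   stream_pop)`.
#' @param alpha significance level of the per-SNP permutation test.
#' @param n_perm permutations per SNP and contrast.
#' @param seed RNG seed.
#' @return data.frame per SNP: `parallel` flag, per-contrast `fst`, `p` and
#'   allele-frequency differential.
#' @export
classify_parallel_snps <- function(gm, snp_idx,
                                   contrasts = list(c("L1", "S1"), c("L2", "S2")),
                                   alpha = 0.05, n_perm = 999, seed = NULL) {
  stopifnot(length(contrasts) == 2)
  if (!is.null(seed)) set.seed(seed)
  r1 <- snp_pairwise_perm(gm, snp_idx, contrasts[[1]][1], contrasts[[1]][2], n_perm)
  r2 <- snp_pairwise_perm(gm, snp_idx, contrasts[[2]][1], contrasts[[2]][2], n_perm)
  # direction: sign of (stream frequency - lake frequency) of the alt allele
  d1 <- r1$freqB - r1$freqA
  d2 <- r2$freqB - r2$freqA
  same_dir <- !is.na(d1) & !is.na(d2) & (d1 * d2 > 0)   # strict: ties fail
  sig <- !is.na(r1$p) & !is.na(r2$p) & r1$p < alpha & r2$p < alpha
  data.frame(snp = snp_idx, parallel = same_dir & sig,
             fst1 = r1$fst, p1 = r1$p, diff1 = d1,
             fst2 = r2$fst, p2 = r2$p, diff2 = d2)
}

#' Classify islands as parallel (IPD) or non-parallel (IND)
#'
#' An island of parallel differentiation (IPD) contains at least one
#' parallel-differentiation SNP; otherwise it is an island of non-parallel
#' differentiation (IND). Per-island counts of member SNPs with significant
#' pairwise differentiation in the sympatric and parapatric contrasts are
#' attached.
#'
#' @param islands output of [call_islands()].
#' @param snp_flags output of [classify_parallel_snps()] covering all member
#'   SNPs.
#' @param alpha significance level used for the per-contrast counts.
#' @return `islands` with columns `class` ("IPD"/"IND"), `n_parallel`,
#'   `n_sig_sympatry`, `n_sig_parapatry`.
#' @export
classify_islands <- function(islands, snp_flags, alpha = 0.05) {
  if (nrow(islands) == 0) {
    islands$class <- character(0)
    islands$n_parallel <- islands$n_sig_sympatry <- islands$n_sig_parapatry <- integer(0)
    return(islands)
  }
  flag <- stats::setNames(snp_flags$parallel, snp_flags$snp)
  s1 <- stats::setNames(!is.na(snp_flags$p1) & snp_flags$p1 < alpha, snp_flags$snp)
  s2 <- stats::setNames(!is.na(snp_flags$p2) & snp_flags$p2 < alpha, snp_flags$snp)
  islands$n_parallel <- vapply(islands$snps, function(ix)
    sum(flag[as.character(ix)], na.rm = TRUE), integer(1))
  islands$n_sig_sympatry <- vapply(islands$snps, function(ix)
    sum(s1[as.character(ix)], na.rm = TRUE), integer(1))
  islands$n_sig_parapatry <- vapply(islands$snps, function(ix)
    sum(s2[as.character(ix)], na.rm = TRUE), integer(1))
  islands$class <- ifelse(islands$n_parallel >= 1, "IPD", "IND")
  islands
}
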