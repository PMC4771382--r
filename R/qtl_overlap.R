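# Permutation test for clustering of islands of parallel differentiation
# inside QTL confidence intervals, per trait, on the physical or genetic map.

# per-trait, per-chromosome interval index for fast stabbing queries:
# sorted starts with running max of ends
build_qtl_index <- function(qtls) {
  idx <- list()
  for (tr in unique(qtls$trait)) {
    q <- qtls[qtls$trait == tr, , drop = FALSE]
    by_ch <- list()
    for (ch in unique(q$chrom)) {
      d <- q[q$chrom == ch, , drop = FALSE]
      o <- order(d$start)
      by_ch[[as.character(ch)]] <- list(start = d$start[o],
                                        cummax_end = cummax(d$end[o]))
    }
    idx[[tr]] <- by_ch
  }
  idx
}

# does interval [a, b] on chrom ch intersect any trait interval? vectorized
# over a, b (same chrom)
qtl_hit <- function(index_ch, a, b) {
  if (is.null(index_ch)) return(rep(FALSE, length(a)))
  j <- findInterval(b, index_ch$start)
  hit <- j >= 1
  hit[hit] <- index_ch$cummax_end[j[hit]] >= a[hit]
  hit
}

#' Count islands overlapping QTLs, per trait
#'
#' An island extended by `buffer_bp` on both sides overlaps a trait when it
#' intersects at least one of the trait's QTL confidence intervals on the
#' same chromosome; each island counts once per trait.
#'
#' @param islands data.frame with `chrom`, `start`, `end` (typically IPD
#'   islands only).
#' @param qtls data.frame with `chrom`, `start`, `end`, `trait`.
#' @param buffer_bp buffer added to both island ends.
#' @return named integer vector of overlap counts, one per trait.
#' @export
count_overlaps <- function(islands, qtls, buffer_bp = 10000) {
  idx <- build_qtl_index(qtls)
  traits <- names(idx)
  counts <- stats::setNames(integer(length(traits)), traits)
  for (tr in traits) {
    n <- 0L
    for (k in seq_len(nrow(islands))) {
      ch <- as.character(islands$chrom[k])
      if (qtl_hit(idx[[tr]][[ch]], islands$start[k] - buffer_bp,
                  islands$end[k] + buffer_bp))
        n <- n + 1L
    }
    counts[tr] <- n
  }
  counts
}

#' Permutation test of island-QTL clustering
#'
#' Re-places all islands `n_perm` times uniformly at random across the
#' genome (each island keeps its length, draws an independent start position
#' in the chosen coordinate system, never crosses a chromosome end; placed
#' islands may overlap each other), recomputes the per-trait overlap count,
#' and reports the empirical p-value
#' p = (1 + #\{null >= observed\}) / (n_perm + 1), Bonferroni-corrected over
#' traits. Run it once with physical coordinates and once with genetic-map
#' coordinates to control for recombination-rate variation inflating
#' confidence intervals.
#'
#' @param islands data.frame `chrom`, `start`, `end` (IPD islands).
#' @param qtls data.frame `chrom`, `start`, `end`, `trait` in the same
#'   coordinate system as `islands`.
#' @param chrom_lengths named numeric vector of chromosome lengths in that
#'   coordinate system.
#' @param n_perm number of permutations.
#' @param buffer_bp island buffer (same units as coordinates).
#' @param alpha family-wise level; Bonferroni over the number of traits.
#' @param seed RNG seed.
#' @return data.frame per trait: observed count, mean null count, p,
#'   p_bonferroni, significant.
#' @export
permutation_test <- function(islands, qtls, chrom_lengths, n_perm = 100000,
                             buffer_bp = 10000, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(islands) > 0)
  len <- islands$end - islands$start
  chroms <- names(chrom_lengths)
  feasible <- outer(chrom_lengths, len, "-") # chrom x island feasible span
  if (any(apply(feasible, 2, max) <= 0))
    stop("an island is longer than every chromosome")
  idx <- build_qtl_index(qtls)
  traits <- names(idx)
  observed <- count_overlaps(islands, qtls, buffer_bp)[traits]

  null_counts <- matrix(0L, n_perm, length(traits),
                        dimnames = list(NULL, traits))
  for (k in seq_len(nrow(islands))) {
    span <- pmax(feasible[, k], 0)
    ch_draw <- sample(chroms, n_perm, replace = TRUE, prob = span)
    start_draw <- stats::runif(n_perm) * span[ch_draw] + 1
    end_draw <- start_draw + len[k]
    for (tr in traits) {
      hit <- logical(n_perm)
      for (ch in names(idx[[tr]])) {
        on <- which(ch_draw == ch)
        if (length(on) == 0) next
        hit[on] <- qtl_hit(idx[[tr]][[ch]], start_draw[on] - buffer_bp,
                           end_draw[on] + buffer_bp)
      }
      null_counts[, tr] <- null_counts[, tr] + hit
    }
  }
  p <- vapply(traits, function(tr)
    (1 + sum(null_counts[, tr] >= observed[tr])) / (n_perm + 1), numeric(1))
  out <- data.frame(trait = traits, observed = as.integer(observed),
                    mean_null = colMeans(null_counts), p = p,
                    p_bonferroni = pmin(p * length(traits), 1),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}
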