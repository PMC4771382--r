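# Per-population nucleotide diversity in RAD-locus-aware windows of variable
# physical size but near-constant sequenced-site content, with island-versus-
# background contrasts.

#' Build diversity windows from RAD loci
#'
#' Greedy accumulation of whole RAD loci along each chromosome until the
#' window holds at least `min_sites` sequenced sites; single loci never span
#' two windows. Trailing loci that fall short of the threshold are merged
#' into the previous window. A chromosome whose total sites fall below the
#' threshold becomes one undersized window, flagged with a warning.
#'
#' @param rad_loci data.frame: `chrom`, `start`, `end`, `n_sites`
#'   (sequenced bases per locus), sorted and non-overlapping.
#' @param min_sites minimum sequenced sites per window.
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `undersized`.
#' @export
build_windows <- function(rad_loci, min_sites = 2500) {
  out <- list()
  for (ch in unique(rad_loci$chrom)) {
    d <- rad_loci[rad_loci$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (sum(d$n_sites) < min_sites) {
      warning("chromosome ", ch, " holds ", sum(d$n_sites),
              " sites (< ", min_sites, "); single undersized window")
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = d$start[1], end = d$end[nrow(d)],
        n_sites = sum(d$n_sites), undersized = TRUE)
      next
    }
    acc <- 0; first <- 1
    bounds <- list()
    for (i in seq_len(nrow(d))) {
      acc <- acc + d$n_sites[i]
      if (acc >= min_sites) {
        bounds[[length(bounds) + 1]] <- c(first, i, acc)
        first <- i + 1; acc <- 0
      }
    }
    if (acc > 0) { # trailing loci below threshold: merge into previous window
      last <- bounds[[length(bounds)]]
      bounds[[length(bounds)]] <- c(last[1], nrow(d), last[3] + acc)
    }
    for (b in bounds)
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = d$start[b[1]], end = d$end[b[2]],
        n_sites = b[3], undersized = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-population nucleotide diversity per window
#'
#' Unbiased per-site diversity from the random-allele dataset (one allele
#' per individual and site): at a variant site with `n` non-missing alleles
#' and allele frequency `p` in a population, pi_site = n/(n-1) * 2p(1-p).
#' Window pi averages over all sequenced sites (monomorphic sites contribute
#' zero); variant sites with n < 2 in a population are excluded from both
#' numerator and denominator for that population.
#'
#' @param am an `allele_matrix` from [sample_allele_dataset()].
#' @param windows output of [build_windows()].
#' @return `windows` with one pi column per population (`pi_<pop>`).
#' @export
window_pi <- function(am, windows) {
  stopifnot(inherits(am, "allele_matrix"))
  pops <- unique(am$populations)
  win_of <- rep(NA_integer_, nrow(am$loci))
  for (w in seq_len(nrow(windows))) {
    sel <- am$loci$chrom == windows$chrom[w] &
      am$loci$pos >= windows$start[w] & am$loci$pos <= windows$end[w]
    win_of[sel] <- w
  }
  for (p in pops) {
    al <- am$alleles[am$populations == p, , drop = FALSE]
    n <- colSums(!is.na(al))
    cnt <- colSums(al, na.rm = TRUE)
    pfreq <- ifelse(n > 0, cnt / n, NA_real_)
    ok <- n >= 2
    pi_site <- ifelse(ok, n / (n - 1) * 2 * pfreq * (1 - pfreq), NA_real_)
    num <- den <- numeric(nrow(windows))
    for (w in seq_len(nrow(windows))) {
      j <- which(win_of == w)
      num[w] <- sum(pi_site[j], na.rm = TRUE)
      den[w] <- windows$n_sites[w] - sum(!ok[j])
    }
    windows[[paste0("pi_", p)]] <- num / den
  }
  windows
}

#' Label diversity windows by island overlap and test group contrasts
#'
#' A window overlapping (any bp) an island takes that island's class as its
#' label; when a window overlaps both classes, IPD takes precedence over IND
#' (logged via message). Within each population, Welch t-tests compare mean
#' window diversity between background vs IPD, background vs IND and IPD vs
#' IND, Bonferroni-adjusted over the three comparisons. Comparisons with
#' fewer than two windows in a group are reported as not testable (`NA`).
#'
#' @param windows_pi output of [window_pi()].
#' @param islands classified islands ([classify_islands()]).
#' @param alpha significance level after Bonferroni adjustment.
#' @return list: `windows` (with `label`), `tests` (per population and
#'   comparison: group means, p, p_bonferroni, significant).
#' @export
label_and_test <- function(windows_pi, islands, alpha = 0.05) {
  w <- windows_pi
  w$label <- "background"
  if (nrow(islands) > 0) {
    for (cls in c("IND", "IPD")) { # IPD applied last: precedence on overlap
      isl <- islands[islands$class == cls, , drop = FALSE]
      for (k in seq_len(nrow(isl))) {
        hit <- w$chrom == isl$chrom[k] & w$start <= isl$end[k] &
          w$end >= isl$start[k]
        if (cls == "IPD" && any(w$label[hit] == "IND"))
          message("window overlapping both IPD and IND labelled IPD")
        w$label[hit] <- cls
      }
    }
  }
  pi_cols <- grep("^pi_", names(w), value = TRUE)
  combos <- list(c("background", "IPD"), c("background", "IND"), c("IPD", "IND"))
  rows <- list()
  for (pc in pi_cols) {
    pop <- sub("^pi_", "", pc)
    for (cmb in combos) {
      x <- w[[pc]][w$label == cmb[1]]
      y <- w[[pc]][w$label == cmb[2]]
      if (length(x) < 2 || length(y) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          population = pop, comparison = paste(cmb, collapse = "_vs_"),
          mean1 = mean(x), mean2 = mean(y), p = NA_real_)
        next
      }
      p <- tryCatch(stats::t.test(x, y)$p.value,
                    error = function(e) NA_real_)  # e.g. constant data
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, comparison = paste(cmb, collapse = "_vs_"),
        mean1 = mean(x), mean2 = mean(y), p = p)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_bonferroni <- pmin(tests$p * length(combos), 1)
  tests$significant <- !is.na(tests$p_bonferroni) & tests$p_bonferroni < alpha
  list(windows = w, tests = tests)
}
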