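# Synthetic-data generator emulating a six-deme, three-group lake-stream
# sampling design: hierarchical Balding-Nichols allele frequencies, planted
# high-differentiation islands with habitat-parallel (or group-specific)
# frequency shifts, per-population inbreeding/PCR-duplicate homozygote excess,
# a piecewise-constant recombination map and trait-annotated QTL intervals.

#' Simulation configuration
#'
#' Defaults reproduce the emulated study design: six demes of 10-21 diploids
#' in three hierarchical groups (two stream-resident demes forming their own
#' groups, four lake-like demes in one group), ~10^4 biallelic SNPs on 20
#' chromosomes, background differentiation around 0.03, and homozygote excess
#' (F_IS up to ~0.25) in three demes.
#'
#' @param n_chromosomes number of autosomes (named by Roman numerals,
#'   skipping the sex chromosome XIX).
#' @param chrom_length_bp chromosome length in bp.
#' @param n_snps total SNPs across the genome.
#' @param deme_spec data.frame with columns pop, group, habitat
#'   ("lake"/"stream"), n (diploids).
#' @param background_fst total neutral differentiation among demes (two-level
#'   Balding-Nichols: half allocated among groups, half among demes within
#'   groups, on the scale 1-(1-f)^2 = background_fst).
#' @param island_spec data.frame with columns chrom, start, end, strength
#'   (expected habitat allele-frequency differential in \[0,1\]) and parallel
#'   (logical); islands must not overlap within a chromosome.
#' @param fis_per_pop named numeric vector of per-population IBD probability.
#' @param recomb_profile data.frame (chrom, start, end, rate_cm_per_mb) or a
#'   single rate applied genome-wide.
#' @param rad_cluster cluster SNPs into ~90 bp RAD loci (otherwise SNP
#'   positions are uniform and loci are derived from a 90 bp grid).
#' @param rad_locus_bp sequenced sites per RAD locus.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 20,
                       chrom_length_bp = 2e7,
                       n_snps = 10000,
                       deme_spec = NULL,
                       background_fst = 0.03,
                       island_spec = NULL,
                       fis_per_pop = NULL,
                       recomb_profile = 3,
                       rad_cluster = FALSE,
                       rad_locus_bp = 90,
                       seed = 1) {
  if (is.null(deme_spec))
    deme_spec <- data.frame(
      pop = c("L1", "S1a", "S1b", "S1", "L2", "S2"),
      group = c("lake", "lake", "lake", "stream1", "lake", "stream2"),
      habitat = c("lake", "lake", "lake", "stream", "lake", "stream"),
      n = c(20L, 10L, 10L, 21L, 10L, 20L),
      stringsAsFactors = FALSE)
  if (is.null(fis_per_pop))
    fis_per_pop <- c(L1 = 0.25, S1a = 0.05, S1b = 0.05, S1 = 0.25,
                     L2 = 0.05, S2 = 0.25)[deme_spec$pop]
  fis_per_pop[is.na(fis_per_pop)] <- 0
  names(fis_per_pop) <- deme_spec$pop
  stopifnot(all(fis_per_pop >= 0 & fis_per_pop <= 1),
            background_fst >= 0, background_fst < 1)
  chroms <- setdiff(as.character(utils::as.roman(1:25)), "XIX")[seq_len(n_chromosomes)]
  if (is.null(island_spec))
    island_spec <- data.frame(chrom = character(0), start = numeric(0),
                              end = numeric(0), strength = numeric(0),
                              parallel = logical(0))
  island_spec <- as.data.frame(island_spec)
  if (nrow(island_spec) > 0) {
    stopifnot(all(island_spec$chrom %in% chroms),
              all(island_spec$strength >= 0))
    for (ch in unique(island_spec$chrom)) {
      d <- island_spec[island_spec$chrom == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
        stop("islands overlap on chromosome ", ch)
    }
  }
  if (is.numeric(recomb_profile) && length(recomb_profile) == 1) {
    recomb_profile <- do.call(rbind, lapply(chroms, function(ch)
      data.frame(chrom = ch, start = 0, end = chrom_length_bp,
                 rate_cm_per_mb = recomb_profile)))
  }
  if (any(recomb_profile$rate_cm_per_mb < 0))
    stop("negative recombination rate")
  structure(list(n_chromosomes = n_chromosomes, chroms = chroms,
                 chrom_length_bp = chrom_length_bp, n_snps = n_snps,
                 deme_spec = deme_spec, background_fst = background_fst,
                 island_spec = island_spec, fis_per_pop = fis_per_pop,
                 recomb_profile = recomb_profile, rad_cluster = rad_cluster,
                 rad_locus_bp = rad_locus_bp, seed = seed),
            class = "sim_config")
}

# Balding-Nichols draw of a daughter frequency around p with coefficient f
bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  stats::rbeta(length(p), a, b)
}

#' Simulate a complete genotype dataset with planted islands
#'
#' Background SNPs: per-deme allele frequencies follow a two-level
#' Balding-Nichols hierarchy (ancestral -> group -> deme) with total
#' differentiation `background_fst`. Island SNPs: habitat-associated
#' frequency shifts of magnitude `strength` (same direction in all demes of a
#' habitat when `parallel`, restricted to one randomly chosen stream group
#' otherwise). Genotypes are drawn with per-population inbreeding: each
#' individual's second gene copy is identical by descent with probability
#' `fis_per_pop`. Shifted frequencies falling outside \[0,1\] are clipped and
#' counted.
#'
#' @param cfg a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()]), `map` (genetic map,
#'   data.frame chrom/bp/cm), `truth` (per-SNP island id, parallel flag, true
#'   per-deme frequencies), `rad_loci` (chrom/start/end/n_sites) and
#'   `islands` (the island spec with ids).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ds <- cfg$deme_spec
  D <- nrow(ds)

  # SNP positions
  per_chrom <- as.vector(stats::rmultinom(1, cfg$n_snps,
                                          rep(1 / cfg$n_chromosomes, cfg$n_chromosomes)))
  loci <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(i) {
    n <- per_chrom[i]
    if (cfg$rad_cluster) {
      n_loc <- max(1L, ceiling(n / 2))
      starts <- sort(sample.int(cfg$chrom_length_bp %/% cfg$rad_locus_bp, n_loc)) *
        cfg$rad_locus_bp - cfg$rad_locus_bp + 1
      pos <- sort(sample(as.vector(outer(0:(cfg$rad_locus_bp - 1), starts, "+")), n))
    } else {
      pos <- sort(sample.int(cfg$chrom_length_bp, n))
    }
    data.frame(chrom = cfg$chroms[i], pos = pos, stringsAsFactors = FALSE)
  }))
  loci <- loci[!duplicated(loci[c("chrom", "pos")]), ]
  rownames(loci) <- NULL
  L <- nrow(loci)

  # truth assignment
  isl <- cfg$island_spec
  island_id <- rep(NA_character_, L)
  parallel <- rep(NA, L)
  if (nrow(isl) > 0) {
    ids <- character(nrow(isl))
    for (k in seq_len(nrow(isl))) {
      ch <- isl$chrom[k]
      on <- which(loci$chrom == ch)
      idx_on_ch <- sum(isl$chrom[seq_len(k)] == ch)
      ids[k] <- paste0(match(ch, cfg$chroms), ".", idx_on_ch)
      hit <- on[loci$pos[on] >= isl$start[k] & loci$pos[on] <= isl$end[k]]
      island_id[hit] <- ids[k]
      parallel[hit] <- isl$parallel[k]
    }
    isl$id <- ids
  }

  # allele frequencies
  f_level <- 1 - sqrt(1 - cfg$background_fst)
  p_anc <- stats::runif(L, 0.05, 0.95)
  groups <- unique(ds$group)
  p_group <- vapply(groups, function(g) bn_draw(p_anc, f_level), numeric(L))
  colnames(p_group) <- groups
  p_deme <- vapply(seq_len(D), function(d)
    bn_draw(p_group[, ds$group[d]], f_level), numeric(L))
  colnames(p_deme) <- ds$pop

  n_clipped <- 0L
  if (nrow(isl) > 0) {
    stream_groups <- unique(ds$group[ds$habitat == "stream"])
    for (k in seq_len(nrow(isl))) {
      hit <- which(!is.na(island_id) & island_id == isl$id[k])
      if (length(hit) == 0) next
      delta <- isl$strength[k]
      sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
      base <- stats::runif(length(hit), 0.3, 0.7)
      if (isl$parallel[k]) {
        shifted_demes <- which(ds$habitat == "stream")
      } else {
        g <- if (length(stream_groups) > 0) sample(stream_groups, 1) else sample(unique(ds$group), 1)
        shifted_demes <- which(ds$group == g)
      }
      for (d in seq_len(D)) {
        shift <- if (d %in% shifted_demes) sgn * delta / 2 else -sgn * delta / 2
        tgt <- base + shift
        n_clipped <- n_clipped + sum(tgt < 0 | tgt > 1)
        tgt <- pmin(pmax(tgt, 0.02), 0.98)
        p_deme[hit, d] <- bn_draw(tgt, min(f_level, 0.01))
      }
    }
  }

  # genotypes with inbreeding
  n_ind <- sum(ds$n)
  geno <- matrix(NA_integer_, n_ind, L)
  sample_ids <- character(n_ind)
  pops <- character(n_ind)
  row0 <- 0L
  for (d in seq_len(D)) {
    nd <- ds$n[d]
    idx <- row0 + seq_len(nd)
    sample_ids[idx] <- paste0(ds$pop[d], "_", seq_len(nd))
    pops[idx] <- ds$pop[d]
    fis <- cfg$fis_per_pop[[ds$pop[d]]]
    pm <- matrix(p_deme[, d], nd, L, byrow = TRUE)
    a1 <- matrix(stats::rbinom(nd * L, 1, pm), nd, L)
    a2 <- matrix(stats::rbinom(nd * L, 1, pm), nd, L)
    if (fis > 0) {
      ibd <- matrix(stats::runif(nd * L) < fis, nd, L)
      a2[ibd] <- a1[ibd]
    }
    geno[idx, ] <- a1 + a2
    row0 <- row0 + nd
  }
  rownames(geno) <- sample_ids
  populations <- stats::setNames(pops, sample_ids)
  hierarchy <- stats::setNames(ds$group, ds$pop)

  loci$ref <- "A"; loci$alt <- "T"; loci$qual <- 100
  gm <- genotype_matrix(geno, loci, populations, hierarchy)

  truth <- data.frame(chrom = loci$chrom, pos = loci$pos,
                      island_id = island_id, parallel = parallel,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(p_deme))
  attr(truth, "n_clipped") <- n_clipped

  map <- simulate_genetic_map(cfg)
  rad <- derive_rad_loci(loci, cfg$rad_locus_bp)
  list(gm = gm, map = map, truth = truth, rad_loci = rad, islands = isl,
       config = cfg)
}

derive_rad_loci <- function(loci, locus_bp) {
  key <- paste(loci$chrom, (loci$pos - 1) %/% locus_bp)
  u <- !duplicated(key)
  data.frame(chrom = loci$chrom[u],
             start = ((loci$pos[u] - 1) %/% locus_bp) * locus_bp + 1,
             end = ((loci$pos[u] - 1) %/% locus_bp) * locus_bp + locus_bp,
             n_sites = locus_bp, stringsAsFactors = FALSE)
}

#' Simulate a genetic map from a piecewise-constant recombination profile
#'
#' Markers are placed every `marker_spacing_bp`; the cM position is the
#' integral of the local cM/Mb rate, so it is monotone non-decreasing.
#'
#' @param cfg a [sim_config()].
#' @param marker_spacing_bp distance between adjacent map markers.
#' @return data.frame with columns chrom, bp, cm.
#' @export
simulate_genetic_map <- function(cfg, marker_spacing_bp = 2e5) {
  prof <- cfg$recomb_profile
  if (any(prof$rate_cm_per_mb < 0)) stop("negative recombination rate")
  out <- lapply(cfg$chroms, function(ch) {
    p <- prof[prof$chrom == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    bp <- seq(0, cfg$chrom_length_bp, by = marker_spacing_bp)
    cm_at <- function(x) {
      covered <- pmin(pmax(x - p$start, 0), p$end - p$start)
      sum(covered * p$rate_cm_per_mb) / 1e6
    }
    data.frame(chrom = ch, bp = bp, cm = vapply(bp, cm_at, numeric(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate trait-annotated QTL confidence intervals
#'
#' Emits `n_per_trait` intervals for each of `n_traits` traits. A fraction
#' `frac_overlapping` of intervals is placed to cover a randomly chosen true
#' island; the remainder are placed uniformly on the genome. Each interval
#' carries an ordinal effect-size label and a `ci_rule` column recording how
#' its bounds were constructed.
#'
#' @param cfg a [sim_config()].
#' @param islands island table (e.g. `simulate_dataset(cfg)$islands`).
#' @param n_traits number of distinct trait labels.
#' @param frac_overlapping fraction of intervals covering a true island.
#' @param n_per_trait intervals per trait.
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @return data.frame: chrom, start, end, trait, effect, ci_rule.
#' @export
simulate_qtl_intervals <- function(cfg, islands, n_traits = 32,
                                   frac_overlapping = 0.5, n_per_trait = 3,
                                   seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  glen <- cfg$chrom_length_bp
  rows <- list()
  for (t in seq_len(n_traits)) {
    for (j in seq_len(n_per_trait)) {
      width <- round(stats::runif(1, 5e5, 2e6))
      if (nrow(islands) > 0 && stats::runif(1) < frac_overlapping) {
        k <- sample.int(nrow(islands), 1)
        centre <- (islands$start[k] + islands$end[k]) / 2
        start <- max(1, round(centre - width / 2))
        ch <- islands$chrom[k]
      } else {
        ch <- sample(cfg$chroms, 1)
        start <- sample.int(max(1, glen - width), 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = start, end = min(start + width, glen),
        trait = sprintf("trait_%02d", t),
        effect = sample(c("minor", "moderate", "major"), 1,
                        prob = c(0.6, 0.3, 0.1)),
        ci_rule = "ci", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
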