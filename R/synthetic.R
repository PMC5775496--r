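#' Simulation configuration for synthetic genotype matrices
#'
#' The defaults emulate the study conditions the pipeline is designed for:
#' eleven river populations of 17-22 juveniles, thousands of bi-allelic loci
#' with weak differentiation (a two-component FST mixture whose mean is
#' 0.059, giving realized per-locus values spanning roughly 0-0.6), an
#' ancestral minor-allele frequency uniform on \[0.05, 0.5\], and sparse
#' missingness of 0.08% of cells. An optional two-level hierarchy nests
#' populations within regions.
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population (recycled if scalar).
#' @param n_loci number of loci.
#' @param fst_levels FST of each mixture component, all in (0, 1) (or 0 for
#'   the degenerate no-differentiation component).
#' @param fst_weights mixture weights (sum to 1).
#' @param maf_range range of the uniform ancestral minor-allele frequency.
#' @param hierarchy `NULL`, or `list(n_regions =, fst_between =)`: ancestral
#'   frequencies first drift into regional frequencies at `fst_between`, then
#'   into population frequencies at the locus's own FST level.
#' @param fst_per_locus optional length-`n_loci` vector fixing each locus's
#'   FST level explicitly (e.g. an exact planted-signal design); overrides
#'   the mixture draw.
#' @param missing_rate independent per-cell missing probability.
#' @param seed integer seed; the same configuration and seed give a
#'   byte-identical matrix (R's default Mersenne-Twister RNG).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 11,
                       n_per_pop = c(21, 20, 21, 22, 22, 21, 22, 21, 17, 22, 22),
                       n_loci = 3000,
                       fst_levels = c(0.04, 0.23),
                       fst_weights = c(0.9, 0.1),
                       maf_range = c(0.05, 0.5),
                       hierarchy = NULL,
                       fst_per_locus = NULL,
                       missing_rate = 0.0008,
                       seed = 1) {
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, n_pops)
  stopifnot(n_pops >= 2, length(n_per_pop) == n_pops, all(n_per_pop >= 2),
            length(fst_levels) == length(fst_weights),
            all(fst_levels >= 0), all(fst_levels < 1),
            abs(sum(fst_weights) - 1) < 1e-8,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(hierarchy))
    stopifnot(hierarchy$n_regions >= 1,
              hierarchy$fst_between > 0, hierarchy$fst_between < 1)
  if (!is.null(fst_per_locus))
    stopifnot(length(fst_per_locus) == n_loci,
              all(fst_per_locus >= 0), all(fst_per_locus < 1))
  structure(list(n_pops = as.integer(n_pops),
                 n_per_pop = as.integer(n_per_pop),
                 n_loci = as.integer(n_loci),
                 fst_levels = fst_levels, fst_weights = fst_weights,
                 maf_range = maf_range, hierarchy = hierarchy,
                 fst_per_locus = fst_per_locus,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# one Balding-Nichols draw per cell of `p` (ancestral freq) at differentiation F
bn_draw <- function(p, f) {
  out <- p
  pos <- f > 0
  if (any(pos)) {
    shape1 <- p[pos] * (1 - f[pos]) / f[pos]
    shape2 <- (1 - p[pos]) * (1 - f[pos]) / f[pos]
    out[pos] <- rbeta(sum(pos), shape1, shape2)
  }
  out  # F = 0: frequency equals the ancestral value exactly
}

#' Simulate per-population allele frequencies (Balding-Nichols)
#'
#' Each locus draws an ancestral frequency from the configured MAF
#' distribution and an FST level from the mixture; each population's
#' frequency is then Beta-distributed around the ancestral value with
#' variance `p (1 - p) F`. In hierarchical mode the draw is composed twice:
#' ancestral to region (at `fst_between`), region to population (at the
#' locus FST).
#'
#' @param cfg a [sim_config()].
#' @return A list with `freq` (populations x loci matrix), `ancestral`,
#'   `fst` (per-locus level) and `cfg`.
#' @export
simulate_frequencies <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    p <- runif(cfg$n_loci, cfg$maf_range[1], cfg$maf_range[2])
    f <- if (!is.null(cfg$fst_per_locus)) {
      cfg$fst_per_locus
    } else {
      lvl <- sample.int(length(cfg$fst_levels), cfg$n_loci, replace = TRUE,
                        prob = cfg$fst_weights)
      cfg$fst_levels[lvl]
    }
    freq <- matrix(NA_real_, cfg$n_pops, cfg$n_loci)
    if (is.null(cfg$hierarchy)) {
      for (k in seq_len(cfg$n_pops)) freq[k, ] <- bn_draw(p, f)
    } else {
      nr <- cfg$hierarchy$n_regions
      regional <- matrix(NA_real_, nr, cfg$n_loci)
      for (r in seq_len(nr))
        regional[r, ] <- bn_draw(p, rep(cfg$hierarchy$fst_between, cfg$n_loci))
      region_of <- rep_len(seq_len(nr), cfg$n_pops)
      for (k in seq_len(cfg$n_pops))
        freq[k, ] <- bn_draw(regional[region_of[k], ], f)
    }
  })
  rownames(freq) <- sprintf("pop%02d", seq_len(cfg$n_pops))
  colnames(freq) <- sprintf("L%05d", seq_len(cfg$n_loci))
  list(freq = freq, ancestral = p, fst = f, cfg = cfg)
}

#' Simulate a genotype matrix from population frequencies
#'
#' Genotypes are binomial draws of two alleles at the population frequency,
#' encoded in the minor-allele dosage orientation (0 = minor homozygote,
#' 1 = major homozygote). Cells are masked missing independently at
#' `missing_rate`. After simulation each locus is re-oriented so that the
#' dosage-0 allele is the globally rarer one, matching the reader's
#' convention (FST is invariant to this flip).
#'
#' @param freqs output of [simulate_frequencies()].
#' @param cfg a [sim_config()]; defaults to the one inside `freqs`.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(freqs, cfg = freqs$cfg) {
  q <- freqs$freq
  L <- ncol(q)
  with_seed(cfg$seed + 1L, {
    rows <- vector("list", cfg$n_pops)
    labs <- character(0); ids <- character(0)
    for (k in seq_len(cfg$n_pops)) {
      n <- cfg$n_per_pop[k]
      mc <- matrix(rbinom(n * L, 2, rep(q[k, ], each = n)), n, L)
      rows[[k]] <- 1 - mc / 2
      labs <- c(labs, rep(rownames(q)[k], n))
      ids <- c(ids, sprintf("%s_%03d", rownames(q)[k], seq_len(n)))
    }
    d <- do.call(rbind, rows)
    if (cfg$missing_rate > 0)
      d[runif(length(d)) < cfg$missing_rate] <- NA_real_
  })
  # orient each locus to the globally rarer allele
  fm <- colMeans(1 - d, na.rm = TRUE)
  flip <- !is.na(fm) & fm > 0.5
  d[, flip] <- 1 - d[, flip]
  dimnames(d) <- list(ids, colnames(q))
  genotype_matrix(d, labs)
}

#' Simulate frequencies and genotypes in one call
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  simulate_genotypes(simulate_frequencies(cfg), cfg)
}

#' Small deterministic test fixtures
#'
#' Named matrices (at most 60 individuals and 100 loci) with hand-verifiable
#' expectations returned alongside in a manifest:
#'
#' * `tiny_separable`: three populations with fixed allelic differences; any
#'   panel of its loci self-assigns the holdout set perfectly.
#' * `null_shuffled`: labels carry no genotype information; assignment can do
#'   no better than chance, forest OOB error sits at the majority rate.
#' * `planted_signal`: 10 strongly differentiated loci among 90 near-neutral
#'   ones; the manifest lists the 10 ids expected to dominate MDA.
#' * `duplicate_loci`: two identical high-FST columns; redundancy pruning
#'   must keep exactly one (the first by locus id).
#'
#' @param name fixture name.
#' @return A list with `matrix` (a [genotype_matrix()]) and `manifest`.
#' @export
make_fixture <- function(name = c("tiny_separable", "null_shuffled",
                                  "planted_signal", "duplicate_loci")) {
  name <- match.arg(name)
  if (name == "tiny_separable") {
    n <- 12; pops <- rep(c("A", "B", "C"), each = n)
    d <- matrix(1, 3 * n, 18)
    for (k in 1:3) d[pops == c("A", "B", "C")[k], (k - 1) * 6 + 1:6] <- 0
    dimnames(d) <- list(sprintf("%s_%02d", pops, rep(seq_len(n), 3)),
                        sprintf("S%02d", 1:18))
    return(list(matrix = genotype_matrix(d, pops),
                manifest = list(expected_holdout_accuracy = 100)))
  }
  if (name == "null_shuffled") {
    cfg <- sim_config(n_pops = 4, n_per_pop = 12, n_loci = 60,
                      fst_levels = 0, fst_weights = 1,
                      missing_rate = 0, seed = 424)
    m <- simulate_dataset(cfg)
    return(list(matrix = m,
                manifest = list(chance_accuracy = 25,
                                majority_error = 0.75)))
  }
  if (name == "planted_signal") {
    cfg <- sim_config(n_pops = 5, n_per_pop = 10, n_loci = 100,
                      fst_levels = c(0.005, 0.4), fst_weights = c(0.9, 0.1),
                      missing_rate = 0, seed = 77)
    freqs <- simulate_frequencies(cfg)
    informative <- colnames(freqs$freq)[freqs$fst == 0.4]
    m <- simulate_genotypes(freqs, cfg)
    return(list(matrix = m,
                manifest = list(informative = informative)))
  }
  # duplicate_loci: two extra copies of the most differentiated locus, so the
  # copies always clear the pruning FST floor
  cfg <- sim_config(n_pops = 3, n_per_pop = 10, n_loci = 12,
                    fst_levels = 0.25, fst_weights = 1,
                    missing_rate = 0, seed = 99)
  m <- simulate_dataset(cfg)
  d <- m$dosages
  best <- names(which.max(wc_theta_locus(m)))
  d <- cbind(d, DUPA = d[, best], DUPB = d[, best])
  list(matrix = genotype_matrix(d, m$populations),
       manifest = list(duplicated = c(best, "DUPA", "DUPB")))
}
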