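# Independent oracles used to cross-check the package implementations.
# These are deliberately written from different formulations than the
# package code (nested ANOVA on allele indicators, plain loops) and must
# stay independent of the functions they check.

# Weir-Cockerham theta for ONE locus via the allele-level nested ANOVA:
# alleles within individuals within populations, mean squares MSP/MSI/MSG.
oracle_wc_theta <- function(dosages, pops) {
  ok <- !is.na(dosages)
  d <- dosages[ok]
  pp <- pops[ok]
  tab <- table(pp)
  r <- length(tab)
  if (r < 2) return(NA_real_)
  x <- 1 - d                       # minor-allele frequency per individual
  n_i <- as.numeric(tab[match(unique(pp), names(tab))])
  upops <- unique(pp)
  N <- sum(n_i)
  if (N / r <= 1) return(NA_real_)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  grand <- mean(x[match(pp, pp)] * 0 + x)  # grand mean of individual freqs
  grand <- sum(x) / N
  ssp <- 0; ssi <- 0; ssg <- 0
  for (k in seq_along(upops)) {
    xi <- x[pp == upops[k]]
    pm <- mean(xi)
    ssp <- ssp + 2 * length(xi) * (pm - grand)^2
    ssi <- ssi + sum(2 * (xi - pm)^2)
    # within-individual allele SS: heterozygote contributes 2*(0.5)^2 = 0.5
    ssg <- ssg + sum(ifelse(abs(xi - 0.5) < 1e-9, 0.5, 0))
  }
  msp <- ssp / (r - 1)
  msi <- ssi / (N - r)
  msg <- ssg / N
  s_a <- (msp - msi) / (2 * nc)
  s_b <- (msi - msg) / 2
  s_c <- msg
  denom <- s_a + s_b + s_c
  if (denom == 0) return(NA_real_)
  s_a / denom
}

oracle_wc_theta_matrix <- function(m) {
  vapply(seq_len(ncol(m$dosages)),
         function(l) oracle_wc_theta(m$dosages[, l], m$populations),
         numeric(1))
}

# exhaustive greedy LD/FST pruning, re-coded as a plain double loop
oracle_prune <- function(m, stats, r2_max, fst_min) {
  th <- setNames(stats$global_theta, stats$locus_id)
  cand <- names(th)[!is.na(th) & th >= fst_min]
  cand <- cand[order(-th[cand], cand)]
  kept <- character(0)
  for (l in cand) {
    ok <- TRUE
    for (k in kept) {
      x <- m$dosages[, l]; yv <- m$dosages[, k]
      cc <- sum(!is.na(x) & !is.na(yv))
      r2 <- if (cc < 10) 0 else suppressWarnings(cor(x, yv, use = "pairwise.complete.obs")^2)
      if (is.na(r2)) r2 <- 0
      if (r2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, l)
  }
  kept
}

# two-population, one-locus heterozygote posterior by scalar arithmetic
oracle_het_posterior <- function(c1, t1, c2, t2) {
  q1 <- (c1 + 0.5) / (t1 + 1)
  q2 <- (c2 + 0.5) / (t2 + 1)
  l1 <- 2 * q1 * (1 - q1)
  l2 <- 2 * q2 * (1 - q2)
  c(l1, l2) / (l1 + l2)
}

# small random genotype matrix for property tests
random_gm <- function(n_pops = 3, n_per_pop = 20, n_loci = 15, seed = 1,
                      miss = 0.02) {
  set.seed(seed)
  n <- n_pops * n_per_pop
  freqs <- matrix(runif(n_pops * n_loci, 0.05, 0.95), n_pops, n_loci)
  pops <- rep(sprintf("P%02d", seq_len(n_pops)), each = n_per_pop)
  d <- matrix(NA_real_, n, n_loci)
  for (k in seq_len(n_pops)) {
    rows <- which(pops == sprintf("P%02d", k))
    d[rows, ] <- matrix(rbinom(length(rows) * n_loci, 2,
                               rep(freqs[k, ], each = length(rows))),
                        length(rows), n_loci)
  }
  d <- 1 - d / 2
  if (miss > 0) d[runif(length(d)) < miss] <- NA
  dimnames(d) <- list(sprintf("%s_%03d", pops, seq_len(n)),
                      sprintf("L%03d", seq_len(n_loci)))
  genotype_matrix(d, pops)
}
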