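#' Weir-Cockerham variance components per locus
#'
#' Computes the three variance components of the Weir & Cockerham (1984)
#' theta estimator at every locus: `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals), using
#' per-locus complete-case sample sizes, population allele frequencies and
#' observed heterozygote proportions. Missing genotypes are handled through
#' the estimator's unequal-sample-size correction (n_c); populations with no
#' genotyped individual at a locus simply drop out of that locus.
#'
#' @param m a [genotype_matrix()] with at least two populations.
#' @return A data.frame with columns `locus_id`, `a`, `b`, `c`. Components are
#'   `NA` where fewer than two populations are genotyped or the mean sample
#'   size is 1 (the estimator is undefined there).
#' @export
wc_components <- function(m) {
  stop_if_not_gm(m)
  pops <- m$populations
  if (length(unique(pops)) < 2)
    stop("Weir-Cockerham theta needs at least two populations", call. = FALSE)
  d <- m$dosages
  called <- !is.na(d)
  d0 <- d
  d0[!called] <- 0

  grp <- factor(pops, levels = sort(unique(pops)))
  nn <- rowsum(called * 1, grp)                  # pops x loci sample sizes
  minor_sum <- rowsum((1 - d0) * called, grp)    # per-pop minor allele freq * n
  het_sum <- rowsum((d0 == 0.5) * called, grp)

  p <- ifelse(nn > 0, minor_sum / pmax(nn, 1), 0)
  h <- ifelse(nn > 0, het_sum / pmax(nn, 1), 0)

  r <- colSums(nn > 0)
  ntot <- colSums(nn)
  nbar <- ifelse(r > 0, ntot / pmax(r, 1), NA_real_)
  # n_c: correction for unequal sample sizes
  nc <- ifelse(r > 1, (ntot - colSums(nn^2) / ntot) / (r - 1), NA_real_)
  pbar <- colSums(nn * p) / ntot
  s2 <- colSums(nn * sweep(p, 2, pbar, "-")^2) / ((r - 1) * nbar)
  hbar <- colSums(nn * h) / ntot

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  bad <- r < 2 | !is.finite(nbar) | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  data.frame(locus_id = colnames(d), a = a, b = b, c = cc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-locus global Weir-Cockerham theta
#'
#' `theta = a / (a + b + c)` from [wc_components()]. Monomorphic loci (all
#' three components zero) are undefined and return `NA` rather than 0.
#'
#' @inheritParams wc_components
#' @return Named numeric vector of per-locus theta, `NA` where undefined.
#' @export
wc_theta_locus <- function(m) {
  comp <- wc_components(m)
  denom <- comp$a + comp$b + comp$c
  theta <- ifelse(!is.na(denom) & denom != 0, comp$a / denom, NA_real_)
  setNames(theta, comp$locus_id)
}

#' Multi-locus Weir-Cockerham theta (ratio of sums)
#'
#' Sums the `a` components over loci and divides by the summed
#' `a + b + c` (never a mean of per-locus ratios), following the estimator's
#' multi-locus definition. Loci with undefined components are skipped.
#'
#' @param comp either the output of [wc_components()] or a
#'   [genotype_matrix()] (components are then computed internally).
#' @return A single theta value; `NA` if every locus is monomorphic.
#' @export
wc_theta_multilocus <- function(comp) {
  if (inherits(comp, "genotype_matrix")) comp <- wc_components(comp)
  ok <- !is.na(comp$a)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!length(which(ok)) || denom == 0) return(NA_real_)
  sum(comp$a[ok]) / denom
}

#' Per-locus summary statistics
#'
#' MAF (pooled, over non-missing calls), missing rate and global
#' Weir-Cockerham theta for every locus.
#'
#' @inheritParams wc_components
#' @return A data.frame with columns `locus_id`, `maf`, `missing_rate`,
#'   `global_theta`.
#' @export
locus_stats <- function(m) {
  stop_if_not_gm(m)
  d <- m$dosages
  f_minor <- colMeans(1 - d, na.rm = TRUE)       # pooled minor allele freq
  maf <- pmin(f_minor, 1 - f_minor)
  maf[is.nan(maf)] <- NA_real_
  data.frame(locus_id = colnames(d),
             maf = maf,
             missing_rate = colMeans(is.na(d)),
             global_theta = unname(wc_theta_locus(m)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise population FST matrix
#'
#' Multi-locus Weir-Cockerham theta for every unordered pair of populations,
#' computed by restricting the matrix to the two populations. Populations
#' with fewer than two individuals are excluded with a warning. The result is
#' symmetric with a zero diagonal.
#'
#' @inheritParams wc_components
#' @return A symmetric numeric matrix (populations x populations).
#' @export
pairwise_fst <- function(m) {
  stop_if_not_gm(m)
  tab <- table(m$populations)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding population(s) with < 2 individuals: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(sort(unique(m$populations)), small)
  if (length(keep) < 2)
    stop("pairwise FST needs at least two populations of size >= 2",
         call. = FALSE)
  k <- length(keep)
  out <- matrix(0, k, k, dimnames = list(keep, keep))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sel <- m$populations %in% keep[c(i, j)]
      sub <- genotype_matrix(m$dosages[sel, , drop = FALSE],
                             m$populations[sel])
      th <- wc_theta_multilocus(sub)
      out[i, j] <- th
      out[j, i] <- th
    }
  }
  out
}

#' Rank loci by descending global FST
#'
#' Ties are broken by locus id so the ranking is deterministic; loci with
#' undefined theta (monomorphic) sort last.
#'
#' @param stats output of [locus_stats()] (needs `locus_id`, `global_theta`).
#' @return Character vector of locus ids, best first.
#' @export
rank_by_global_fst <- function(stats) {
  if (!all(c("locus_id", "global_theta") %in% names(stats)))
    stop("stats must have locus_id and global_theta columns", call. = FALSE)
  ord <- order(-stats$global_theta, stats$locus_id, na.last = TRUE)
  stats$locus_id[ord]
}
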