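#' Baseline allele counts for assignment
#'
#' Per population and panel locus: the minor-allele count and the total
#' number of called alleles, accumulated over the non-missing calls of ALL
#' individuals (training and holdout alike — the leave-one-out step below is
#' what prevents self-inflation).
#'
#' @param m a [genotype_matrix()].
#' @param panel an [snp_panel()] or a character vector of locus ids.
#' @return A list of class `gsi_baseline` with integer matrices `counts` and
#'   `totals` (populations x loci), plus `populations` and `loci`.
#' @export
build_baseline <- function(m, panel) {
  stop_if_not_gm(m)
  loci <- if (inherits(panel, "snp_panel")) panel$loci else as.character(panel)
  sub <- subset_loci(m, loci)
  d <- sub$dosages
  called <- !is.na(d)
  d0 <- d; d0[!called] <- 0
  grp <- factor(m$populations, levels = sort(unique(m$populations)))
  counts <- rowsum(2 * (1 - d0) * called, grp)
  totals <- rowsum(2 * called, grp)
  if (length(loci)) {
    dead <- rowSums(totals) == 0
    if (any(dead))
      stop("population(s) with no called allele at any panel locus: ",
           paste(levels(grp)[dead], collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, totals = totals,
                 populations = levels(grp), loci = loci),
            class = "gsi_baseline")
}

# log P(genotype dosage | smoothed minor-allele frequency q), HWE proportions
genotype_loglik <- function(d, q) {
  ifelse(d == 0, 2 * log(q),
         ifelse(d == 0.5, log(2) + log(q) + log(1 - q), 2 * log(1 - q)))
}

#' Posterior population membership for one genotype vector
#'
#' Per population the likelihood multiplies Hardy-Weinberg genotype
#' probabilities at every non-missing panel locus, using Dirichlet(1/2, 1/2)
#' smoothed allele frequencies `q = (count + 0.5) / (total + 1)`; the
#' posterior is the normalized likelihood under a uniform population prior,
#' accumulated in log space. When `leave_out_pop` is given, the individual's
#' own alleles are first subtracted from that population's counts
#' (leave-one-out).
#'
#' @param dosages numeric vector of dosages aligned to `baseline$loci`
#'   (`NA` = missing; missing loci are skipped).
#' @param baseline a [build_baseline()] object.
#' @param leave_out_pop population whose counts should exclude this
#'   individual, or `NULL` for an individual not in the baseline.
#' @return Named posterior vector over populations (sums to 1).
#' @export
assign_posterior <- function(dosages, baseline, leave_out_pop = NULL) {
  pops <- baseline$populations
  K <- length(pops)
  obs <- !is.na(dosages)
  if (!any(obs)) return(setNames(rep(1 / K, K), pops))
  d <- dosages[obs]
  ll <- numeric(K)
  for (k in seq_len(K)) {
    cnt <- baseline$counts[k, obs]
    tot <- baseline$totals[k, obs]
    if (!is.null(leave_out_pop) && pops[k] == leave_out_pop) {
      cnt <- cnt - 2 * (1 - d)
      tot <- tot - 2
      if (any(cnt < -1e-9) || any(tot < 0))
        stop("internal error: leave-one-out produced negative allele counts",
             call. = FALSE)
      cnt <- pmax(cnt, 0)
    }
    q <- (cnt + 0.5) / (tot + 1)
    ll[k] <- sum(genotype_loglik(d, q))
  }
  w <- exp(ll - max(ll))
  setNames(w / sum(w), pops)
}

#' Leave-one-out posterior for a baseline individual
#'
#' Convenience wrapper around [assign_posterior()]: pulls the individual's
#' panel dosages from the matrix and subtracts its alleles from its own
#' population's baseline counts before computing frequencies.
#'
#' @param ind individual id (present in `m`).
#' @param m the [genotype_matrix()] the baseline was built from.
#' @param baseline a [build_baseline()] object.
#' @param panel panel used for the baseline (for locus alignment).
#' @return Named posterior vector over populations.
#' @export
loo_posterior <- function(ind, m, baseline, panel) {
  stop_if_not_gm(m)
  i <- match(ind, individual_ids(m))
  if (is.na(i)) stop("unknown individual: ", ind, call. = FALSE)
  loci <- if (inherits(panel, "snp_panel")) panel$loci else as.character(panel)
  dos <- m$dosages[i, loci]
  assign_posterior(dos, baseline, leave_out_pop = m$populations[i])
}

#' Leave-one-out self-assignment of every individual
#'
#' Builds the baseline from all individuals, assigns each individual to the
#' population with the highest leave-one-out posterior (ties to the lowest
#' population label), and flags which individuals belong to the holdout set
#' of `split`. Only the holdout rows should enter accuracy summaries.
#'
#' @param m a [genotype_matrix()].
#' @param panel an [snp_panel()] or character vector of locus ids.
#' @param split a [training_split()] over the individuals of `m`.
#' @return A data.frame of class `assignment_result` with columns
#'   `individual`, `true_pop`, `assigned_pop`, `correct`, `holdout`, then one
#'   `post.<population>` column per population.
#' @export
self_assign <- function(m, panel, split) {
  stop_if_not_gm(m)
  baseline <- build_baseline(m, panel)
  ids <- individual_ids(m)
  K <- length(baseline$populations)
  post <- matrix(NA_real_, length(ids), K,
                 dimnames = list(ids, baseline$populations))
  loci <- baseline$loci
  for (i in seq_along(ids)) {
    dos <- if (length(loci)) m$dosages[i, loci] else numeric(0)
    post[i, ] <- assign_posterior(dos, baseline,
                                  leave_out_pop = m$populations[i])
  }
  assigned <- baseline$populations[apply(post, 1, which.max)]  # tie -> lowest
  out <- data.frame(individual = ids,
                    true_pop = m$populations,
                    assigned_pop = assigned,
                    correct = assigned == m$populations,
                    holdout = ids %in% split$holdout,
                    stringsAsFactors = FALSE)
  colnames(post) <- paste0("post.", colnames(post))
  out <- cbind(out, as.data.frame(post, optional = TRUE))
  rownames(out) <- NULL
  class(out) <- c("assignment_result", "data.frame")
  out
}

#' Overall and per-population self-assignment accuracy
#'
#' Overall accuracy is the percentage of correctly assigned individuals;
#' per-population accuracy is the same within each true population. By the
#' training/holdout design only holdout individuals are scored by default;
#' `holdout_only = FALSE` exposes the all-individual diagnostic.
#'
#' @param results an `assignment_result` from [self_assign()].
#' @param holdout_only score holdout individuals only (default `TRUE`).
#' @return A list with `overall` (percent) and `per_population` (named
#'   percent vector).
#' @export
accuracy_summary <- function(results, holdout_only = TRUE) {
  r <- if (holdout_only) results[results$holdout, , drop = FALSE] else results
  if (!nrow(r)) stop("no individuals to score", call. = FALSE)
  per <- 100 * vapply(split(r$correct, r$true_pop), mean, numeric(1))
  list(overall = 100 * mean(r$correct),
       per_population = per[sort(names(per))])
}

#' Simulate genotypes from a baseline by bootstrap sampling
#'
#' Draws `n_per_pop` individuals per population with genotypes sampled
#' locus-independently under Hardy-Weinberg proportions from the smoothed
#' baseline frequencies. Intended for power checks; the headline accuracy is
#' computed on the real (or simulated-input) individuals via [self_assign()].
#'
#' @param baseline a [build_baseline()] object with at least one locus.
#' @param n_per_pop individuals to draw per population.
#' @param seed integer seed.
#' @return A [genotype_matrix()] of simulated individuals.
#' @export
simulate_baseline_genotypes <- function(baseline, n_per_pop, seed = 1) {
  if (!length(baseline$loci)) stop("empty baseline", call. = FALSE)
  pops <- baseline$populations
  L <- length(baseline$loci)
  with_seed(seed, {
    rows <- list(); labs <- character(0); ids <- character(0)
    for (k in seq_along(pops)) {
      q <- (baseline$counts[k, ] + 0.5) / (baseline$totals[k, ] + 1)
      mc <- matrix(rbinom(n_per_pop * L, 2, rep(q, each = n_per_pop)),
                   n_per_pop, L)
      rows[[k]] <- 1 - mc / 2
      labs <- c(labs, rep(pops[k], n_per_pop))
      ids <- c(ids, sprintf("%s_sim%03d", pops[k], seq_len(n_per_pop)))
    }
  })
  d <- do.call(rbind, rows)
  dimnames(d) <- list(ids, baseline$loci)
  genotype_matrix(d, labs)
}
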