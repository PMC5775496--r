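#' Locus-filtering configuration
#'
#' Bundles the filtering thresholds: loci with pooled minor allele frequency
#' below `maf_min` are removed, as are loci missing in more than
#' `missing_max` of the individuals; redundancy pruning keeps loci with
#' global FST of at least `fst_min` whose squared dosage correlation with
#' every already-kept locus is at most `r2_max`. `impute_trees` and
#' `impute_iters` control the proximity-based forest imputer.
#'
#' @param maf_min minimum pooled minor allele frequency (default 0.05).
#' @param missing_max maximum per-locus missing rate (default 0.05).
#' @param r2_max maximum squared dosage correlation between kept loci
#'   (default 0.2).
#' @param fst_min minimum per-locus global FST for pruning (default 0.05).
#' @param impute_trees trees per imputation forest (default 5000).
#' @param impute_iters proximity-update rounds (default 5).
#' @param seed integer seed for the imputation forests.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05, missing_max = 0.05, r2_max = 0.2,
                          fst_min = 0.05, impute_trees = 5000,
                          impute_iters = 5, seed = 1) {
  stopifnot(maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1,
            r2_max >= 0, r2_max <= 1, fst_min >= 0, fst_min <= 1,
            impute_trees >= 1, impute_iters >= 1)
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 r2_max = r2_max, fst_min = fst_min,
                 impute_trees = as.integer(impute_trees),
                 impute_iters = as.integer(impute_iters),
                 seed = as.integer(seed)),
            class = "filter_config")
}

#' Filter loci on pooled minor allele frequency
#'
#' Removes loci whose pooled MAF (over non-missing calls, all populations
#' pooled) is below `maf_min`; a locus at exactly the threshold is retained.
#'
#' @param m a [genotype_matrix()].
#' @param maf_min MAF threshold.
#' @return A list with elements `matrix` (the filtered [genotype_matrix()])
#'   and `removed` (ids of dropped loci).
#' @export
filter_maf <- function(m, maf_min = 0.05) {
  stop_if_not_gm(m)
  f <- colMeans(1 - m$dosages, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0  # fully missing locus: no observed minor allele
  keep <- maf >= maf_min
  if (!any(keep)) warning("all loci removed by the MAF filter", call. = FALSE)
  list(matrix = genotype_matrix(m$dosages[, keep, drop = FALSE], m$populations),
       removed = colnames(m$dosages)[!keep])
}

#' Filter loci on missing rate
#'
#' Removes loci with missing data in more than `missing_max` of all
#' individuals pooled (strictly more; a locus at the boundary is kept).
#'
#' @inheritParams filter_maf
#' @param missing_max missing-rate threshold.
#' @return Same shape as [filter_maf()].
#' @export
filter_missing <- function(m, missing_max = 0.05) {
  stop_if_not_gm(m)
  rate <- colMeans(is.na(m$dosages))
  keep <- rate <= missing_max
  if (!any(keep))
    warning("all loci removed by the missingness filter", call. = FALSE)
  list(matrix = genotype_matrix(m$dosages[, keep, drop = FALSE], m$populations),
       removed = colnames(m$dosages)[!keep])
}

#' Impute sparse missing genotypes with forest proximities
#'
#' Missing cells are initialised to the within-population per-locus mode
#' (falling back to the global mode when the population has no observed call
#' at the locus), then refined over `impute_iters` rounds: a classification
#' forest of `impute_trees` trees is grown on the current matrix to predict
#' population labels, and each missing cell is replaced by the
#' proximity-weighted average of the observed dosages at its locus. After the
#' final round values snap to the nearest of `{0, 0.5, 1}` (ties to the lower
#' code). Observed cells are never altered.
#'
#' @param m a [genotype_matrix()] whose per-locus missing rate has already
#'   been capped by [filter_missing()].
#' @param cfg a [filter_config()].
#' @return A complete [genotype_matrix()] (no missing cells).
#' @export
impute_missing <- function(m, cfg = filter_config()) {
  stop_if_not_gm(m)
  d <- m$dosages
  if (!anyNA(d)) return(m)
  all_miss <- colSums(!is.na(d)) == 0
  if (any(all_miss))
    stop("cannot impute: locus with no observed call: ",
         paste(colnames(d)[all_miss], collapse = ", "), call. = FALSE)

  miss_idx <- which(is.na(d), arr.ind = TRUE)
  obs <- !is.na(d)
  mode_of <- function(x) {
    tab <- table(factor(x, levels = c(0, 0.5, 1)))
    as.numeric(names(tab)[which.max(tab)])  # tie -> lower dosage code
  }
  work <- d
  for (r in seq_len(nrow(miss_idx))) {
    i <- miss_idx[r, 1]; l <- miss_idx[r, 2]
    same <- m$populations == m$populations[i] & obs[, l]
    work[i, l] <- if (any(same)) mode_of(d[same, l]) else mode_of(d[obs[, l], l])
  }

  classes <- sort(unique(m$populations))
  y <- match(m$populations, classes) - 1L
  p <- ncol(work)
  mtry <- min(p, 2L * ceiling(sqrt(p)))
  for (it in seq_len(cfg$impute_iters)) {
    fit <- cpp_grow_forest(work, y, length(classes), cfg$impute_trees,
                           mtry, 5L, cfg$seed + it)
    prox <- cpp_proximity(fit$trees, work)
    for (r in seq_len(nrow(miss_idx))) {
      i <- miss_idx[r, 1]; l <- miss_idx[r, 2]
      w <- prox[i, obs[, l]]
      if (sum(w) > 0)
        work[i, l] <- sum(w * d[obs[, l], l]) / sum(w)
    }
  }
  codes <- c(0, 0.5, 1)
  for (r in seq_len(nrow(miss_idx))) {
    i <- miss_idx[r, 1]; l <- miss_idx[r, 2]
    work[i, l] <- codes[which.min(abs(codes - work[i, l]))]
  }
  genotype_matrix(work, m$populations)
}

#' Greedy LD/FST redundancy pruning ("top loci")
#'
#' Scans loci in descending global-FST order (ties by locus id, undefined
#' theta last) and keeps a locus iff its global FST is at least `fst_min`
#' and its squared Pearson correlation of dosage codes with every
#' already-kept locus is at most `r2_max`. Correlations use
#' pairwise-complete individuals; pairs with fewer than 10 complete
#' individuals are treated as uncorrelated. The result is ordered by
#' descending FST and is independent of the input column order.
#'
#' @param m a [genotype_matrix()].
#' @param stats [locus_stats()] covering every locus of `m`.
#' @param r2_max squared-correlation ceiling.
#' @param fst_min FST floor.
#' @return Ordered character vector of kept locus ids.
#' @export
prune_top_loci <- function(m, stats, r2_max = 0.2, fst_min = 0.05) {
  stop_if_not_gm(m)
  if (!all(locus_ids(m) %in% stats$locus_id))
    stop("stats are missing for some loci", call. = FALSE)
  theta <- setNames(stats$global_theta, stats$locus_id)[locus_ids(m)]
  cand <- names(theta)[!is.na(theta) & theta >= fst_min]
  cand <- cand[order(-theta[cand], cand)]
  if (!length(cand)) return(character(0))

  d <- m$dosages
  kept <- character(0)
  few_pairs <- 0L
  for (l in cand) {
    if (length(kept)) {
      x <- d[, l]
      kd <- d[, kept, drop = FALSE]
      npair <- colSums(!is.na(kd) & !is.na(x))
      suppressWarnings(cc <- cor(x, kd, use = "pairwise.complete.obs"))
      r2 <- as.numeric(cc)^2
      r2[is.na(r2)] <- 0           # zero-variance pair: no usable correlation
      low <- npair < 10
      if (any(low)) {
        few_pairs <- few_pairs + sum(low)
        r2[low] <- 0
      }
      if (any(r2 > r2_max)) next
    }
    kept <- c(kept, l)
  }
  if (few_pairs > 0)
    message(few_pairs, " locus pair(s) had < 10 complete individuals; treated as uncorrelated")
  kept
}

#' Run the full locus-filtering stage
#'
#' Convenience wrapper: MAF filter, missingness filter, imputation, then
#' LD/FST pruning; returns the pruned matrix together with a per-locus
#' removal report.
#'
#' @param m a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return A list with `matrix` (filtered, imputed, pruned
#'   [genotype_matrix()]), `stats` (post-imputation [locus_stats()]) and
#'   `report` (data.frame: locus, removal reason).
#' @export
apply_filters <- function(m, cfg = filter_config()) {
  s1 <- filter_maf(m, cfg$maf_min)
  s2 <- filter_missing(s1$matrix, cfg$missing_max)
  imp <- impute_missing(s2$matrix, cfg)
  stats <- locus_stats(imp)
  kept <- prune_top_loci(imp, stats, cfg$r2_max, cfg$fst_min)
  pruned <- setdiff(locus_ids(imp), kept)
  report <- data.frame(
    locus = c(s1$removed, s2$removed, pruned),
    reason = c(rep("maf", length(s1$removed)),
               rep("missing", length(s2$removed)),
               rep("redundancy", length(pruned))),
    stringsAsFactors = FALSE)
  list(matrix = subset_loci(imp, kept), stats = stats, report = report)
}
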