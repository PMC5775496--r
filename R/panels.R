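#' SNP panel object
#'
#' An ordered locus whitelist tagged with the selection method (`"FST"`,
#' `"RF"`, `"RRF"` or `"GRRF"`) and the parameter that produced it (a rank
#' level k, a lambda or a gamma).
#'
#' @param method one of `"FST"`, `"RF"`, `"RRF"`, `"GRRF"`.
#' @param parameter the selection parameter value.
#' @param loci ordered character vector of unique locus ids.
#' @return A list of class `snp_panel` with elements `method`, `parameter`,
#'   `loci`, `size`.
#' @export
snp_panel <- function(method, parameter, loci) {
  method <- match.arg(method, c("FST", "RF", "RRF", "GRRF"))
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("panel loci must be unique", call. = FALSE)
  structure(list(method = method, parameter = parameter, loci = loci,
                 size = length(loci)),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %s (parameter %s), %d loci\n",
              x$method, format(x$parameter), x$size))
  invisible(x)
}

#' Stratified training/holdout split
#'
#' Randomly samples `fraction` of each population (without replacement) as
#' the training set used for locus selection; the rest is the holdout set on
#' which self-assignment accuracy is scored. The per-population training
#' count is `fraction * n` rounded half up, with a minimum of 1.
#'
#' @param m a [genotype_matrix()]; every population needs at least 2
#'   individuals.
#' @param fraction training fraction per population (default 1/3).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return A list of class `split_spec` with `training` and `holdout`
#'   individual ids, `fraction` and `seed`.
#' @export
training_split <- function(m, fraction = 1 / 3, seed = 1) {
  stop_if_not_gm(m)
  stopifnot(fraction > 0, fraction < 1)
  tab <- table(m$populations)
  if (any(tab < 2))
    stop("population(s) with a single individual cannot be split: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  ids <- individual_ids(m)
  training <- character(0)
  with_seed(seed, {
    for (pp in sort(unique(m$populations))) {
      pool <- ids[m$populations == pp]
      k <- max(1L, round_half_up(length(pool) * fraction))
      training <- c(training, sample(pool, k))
    }
  })
  structure(list(training = sort(training),
                 holdout = sort(setdiff(ids, training)),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec: %d training / %d holdout (fraction %.3f, seed %d)\n",
              length(x$training), length(x$holdout), x$fraction, x$seed))
  invisible(x)
}

#' FST-ranked panel
#'
#' The top `size` loci of [rank_by_global_fst()]. Pass statistics computed on
#' the training individuals only, so that panel selection never sees the
#' holdout set.
#'
#' @param stats [locus_stats()] (training individuals).
#' @param size panel size; must not exceed the number of loci.
#' @return An [snp_panel()] with method `"FST"`.
#' @export
fst_rank_panel <- function(stats, size) {
  if (size > nrow(stats))
    stop("requested panel size exceeds the number of loci", call. = FALSE)
  snp_panel("FST", size, rank_by_global_fst(stats)[seq_len(size)])
}

#' Consensus panel across ranked importance lists
#'
#' The panel is the intersection of the top-`k` loci of every list (each list
#' already truncated to positive-MDA loci), ordered by mean rank across the
#' lists with ties broken by locus id. Five lists from independently seeded
#' forest runs is the standard input.
#'
#' @param importance_lists list of ranked character vectors (best first).
#' @param k rank level; must not exceed any list's length.
#' @return An [snp_panel()] with method `"RF"` and parameter `k`.
#' @export
rf_consensus_panel <- function(importance_lists, k) {
  stopifnot(length(importance_lists) >= 2)
  lens <- lengths(importance_lists)
  if (any(k > lens)) {
    short <- which(k > lens)[1]
    stop(sprintf("rank level %d exceeds the length of list %d (%d loci)",
                 k, short, lens[short]), call. = FALSE)
  }
  tops <- lapply(importance_lists, function(x) x[seq_len(k)])
  common <- Reduce(intersect, tops)
  if (length(common)) {
    ranks <- vapply(importance_lists, function(x) match(common, x),
                    numeric(length(common)))
    mean_rank <- rowMeans(matrix(ranks, nrow = length(common)))
    common <- common[order(mean_rank, common)]
  }
  snp_panel("RF", k, common)
}

rf_ranked_lists <- function(train, cfg, n_runs = 5) {
  lapply(seq_len(n_runs) - 1L, function(s) {
    run_cfg <- forest_config(cfg$ntree, cfg$mtry, cfg$min_node, cfg$seed + s)
    f <- grow_forest(train, cfg = run_cfg)
    imp <- mda_importance(f, train, seed = cfg$seed + 100L + s)
    imp <- imp[imp > 0]
    names(imp)[order(-imp, names(imp))]
  })
}

# smallest k whose consensus panel size is closest to `target`
bisect_rank_level <- function(importance_lists, target, tol = 0.1) {
  hi <- min(lengths(importance_lists))
  size_at <- function(k) length(rf_consensus_panel(importance_lists, k)$loci)
  lo <- 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (size_at(mid) < target) lo <- mid + 1L else hi <- mid
  }
  cand <- unique(pmax(1L, pmin(min(lengths(importance_lists)),
                               c(lo - 1L, lo, lo + 1L))))
  sizes <- vapply(cand, size_at, integer(1))
  best <- cand[which.min(abs(sizes - target))]
  achieved <- size_at(best)
  if (abs(achieved - target) > tol * target)
    warning(sprintf("target size %d unreachable; closest consensus size is %d (rank %d)",
                    target, achieved, best), call. = FALSE)
  best
}

#' Build a family of panels by one selection method
#'
#' Runs one selection method over a parameter grid on the training
#' individuals and returns one panel per grid value.
#'
#' * `"FST"`: grid of panel sizes; top loci by training global FST.
#' * `"RF"`: grid of target panel sizes; five forest runs differing only by
#'   seed give five positive-MDA ranked lists, and the consensus rank level
#'   is found by bisection to land within 10% of each target.
#' * `"RRF"`: grid of lambda values; the selected set of each regularized
#'   forest is the panel.
#' * `"GRRF"`: grid of gamma values; a single fresh forest run's MDA guides
#'   all gammas.
#'
#' @param train a complete [genotype_matrix()] of training individuals only.
#' @param cfg a [forest_config()] (also used for the guide/list runs).
#' @param method selection method.
#' @param grid numeric parameter grid (sizes, lambdas or gammas).
#' @return A list of [snp_panel()] objects, one per grid value.
#' @export
sweep_panels <- function(train, cfg = forest_config(), method, grid) {
  method <- match.arg(method, c("FST", "RF", "RRF", "GRRF"))
  if (!length(grid)) stop("empty parameter grid", call. = FALSE)
  switch(method,
    FST = {
      stats <- locus_stats(train)
      lapply(grid, function(sz) fst_rank_panel(stats, sz))
    },
    RF = {
      lists <- rf_ranked_lists(train, cfg)
      lapply(grid, function(target) {
        k <- bisect_rank_level(lists, target)
        rf_consensus_panel(lists, k)
      })
    },
    RRF = {
      lapply(grid, function(lam) {
        rrf <- grow_regularized_forest(train, cfg = cfg,
                                       reg = reg_params(lambda = lam))
        snp_panel("RRF", lam, rrf$selected)
      })
    },
    GRRF = {
      guide_cfg <- forest_config(cfg$ntree, cfg$mtry, cfg$min_node,
                                 cfg$seed + 500L)
      guide_f <- grow_forest(train, cfg = guide_cfg)
      guide <- mda_importance(guide_f, train, seed = cfg$seed + 600L)
      lapply(grid, function(g) {
        grrf <- grow_regularized_forest(train, cfg = cfg,
                                        reg = reg_params(lambda = 1, gamma = g,
                                                         base_importance = guide))
        snp_panel("GRRF", g, grrf$selected)
      })
    })
}
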