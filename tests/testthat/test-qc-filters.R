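# matrix with hand-chosen allele counts: 50 individuals, pooled MAF per locus
# is the mean of (1 - dosage)
maf_fixture <- function() {
  n <- 50
  make_col <- function(n0, nh) c(rep(0, n0), rep(0.5, nh), rep(1, n - n0 - nh))
  d <- cbind(
    maf_0.04  = make_col(0, 4),    # 4 minor alleles of 100
    maf_0.05  = make_col(0, 5),    # exactly at the threshold
    maf_0.10  = make_col(2, 6),
    maf_0.30  = make_col(10, 10),
    maf_0.00  = make_col(0, 0)     # monomorphic
  )
  rownames(d) <- sprintf("i%02d", 1:n)
  genotype_matrix(d, rep(c("A", "B"), each = 25))
}

test_that("MAF filter removes below-threshold loci, keeps the boundary", {
  res <- filter_maf(maf_fixture(), 0.05)
  expect_setequal(res$removed, c("maf_0.04", "maf_0.00"))
  expect_equal(locus_ids(res$matrix), c("maf_0.05", "maf_0.10", "maf_0.30"))
  # hand-recount over a random fixture
  m <- random_gm(3, 15, 30, seed = 23)
  got <- filter_maf(m, 0.1)
  f <- colMeans(1 - m$dosages, na.rm = TRUE)
  expect_setequal(got$removed, locus_ids(m)[pmin(f, 1 - f) < 0.1])
})

test_that("missingness filter is strict 'more than' and recounts correctly", {
  n <- 100
  d <- cbind(ok5 = c(rep(NA, 5), rep(1, 95)),
             bad6 = c(rep(NA, 6), rep(0.5, 94)),
             clean = rep(0, n))
  m <- genotype_matrix(d, rep(c("A", "B"), each = 50))
  res <- filter_missing(m, 0.05)
  expect_equal(res$removed, "bad6")

  m2 <- random_gm(4, 20, 40, seed = 29, miss = 0.05)
  got <- filter_missing(m2, 0.05)
  expect_setequal(got$removed,
                  locus_ids(m2)[colMeans(is.na(m2$dosages)) > 0.05])
  # no missing cells: identity
  m3 <- random_gm(2, 10, 10, seed = 31, miss = 0)
  expect_equal(filter_missing(m3, 0.05)$matrix$dosages, m3$dosages)
})

test_that("filters are idempotent", {
  m <- random_gm(3, 20, 40, seed = 37, miss = 0.04)
  once <- filter_maf(m, 0.1)$matrix
  expect_equal(filter_maf(once, 0.1)$matrix$dosages, once$dosages)
  oncem <- filter_missing(m, 0.03)$matrix
  expect_equal(filter_missing(oncem, 0.03)$matrix$dosages, oncem$dosages)
})

test_that("imputation preserves observed cells and fills plausibly", {
  # no missing cells: exact no-op
  m0 <- random_gm(2, 10, 8, seed = 41, miss = 0)
  expect_equal(impute_missing(m0)$dosages, m0$dosages)

  # unanimous within-population neighbourhood
  d <- matrix(1, 12, 4, dimnames = list(sprintf("i%02d", 1:12),
                                        paste0("L", 1:4)))
  d[7:12, ] <- 0
  d[1, 2] <- NA
  m1 <- genotype_matrix(d, rep(c("A", "B"), each = 6))
  cfg <- filter_config(impute_trees = 100, impute_iters = 2, seed = 3)
  imp <- impute_missing(m1, cfg)
  expect_equal(imp$dosages[1, 2], 1)
  # observed cells untouched
  expect_equal(imp$dosages[!is.na(d)], d[!is.na(d)])

  # fully missing locus is not imputable
  d2 <- d; d2[, 3] <- NA
  expect_error(impute_missing(genotype_matrix(d2, rep(c("A", "B"), each = 6)),
                              cfg),
               "no observed call")
})

test_that("mask-and-recover: near-fixed major homozygotes are restored", {
  cfg <- sim_config(n_pops = 5, n_per_pop = 30, n_loci = 800,
                    fst_levels = 0.08, fst_weights = 1,
                    maf_range = c(0.05, 0.3),
                    missing_rate = 0, seed = 47)
  m <- simulate_dataset(cfg)
  d <- m$dosages
  set.seed(48)
  mask <- sample(length(d), round(0.001 * length(d)))
  truth <- d[mask]
  dm <- d; dm[mask] <- NA
  masked <- genotype_matrix(dm, m$populations)

  imp <- impute_missing(masked, filter_config(impute_trees = 500,
                                              impute_iters = 2, seed = 49))
  # among masked cells that were major homozygotes in a population where the
  # major allele is at >= 0.95, at least 90% must come back as 1
  idx <- arrayInd(mask, dim(d))
  pop_freq <- rowsum(1 - dm, m$populations, na.rm = TRUE) /
    rowsum((!is.na(dm)) * 1, m$populations)
  within_major <- 1 - pop_freq[cbind(match(m$populations[idx[, 1]],
                                           rownames(pop_freq)), idx[, 2])]
  sel <- truth == 1 & within_major >= 0.95
  expect_gte(sum(sel), 10)
  recovered <- imp$dosages[mask][sel] == 1
  expect_gte(mean(recovered), 0.9)
  # and observed cells are bit-identical
  expect_identical(imp$dosages[-mask], d[-mask])
})

test_that("redundancy pruning drops duplicates and matches the greedy oracle", {
  fx <- make_fixture("duplicate_loci")
  m <- fx$matrix
  stats <- locus_stats(m)
  kept <- prune_top_loci(m, stats, r2_max = 0.2, fst_min = 0.05)
  # of the three identical copies exactly one survives, the first by id
  copies <- fx$manifest$duplicated
  expect_equal(sum(copies %in% kept), 1)
  expect_equal(intersect(copies, kept), "DUPA")

  # correlated-block fixture vs the independent double-loop oracle
  m2 <- random_gm(4, 20, 14, seed = 53, miss = 0.02)
  d2 <- m2$dosages
  d2 <- cbind(d2, COPY1 = d2[, 2], COPY2 = d2[, 5])
  m2 <- genotype_matrix(d2, m2$populations)
  st2 <- locus_stats(m2)
  expect_equal(prune_top_loci(m2, st2, 0.3, 0.01),
               oracle_prune(m2, st2, 0.3, 0.01))

  # uncorrelated loci above the FST floor are all kept
  m3 <- simulate_dataset(sim_config(n_pops = 4, n_per_pop = 25, n_loci = 20,
                                    fst_levels = 0.3, fst_weights = 1,
                                    missing_rate = 0, seed = 59))
  st3 <- locus_stats(m3)
  kept3 <- prune_top_loci(m3, st3, r2_max = 0.9, fst_min = 0.01)
  expect_gte(length(kept3), 18)  # near-complete retention
})

test_that("pruning is invariant to input column order", {
  m <- random_gm(4, 15, 12, seed = 61, miss = 0)
  st <- locus_stats(m)
  kept <- prune_top_loci(m, st, 0.5, 0.01)
  perm <- sample(n_loci(m))
  mp <- genotype_matrix(m$dosages[, perm], m$populations)
  expect_equal(prune_top_loci(mp, locus_stats(mp), 0.5, 0.01), kept)
})

test_that("apply_filters chains the stages and reports removals", {
  m <- simulate_dataset(sim_config(n_pops = 4, n_per_pop = 15, n_loci = 120,
                                   missing_rate = 0.002, seed = 67))
  out <- apply_filters(m, filter_config(impute_trees = 200, impute_iters = 2,
                                        seed = 5))
  expect_false(anyNA(out$matrix$dosages))
  expect_setequal(c(locus_ids(out$matrix), out$report$locus), locus_ids(m))
  th <- setNames(out$stats$global_theta, out$stats$locus_id)
  expect_true(all(th[locus_ids(out$matrix)] >= 0.05))
})
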