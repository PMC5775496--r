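test_that("baseline counts alleles by hand-verifiable arithmetic", {
  d <- rbind(a1 = c(L1 = 0), a2 = c(L1 = 0.5))
  m <- genotype_matrix(rbind(d, b1 = c(L1 = 1), b2 = c(L1 = NA)),
                       c("A", "A", "B", "B"))
  bl <- build_baseline(m, "L1")
  # pop A: dosage 0 carries 2 minor alleles, 0.5 carries 1 -> 3 of 4
  expect_equal(bl$counts["A", "L1"], 3)
  expect_equal(bl$totals["A", "L1"], 4)
  # missing call contributes nothing
  expect_equal(bl$counts["B", "L1"], 0)
  expect_equal(bl$totals["B", "L1"], 2)

  empty <- build_baseline(m, character(0))
  expect_equal(length(empty$loci), 0)
})

test_that("the hand-computed two-population heterozygote posterior matches", {
  bl <- structure(list(counts = matrix(c(9, 1), 2, 1,
                                       dimnames = list(c("P1", "P2"), "L1")),
                       totals = matrix(c(20, 20), 2, 1,
                                       dimnames = list(c("P1", "P2"), "L1")),
                       populations = c("P1", "P2"), loci = "L1"),
                  class = "gsi_baseline")
  post <- assign_posterior(c(L1 = 0.5), bl)
  want <- oracle_het_posterior(9, 20, 1, 20)
  expect_equal(unname(post), want, tolerance = 1e-12)
  # the scalar arithmetic itself: q1 = 9.5/21, q2 = 1.5/21
  expect_equal(want[1],
               (9.5 / 21 * 11.5 / 21) / (9.5 / 21 * 11.5 / 21 + 1.5 / 21 * 19.5 / 21),
               tolerance = 1e-15)
})

test_that("posterior symmetry, single population, and empty panel", {
  eq <- structure(list(counts = matrix(5, 2, 1,
                                       dimnames = list(c("A", "B"), "L1")),
                       totals = matrix(20, 2, 1,
                                       dimnames = list(c("A", "B"), "L1")),
                       populations = c("A", "B"), loci = "L1"),
                  class = "gsi_baseline")
  expect_equal(unname(assign_posterior(c(L1 = 0.5), eq)), c(0.5, 0.5))

  m <- random_gm(2, 10, 5, seed = 151, miss = 0)
  one <- genotype_matrix(m$dosages[1:10, ], rep("solo", 10))
  bl1 <- build_baseline(one, locus_ids(one))
  expect_equal(unname(assign_posterior(one$dosages[1, ], bl1)), 1)

  sp <- training_split(m, seed = 1)
  res <- self_assign(m, character(0), sp)
  post <- as.matrix(res[, grepl("^post\\.", names(res))])
  expect_true(all(abs(post - 0.5) < 1e-12))
})

test_that("an individual missing at all panel loci gets the uniform posterior", {
  m <- random_gm(3, 8, 6, seed = 157, miss = 0)
  d <- m$dosages
  d[1, ] <- NA
  m2 <- genotype_matrix(d, populations(m))
  bl <- build_baseline(m2, locus_ids(m2))
  post <- loo_posterior(individual_ids(m2)[1], m2, bl, locus_ids(m2))
  expect_equal(unname(post), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("posteriors are normalized to machine precision across a cohort", {
  m <- simulate_dataset(sim_config(n_pops = 4, n_per_pop = 12, n_loci = 200,
                                   fst_levels = 0.05, fst_weights = 1,
                                   missing_rate = 0.005, seed = 163))
  sp <- training_split(m, seed = 2)
  res <- self_assign(m, locus_ids(m)[1:150], sp)
  post <- as.matrix(res[, grepl("^post\\.", names(res))])
  expect_true(all(abs(rowSums(post) - 1) < 1e-12))
  expect_true(all(res$assigned_pop %in% populations(m)))
})

test_that("leave-one-out subtraction actually removes the focal alleles", {
  m <- random_gm(2, 12, 30, seed = 167, miss = 0)
  bl <- build_baseline(m, locus_ids(m))
  ind <- individual_ids(m)[1]
  own <- populations(m)[1]
  # build the equivalent baseline without the individual and compare
  rest <- genotype_matrix(m$dosages[-1, , drop = FALSE], populations(m)[-1])
  bl_rest <- build_baseline(rest, locus_ids(m))
  p_loo <- loo_posterior(ind, m, bl, locus_ids(m))
  p_direct <- assign_posterior(m$dosages[1, ], bl_rest)
  expect_equal(p_loo, p_direct, tolerance = 1e-12)
})

test_that("separable fixtures self-assign perfectly; null data at chance", {
  fx <- make_fixture("tiny_separable")
  sp <- training_split(fx$matrix, seed = 5)
  res <- self_assign(fx$matrix, locus_ids(fx$matrix), sp)
  acc <- accuracy_summary(res)
  expect_equal(acc$overall, fx$manifest$expected_holdout_accuracy)
  expect_true(all(acc$per_population == 100))

  nul <- make_fixture("null_shuffled")
  spn <- training_split(nul$matrix, seed = 6)
  resn <- self_assign(nul$matrix, locus_ids(nul$matrix), spn)
  accn <- accuracy_summary(resn)
  expect_lt(abs(accn$overall - nul$manifest$chance_accuracy), 20)
})

test_that("accuracy summary arithmetic and contracts", {
  res <- data.frame(individual = sprintf("i%02d", 1:20),
                    true_pop = rep(c("A", "B"), each = 10),
                    assigned_pop = c(rep("A", 9), "B", rep("B", 10)),
                    correct = c(rep(TRUE, 9), FALSE, rep(TRUE, 10)),
                    holdout = TRUE)
  class(res) <- c("assignment_result", "data.frame")
  acc <- accuracy_summary(res)
  expect_equal(acc$overall, 95)
  expect_equal(unname(acc$per_population), c(90, 100))
  res$holdout <- FALSE
  expect_error(accuracy_summary(res), "no individuals")
})

test_that("bootstrap genotype simulation respects baseline frequencies", {
  m <- random_gm(3, 20, 40, seed = 173, miss = 0)
  bl <- build_baseline(m, locus_ids(m))
  sim1 <- simulate_baseline_genotypes(bl, 300, seed = 7)
  # realized minor-allele frequency close to the smoothed baseline
  q <- (bl$counts + 0.5) / (bl$totals + 1)
  realized <- rowsum(1 - sim1$dosages, populations(sim1)) / 300
  expect_lt(max(abs(realized - q)), 0.06)
  # determinism
  expect_identical(simulate_baseline_genotypes(bl, 10, seed = 8)$dosages,
                   simulate_baseline_genotypes(bl, 10, seed = 8)$dosages)
  # fixed frequencies produce fixed genotypes
  blf <- structure(list(counts = matrix(c(0, 40), 2, 1,
                                        dimnames = list(c("A", "B"), "L1")),
                        totals = matrix(40, 2, 1,
                                        dimnames = list(c("A", "B"), "L1")),
                        populations = c("A", "B"), loci = "L1"),
                   class = "gsi_baseline")
  simf <- simulate_baseline_genotypes(blf, 50, seed = 9)
  da <- simf$dosages[populations(simf) == "A", 1]
  db <- simf$dosages[populations(simf) == "B", 1]
  expect_gte(mean(da == 1), 0.9)   # q ~= 0.012: almost all major homozygotes
  expect_gte(mean(db == 0), 0.9)   # q ~= 0.988: almost all minor homozygotes
})

test_that("holdout accuracy rises with simulated differentiation", {
  accs <- vapply(c(0.01, 0.05, 0.10, 0.20), function(f) {
    cfg <- sim_config(n_pops = 5, n_per_pop = 20, n_loci = 500,
                      fst_levels = f, fst_weights = 1,
                      missing_rate = 0, seed = 179)
    m <- simulate_dataset(cfg)
    sp <- training_split(m, seed = 11)
    train <- subset_individuals(m, sp$training)
    panel <- fst_rank_panel(locus_stats(train), 100)
    accuracy_summary(self_assign(m, panel, sp))$overall
  }, numeric(1))
  expect_true(all(diff(accs) >= -2))
})
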