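fake_results <- function(true, assigned, holdout = TRUE) {
  res <- data.frame(individual = sprintf("i%03d", seq_along(true)),
                    true_pop = true, assigned_pop = assigned,
                    correct = true == assigned,
                    holdout = holdout, stringsAsFactors = FALSE)
  class(res) <- c("assignment_result", "data.frame")
  res
}

test_that("accuracy_curve rows agree with per-panel recomputation", {
  m <- simulate_dataset(sim_config(n_pops = 3, n_per_pop = 15, n_loci = 120,
                                   fst_levels = 0.15, fst_weights = 1,
                                   missing_rate = 0, seed = 233))
  sp <- training_split(m, seed = 3)
  train <- subset_individuals(m, sp$training)
  st <- locus_stats(train)
  panels <- list(fst_rank_panel(st, 20), fst_rank_panel(st, 60))
  tab <- accuracy_curve(panels, m, sp)
  expect_equal(nrow(tab), 2)
  for (i in 1:2) {
    direct <- accuracy_summary(self_assign(m, panels[[i]], sp))
    row <- tab[tab$size == panels[[i]]$size, ]
    expect_equal(row$accuracy, direct$overall)
    expect_equal(unlist(row[paste0("acc.", names(direct$per_population))],
                        use.names = FALSE),
                 unname(direct$per_population))
  }
  # a duplicated panel yields an identical row
  tab2 <- accuracy_curve(list(panels[[1]], panels[[1]]), m, sp)
  expect_equal(tab2$accuracy[1], tab2$accuracy[2])
})

test_that("the overall accuracy equals the confusion matrix's weighted diagonal", {
  m <- simulate_dataset(sim_config(n_pops = 4, n_per_pop = 15, n_loci = 150,
                                   fst_levels = 0.05, fst_weights = 1,
                                   missing_rate = 0, seed = 239))
  sp <- training_split(m, seed = 5)
  res <- self_assign(m, locus_ids(m)[1:80], sp)
  cm <- confusion_matrix(res)
  expect_equal(unname(rowSums(cm)), rep(100, 4))
  hold <- res[res$holdout, ]
  weights <- table(hold$true_pop)[rownames(cm)]
  weighted_diag <- sum(diag(cm) * as.numeric(weights)) / sum(weights)
  expect_equal(weighted_diag, accuracy_summary(res)$overall, tolerance = 1e-10)
})

test_that("confusion matrix arithmetic on constructed assignments", {
  res <- fake_results(rep(c("A", "B"), each = 10),
                      c(rep("A", 7), rep("B", 3), rep("B", 10)))
  cm <- confusion_matrix(res)
  expect_equal(cm["A", ], c(A = 70, B = 30))
  expect_equal(cm["B", ], c(A = 0, B = 100))

  all_right <- fake_results(rep(c("A", "B"), 5), rep(c("A", "B"), 5))
  expect_equal(confusion_matrix(all_right), diag(2) * 100,
               ignore_attr = TRUE)

  part <- fake_results(c("A", "A", "B"), c("A", "A", "B"),
                       holdout = c(TRUE, TRUE, FALSE))
  expect_warning(cm2 <- confusion_matrix(part), "no holdout")
  expect_true(all(is.na(cm2["B", ])))
})

test_that("the nested polynomial F-test detects a constant method offset", {
  sizes <- seq(50, 500, by = 50)
  # deterministic wiggle keeps the quadratic fit from being exact
  base <- 60 + 0.1 * sizes - 5e-5 * sizes^2 + 2 * sin(sizes / 30)
  tab <- data.frame(method = rep(c("FST", "GRRF"), each = 10),
                    parameter = c(sizes, sizes),
                    size = c(sizes, sizes),
                    accuracy = c(base, base + 10))
  out <- method_effect_test(tab)
  expect_lt(out$p, 0.01)
  expect_equal(out$df1, 1)

  # identical methods: F ~ 0, p ~ 1
  tab0 <- tab
  tab0$accuracy <- c(base, base)
  out0 <- method_effect_test(tab0)
  expect_lt(out0$F, 1e-10)
  expect_gt(out0$p, 0.99)

  # invariance to method label permutation
  tabp <- tab
  tabp$method <- ifelse(tab$method == "FST", "Z", "A")
  expect_equal(method_effect_test(tabp)$F, out$F, tolerance = 1e-10)

  expect_error(method_effect_test(tab[tab$method == "FST", ]), "two methods")
  expect_error(method_effect_test(tab[c(1, 2, 11, 12), ]), "three panel sizes")
})

test_that("noisy per-seed accuracies give a calibrated null for the F-test", {
  set.seed(241)
  sizes <- rep(seq(40, 400, length.out = 8), 2)
  tab <- data.frame(method = rep(c("A", "B"), each = 8),
                    parameter = sizes, size = sizes,
                    accuracy = 70 + 0.02 * sizes + rnorm(16, 0, 2))
  out <- method_effect_test(tab)
  expect_true(out$p > 0.001)  # no systematic effect was injected
})

test_that("mismatch deltas recount cross-assignments between methods", {
  trueA <- c(rep("A", 20), rep("B", 20))
  resA <- fake_results(trueA, c(rep("A", 19), "B", rep("B", 20)))
  resB <- fake_results(trueA, c(rep("A", 18), "B", "B", rep("B", 20)))
  pw <- matrix(c(0, 0.05, 0.05, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  md <- mismatch_delta(resA, resB, pw)
  expect_equal(md$delta, (2 - 1) / 40)
  expect_equal(md$pairwise_theta, 0.05)

  expect_equal(mismatch_delta(resA, resA, pw)$delta, 0)

  resC <- fake_results(trueA[-1], c(rep("A", 19), rep("B", 20)))
  expect_error(mismatch_delta(resA, resC, pw), "different individuals")
})

test_that("mismatch deltas equal a brute-force recount on simulated runs", {
  m <- simulate_dataset(sim_config(n_pops = 5, n_per_pop = 12, n_loci = 150,
                                   fst_levels = 0.04, fst_weights = 1,
                                   missing_rate = 0, seed = 251))
  sp <- training_split(m, seed = 7)
  resA <- self_assign(m, locus_ids(m)[1:40], sp)
  resB <- self_assign(m, locus_ids(m)[41:80], sp)
  pw <- pairwise_fst(m)
  md <- mismatch_delta(resA, resB, pw)
  h <- function(res, p1, p2) {
    hh <- res[res$holdout & res$true_pop %in% c(p1, p2), ]
    sum(hh$true_pop != hh$assigned_pop & hh$assigned_pop %in% c(p1, p2) &
          hh$true_pop %in% c(p1, p2)) / nrow(hh)
  }
  for (r in seq_len(nrow(md))) {
    expect_equal(md$delta[r],
                 h(resB, md$pop_a[r], md$pop_b[r]) -
                   h(resA, md$pop_a[r], md$pop_b[r]))
  }
  expect_equal(nrow(md), choose(5, 2))
})

test_that("minimum panel search scans thresholds correctly", {
  tab <- data.frame(method = rep(c("FST", "GRRF"), each = 3),
                    parameter = rep(c(50, 100, 200), 2),
                    size = rep(c(50, 100, 200), 2),
                    accuracy = c(70, 85, 91, 80, 92, 95))
  out <- min_panel_for_threshold(tab, 90)
  expect_equal(out$size[out$method == "FST"], 200)
  expect_equal(out$size[out$method == "GRRF"], 100)
  expect_equal(out$size[out$method == "any"], 100)

  low <- min_panel_for_threshold(tab, 0)
  expect_equal(low$size[low$method == "any"], 50)
  high <- min_panel_for_threshold(tab, 101)
  expect_true(all(is.na(high$size)))
})
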