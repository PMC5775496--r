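#' Accuracy-versus-size table for a set of panels
#'
#' Runs [self_assign()] for every panel and collects one row per
#' (method, parameter): panel size, overall holdout accuracy (percent) and
#' per-population holdout accuracies. Rows are sorted by method, then size.
#'
#' @param panels list of [snp_panel()] objects.
#' @param m a [genotype_matrix()].
#' @param split a [training_split()].
#' @return A data.frame of class `eval_table` with columns `method`,
#'   `parameter`, `size`, `accuracy`, then `acc.<population>` columns.
#' @export
accuracy_curve <- function(panels, m, split) {
  if (inherits(panels, "snp_panel")) panels <- list(panels)
  rows <- lapply(panels, function(pn) {
    res <- self_assign(m, pn, split)
    acc <- accuracy_summary(res, holdout_only = TRUE)
    row <- data.frame(method = pn$method,
                      parameter = as.numeric(pn$parameter),
                      size = pn$size,
                      accuracy = acc$overall,
                      stringsAsFactors = FALSE)
    per <- as.data.frame(t(acc$per_population))
    names(per) <- paste0("acc.", names(acc$per_population))
    cbind(row, per)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$size), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eval_table", "data.frame")
  out
}

#' Confusion matrix of holdout assignments
#'
#' Rows are true populations, columns assigned populations; entries are the
#' percentage of each true population's holdout individuals assigned to the
#' column population, so every scored row sums to 100. Populations with no
#' holdout individuals get an `NA` row and a warning.
#'
#' @param results an `assignment_result` from [self_assign()].
#' @return A numeric matrix (percent), true populations x assigned.
#' @export
confusion_matrix <- function(results) {
  r <- results[results$holdout, , drop = FALSE]
  pops <- sort(unique(results$true_pop))
  out <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(true = pops, assigned = pops))
  for (pp in pops) {
    sub <- r[r$true_pop == pp, , drop = FALSE]
    if (!nrow(sub)) next
    tab <- table(factor(sub$assigned_pop, levels = pops))
    out[pp, ] <- 100 * as.numeric(tab) / nrow(sub)
  }
  empty <- rowSums(!is.na(out)) == 0
  if (any(empty))
    warning("no holdout individuals for population(s): ",
            paste(pops[empty], collapse = ", "), call. = FALSE)
  out
}

#' Nested F-test for a selection-method effect on accuracy
#'
#' Fits accuracy on a second-degree polynomial in panel size, with and
#' without method indicator terms, and compares the nested least-squares
#' fits with an F-test. One accuracy point per (method, size) pair is the
#' expected input.
#'
#' @param table an `eval_table` from [accuracy_curve()] with at least two
#'   methods and three sizes per method.
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
method_effect_test <- function(table) {
  if (length(unique(table$method)) < 2)
    stop("need at least two methods", call. = FALSE)
  if (any(tapply(table$size, table$method, length) < 3))
    stop("need at least three panel sizes per method", call. = FALSE)
  reduced <- lm(accuracy ~ size + I(size^2), data = table)
  full <- lm(accuracy ~ size + I(size^2) + method, data = table)
  if (any(is.na(coef(full))))
    stop("rank-deficient design: method effect is not estimable", call. = FALSE)
  an <- anova(reduced, full)
  df1 <- an$Df[2]
  df2 <- an$Res.Df[2]
  # compute the F ratio directly: anova() leaves it NA when the sum of
  # squares underflows to a tiny negative for an exactly null effect
  ss <- max(an$RSS[1] - an$RSS[2], 0)
  fstat <- (ss / df1) / (an$RSS[2] / df2)
  list(F = fstat, df1 = df1, df2 = df2,
       p = pf(fstat, df1, df2, lower.tail = FALSE))
}

#' Pairwise mismatch difference between two selection methods
#'
#' For every unordered population pair: the proportion of holdout
#' individuals cross-assigned between the two populations (true in one,
#' assigned to the other, over the pair's holdout total) under method B
#' minus under method A, paired with the pair's multi-locus FST for
#' plotting against differentiation.
#'
#' @param results_a,results_b `assignment_result` objects from
#'   [self_assign()] on the same individuals and split.
#' @param pairwise symmetric pairwise FST matrix from [pairwise_fst()].
#' @return A data.frame with columns `pop_a`, `pop_b`, `pairwise_theta`,
#'   `delta`.
#' @export
mismatch_delta <- function(results_a, results_b, pairwise) {
  if (!identical(results_a$individual, results_b$individual) ||
      !identical(results_a$true_pop, results_b$true_pop) ||
      !identical(results_a$holdout, results_b$holdout))
    stop("the two result sets cover different individuals or splits",
         call. = FALSE)
  pops <- sort(unique(results_a$true_pop))
  cross_rate <- function(res, p1, p2) {
    h <- res[res$holdout & res$true_pop %in% c(p1, p2), , drop = FALSE]
    if (!nrow(h)) return(NA_real_)
    n_cross <- sum((h$true_pop == p1 & h$assigned_pop == p2) |
                   (h$true_pop == p2 & h$assigned_pop == p1))
    n_cross / nrow(h)
  }
  out <- list()
  for (i in seq_len(length(pops) - 1)) {
    for (j in (i + 1):length(pops)) {
      p1 <- pops[i]; p2 <- pops[j]
      theta <- if (p1 %in% rownames(pairwise) && p2 %in% rownames(pairwise))
        pairwise[p1, p2] else NA_real_
      out[[length(out) + 1]] <- data.frame(
        pop_a = p1, pop_b = p2, pairwise_theta = theta,
        delta = cross_rate(results_b, p1, p2) - cross_rate(results_a, p1, p2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Smallest panel reaching an accuracy threshold
#'
#' Per method (and overall), the smallest panel size in the table whose
#' overall holdout accuracy meets `threshold` percent; `NA` when the
#' threshold is never reached.
#'
#' @param table an `eval_table` from [accuracy_curve()].
#' @param threshold accuracy threshold in percent (e.g. 90).
#' @return A data.frame with columns `method`, `size`, `accuracy`; the last
#'   row (`method = "any"`) is the overall minimum.
#' @export
min_panel_for_threshold <- function(table, threshold) {
  if (!nrow(table)) stop("empty evaluation table", call. = FALSE)
  pick <- function(sub) {
    hit <- sub[sub$accuracy >= threshold, , drop = FALSE]
    if (!nrow(hit)) return(c(NA_real_, NA_real_))
    best <- hit[which.min(hit$size), ]
    c(best$size, best$accuracy)
  }
  methods <- sort(unique(table$method))
  rows <- t(vapply(methods,
                   function(mm) pick(table[table$method == mm, , drop = FALSE]),
                   numeric(2)))
  overall <- pick(table)
  data.frame(method = c(methods, "any"),
             size = c(rows[, 1], overall[1]),
             accuracy = c(rows[, 2], overall[2]),
             stringsAsFactors = FALSE)
}
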