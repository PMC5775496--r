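#' Forest configuration
#'
#' Defaults follow the settings under which out-of-bag error stabilises on
#' low-differentiation SNP data: 2000 trees, `mtry` at twice the square root
#' of the number of loci, and a minimum terminal node size of five (larger
#' trees than the classification default).
#'
#' @param ntree number of trees (default 2000).
#' @param mtry loci sampled per node; `NULL` means `2 * ceiling(sqrt(p))`,
#'   resolved when the forest is grown.
#' @param min_node minimum terminal node size (default 5).
#' @param seed integer seed; the same seed, data and configuration give a
#'   bit-identical forest.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(ntree = 2000, mtry = NULL, min_node = 5, seed = 1) {
  stopifnot(ntree >= 1, min_node >= 1, is.null(mtry) || mtry >= 1)
  structure(list(ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 min_node = as.integer(min_node),
                 seed = as.integer(seed)),
            class = "forest_config")
}

resolve_mtry <- function(cfg, p) {
  m <- cfg$mtry %||% (2L * as.integer(ceiling(sqrt(p))))
  if (m > p) m <- as.integer(p)
  if (m < 1) stop("mtry must be at least 1", call. = FALSE)
  m
}

forest_inputs <- function(train, labels) {
  stop_if_not_gm(train)
  labels <- as.character(labels %||% train$populations)
  if (anyNA(train$dosages))
    stop("forests require a complete matrix; impute missing genotypes first",
         call. = FALSE)
  if (n_loci(train) == 0) stop("no loci to grow a forest on", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("forest classification needs at least two classes", call. = FALSE)
  list(X = train$dosages, y = match(labels, classes) - 1L, classes = classes)
}

#' Grow a classification random forest on dosage codes
#'
#' Each tree is grown on a bootstrap sample of the individuals (n draws with
#' replacement); at every node `mtry` loci are sampled without replacement
#' and the split with the largest Gini impurity decrease is taken, testing
#' the dosage midpoints 0.25 and 0.75 as thresholds. Recursion stops at
#' purity or at `min_node` cases; leaves vote with their in-bag majority and
#' the forest predicts by plurality (ties to the lowest class label).
#'
#' @param train a complete (no missing cells) [genotype_matrix()].
#' @param labels class labels, one per individual; defaults to the matrix's
#'   population labels.
#' @param cfg a [forest_config()].
#' @return An object of class `rf_forest` with the grown trees, per-tree
#'   out-of-bag case lists, `oob_error`, out-of-bag predictions, the class
#'   labels and the resolved configuration.
#' @export
grow_forest <- function(train, labels = NULL, cfg = forest_config()) {
  inp <- forest_inputs(train, labels)
  mtry <- resolve_mtry(cfg, ncol(inp$X))
  fit <- cpp_grow_forest(inp$X, inp$y, length(inp$classes),
                         cfg$ntree, mtry, cfg$min_node, cfg$seed)
  structure(list(trees = fit$trees,
                 oob = fit$oob,
                 oob_error = fit$oob_error,
                 oob_pred = inp$classes[fit$oob_pred],
                 classes = inp$classes,
                 locus_ids = colnames(inp$X),
                 y = inp$y,
                 mtry = mtry,
                 config = cfg),
            class = "rf_forest")
}

#' @export
print.rf_forest <- function(x, ...) {
  cat(sprintf("rf_forest: %d trees, %d loci, %d classes, mtry %d\n",
              length(x$trees), length(x$locus_ids), length(x$classes),
              x$mtry))
  cat(sprintf("  OOB error: %.4f\n", x$oob_error))
  if (!is.null(x$selected))
    cat(sprintf("  selected loci: %d\n", length(x$selected)))
  invisible(x)
}

#' @export
predict.rf_forest <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "genotype_matrix")) {
    miss <- setdiff(object$locus_ids, locus_ids(newdata))
    if (length(miss))
      stop("newdata lacks training loci: ", paste(miss, collapse = ", "),
           call. = FALSE)
    newdata$dosages[, object$locus_ids, drop = FALSE]
  } else {
    as.matrix(newdata)
  }
  if (anyNA(X)) stop("newdata must be complete (no missing cells)", call. = FALSE)
  idx <- cpp_predict_forest(object$trees, X, length(object$classes))
  object$classes[idx]
}

#' Permutation importance (mean decrease in accuracy)
#'
#' For every tree with at least one out-of-bag case: the tree's accuracy on
#' its OOB cases minus its accuracy after permuting one locus's dosages among
#' those cases, averaged over such trees. The value is reported raw (not
#' divided by its standard error). A locus never used by a tree contributes an
#' exact zero for that tree, so a constant locus has MDA exactly 0.
#'
#' @param forest an `rf_forest` grown on `train`.
#' @param train the same [genotype_matrix()] the forest was grown on.
#' @param labels labels used at growth (defaults to population labels).
#' @param seed seed for the permutations (independent of the growth seed).
#' @return Named numeric vector of per-locus MDA.
#' @export
mda_importance <- function(forest, train, labels = NULL,
                           seed = forest$config$seed + 1L) {
  inp <- forest_inputs(train, labels)
  if (!identical(colnames(inp$X), forest$locus_ids))
    stop("train does not match the loci the forest was grown on", call. = FALSE)
  imp <- cpp_mda(forest$trees, forest$oob, inp$X, inp$y, seed)
  setNames(as.numeric(imp), forest$locus_ids)
}

#' Regularization parameters for RRF/GRRF
#'
#' The per-locus gain penalty is
#' `lambda_i = (1 - gamma) * lambda + gamma * norm_imp_i`, with the base
#' penalty fixed at 1 so the guided variant is driven by `gamma` alone.
#' `norm_imp` is the guiding importance clipped at zero and scaled by its
#' maximum. A larger `lambda` (toward 1) means a smaller penalty and a larger
#' selected panel; a larger `gamma` (toward 1) shrinks the effective penalty
#' coefficient and the panel.
#'
#' @param lambda base penalty coefficient in (0, 1].
#' @param gamma guidance weight in \[0, 1); `gamma > 0` requires
#'   `base_importance`.
#' @param base_importance named per-locus importance vector (e.g. an MDA from
#'   a single plain forest run) guiding the penalty; `NULL` for plain RRF.
#' @return A list of class `reg_params`.
#' @export
reg_params <- function(lambda = 1, gamma = 0, base_importance = NULL) {
  stopifnot(lambda > 0, lambda <= 1, gamma >= 0, gamma < 1)
  if (gamma > 0 && is.null(base_importance))
    stop("gamma > 0 requires base_importance (guided regularization)",
         call. = FALSE)
  structure(list(lambda = lambda, gamma = gamma,
                 base_importance = base_importance),
            class = "reg_params")
}

#' Grow a (guided) regularized random forest
#'
#' Trees are grown sequentially and share a growing selected-feature set F
#' (initially empty). At each node the candidate loci are the `mtry` sampled
#' ones plus every member of F; a locus outside F competes with its Gini gain
#' multiplied by its penalty `lambda_i`, members of F compete with their raw
#' gain, and the node splits on the maximum (gain ties prefer F members, then
#' the lowest locus index). The winning locus joins F. With `lambda = 1`,
#' `gamma = 0` a new locus must still match the raw gain of those already
#' selected (minimum regularization), which suppresses exact duplicates.
#'
#' @inheritParams grow_forest
#' @param reg a [reg_params()].
#' @return An `rf_forest` with an extra element `selected`: the locus ids of
#'   F in order of first selection (the method's native panel).
#' @export
grow_regularized_forest <- function(train, labels = NULL,
                                    cfg = forest_config(),
                                    reg = reg_params()) {
  inp <- forest_inputs(train, labels)
  p <- ncol(inp$X)
  norm_imp <- rep(0, p)
  if (reg$gamma > 0) {
    bi <- reg$base_importance
    if (is.null(names(bi)) || !all(colnames(inp$X) %in% names(bi)))
      stop("base_importance must be named and cover every locus", call. = FALSE)
    bi <- pmax(bi[colnames(inp$X)], 0)
    if (max(bi) > 0) norm_imp <- as.numeric(bi / max(bi))
  }
  penalty <- (1 - reg$gamma) * reg$lambda + reg$gamma * norm_imp
  mtry <- resolve_mtry(cfg, p)
  fit <- cpp_grow_regularized(inp$X, inp$y, length(inp$classes),
                              cfg$ntree, mtry, cfg$min_node, cfg$seed,
                              penalty)
  structure(list(trees = fit$trees,
                 oob = fit$oob,
                 oob_error = fit$oob_error,
                 oob_pred = inp$classes[fit$oob_pred],
                 classes = inp$classes,
                 locus_ids = colnames(inp$X),
                 y = inp$y,
                 mtry = mtry,
                 config = cfg,
                 reg = reg[c("lambda", "gamma")],
                 selected = colnames(inp$X)[fit$selected]),
            class = "rf_forest")
}
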