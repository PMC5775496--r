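#' Genotype matrix with population labels
#'
#' The pipeline's common currency: an individuals-by-loci matrix of dosage
#' codes with one population label per individual. Dosage coding follows the
#' minor-allele orientation used throughout: 0 for a minor-allele homozygote,
#' 0.5 for a heterozygote, 1 for a major-allele homozygote, `NA` for a missing
#' call. The minor allele is defined globally, across all populations pooled.
#'
#' @param dosages numeric matrix (individuals x loci) with values in
#'   `{0, 0.5, 1, NA}`; row names are individual ids, column names locus ids.
#' @param populations character vector of population labels, one per row of
#'   `dosages`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` and `populations`.
#' @examples
#' d <- matrix(c(0, 0.5, 1, 1), nrow = 2,
#'             dimnames = list(c("a1", "b1"), c("L1", "L2")))
#' genotype_matrix(d, c("A", "B"))
#' @export
genotype_matrix <- function(dosages, populations) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)) && nrow(dosages) > 0)
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)) && ncol(dosages) > 0)
    colnames(dosages) <- paste0("locus", seq_len(ncol(dosages)))
  populations <- as.character(populations)
  m <- structure(list(dosages = dosages, populations = populations),
                 class = "genotype_matrix")
  validate_genotype_matrix(m)
  m
}

validate_genotype_matrix <- function(m) {
  d <- m$dosages
  if (length(m$populations) != nrow(d))
    stop("one population label is required per individual", call. = FALSE)
  if (anyNA(m$populations) || any(!nzchar(m$populations)))
    stop("every individual needs a non-empty population label", call. = FALSE)
  if (anyDuplicated(colnames(d)))
    stop("locus ids must be unique", call. = FALSE)
  if (anyDuplicated(rownames(d)))
    stop("individual ids must be unique", call. = FALSE)
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 0.5, 1)))
    stop("dosages must be 0, 0.5, 1 or NA", call. = FALSE)
  invisible(m)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d populations\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$populations))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param m a `genotype_matrix`.
#' @export
n_individuals <- function(m) {
  stop_if_not_gm(m)
  nrow(m$dosages)
}

#' @rdname genotype_matrix
#' @export
n_loci <- function(m) {
  stop_if_not_gm(m)
  ncol(m$dosages)
}

#' @rdname genotype_matrix
#' @export
locus_ids <- function(m) {
  stop_if_not_gm(m)
  colnames(m$dosages)
}

#' @rdname genotype_matrix
#' @export
individual_ids <- function(m) {
  stop_if_not_gm(m)
  rownames(m$dosages)
}

#' @rdname genotype_matrix
#' @export
populations <- function(m) {
  stop_if_not_gm(m)
  m$populations
}

#' Subset loci by an ordered whitelist
#'
#' Returns the matrix restricted to the whitelisted loci, columns in whitelist
#' order; individuals are unchanged. An empty whitelist yields a matrix with
#' zero loci.
#'
#' @param m a `genotype_matrix`.
#' @param whitelist character vector of locus ids (ordered).
#' @return A `genotype_matrix` with `length(whitelist)` loci.
#' @export
subset_loci <- function(m, whitelist) {
  stop_if_not_gm(m)
  whitelist <- as.character(whitelist)
  unknown <- setdiff(whitelist, locus_ids(m))
  if (length(unknown))
    stop("unknown locus id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  d <- m$dosages[, whitelist, drop = FALSE]
  genotype_matrix(d, m$populations)
}

#' Subset individuals by id
#'
#' @param m a `genotype_matrix`.
#' @param ids individual ids to keep (ordered).
#' @return A `genotype_matrix` with the selected individuals.
#' @export
subset_individuals <- function(m, ids) {
  stop_if_not_gm(m)
  ids <- as.character(ids)
  unknown <- setdiff(ids, individual_ids(m))
  if (length(unknown))
    stop("unknown individual id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- match(ids, individual_ids(m))
  genotype_matrix(m$dosages[keep, , drop = FALSE], m$populations[keep])
}

#' Encode a diploid call as a dosage code
#'
#' Minor/minor maps to 0, heterozygote to 0.5, major/major to 1; a call with
#' any unknown allele is missing (`NA`). The minor allele must have been
#' designated beforehand from pooled global allele frequencies.
#'
#' @param call character vector of length 2: the two allele ids, `NA` for an
#'   unknown allele.
#' @param minor_allele,major_allele allele ids.
#' @return A dosage in `{0, 0.5, 1}` or `NA`.
#' @export
encode_dosage <- function(call, minor_allele, major_allele) {
  if (length(call) != 2)
    stop("a diploid call has exactly two alleles", call. = FALSE)
  if (anyNA(call)) return(NA_real_)
  ok <- call %in% c(minor_allele, major_allele)
  if (!all(ok))
    stop("unknown allele(s) in call: ", paste(call[!ok], collapse = ", "),
         call. = FALSE)
  n_minor <- sum(call == minor_allele)
  1 - n_minor / 2
}
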