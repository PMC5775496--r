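#' Read a Genepop file into a genotype matrix
#'
#' Parses the classical Genepop dialect: a title line, one locus name per line
#' (or a single comma-separated line), then `POP`-delimited population blocks
#' whose rows are `individual_id ,  genotype genotype ...` with 2- or 3-digit
#' allele codes (allele `00`/`000` = missing). Allele code width is detected
#' per file; mixed widths are rejected. At each locus the two observed alleles
#' are oriented by pooled global frequency (the rarer allele is minor, ties at
#' 0.5 broken by the lexicographically smaller code) and genotypes are encoded
#' as dosages via [encode_dosage()].
#'
#' Population labels are not part of the Genepop format proper; following the
#' common `POP_ID`-prefix convention, a block whose individual ids all share
#' the prefix before their first underscore is labelled with that prefix,
#' otherwise the block is labelled `pop_<block number>`.
#'
#' @param path path to a Genepop text file.
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too few lines", call. = FALSE)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop("malformed POP structure: no POP line after the locus names",
         call. = FALSE)
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci))
    stop("duplicate locus names in header", call. = FALSE)
  n_loci <- length(loci)

  blocks <- cumsum(is_pop)
  body <- which(!is_pop & blocks > 0)
  if (!length(body))
    stop("malformed POP structure: empty file body", call. = FALSE)

  ids <- character(0); pops <- integer(0)
  geno <- list()
  for (i in body) {
    ln <- lines[i]
    cpos <- regexpr(",", ln, fixed = TRUE)
    if (cpos < 0)
      stop(sprintf("malformed POP structure at line %d: no comma separator", i),
           call. = FALSE)
    id <- trimws(substr(ln, 1, cpos - 1))
    toks <- strsplit(trimws(substr(ln, cpos + 1, nchar(ln))), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != n_loci)
      stop(sprintf("line %d: expected %d genotypes, found %d", i, n_loci,
                   length(toks)), call. = FALSE)
    ids <- c(ids, id)
    pops <- c(pops, blocks[i])
    geno[[length(geno) + 1]] <- toks
  }
  gm <- do.call(rbind, geno)

  widths <- unique(as.vector(nchar(gm)))
  if (length(widths) != 1 || !widths %in% c(4, 6))
    stop("mixed or unsupported allele code widths (need uniform 2- or 3-digit codes)",
         call. = FALSE)
  aw <- widths / 2
  missing_code <- strrep("0", aw)
  a1 <- substr(gm, 1, aw)
  a2 <- substr(gm, aw + 1, 2 * aw)
  a1[a1 == missing_code] <- NA
  a2[a2 == missing_code] <- NA

  n_ind <- length(ids)
  dos <- matrix(NA_real_, n_ind, n_loci)
  for (l in seq_len(n_loci)) {
    al <- c(a1[, l], a2[, l])
    tab <- sort(table(al[!is.na(al)]), decreasing = FALSE)
    alleles <- names(tab)
    if (length(alleles) > 2)
      stop(sprintf("ploidy error at locus %s: %d alleles observed", loci[l],
                   length(alleles)), call. = FALSE)
    if (length(alleles) == 0) next  # fully missing column
    if (length(alleles) == 1) {
      minor <- NA_character_; major <- alleles[1]
    } else {
      # rarer allele is minor; exact tie -> lexicographically smaller code
      if (tab[[1]] < tab[[2]]) {
        minor <- alleles[1]; major <- alleles[2]
      } else if (tab[[1]] > tab[[2]]) {
        minor <- alleles[2]; major <- alleles[1]
      } else {
        minor <- min(alleles); major <- max(alleles)
      }
    }
    nm <- (!is.na(a1[, l])) & (!is.na(a2[, l]))
    cnt_minor <- (a1[, l] == minor) + (a2[, l] == minor)
    dos[nm, l] <- 1 - ifelse(is.na(cnt_minor[nm]), 0, cnt_minor[nm]) / 2
  }

  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)]
    message("duplicate individual ids suffixed: ", paste(unique(dup), collapse = ", "))
    ids <- make.unique(ids, sep = "_dup")
  }
  rownames(dos) <- ids
  colnames(dos) <- loci

  labels <- character(max(pops))
  for (b in unique(pops)) {
    bids <- ids[pops == b]
    pref <- sub("_.*$", "", bids)
    labels[b] <- if (length(unique(pref)) == 1 && all(grepl("_", bids)))
      pref[1] else paste0("pop_", b)
  }
  genotype_matrix(dos, labels[pops])
}

#' Write a genotype matrix as a Genepop file
#'
#' Emits 2-digit allele codes with the minor allele as `01` and the major as
#' `02` (`0000` for a missing call), one `POP` block per population label in
#' order of first appearance. Individual ids are prefixed with
#' `<population>_` when they do not already carry that prefix, so that
#' [read_genepop()] recovers the population labels.
#'
#' @param m a [genotype_matrix()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @export
write_genepop <- function(m, path, title = "finepanel export") {
  stop_if_not_gm(m)
  d <- m$dosages
  code <- matrix("0000", nrow(d), ncol(d))
  code[!is.na(d) & d == 0] <- "0101"
  code[!is.na(d) & d == 0.5] <- "0102"
  code[!is.na(d) & d == 1] <- "0202"
  out <- c(title, colnames(d))
  for (pp in unique(m$populations)) {
    out <- c(out, "POP")
    for (i in which(m$populations == pp)) {
      id <- rownames(d)[i]
      if (!startsWith(id, paste0(pp, "_"))) id <- paste0(pp, "_", id)
      out <- c(out, paste(id, ",", paste(code[i, ], collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read/write the tabular dosage format
#'
#' A plain TSV with columns `individual`, `population`, then one column per
#' locus holding dosage codes (`NA` = missing). This is the fixture and
#' simulator interchange format.
#'
#' @param path file path.
#' @return `read_dosage_tsv()` returns a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("individual", "population") %in% names(df)[1:2]))
    stop("dosage TSV must start with columns 'individual' and 'population'",
         call. = FALSE)
  d <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- df$individual
  genotype_matrix(d, df$population)
}

#' @rdname read_dosage_tsv
#' @param m a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(m, path) {
  stop_if_not_gm(m)
  df <- data.frame(individual = individual_ids(m),
                   population = m$populations,
                   m$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a locus whitelist (one locus id per line)
#'
#' @param path file path.
#' @export
read_whitelist <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' @rdname read_whitelist
#' @param loci character vector of locus ids (or a panel's `$loci`).
#' @export
write_whitelist <- function(loci, path) {
  if (inherits(loci, "snp_panel")) loci <- loci$loci
  writeLines(loci, path)
  invisible(path)
}
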