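# Diagnostic-SNP parent-of-origin tracks: the caller's input data model.

#' Construct a genotype table for one individual and chromosome arm
#'
#' A genotype table is the ordered list of diagnostic-SNP parent-of-origin
#' calls along one chromosome arm of one F2 individual.  Positions are
#' 1-based base pairs and must be strictly increasing; origins are `"P1"`,
#' `"P2"` or `"MISSING"`.  The *detectable span* — the region in which a
#' crossover could in principle be observed — is the interval from the first
#' to the last non-missing diagnostic SNP.
#'
#' @param individual Individual identifier (scalar character).
#' @param cross Cross identifier (scalar character).
#' @param arm Chromosome arm, one of `"X"`, `"2L"`, `"2R"`, `"3L"`, `"3R"`,
#'   `"4"`.
#' @param pos Integer vector of 1-based SNP positions, strictly increasing.
#' @param origin Character vector of parental origins, same length as `pos`,
#'   values in `c("P1", "P2", "MISSING")`.
#' @return An object of class `"genotype_table"`: a list with elements
#'   `individual_id`, `cross_id`, `arm`, `pos`, `origin` and
#'   `detectable_span` (length-2 integer vector, `NA` if no non-missing SNP).
#' @seealso [read_genotype_table()], [detect_blocks()]
#' @export
#' @examples
#' gt <- genotype_table("f1", "c1", "X", c(1000L, 3000L, 5000L),
#'                      c("P1", "P1", "P2"))
#' gt$detectable_span
genotype_table <- function(individual, cross, arm, pos, origin) {
  stopifnot(length(individual) == 1L, length(cross) == 1L, length(arm) == 1L)
  if (!arm %in% .xo_arms)
    stop("unknown chromosome arm: ", arm)
  pos <- as.integer(pos)
  origin <- as.character(origin)
  if (length(pos) != length(origin))
    stop("pos and origin must have the same length")
  bad <- setdiff(unique(origin), .xo_origins)
  if (length(bad))
    stop("unknown origin code(s): ", paste(bad, collapse = ", "))
  if (length(pos) > 1L && any(diff(pos) <= 0L)) {
    off <- which(diff(pos) <= 0L)[1L] + 1L
    stop(sprintf(
      "positions not strictly increasing for %s/%s (record %d, pos %d)",
      individual, arm, off, pos[off]))
  }
  informative <- pos[origin != "MISSING"]
  span <- if (length(informative)) range(informative) else c(NA_integer_, NA_integer_)
  structure(
    list(individual_id = individual, cross_id = cross, arm = arm,
         pos = pos, origin = origin, detectable_span = span),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  n_inf <- sum(x$origin != "MISSING")
  cat(sprintf("<genotype_table> %s (cross %s), arm %s: %d SNPs (%d informative)\n",
              x$individual_id, x$cross_id, x$arm, length(x$pos), n_inf))
  if (!is.na(x$detectable_span[1L]))
    cat(sprintf("  detectable span: %d..%d bp\n",
                x$detectable_span[1L], x$detectable_span[2L]))
  invisible(x)
}

#' Read diagnostic-SNP genotype tables from a TSV file
#'
#' Reads a tab-separated file with header columns `individual`, `cross`,
#' `arm`, `pos`, `origin` (1-based positions) and returns one
#' [genotype_table()] per (individual, arm).  Rows are sorted by position
#' within each table; `MISSING` rows are retained.  Duplicated positions
#' within an individual/arm and unknown origin codes are errors that name the
#' offending file lines.
#'
#' @param path Path to the TSV file.
#' @return A named list of `genotype_table` objects (names
#'   `"individual/arm"`), ordered by individual then arm.
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   comment.char = "#")
  need <- c("individual", "cross", "arm", "pos", "origin")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  # line numbers in the file: header is line 1
  df$.line <- seq_len(nrow(df)) + 1L
  pos <- suppressWarnings(as.integer(df$pos))
  malformed <- which(is.na(pos) | pos < 1L)
  if (length(malformed))
    stop("malformed position(s) at line(s): ",
         paste(df$.line[malformed], collapse = ", "))
  badorig <- which(!df$origin %in% .xo_origins)
  if (length(badorig))
    stop("unknown origin code(s) at line(s): ",
         paste(df$.line[badorig], collapse = ", "))
  df$pos <- pos
  key <- paste(df$individual, df$arm, sep = "/")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    dup <- duplicated(sub$pos)
    if (any(dup))
      stop(sprintf(
        "duplicate position(s) for %s at line(s): %s", k,
        paste(sub$.line[dup], collapse = ", ")))
    sub <- sub[order(sub$pos), , drop = FALSE]
    cross <- unique(sub$cross)
    if (length(cross) != 1L)
      stop("conflicting cross ids for ", k)
    out[[k]] <- genotype_table(sub$individual[1L], cross, sub$arm[1L],
                               sub$pos, sub$origin)
  }
  out[order(names(out))]
}

#' Write genotype tables to a TSV file
#'
#' Inverse of [read_genotype_table()]: `read_genotype_table(write_genotype_table(x))`
#' reproduces the tables exactly.
#'
#' @param tables A `genotype_table` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(tables, path) {
  if (inherits(tables, "genotype_table")) tables <- list(tables)
  rows <- lapply(tables, function(gt)
    data.frame(individual = gt$individual_id, cross = gt$cross_id,
               arm = gt$arm, pos = gt$pos, origin = gt$origin,
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter chromosome arms by diagnostic-SNP count and inversion status
#'
#' Arms with too few informative diagnostic SNPs cannot support reliable
#' block-based crossover calling and are excluded (`LOW_SNP_COUNT`); the dot
#' chromosome has a lower threshold because of its much lower polymorphism
#' density.  Arms of crosses segregating a heterozygous inversion are
#' excluded outright (`INVERSION_HET`) since crossing over is suppressed and
#' reordered within the inverted region.
#'
#' @param tables List of [genotype_table()] objects.
#' @param min_snps_main Minimum informative SNPs for major arms (default 100).
#' @param min_snps_dot Minimum for the dot chromosome, arm `"4"` (default 10).
#' @param inversion_excludes Optional data.frame or list of `c(cross, arm)`
#'   pairs; every table whose `(cross_id, arm)` matches is excluded.
#' @return A list with elements `kept` (list of genotype tables) and
#'   `excluded` (data.frame `individual`, `cross`, `arm`, `reason`).  The two
#'   partition the input.
#' @export
filter_arms <- function(tables, min_snps_main = 100L, min_snps_dot = 10L,
                        inversion_excludes = NULL) {
  if (inherits(tables, "genotype_table")) tables <- list(tables)
  inv <- character(0)
  if (!is.null(inversion_excludes)) {
    if (is.data.frame(inversion_excludes)) {
      inv <- paste(inversion_excludes[[1L]], inversion_excludes[[2L]], sep = "/")
    } else {
      inv <- vapply(inversion_excludes, function(p) paste(p[1L], p[2L], sep = "/"),
                    character(1))
    }
  }
  kept <- list(); exc <- list()
  for (gt in tables) {
    n_inf <- sum(gt$origin != "MISSING")
    thr <- if (gt$arm == "4") min_snps_dot else min_snps_main
    reason <- NULL
    if (paste(gt$cross_id, gt$arm, sep = "/") %in% inv) reason <- "INVERSION_HET"
    else if (n_inf < thr) reason <- "LOW_SNP_COUNT"
    if (is.null(reason)) kept[[length(kept) + 1L]] <- gt
    else exc[[length(exc) + 1L]] <-
      data.frame(individual = gt$individual_id, cross = gt$cross_id,
                 arm = gt$arm, reason = reason, stringsAsFactors = FALSE)
  }
  excluded <- if (length(exc)) do.call(rbind, exc) else
    data.frame(individual = character(0), cross = character(0),
               arm = character(0), reason = character(0))
  list(kept = kept, excluded = excluded)
}
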