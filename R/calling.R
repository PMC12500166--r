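# Crossover calling: origin switches between validated diagnostic-SNP blocks.

#' Detect validated parent-of-origin blocks along a genotype track
#'
#' A block is a maximal run of consecutive same-origin diagnostic SNPs that
#' contains at least `min_snps` SNPs *and* spans at least `min_span_bp`
#' (span measured as the distance between its first and last SNP).  Runs
#' failing either threshold are treated as unassigned noise islands: they do
#' not interrupt the flanking same-origin context, so flanking validated
#' blocks of the same origin are merged across them.  `MISSING` SNPs are
#' ignored and never break a run.
#'
#' @param track A [genotype_table()].
#' @param min_snps Minimum SNPs per block (default 25; use 4 for the dot
#'   chromosome, whose diagnostic-SNP density is far lower).
#' @param min_span_bp Minimum block span in bp (default 250000).
#' @return data.frame with columns `origin`, `first_pos`, `last_pos`,
#'   `n_snps`, blocks ordered along the arm with alternating origins.  If the
#'   track has no informative SNP, an empty data.frame with attribute
#'   `qc = "NO_INFORMATIVE_SNPS"`.
#' @export
#' @examples
#' gt <- genotype_table("f1", "c1", "2L",
#'                      seq(1e6, 2e6, by = 2000),
#'                      rep(c("P1", "P2"), c(250, 251)))
#' detect_blocks(gt)
detect_blocks <- function(track, min_snps = 25L, min_span_bp = 250000L) {
  stopifnot(inherits(track, "genotype_table"))
  keep <- track$origin != "MISSING"
  pos <- track$pos[keep]
  ori <- track$origin[keep]
  if (!length(pos)) {
    out <- data.frame(origin = character(0), first_pos = integer(0),
                      last_pos = integer(0), n_snps = integer(0))
    attr(out, "qc") <- "NO_INFORMATIVE_SNPS"
    return(out)
  }
  r <- rle(ori)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first_pos <- pos[starts]
  last_pos <- pos[ends]
  valid <- r$lengths >= min_snps & (last_pos - first_pos) >= min_span_bp
  blocks <- data.frame(origin = r$values, first_pos = first_pos,
                       last_pos = last_pos, n_snps = r$lengths,
                       stringsAsFactors = FALSE)[valid, , drop = FALSE]
  if (!nrow(blocks)) {
    rownames(blocks) <- NULL
    attr(blocks, "qc") <- "NO_VALIDATED_BLOCKS"
    return(blocks)
  }
  # merge consecutive validated blocks sharing origin (noise island absorbed)
  grp <- cumsum(c(TRUE, blocks$origin[-1L] != blocks$origin[-nrow(blocks)]))
  merged <- data.frame(
    origin = tapply(blocks$origin, grp, `[`, 1L),
    first_pos = as.integer(tapply(blocks$first_pos, grp, min)),
    last_pos = as.integer(tapply(blocks$last_pos, grp, max)),
    n_snps = as.integer(tapply(blocks$n_snps, grp, sum)),
    stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  merged
}

#' Call crossovers from an alternating block sequence
#'
#' Every adjacent pair of validated blocks with different origins yields one
#' crossover call whose interval is the gap between the last SNP of the
#' upstream block and the first SNP of the downstream block (0-based
#' half-open) and whose point estimate is the floored midpoint.  Two
#' successive calls closer than `min_separation_bp` (point distance) are
#' most plausibly a single non-crossover event (e.g. a gene-conversion
#' tract) rather than a genuine double crossover: both calls are removed.
#' With `close_mode = "drop"` (default) the chromatid is additionally
#' flagged for QC; `"merge"` removes the pair silently, treating the short
#' intervening block as absorbed noise.
#'
#' @param blocks Block data.frame from [detect_blocks()].
#' @param min_separation_bp Minimum distance between successive crossover
#'   points on one chromatid (default 250000).
#' @param close_mode How to handle closer-than-minimum double switches:
#'   `"drop"` or `"merge"` (both remove the calls; see Details).
#' @return data.frame with columns `left`, `right`, `point`, `index`;
#'   attribute `flagged` is `TRUE` if a close double switch was removed
#'   under `close_mode = "drop"`.
#' @export
call_crossovers <- function(blocks, min_separation_bp = 250000L,
                            close_mode = c("drop", "merge")) {
  close_mode <- match.arg(close_mode)
  n <- nrow(blocks)
  flagged <- FALSE
  if (is.null(n) || n < 2L) {
    out <- data.frame(left = integer(0), right = integer(0),
                      point = integer(0), index = integer(0))
    attr(out, "flagged") <- flagged
    return(out)
  }
  if (any(blocks$origin[-1L] == blocks$origin[-n]))
    stop("internal error: adjacent blocks with identical origin")
  left <- blocks$last_pos[-n]
  right <- blocks$first_pos[-1L]
  point <- as.integer((left + right) %/% 2L)
  drop <- rep(FALSE, length(point))
  if (length(point) > 1L) {
    too_close <- diff(point) < min_separation_bp
    if (any(too_close)) {
      idx <- which(too_close)
      drop[idx] <- TRUE
      drop[idx + 1L] <- TRUE
      flagged <- close_mode == "drop"
    }
  }
  out <- data.frame(left = as.integer(left[!drop]),
                    right = as.integer(right[!drop]),
                    point = point[!drop])
  out$index <- seq_len(nrow(out))
  attr(out, "flagged") <- flagged
  out
}

#' Call crossovers on a set of genotype tables
#'
#' Applies [detect_blocks()] and [call_crossovers()] to each kept
#' (individual, arm) genotype track.  The dot chromosome (arm `"4"`) uses a
#' relaxed block requirement of `dot_min_snps` consecutive SNPs to account
#' for its lower diagnostic-SNP density.
#'
#' @param tables List of [genotype_table()] objects (e.g. the `kept` element
#'   of [filter_arms()]).
#' @param min_snps,min_span_bp Block validation thresholds, see
#'   [detect_blocks()].
#' @param min_separation_bp,close_mode See [call_crossovers()].
#' @param dot_min_snps Block SNP threshold for arm `"4"` (default 4).
#' @param excluded Optional exclusion data.frame (from [filter_arms()]) to
#'   carry through into the call set.
#' @return A [crossover_callset()].
#' @export
call_genotype_tables <- function(tables, min_snps = 25L, min_span_bp = 250000L,
                                 min_separation_bp = 250000L,
                                 close_mode = "drop", dot_min_snps = 4L,
                                 excluded = NULL) {
  if (inherits(tables, "genotype_table")) tables <- list(tables)
  call_rows <- list(); chr_rows <- list()
  for (gt in tables) {
    ms <- if (gt$arm == "4") dot_min_snps else min_snps
    blocks <- detect_blocks(gt, min_snps = ms, min_span_bp = min_span_bp)
    calls <- call_crossovers(blocks, min_separation_bp = min_separation_bp,
                             close_mode = close_mode)
    chr_rows[[length(chr_rows) + 1L]] <- data.frame(
      individual = gt$individual_id, cross = gt$cross_id, arm = gt$arm,
      span_start = gt$detectable_span[1L], span_end = gt$detectable_span[2L],
      n_co = nrow(calls), flagged = isTRUE(attr(calls, "flagged")),
      stringsAsFactors = FALSE)
    if (nrow(calls))
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        individual = gt$individual_id, cross = gt$cross_id, arm = gt$arm,
        calls, stringsAsFactors = FALSE)
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else NULL
  chromatids <- if (length(chr_rows)) do.call(rbind, chr_rows) else NULL
  crossover_callset(calls = calls, chromatids = chromatids, excluded = excluded)
}

#' Tally chromatids by crossover class
#'
#' Counts, per arm, the chromatids carrying 0, 1, 2, ... crossovers
#' (classes above `kmax` are pooled into the top class).  Totals per arm
#' equal the number of kept chromatids.
#'
#' @param callset A [crossover_callset()].
#' @param kmax Highest class to report separately (default 4).
#' @return A [co_class_counts()] object.
#' @export
classify_chromatids <- function(callset, kmax = 4L) {
  stopifnot(inherits(callset, "crossover_callset"))
  chr <- callset$chromatids
  if (!nrow(chr)) stop("empty chromatid roster")
  arms <- sort(unique(chr$arm))
  k <- pmin(chr$n_co, kmax)
  mat <- matrix(0L, nrow = length(arms), ncol = kmax + 1L,
                dimnames = list(arms, as.character(0:kmax)))
  tab <- table(chr$arm, factor(k, levels = 0:kmax))
  mat[rownames(tab), ] <- as.integer(tab)
  co_class_counts(mat, provenance = "classify_chromatids")
}
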