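# Crossover call sets: called intervals per chromatid plus the chromatid
# roster needed as denominator for every downstream rate statistic.

#' Construct a crossover call set
#'
#' Container for crossover calls across chromatids.  `calls` holds one row
#' per crossover with its uncertainty interval in 0-based half-open (BED)
#' coordinates: `left` is the position of the last SNP of the upstream
#' origin block, `right` the position of the first SNP of the downstream
#' block, and `point` the floored interval midpoint.  `chromatids` is the
#' roster of all kept (individual, arm) chromatids — including those with
#' zero calls — with per-chromatid QC flags and detectable spans;
#' `excluded` records chromatids removed before calling, with reason codes.
#'
#' @param calls data.frame with columns `individual`, `cross`, `arm`,
#'   `left`, `right`, `point`, `index` (1-based crossover index along the
#'   chromatid).
#' @param chromatids data.frame with columns `individual`, `cross`, `arm`,
#'   `span_start`, `span_end`, `n_co`, `flagged`.
#' @param excluded data.frame with columns `individual`, `cross`, `arm`,
#'   `reason`.
#' @return An object of class `"crossover_callset"`.
#' @export
crossover_callset <- function(calls = NULL, chromatids = NULL, excluded = NULL) {
  empty_calls <- data.frame(individual = character(0), cross = character(0),
                            arm = character(0), left = integer(0),
                            right = integer(0), point = integer(0),
                            index = integer(0))
  empty_chr <- data.frame(individual = character(0), cross = character(0),
                          arm = character(0), span_start = integer(0),
                          span_end = integer(0), n_co = integer(0),
                          flagged = logical(0))
  empty_exc <- data.frame(individual = character(0), cross = character(0),
                          arm = character(0), reason = character(0))
  if (is.null(calls)) calls <- empty_calls
  if (is.null(chromatids)) chromatids <- empty_chr
  if (is.null(excluded)) excluded <- empty_exc
  stopifnot(all(c("individual", "arm", "left", "right", "point") %in% names(calls)))
  if (nrow(calls) && any(calls$left >= calls$right))
    stop("call interval with left >= right")
  ord <- order(calls$arm, calls$individual, calls$left)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  rownames(chromatids) <- NULL
  structure(list(calls = calls, chromatids = chromatids, excluded = excluded),
            class = "crossover_callset")
}

#' @export
print.crossover_callset <- function(x, ...) {
  cat(sprintf("<crossover_callset> %d calls on %d chromatids (%d excluded)\n",
              nrow(x$calls), nrow(x$chromatids), nrow(x$excluded)))
  if (nrow(x$chromatids)) {
    tab <- table(x$chromatids$arm)
    cat("  chromatids per arm: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write crossover calls as BED6
#'
#' One line per crossover: `arm  left  right  individual:cross  index  .`
#' with 0-based half-open intervals and deterministic ordering (arm,
#' individual, left).  A header comment records the column layout.
#'
#' @param callset A [crossover_callset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_crossovers_bed()]
#' @export
write_crossovers_bed <- function(callset, path) {
  stopifnot(inherits(callset, "crossover_callset"))
  calls <- callset$calls
  if (nrow(calls) && any(calls$left >= calls$right))
    stop("refusing to write interval with left >= right")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname\tscore\tstrand (0-based half-open)", con)
  if (nrow(calls)) {
    ord <- order(calls$arm, calls$individual, calls$left)
    calls <- calls[ord, , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%s:%s\t%d\t.",
                     calls$arm, calls$left, calls$right,
                     calls$individual, calls$cross, calls$index)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read crossover calls from a BED6 file written by [write_crossovers_bed()]
#'
#' @param path Path to the BED file.
#' @return data.frame with columns `individual`, `cross`, `arm`, `left`,
#'   `right`, `point`, `index` (point recomputed as floored midpoint).
#' @export
read_crossovers_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(crossover_callset()$calls)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 6L)
  if (length(bad))
    stop("malformed BED line(s): ", paste(bad, collapse = ", "))
  m <- do.call(rbind, parts)
  name <- strsplit(m[, 4L], ":", fixed = TRUE)
  left <- as.integer(m[, 2L]); right <- as.integer(m[, 3L])
  data.frame(
    individual = vapply(name, `[`, character(1), 1L),
    cross = vapply(name, `[`, character(1), 2L),
    arm = m[, 1L], left = left, right = right,
    point = as.integer((left + right) %/% 2L),
    index = as.integer(m[, 5L]), stringsAsFactors = FALSE)
}
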