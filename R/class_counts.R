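# Crossover-class counts: per-arm numbers of chromatids with 0,1,2,... COs.
# These tallies are the observed gamete-class frequencies g_k feeding the
# genetic map summaries and the Weinstein tetrad inversion.

#' Construct a crossover-class count table
#'
#' @param mat Integer matrix, rows = chromosome arms, columns = crossover
#'   classes `0 ... kmax` (column names coerced to `"0"`, `"1"`, ...).
#' @param provenance Free-text tag recording where the counts came from.
#' @return Object of class `"co_class_counts"` (a matrix with attributes).
#' @export
co_class_counts <- function(mat, provenance = "unspecified") {
  mat <- as.matrix(mat)
  if (any(mat < 0) || any(mat != round(mat)))
    stop("counts must be non-negative integers")
  storage.mode(mat) <- "integer"
  colnames(mat) <- as.character(seq_len(ncol(mat)) - 1L)
  structure(mat, provenance = provenance, class = c("co_class_counts", "matrix"))
}

#' @export
print.co_class_counts <- function(x, ...) {
  cat("<co_class_counts> chromatids by crossover class (provenance: ",
      attr(x, "provenance"), ")\n", sep = "")
  m <- unclass(x)
  attr(m, "provenance") <- NULL
  print(cbind(m, total = rowSums(m)))
  invisible(x)
}

#' Mean crossovers per meiotic product and map lengths
#'
#' Per arm, the mean number of crossovers per chromatid is
#' `sum(k * N_k) / n`; 100 times that mean is the arm's genetic map length
#' in cM (1 cM = 1 crossover per 100 meiotic products).  The genome-wide
#' mean crossovers per viable meiotic product is the *sum of the per-arm
#' means* — not total crossovers over total chromatids — because arms may
#' have unequal chromatid counts (e.g. when an arm is excluded from some
#' crosses).
#'
#' @param counts A [co_class_counts()].
#' @return List with `per_arm` (named mean vector), `map_cM` (named vector),
#'   `genome_wide` (sum of per-arm means) and `total_cM`.
#' @export
mean_crossovers_per_product <- function(counts) {
  stopifnot(inherits(counts, "co_class_counts"))
  n <- rowSums(counts)
  if (any(n == 0)) stop("arm with zero chromatids")
  k <- as.numeric(colnames(counts))
  per_arm <- as.vector(counts %*% k) / n
  names(per_arm) <- rownames(counts)
  list(per_arm = per_arm, map_cM = 100 * per_arm,
       genome_wide = sum(per_arm), total_cM = 100 * sum(per_arm))
}

#' Frequencies of meiotic event classes with binomial confidence intervals
#'
#' Pools chromatids over the non-excluded arms and reports the frequency of
#' chromatids with no crossover (NCO), a single crossover (1CO), and
#' multiple crossovers (2 or more, pooled), with normal-approximation
#' binomial confidence intervals.
#'
#' @param counts A [co_class_counts()].
#' @param exclude_arms Character vector of arms to drop (e.g. an arm
#'   confounded by a segregating inversion).
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame with columns `class`, `count`, `freq`, `lower`,
#'   `upper`; frequencies sum to 1.
#' @export
class_frequencies <- function(counts, exclude_arms = NULL, conf_level = 0.95) {
  stopifnot(inherits(counts, "co_class_counts"))
  keep <- setdiff(rownames(counts), exclude_arms)
  if (!length(keep)) stop("all arms excluded")
  m <- counts[keep, , drop = FALSE]
  tot <- colSums(m)
  n <- sum(tot)
  cls <- c(NCO = tot[["0"]], `1CO` = tot[["1"]],
           multiCO = sum(tot[-(1:2)]))
  p <- cls / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(p * (1 - p) / n)
  data.frame(class = names(cls), count = as.integer(cls), freq = unname(p),
             lower = pmax(0, unname(p - z * se)),
             upper = pmin(1, unname(p + z * se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summary of a crossover-class count table
#'
#' Reports the headline numbers of an F2 crossover experiment: total
#' crossovers, chromatid totals per class, per-arm and genome-wide mean
#' crossovers per meiotic product, and NCO/1CO/multi-CO frequencies after
#' excluding `exclude_arms`.
#'
#' @param object A [co_class_counts()].
#' @param exclude_arms Arms excluded from pooled class frequencies.
#' @param ... Unused.
#' @return List of class `"summary.co_class_counts"` with elements
#'   `total_crossovers`, `class_totals`, `mean_per_product` (result of
#'   [mean_crossovers_per_product()]) and `frequencies` (result of
#'   [class_frequencies()]).
#' @export
summary.co_class_counts <- function(object, exclude_arms = NULL, ...) {
  k <- as.numeric(colnames(object))
  out <- list(
    total_crossovers = as.integer(sum(object %*% k)),
    class_totals = colSums(object),
    n_chromatids = as.integer(sum(object)),
    mean_per_product = mean_crossovers_per_product(object),
    exclude_arms = exclude_arms,
    frequencies = class_frequencies(object, exclude_arms = exclude_arms))
  class(out) <- "summary.co_class_counts"
  out
}

#' @export
print.summary.co_class_counts <- function(x, ...) {
  cat(sprintf("Total crossovers: %d on %d chromatids\n",
              x$total_crossovers, x$n_chromatids))
  cat("Chromatids per crossover class:\n")
  print(x$class_totals)
  cat(sprintf("Mean crossovers per meiotic product (genome-wide): %.2f\n",
              x$mean_per_product$genome_wide))
  if (length(x$exclude_arms))
    cat("Event-class frequencies (excluding ",
        paste(x$exclude_arms, collapse = ", "), "):\n", sep = "")
  else cat("Event-class frequencies:\n")
  f <- x$frequencies
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-8s %5.1f%%  (95%% CI %.1f-%.1f)\n", f$class[i],
                100 * f$freq[i], 100 * f$lower[i], 100 * f$upper[i]))
  invisible(x)
}
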