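# Published reference values for the D. santomea F2 crossover study used as
# worked examples: the observed crossover-class counts (784 genotyped
# meiotic products; 2R restricted to inversion-free crosses) and the
# arm-level genetic map summaries.

#' Observed crossover-class counts for *D. santomea* F2 chromatids
#'
#' Chromatid counts by crossover class (0-4 crossovers) for each major
#' chromosome arm from a genome-wide F2 genotyping experiment in
#' *Drosophila santomea* (784 meiotic products; arm 2R restricted to the
#' three crosses free of a segregating inversion).  These are the observed
#' gamete-class data behind the package's worked examples: map-length
#' summaries, event-class frequencies and the Weinstein tetrad inversion.
#'
#' @return A [co_class_counts()] with arms `2L`, `2R`, `3L`, `3R`, `X`.
#' @export
#' @examples
#' summary(dsantomea_class_counts(), exclude_arms = "2R")
dsantomea_class_counts <- function() {
  mat <- rbind(
    `2L` = c(375L, 336L, 62L, 10L, 0L),
    `2R` = c(154L, 107L, 20L, 6L, 1L),
    `3L` = c(346L, 329L, 99L, 7L, 2L),
    `3R` = c(294L, 348L, 95L, 15L, 4L),
    X    = c(354L, 331L, 64L, 5L, 0L))
  co_class_counts(mat, provenance = "D. santomea F2 study (observed)")
}

#' Arm-level genetic maps and crossover rates for *D. santomea*
#'
#' Published per-arm genetic map lengths (cM) and average crossover rates
#' (cM/Mb per female meiosis) for *D. santomea*, including the pooled
#' autosomal, X and genome-wide rows.  Used in worked examples such as the
#' X-to-autosome rate ratio.
#'
#' @return data.frame with columns `arm`, `map_cM`, `rate_cM_Mb`.
#' @export
#' @examples
#' rates <- dsantomea_arm_rates()
#' xa_ratio(rates$rate_cM_Mb[rates$arm == "autosomes"],
#'          rates$rate_cM_Mb[rates$arm == "X"])
dsantomea_arm_rates <- function() {
  data.frame(
    arm = c("2L", "2R", "3L", "3R", "autosomes", "X", "all"),
    map_cM = c(62.51, 59.80, 61.55, 78.72, 262.58, 62.66, 324.24),
    rate_cM_Mb = c(2.70, 2.69, 2.39, 2.54, 2.57, 2.71, 2.61),
    stringsAsFactors = FALSE)
}
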