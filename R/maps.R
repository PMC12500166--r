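# Windowed crossover-rate tracks and map-level statistics.

#' Windowed crossover-rate track along an arm
#'
#' For each window the per-cross rate is
#' `100 * (crossover points in window / chromatids of the cross) / (window Mb)`
#' — cM/Mb per female meiosis — and the track value is the mean over
#' crosses, with the per-cross minimum and maximum retained (the envelope
#' of cross-to-cross variation).  Chromatid denominators come from the call
#' set's roster.
#'
#' @param callset A [crossover_callset()].
#' @param arm Chromosome arm to track.
#' @param arm_span Length-2 vector, the coordinate range to window (defaults
#'   to the range of detectable spans of the arm's chromatids).
#' @param window_bp Window size (default 1e6).
#' @param step_bp Step between window starts; `NULL` (default) for
#'   non-overlapping windows (`step = window`).
#' @return data.frame of class `"rate_track"` with columns `start`, `end`
#'   (0-based half-open), `rate_cM_Mb`, `rate_min`, `rate_max`, `n_crosses`;
#'   attributes `arm` and `scheme` (`"NON_OVERLAPPING"` or `"SLIDING"`).
#' @export
rate_track <- function(callset, arm, arm_span = NULL, window_bp = 1e6,
                       step_bp = NULL) {
  stopifnot(inherits(callset, "crossover_callset"))
  chr <- callset$chromatids[callset$chromatids$arm == arm, , drop = FALSE]
  if (!nrow(chr)) stop("no chromatids for arm ", arm)
  if (is.null(arm_span))
    arm_span <- c(min(chr$span_start), max(chr$span_end))
  if (diff(arm_span) < window_bp) stop("window larger than arm span")
  scheme <- if (is.null(step_bp)) "NON_OVERLAPPING" else "SLIDING"
  if (is.null(step_bp)) step_bp <- window_bp
  starts <- seq(arm_span[1L], arm_span[2L] - window_bp, by = step_bp)
  ends <- starts + window_bp
  calls <- callset$calls[callset$calls$arm == arm, , drop = FALSE]
  crosses <- sort(unique(chr$cross))
  denom <- vapply(crosses, function(cr) sum(chr$cross == cr), numeric(1))
  per_cross <- matrix(0, nrow = length(starts), ncol = length(crosses),
                      dimnames = list(NULL, crosses))
  mb <- window_bp / 1e6
  for (j in seq_along(crosses)) {
    pts <- calls$point[calls$cross == crosses[j]]
    if (length(pts)) {
      # windows may overlap: count per window
      cnt <- vapply(seq_along(starts), function(i)
        sum(pts >= starts[i] & pts < ends[i]), numeric(1))
    } else cnt <- numeric(length(starts))
    per_cross[, j] <- 100 * (cnt / denom[j]) / mb
  }
  out <- data.frame(start = starts, end = ends,
                    rate_cM_Mb = rowMeans(per_cross),
                    rate_min = apply(per_cross, 1L, min),
                    rate_max = apply(per_cross, 1L, max),
                    n_crosses = length(crosses))
  attr(out, "arm") <- arm
  attr(out, "scheme") <- scheme
  class(out) <- c("rate_track", "data.frame")
  out
}

#' Write / read a rate track as TSV
#'
#' Layout: `arm  start  end  rate_cM_Mb  n_crosses` (tab-separated), the
#' standard exchange format for windowed recombination-rate tracks.
#'
#' @param track A `rate_track` data.frame.
#' @param path File path.
#' @return `path` (write) or a `rate_track` data.frame (read).
#' @export
write_rate_track <- function(track, path) {
  df <- data.frame(arm = attr(track, "arm"), start = track$start,
                   end = track$end, rate_cM_Mb = track$rate_cM_Mb,
                   n_crosses = track$n_crosses)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_track
#' @export
read_rate_track <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE)
  out <- data.frame(start = df$start, end = df$end,
                    rate_cM_Mb = df$rate_cM_Mb,
                    rate_min = NA_real_, rate_max = NA_real_,
                    n_crosses = df$n_crosses)
  attr(out, "arm") <- as.character(df$arm[1L])
  steps <- unique(diff(df$start))
  attr(out, "scheme") <- if (length(steps) && all(steps == (df$end - df$start)[1L]))
    "NON_OVERLAPPING" else "SLIDING"
  class(out) <- c("rate_track", "data.frame")
  out
}

#' X-to-autosome crossover rate ratio
#'
#' @param autosomal_rate Pooled autosomal crossover rate (cM/Mb).
#' @param x_rate X-chromosome crossover rate (cM/Mb).
#' @return `x_rate / autosomal_rate`.
#' @export
#' @examples
#' xa_ratio(2.57, 2.71)  # ~1.05
xa_ratio <- function(autosomal_rate, x_rate) {
  if (autosomal_rate <= 0) stop("autosomal rate must be positive")
  x_rate / autosomal_rate
}

#' Interchromosomal-effect test
#'
#' Tests whether crosses segregating a heterozygous inversion show elevated
#' crossover counts on the *other* chromosome arms (the interchromosomal
#' effect), by one-way ANOVA on cross-level mean crossover counts between
#' inversion-carrier and standard crosses.
#'
#' @param per_cross_means Named numeric vector: per-cross mean crossover
#'   count outside the focal arm.
#' @param groups Named character vector (same names) with values
#'   `"INV_HET"` or `"STANDARD"`.
#' @return List with `F_statistic`, `df`, `p_value`.
#' @export
interchromosomal_test <- function(per_cross_means, groups) {
  groups <- groups[names(per_cross_means)]
  if (anyNA(groups)) stop("groups must be named for every cross")
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 crosses")
  fit <- stats::lm(per_cross_means ~ g)
  a <- stats::anova(fit)
  list(F_statistic = a$`F value`[1L],
       df = c(a$Df[1L], a$Df[2L]),
       p_value = a$`Pr(>F)`[1L])
}

# Rebin a non-overlapping rate track to a coarser scale by length-weighted
# averaging of window overlaps.
.rebin_track <- function(track, scale_bp, origin = 0) {
  start <- track$start; end <- track$end; rate <- track$rate_cM_Mb
  lo <- min(start); hi <- max(end)
  bins <- seq(origin + floor((lo - origin) / scale_bp) * scale_bp, hi, by = scale_bp)
  vals <- rep(NA_real_, length(bins))
  for (i in seq_along(bins)) {
    b0 <- bins[i]; b1 <- bins[i] + scale_bp
    ov <- pmax(0, pmin(end, b1) - pmax(start, b0))
    if (sum(ov) > 0) vals[i] <- sum(rate * ov) / sum(ov)
  }
  data.frame(bin = bins, rate = vals)
}

#' Spearman correlation of two rate tracks across genomic scales
#'
#' Rebins both tracks (non-overlapping windows, length-weighted
#' aggregation) to each requested scale and reports the Spearman rank
#' correlation over bins where both are defined.  Correlations of crossover
#' landscapes typically decay at fine scales; this function quantifies that
#' scale dependence.
#'
#' @param track_a,track_b `rate_track` data.frames on a shared coordinate
#'   system.
#' @param scales Numeric vector of bin sizes in bp.
#' @return data.frame with columns `scale`, `rho`, `p_value`, `n_bins`
#'   (`rho = NA` where fewer than 3 shared bins exist).
#' @export
multiscale_spearman <- function(track_a, track_b, scales) {
  out <- data.frame(scale = scales, rho = NA_real_, p_value = NA_real_,
                    n_bins = 0L)
  for (i in seq_along(scales)) {
    a <- .rebin_track(track_a, scales[i])
    b <- .rebin_track(track_b, scales[i])
    shared <- merge(a, b, by = "bin")
    shared <- shared[stats::complete.cases(shared), , drop = FALSE]
    out$n_bins[i] <- nrow(shared)
    if (nrow(shared) >= 3L) {
      ct <- suppressWarnings(
        cor.test(shared$rate.x, shared$rate.y, method = "spearman"))
      out$rho[i] <- unname(ct$estimate)
      out$p_value[i] <- ct$p.value
    }
  }
  out
}
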