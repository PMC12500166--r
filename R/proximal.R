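# Centromere and telomere effects: proximal-third deficit test and the
# sliding-window estimator of the suppressed region's extent.
#
# Null model throughout: crossovers placed uniformly on the crossover-
# detectable span of the arm (not the assembly span).

# Resolve the scanned/tested end of the arm in bp coordinates.
.proximal_end <- function(side, centromere_at) {
  side <- match.arg(side, c("centromere", "telomere"))
  centromere_at <- match.arg(centromere_at, c("end", "start"))
  if (side == "centromere") centromere_at else
    if (centromere_at == "end") "start" else "end"
}

#' Proximal-third crossover deficit test
#'
#' Compares the number of crossovers observed in the centromere- (or
#' telomere-) proximal third of a chromosome arm with the number expected
#' under uniform placement along the crossover-detectable span, by Monte
#' Carlo: each replicate places the same number of crossovers uniformly on
#' the span and counts those landing in the proximal third (the count of a
#' uniform placement is a Binomial(n, 1/3) draw, which is how the
#' replicates are generated).  The p-value is the fraction of replicates
#' with a proximal-third count less than or equal to the observed count
#' (one-sided deficit test).
#'
#' @param co_points Numeric vector of crossover point positions (bp).
#' @param arm_span Length-2 vector: the crossover-detectable span.
#' @param side `"centromere"` or `"telomere"`.
#' @param n_reps Monte Carlo replicates (default 1e7).
#' @param centromere_at Which end of the coordinate system the centromere
#'   is on (`"end"`, the default for telocentric arm assemblies oriented
#'   telomere-to-centromere, or `"start"`).
#' @param seed Optional RNG seed.
#' @return List with `observed`, `expected` (`n/3`), `p_value`, `n_reps`.
#' @export
proximal_third_test <- function(co_points, arm_span,
                                side = c("centromere", "telomere"),
                                n_reps = 1e7, centromere_at = "end",
                                seed = NULL) {
  side <- match.arg(side)
  if (!is.null(seed)) set.seed(seed)
  n <- length(co_points)
  if (n == 0L) {
    warning("no crossovers supplied; p = 1")
    return(list(observed = 0L, expected = 0, p_value = 1, n_reps = n_reps))
  }
  if (any(co_points < arm_span[1L] | co_points > arm_span[2L]))
    stop("crossover points outside arm span")
  len <- diff(arm_span)
  third <- len / 3
  end <- .proximal_end(side, centromere_at)
  observed <- if (end == "end")
    sum(co_points > arm_span[2L] - third) else
    sum(co_points < arm_span[1L] + third)
  null_counts <- rbinom(n_reps, n, 1 / 3)
  list(observed = as.integer(observed), expected = n / 3,
       p_value = mean(null_counts <= observed), n_reps = n_reps)
}

#' Extent of centromere/telomere crossover suppression
#'
#' Slides 1-Mb windows (step 100 kb) inward from the chromosome-arm end
#' nearest the centromere (or telomere) and tests each window for a
#' crossover deficit with an exact one-sided binomial test:
#' `p_i = P(Bin(N, q_i) <= x_i)` where `N` is the total crossovers on the
#' arm, `q_i` the fraction of the detectable span covered by the window and
#' `x_i` the observed crossovers in the window.  The scan stops at the
#' first run of `stop_run` consecutive windows with `p_i >= alpha`; the
#' extent of the suppressed region is the distance from the arm end to the
#' inner edge of the last significant window before that run (0 if the scan
#' opens with `stop_run` non-significant windows).
#'
#' @inheritParams proximal_third_test
#' @param n_chromatids Unused denominator bookkeeping, kept for interface
#'   symmetry with rate statistics; may be `NULL`.
#' @param alpha Significance level per window (`1e-6` or `1e-3` are the
#'   conventional strict/relaxed choices).
#' @param window_bp,step_bp Window geometry (defaults 1 Mb / 100 kb).
#' @param stop_run Length of the non-significant run that terminates the
#'   scan (default 5).
#' @param boundary `"last_significant"` (default): extent ends at the inner
#'   edge of the last significant window; `"run_start"`: at the outer edge
#'   of the terminating non-significant run (differs by at most
#'   `window - step`).
#' @return List with `extent_bp` and `windows` (data.frame `start`, `end`
#'   in distance-from-arm-end coordinates, `q`, `observed`, `p_value`,
#'   `significant`).
#' @export
scan_effect_extent <- function(co_points, arm_span, n_chromatids = NULL,
                               side = c("centromere", "telomere"),
                               alpha = 1e-6, window_bp = 1e6, step_bp = 1e5,
                               stop_run = 5L, centromere_at = "end",
                               boundary = c("last_significant", "run_start")) {
  side <- match.arg(side)
  boundary <- match.arg(boundary)
  len <- diff(arm_span)
  if (len < window_bp) stop("arm shorter than window")
  end <- .proximal_end(side, centromere_at)
  # distance of each crossover from the scanned arm end
  d <- if (end == "end") arm_span[2L] - co_points else co_points - arm_span[1L]
  if (any(d < 0 | d > len)) stop("crossover points outside arm span")
  N <- length(co_points)
  starts <- seq(0, len - window_bp, by = step_bp)
  n_win <- length(starts)
  obs <- vapply(starts, function(s) sum(d >= s & d < s + window_bp), numeric(1))
  q <- window_bp / len
  p <- pbinom(obs, N, q)
  sig <- p < alpha
  # first run of stop_run consecutive non-significant windows
  run <- 0L; run_start_idx <- NA_integer_
  for (i in seq_len(n_win)) {
    run <- if (sig[i]) 0L else run + 1L
    if (run >= stop_run) { run_start_idx <- i - stop_run + 1L; break }
  }
  windows <- data.frame(start = starts, end = starts + window_bp, q = q,
                        observed = as.integer(obs), p_value = p,
                        significant = sig)
  if (is.na(run_start_idx)) {
    # no terminating run: whole scanned range affected
    last_sig <- if (any(sig)) max(which(sig)) else NA_integer_
  } else {
    last_sig <- if (any(sig[seq_len(run_start_idx - 1L)]))
      max(which(sig[seq_len(run_start_idx - 1L)])) else NA_integer_
  }
  extent <- if (is.na(last_sig)) 0 else if (boundary == "last_significant")
    windows$end[last_sig] else
    if (!is.na(run_start_idx)) windows$start[run_start_idx] else
      windows$end[last_sig]
  list(extent_bp = extent, windows = windows)
}

#' Suppression extent under crossover-count subsampling
#'
#' The extent estimate of [scan_effect_extent()] depends on statistical
#' power and therefore on the number of crossovers; to compare arms or
#' datasets with different crossover counts, each is subsampled to a common
#' `target_n` and the extent recomputed per subsample.
#'
#' @param co_points Crossover points (bp).
#' @param target_n Crossovers per subsample (without replacement); must not
#'   exceed `length(co_points)`.
#' @param n_subsamples Number of subsampling replicates (default 100).
#' @param seed Optional RNG seed.
#' @param ... Passed to [scan_effect_extent()] (`arm_span`, `side`,
#'   `alpha`, ...).
#' @return List with `extents` (vector), `median`, `iqr`.
#' @export
subsampled_extent <- function(co_points, target_n, n_subsamples = 100L,
                              seed = NULL, ...) {
  if (target_n > length(co_points))
    stop("target_n exceeds available crossovers")
  if (!is.null(seed)) set.seed(seed)
  extents <- vapply(seq_len(n_subsamples), function(i) {
    sub <- sample(co_points, target_n, replace = FALSE)
    scan_effect_extent(sub, ...)$extent_bp
  }, numeric(1))
  list(extents = extents, median = median(extents),
       iqr = unname(diff(quantile(extents, c(0.25, 0.75)))))
}
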