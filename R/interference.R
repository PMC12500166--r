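# Crossover interference from inter-crossover distances (ICD) in 2CO
# chromatids, with a data-driven null built from 1CO chromatid positions.
# Using real 1CO positions for the null bakes in centromere/telomere
# suppression and any other rate heterogeneity along the arm.

#' Observed inter-crossover distances on an arm
#'
#' The ICD of a 2CO chromatid is the distance between its two crossover
#' point estimates.  Chromatids with three or more crossovers are excluded
#' by default; set `include_adjacent_gaps = TRUE` to instead use every
#' adjacent crossover gap from chromatids with 2 or more crossovers.
#'
#' @param callset A [crossover_callset()].
#' @param arm Chromosome arm.
#' @param include_adjacent_gaps Include adjacent gaps from >2CO chromatids
#'   (default `FALSE`).
#' @return List with `icds` (bp), `mean`, `min`, `n_2co`; empty `icds` with
#'   a warning if the arm has no 2CO chromatid.
#' @export
observed_icd <- function(callset, arm, include_adjacent_gaps = FALSE) {
  stopifnot(inherits(callset, "crossover_callset"))
  calls <- callset$calls[callset$calls$arm == arm, , drop = FALSE]
  chr <- callset$chromatids[callset$chromatids$arm == arm, , drop = FALSE]
  n2 <- sum(chr$n_co == 2L)
  icds <- numeric(0)
  if (nrow(calls)) {
    by_ind <- split(calls$point, calls$individual)
    for (pts in by_ind) {
      pts <- sort(pts)
      if (length(pts) == 2L) icds <- c(icds, diff(pts))
      else if (length(pts) > 2L && include_adjacent_gaps)
        icds <- c(icds, diff(pts))
    }
  }
  if (!length(icds)) {
    warning("no 2CO chromatids on arm ", arm)
    return(list(icds = numeric(0), mean = NA_real_, min = NA_real_, n_2co = n2))
  }
  list(icds = icds, mean = mean(icds), min = min(icds), n_2co = n2)
}

#' Positions of single crossovers on 1CO chromatids
#'
#' @param callset A [crossover_callset()].
#' @param arm Chromosome arm.
#' @return Numeric vector of crossover points, one per 1CO chromatid.
#' @export
one_co_positions <- function(callset, arm) {
  stopifnot(inherits(callset, "crossover_callset"))
  calls <- callset$calls[callset$calls$arm == arm, , drop = FALSE]
  if (!nrow(calls)) return(numeric(0))
  by_ind <- split(calls$point, calls$individual)
  unlist(by_ind[lengths(by_ind) == 1L], use.names = FALSE)
}

#' Null distribution of inter-crossover distances from 1CO chromatids
#'
#' Each replicate draws two *distinct* 1CO chromatids and records the
#' distance between their single-crossover positions.  Because the null
#' positions are real 1CO crossovers, the null inherits the arm's
#' centromere/telomere suppression and rate heterogeneity; its mean is the
#' expected ICD under no interference.
#'
#' @param positions Vector of 1CO crossover positions (bp), one per
#'   chromatid; at least 2 distinct chromatids required.
#' @param n_reps Replicates (default 1e6).
#' @param seed Optional RNG seed.
#' @return List with `sample` (null ICDs, bp) and `expected_mean`.
#' @export
expected_icd_null <- function(positions, n_reps = 1e6, seed = NULL) {
  n <- length(positions)
  if (n < 2L) stop("need at least 2 one-CO chromatids")
  if (!is.null(seed)) set.seed(seed)
  i <- sample.int(n, n_reps, replace = TRUE)
  j <- sample.int(n, n_reps, replace = TRUE)
  while (any(same <- i == j))
    j[same] <- sample.int(n, sum(same), replace = TRUE)
  icd <- abs(positions[i] - positions[j])
  list(sample = icd, expected_mean = mean(icd))
}

#' Resampling test for positive crossover interference
#'
#' Positive interference spreads the two crossovers of a 2CO chromatid
#' farther apart than the no-interference null.  In `"set_mean"` mode
#' (default) the p-value is the fraction of resampled null sets — each of
#' the same size as the observed ICD set — whose mean is at least the
#' observed mean; in `"single_pair"` mode it is the fraction of single null
#' ICDs at least the observed mean.  Positive interference is inferred at
#' p < 0.05.  A p of 0 is reported as less than one over the number of
#' resamples.
#'
#' @param observed Observed ICDs (bp).
#' @param null_sample Null ICD sample from [expected_icd_null()].
#' @param mode `"set_mean"` or `"single_pair"`.
#' @param n_sets Number of resampled sets in `"set_mean"` mode (default
#'   1e5).
#' @param seed Optional RNG seed.
#' @return List with `p_value`, `p_label` (`"<1/n"` form when 0),
#'   `ratio_obs_exp` and `mode`.
#' @export
icd_interference_test <- function(observed, null_sample,
                                  mode = c("set_mean", "single_pair"),
                                  n_sets = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  if (!length(observed) || !length(null_sample)) stop("empty input")
  if (!is.null(seed)) set.seed(seed)
  obs_mean <- mean(observed)
  if (mode == "single_pair") {
    p <- mean(null_sample >= obs_mean)
    n_eff <- length(null_sample)
  } else {
    m <- length(observed)
    draws <- matrix(sample(null_sample, n_sets * m, replace = TRUE),
                    nrow = m)
    p <- mean(colMeans(draws) >= obs_mean)
    n_eff <- n_sets
  }
  list(p_value = p,
       p_label = if (p == 0) sprintf("< %g", 1 / n_eff) else format(p),
       ratio_obs_exp = obs_mean / mean(null_sample), mode = mode)
}

#' Gamma shape (nu) maximum-likelihood fit
#'
#' Fits a gamma distribution by maximum likelihood with the scale profiled
#' out, solving `log(nu) - digamma(nu) = log(mean(x)) - mean(log(x))` for
#' the shape.  Under random (no-interference) crossover placement the
#' expected shape is 1; shapes above 1 indicate positive interference
#' under the gamma model of ICDs.
#'
#' For distributions that are not actually gamma (such as the triangular
#' null ICD under uniform placement) the ML and moment estimators can
#' differ substantially — the MLE is pulled down by density mass near
#' zero; `method = "moments"` returns `mean(x)^2 / var(x)` instead.
#'
#' @param x Positive distances; `n >= 2` required.
#' @param method `"mle"` (default) or `"moments"`.
#' @param tol Convergence tolerance on the profile equation (default 1e-8).
#' @return The shape estimate `nu_hat`.
#' @export
#' @examples
#' set.seed(1)
#' fit_gamma_shape(rgamma(5000, shape = 1))  # ~1
fit_gamma_shape <- function(x, method = c("mle", "moments"), tol = 1e-8) {
  method <- match.arg(method)
  if (any(x <= 0)) stop("all distances must be positive")
  if (length(x) < 2L) stop("need at least 2 values")
  if (method == "moments") return(mean(x)^2 / stats::var(x))
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) stop("degenerate sample (zero spread)")
  # method-of-moments start brackets the digamma profile root
  f <- function(a) log(a) - digamma(a) - s
  lo <- 1e-3; hi <- max(1, (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)) * 10
  while (f(hi) > 0) hi <- hi * 10
  root <- uniroot(f, c(lo, hi), tol = tol)
  if (abs(root$f.root) > 1e-4)
    stop("gamma shape fit did not converge (residual ", root$f.root, ")")
  root$root
}

#' Expected gamma shape under the data-driven null
#'
#' Fits [fit_gamma_shape()] to the null ICD sample built from 1CO
#' chromatid positions; zero distances (identical positions) are excluded
#' with their count reported.  Because 1CO positions are non-uniform, the
#' expected shape typically exceeds 1 even without interference.
#'
#' @inheritParams expected_icd_null
#' @return List with `nu`, `n_zero_dropped`, `n_used`.
#' @export
expected_nu <- function(positions, n_reps = 1e6, seed = NULL) {
  null <- expected_icd_null(positions, n_reps = n_reps, seed = seed)$sample
  zero <- null == 0
  if (all(zero)) stop("all null ICDs are zero (degenerate positions)")
  list(nu = fit_gamma_shape(null[!zero]),
       n_zero_dropped = sum(zero), n_used = sum(!zero))
}

#' Per-arm crossover interference summary
#'
#' For each arm: number of 2CO chromatids, observed mean and minimum ICD,
#' expected ICD from the 1CO null, observed/expected ratio, resampling
#' p-value, and observed and expected gamma shapes.  A pooled `"all"` row
#' concatenates per-arm observed ICDs and per-arm null samples weighted by
#' their 2CO counts.
#'
#' @param callset A [crossover_callset()].
#' @param arms Arms to analyse (default: all arms with at least one 2CO
#'   chromatid and two 1CO chromatids).
#' @param n_reps Null replicates per arm (default 1e6).
#' @param n_sets Resampled sets for the p-value (default 1e5).
#' @param mode Test mode, see [icd_interference_test()].
#' @param seed Optional RNG seed.
#' @return data.frame with one row per arm plus `"all"`.
#' @export
interference_summary <- function(callset, arms = NULL, n_reps = 1e6,
                                 n_sets = 1e5, mode = "set_mean",
                                 seed = NULL) {
  stopifnot(inherits(callset, "crossover_callset"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(arms)) {
    cand <- sort(unique(callset$chromatids$arm))
    arms <- cand[vapply(cand, function(a) {
      sum(callset$chromatids$n_co[callset$chromatids$arm == a] == 2L) >= 1L &&
        length(one_co_positions(callset, a)) >= 2L
    }, logical(1))]
  }
  rows <- list(); pooled_obs <- numeric(0); pooled_null <- list()
  for (a in arms) {
    obs <- observed_icd(callset, a)
    null <- expected_icd_null(one_co_positions(callset, a), n_reps = n_reps)
    tst <- icd_interference_test(obs$icds, null$sample, mode = mode,
                                 n_sets = n_sets)
    nz <- null$sample[null$sample > 0]
    rows[[a]] <- data.frame(
      arm = a, n_2co = obs$n_2co, mean_icd_kb = obs$mean / 1000,
      min_icd_kb = obs$min / 1000, expected_icd_kb = null$expected_mean / 1000,
      ratio_obs_exp = obs$mean / null$expected_mean, p_value = tst$p_value,
      nu_observed = if (length(obs$icds) >= 2L) fit_gamma_shape(obs$icds)
                    else NA_real_,
      nu_expected = fit_gamma_shape(nz), stringsAsFactors = FALSE)
    pooled_obs <- c(pooled_obs, obs$icds)
    pooled_null[[a]] <- null$sample
  }
  out <- do.call(rbind, rows)
  if (length(pooled_obs) >= 2L) {
    # genome-wide null: mix per-arm nulls in proportion to their 2CO counts
    w <- out$n_2co / sum(out$n_2co)
    pn <- unlist(lapply(seq_along(pooled_null), function(k)
      sample(pooled_null[[k]], max(1L, round(n_reps * w[k])), replace = TRUE)),
      use.names = FALSE)
    tst <- icd_interference_test(pooled_obs, pn, mode = mode, n_sets = n_sets)
    out <- rbind(out, data.frame(
      arm = "all", n_2co = sum(out$n_2co), mean_icd_kb = mean(pooled_obs) / 1000,
      min_icd_kb = min(pooled_obs) / 1000,
      expected_icd_kb = mean(pn) / 1000,
      ratio_obs_exp = mean(pooled_obs) / mean(pn), p_value = tst$p_value,
      nu_observed = fit_gamma_shape(pooled_obs),
      nu_expected = fit_gamma_shape(pn[pn > 0]), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
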