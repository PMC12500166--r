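# Weinstein tetrad analysis: from the observed distribution of crossovers
# on single chromatids (gamete classes g_k) back to the distribution of
# crossovers per tetrad (E_r), assuming random chromatid involvement and no
# chromatid interference, optionally with crossover-associated meiotic
# drive (MD_CO): biased retention, at meiosis II, of the sister chromatid
# carrying more crossovers.

# Retention matrix M(beta): M[k+1, r+1] = P(retained chromatid carries k
# COs | tetrad has r COs).  Each CO lands on one of the two sisters of the
# retained dyad independently (p = 1/2), giving sister counts (j, r-j);
# when the counts differ the sister with more COs is retained with
# probability beta, otherwise either with probability 1/2.  beta = 0.5
# reduces every column to Binomial(r, 1/2).
.retention_matrix <- function(rmax, beta) {
  if (beta < 0.5 || beta > 1) stop("drive_beta must lie in [0.5, 1]")
  M <- matrix(0, rmax + 1L, rmax + 1L,
              dimnames = list(as.character(0:rmax), as.character(0:rmax)))
  for (r in 0:rmax) {
    for (j in 0:r) {
      w <- choose(r, j) / 2^r
      hi <- max(j, r - j); lo <- min(j, r - j)
      if (hi == lo) M[hi + 1L, r + 1L] <- M[hi + 1L, r + 1L] + w
      else {
        M[hi + 1L, r + 1L] <- M[hi + 1L, r + 1L] + w * beta
        M[lo + 1L, r + 1L] <- M[lo + 1L, r + 1L] + w * (1 - beta)
      }
    }
  }
  M
}

#' Weinstein direct (unrestricted) tetrad inversion
#'
#' Inverts the gamete-class frequencies `g_k` to tetrad-class frequencies
#' `E_r` under random chromatid involvement and no drive, using the closed
#' form `E_r = 2^r * sum_{k >= r} (-1)^(k - r) * choose(k, r) * g_k`.  The
#' result always sums to 1, but individual entries can be negative; such a
#' solution is algebraically valid yet non-physical and is flagged
#' infeasible (the signature that the model's assumptions — e.g. unbiased
#' segregation — do not hold for the data).
#'
#' @param g Gamete-class frequencies or counts for classes `0 ... kmax`
#'   (counts are normalised; frequencies must sum to 1 within 1e-6).
#' @return Object of class `"tetrad_dist"`: list with `E` (named vector),
#'   `rmax`, `drive_beta = 0.5`, `feasible`, `method = "direct"`.
#' @export
#' @examples
#' g <- c(354, 331, 64, 5, 0) / 754
#' weinstein_direct(g)$E[1]  # E_0 ~ 0.109
weinstein_direct <- function(g) {
  g <- as.numeric(g)
  if (any(g < 0)) stop("gamete classes must be non-negative")
  s <- sum(g)
  if (s <= 0) stop("empty gamete-class vector")
  if (abs(s - 1) > 1e-6) {
    if (all(g == round(g))) g <- g / s
    else stop("gamete-class frequencies must sum to 1")
  }
  kmax <- length(g) - 1L
  E <- vapply(0:kmax, function(r) {
    k <- r:kmax
    2^r * sum((-1)^(k - r) * choose(k, r) * g[k + 1L])
  }, numeric(1))
  names(E) <- paste0("E", 0:kmax)
  structure(list(E = E, rmax = kmax, drive_beta = 0.5,
                 feasible = all(E >= -1e-12), method = "direct"),
            class = "tetrad_dist")
}

#' @export
print.tetrad_dist <- function(x, ...) {
  cat("<tetrad_dist> tetrad crossover-class frequencies (method: ",
      x$method, ")\n", sep = "")
  print(round(x$E, 4))
  if (x$drive_beta != 0.5)
    cat(sprintf("meiosis-II drive beta = %.3f\n", x$drive_beta))
  if (!x$feasible)
    cat("NOTE: negative entries - non-physical (model assumptions violated)\n")
  invisible(x)
}

#' Forward model: gamete classes from a tetrad distribution
#'
#' A tetrad with `r` crossovers distributes each crossover independently to
#' one of the two chromatids of each homolog (no chromatid interference),
#' so the retained dyad's sister chromatids carry `(j, r - j)` crossovers
#' with probability `choose(r, j) / 2^r`.  Meiosis I retains either
#' homolog pair with probability 1/2 (symmetric, hence irrelevant to the
#' marginal); at meiosis II the sister with more crossovers is retained
#' with probability `drive_beta` when the counts differ.  With
#' `drive_beta = 0.5` this reduces exactly to `Binomial(r, 1/2)` sampling
#' of gamete classes.
#'
#' @param dist A `"tetrad_dist"` or a non-negative `E` vector summing to 1
#'   (classes `0 ... rmax`).
#' @param drive_beta Retention probability in `[0.5, 1]`; default taken
#'   from `dist` or 0.5.
#' @return Named vector of gamete-class probabilities `g_0 ... g_rmax`.
#' @export
#' @examples
#' predict_gamete_classes(c(0, 1), drive_beta = 1)  # always the CO sister
predict_gamete_classes <- function(dist, drive_beta = NULL) {
  if (inherits(dist, "tetrad_dist")) {
    if (is.null(drive_beta)) drive_beta <- dist$drive_beta
    E <- dist$E
  } else E <- as.numeric(dist)
  if (is.null(drive_beta)) drive_beta <- 0.5
  if (any(E < -1e-9) || abs(sum(E) - 1) > 1e-6)
    stop("E must be a probability vector over tetrad classes")
  rmax <- length(E) - 1L
  g <- drop(.retention_matrix(rmax, drive_beta) %*% pmax(E, 0))
  g <- g / sum(g)
  names(g) <- paste0("g", 0:rmax)
  g
}

# Pearson chi-square of observed counts against predicted class
# probabilities, with tail classes pooled until every expected count is at
# least 1 (pooling recorded for the df of the p-value).
.tetrad_chisq <- function(obs, pred, pred_floor = 1e-12) {
  n <- sum(obs)
  exp_full <- n * pmax(pred, pred_floor)
  x2 <- sum((obs - n * pred)^2 / exp_full)
  # pooled cells for the p-value
  o <- obs; e <- exp_full
  while (length(o) > 2L && e[length(e)] < 1) {
    k <- length(o)
    o[k - 1L] <- o[k - 1L] + o[k]; e[k - 1L] <- e[k - 1L] + e[k]
    o <- o[-k]; e <- e[-k]
  }
  x2_pooled <- sum((o - e)^2 / e)
  list(chi_square = x2, chi_square_pooled = x2_pooled,
       n_cells = length(o))
}

# Build (E, beta) from the optimiser's unconstrained parameter vector.
.tetrad_par_decode <- function(par, rmax, allow_drive, fix_E0) {
  n_e <- rmax + 1L - !is.null(fix_E0)
  z <- par[seq_len(n_e)]
  w <- exp(z - max(z))
  w <- w / sum(w)
  if (!is.null(fix_E0)) E <- c(fix_E0, (1 - fix_E0) * w)
  else E <- w
  beta <- 0.5
  if (allow_drive) beta <- 0.5 + 0.5 * stats::plogis(par[length(par)])
  list(E = E, beta = beta)
}

#' Constrained Weinstein tetrad fit
#'
#' Estimates the tetrad crossover-class distribution `E_r` (restricted to
#' the probability simplex) — and optionally the meiosis-II drive bias
#' `beta` of the MD_CO model — by minimising the Pearson chi-square between
#' observed and predicted gamete-class counts, using Dirichlet-proposal
#' random search with annealing-style concentration around the incumbent
#' and gradient-free numeric optimisation (Nelder-Mead on a softmax
#' parameterisation) from multiple starts; the better optimum is returned.
#'
#' When drive is allowed the model is *interval-identified only*: the
#' gamete-class distribution is linear in `E` (`g = M(beta) E` with
#' `M(beta)` invertible), so every `beta` in a feasible interval admits an
#' `E(beta)` in the simplex reproducing the classes exactly.  Use
#' `beta_profile = TRUE` to map that ridge; point estimates of `(E_0,
#' beta)` from class frequencies alone should not be over-interpreted.
#'
#' @param counts Observed chromatid counts for classes `0 ... kmax`.
#' @param rmax Highest tetrad class fitted (default `length(counts) - 1`;
#'   larger values are unidentifiable from the available classes and
#'   refused).
#' @param allow_drive Fit the MD_CO retention bias `beta` in `[0.5, 1]`
#'   (default `FALSE`).
#' @param fix_E0 Optionally fix `E_0` (used by [profile_E0()]).
#' @param fix_beta Optionally fix `beta` at a given value.
#' @param constraints Optional `function(E, beta)` returning `TRUE` for
#'   admissible parameters (e.g. `function(E, b) E[5] <= E[4]`).
#' @param method `"both"` (default), `"random"` or `"optim"`.
#' @param budget Random-search evaluations (default 200000).
#' @param n_starts Nelder-Mead multistarts (default 20).
#' @param beta_profile If `TRUE` (and `allow_drive`), additionally fit on a
#'   fixed grid of beta values and return the profile.
#' @param seed Optional RNG seed.
#' @return Object of class `"tetrad_fit"`: the fitted `"tetrad_dist"` plus
#'   `chi_square`, `df`, `p_value`, `predicted_g`, `observed`, `n`,
#'   `method`, `n_evaluations`, and optionally `beta_profile`.
#' @export
#' @examples
#' fit <- tetrad_fit(c(354, 331, 64, 5, 0), seed = 1, budget = 2000,
#'                   n_starts = 4)
#' coef(fit)
tetrad_fit <- function(counts, rmax = length(counts) - 1L,
                       allow_drive = FALSE, fix_E0 = NULL, fix_beta = NULL,
                       constraints = NULL, method = c("both", "random", "optim"),
                       budget = 200000L, n_starts = 20L,
                       beta_profile = FALSE, seed = NULL) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0) stop("invalid counts")
  kmax <- length(counts) - 1L
  if (rmax > kmax)
    stop("rmax beyond the highest observed class is unidentifiable; ",
         "supply constraints or reduce rmax")
  if (rmax < kmax) stop("rmax below the highest observed class")
  if (!is.null(fix_E0) && (fix_E0 < 0 || fix_E0 > 1))
    stop("fix_E0 must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- sum(counts)
  g_obs <- counts / n

  # the retention matrix depends only on beta; cache the last one
  M_cache_beta <- NA_real_; M_cache <- NULL
  ret_mat <- function(beta) {
    if (!identical(beta, M_cache_beta)) {
      M_cache <<- .retention_matrix(rmax, beta)
      M_cache_beta <<- beta
    }
    M_cache
  }
  objective <- function(E, beta) {
    if (!is.null(constraints) && !isTRUE(constraints(E, beta))) return(Inf)
    pred <- drop(ret_mat(beta) %*% E)
    .tetrad_chisq(counts, pred)$chi_square
  }
  drive_free <- allow_drive && is.null(fix_beta)
  beta_fixed <- if (!is.null(fix_beta)) fix_beta else 0.5

  best <- list(E = NULL, beta = NA_real_, value = Inf)
  n_eval <- 0L

  # seed the search with the direct inversion when it is feasible
  direct <- weinstein_direct(g_obs)
  if (direct$feasible && is.null(fix_E0)) {
    E0c <- pmax(direct$E, 0); E0c <- E0c / sum(E0c)
    v <- objective(E0c, beta_fixed); n_eval <- n_eval + 1L
    if (v < best$value) best <- list(E = E0c, beta = beta_fixed, value = v)
  }

  rand_E <- function(center = NULL, conc = 1) {
    n_e <- rmax + 1L - !is.null(fix_E0)
    alpha <- if (is.null(center)) rep(1, n_e) else 1 + conc * center
    w <- rgamma(n_e, shape = alpha)
    w <- w / sum(w)
    if (!is.null(fix_E0)) c(fix_E0, (1 - fix_E0) * w) else w
  }

  if (method %in% c("both", "random")) {
    phases <- list(list(frac = 0.4, conc = 0), list(frac = 0.3, conc = 50),
                   list(frac = 0.3, conc = 500))
    for (ph in phases) {
      n_it <- ceiling(budget * ph$frac)
      center <- if (ph$conc > 0 && !is.null(best$E)) {
        ce <- if (!is.null(fix_E0)) best$E[-1L] / max(1 - fix_E0, 1e-12)
              else best$E
        ce
      } else NULL
      for (it in seq_len(n_it)) {
        E <- rand_E(center, ph$conc)
        beta <- if (drive_free) {
          if (ph$conc > 0 && !is.na(best$beta))
            min(1, max(0.5, best$beta + rnorm(1, 0, 0.5 / sqrt(ph$conc))))
          else runif(1, 0.5, 1)
        } else beta_fixed
        v <- objective(E, beta); n_eval <- n_eval + 1L
        if (v < best$value) best <- list(E = E, beta = beta, value = v)
      }
    }
  }

  if (method %in% c("both", "optim")) {
    n_e <- rmax + 1L - !is.null(fix_E0)
    n_par <- n_e + drive_free
    pen_obj <- function(par) {
      dec <- .tetrad_par_decode(par, rmax, drive_free, fix_E0)
      v <- objective(dec$E, if (drive_free) dec$beta else beta_fixed)
      if (!is.finite(v)) 1e10 else v
    }
    starts <- lapply(seq_len(n_starts), function(i) rnorm(n_par, 0, 2))
    if (!is.null(best$E)) {
      z <- log(pmax(if (!is.null(fix_E0))
        best$E[-1L] / max(1 - fix_E0, 1e-12) else best$E, 1e-12))
      t0 <- if (drive_free)
        stats::qlogis(min(max((best$beta - 0.5) / 0.5, 1e-6), 1 - 1e-6))
      starts[[1L]] <- c(z - mean(z), if (drive_free) t0)
    }
    for (st in starts) {
      opt <- tryCatch(
        optim(st, pen_obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(opt)) next
      n_eval <- n_eval + opt$counts[1L]
      dec <- .tetrad_par_decode(opt$par, rmax, drive_free, fix_E0)
      beta <- if (drive_free) dec$beta else beta_fixed
      v <- objective(dec$E, beta)
      if (v < best$value) best <- list(E = dec$E, beta = beta, value = v)
    }
  }
  if (is.null(best$E)) stop("optimisation failed (infeasible constraints?)")

  pred <- drop(.retention_matrix(rmax, best$beta) %*% best$E)
  cs <- .tetrad_chisq(counts, pred)
  n_free <- (rmax - !is.null(fix_E0)) + drive_free
  df <- (cs$n_cells - 1L) - n_free
  p <- if (df >= 1L) pchisq(cs$chi_square_pooled, df, lower.tail = FALSE)
       else NA_real_

  E <- best$E
  names(E) <- paste0("E", 0:rmax)
  dist <- structure(list(E = E, rmax = rmax, drive_beta = best$beta,
                         feasible = TRUE, method = "constrained_fit"),
                    class = "tetrad_dist")
  out <- list(distribution = dist, E = E, drive_beta = best$beta,
              chi_square = best$value, df = df, p_value = p,
              predicted_g = stats::setNames(pred, paste0("g", 0:rmax)),
              observed = counts, n = n, method = method,
              allow_drive = allow_drive, n_evaluations = n_eval)
  if (beta_profile && allow_drive) {
    grid <- seq(0.5, 1, by = 0.025)
    prof <- vapply(grid, function(b) {
      f <- tetrad_fit(counts, rmax = rmax, allow_drive = TRUE, fix_beta = b,
                      constraints = constraints, method = "optim",
                      n_starts = 5L, budget = 0L)
      c(f$chi_square, f$E[1L])
    }, numeric(2))
    out$beta_profile <- data.frame(beta = grid, chi_square = prof[1L, ],
                                   E0 = prof[2L, ])
  }
  class(out) <- "tetrad_fit"
  out
}

#' @export
print.tetrad_fit <- function(x, ...) {
  cat("Constrained Weinstein tetrad fit",
      if (x$allow_drive) " (MD_CO drive model)", "\n", sep = "")
  print(round(x$E, 4))
  if (x$allow_drive)
    cat(sprintf("drive beta: %.3f\n", x$drive_beta))
  cat(sprintf("chi-square: %.4g on %d df (p = %s), n = %d, %d evaluations\n",
              x$chi_square, x$df,
              if (is.na(x$p_value)) "NA" else format(signif(x$p_value, 3)),
              as.integer(x$n), x$n_evaluations))
  invisible(x)
}

#' @export
summary.tetrad_fit <- function(object, ...) {
  cmp <- data.frame(class = paste0(seq_along(object$observed) - 1L, "CO"),
                    observed = object$observed,
                    expected = object$n * object$predicted_g)
  out <- list(fit = object, comparison = cmp)
  class(out) <- "summary.tetrad_fit"
  out
}

#' @export
print.summary.tetrad_fit <- function(x, ...) {
  print(x$fit)
  cat("\nObserved vs predicted chromatid classes:\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.tetrad_fit <- function(object, ...) {
  if (object$allow_drive) c(object$E, beta = object$drive_beta) else object$E
}

#' @export
predict.tetrad_fit <- function(object, ...) object$predicted_g

#' Profile the zero-crossover tetrad frequency E0
#'
#' For each value of `E_0` on a grid, the remaining `E_{>0}` (restricted to
#' the simplex) are optimised and the chi-square fit recorded; the
#' resulting curve shows how strongly the data constrain the frequency of
#' tetrads with no crossover (crossover assurance).  Relative support is
#' the chi-square p-value normalised to the best grid point; where the
#' p-values underflow, the likelihood-ratio quantity
#' `exp(-(X2 - X2_min)/2)` is reported alongside.
#'
#' @inheritParams tetrad_fit
#' @param grid Numeric vector of `E_0` values in `[0, 1]`.
#' @return data.frame of class `"tetrad_profile"` with columns `E0`,
#'   `chi_square`, `p_value`, `rel_prob`, `rel_lik`.
#' @export
profile_E0 <- function(counts, grid, rmax = length(counts) - 1L,
                       allow_drive = FALSE, method = "both",
                       budget = 20000L, n_starts = 10L, seed = NULL) {
  if (!length(grid)) stop("empty E0 grid")
  if (any(grid < 0 | grid > 1)) stop("grid must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(grid, function(e0)
    tetrad_fit(counts, rmax = rmax, allow_drive = allow_drive, fix_E0 = e0,
               method = method, budget = budget, n_starts = n_starts))
  x2 <- vapply(res, `[[`, numeric(1), "chi_square")
  df <- vapply(res, `[[`, integer(1), "df")
  p <- ifelse(df >= 1L, pchisq(x2, pmax(df, 1L), lower.tail = FALSE), NA_real_)
  rel_p <- if (all(is.na(p)) || max(p, na.rm = TRUE) == 0) rep(NA_real_, length(p))
           else p / max(p, na.rm = TRUE)
  out <- data.frame(E0 = grid, chi_square = x2, p_value = p,
                    rel_prob = rel_p, rel_lik = exp(-(x2 - min(x2)) / 2))
  class(out) <- c("tetrad_profile", "data.frame")
  out
}

#' @export
plot.tetrad_profile <- function(x, ...) {
  y <- if (all(is.na(x$rel_prob))) x$rel_lik else x$rel_prob
  plot(x$E0, y, type = "b", xlab = expression(E[0]),
       ylab = "relative support", ...)
  invisible(x)
}
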