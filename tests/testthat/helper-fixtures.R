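# Shared fixture builders for the test suite.  All fixtures are generated
# in code; nothing is read from disk except files the tests write.

# A genotype track with evenly spaced SNPs and origins given per segment:
# segments = list(list(origin = "P1", n = 30), ...), spacing in bp.
make_track <- function(segments, spacing = 10000L, start = 1e6L,
                       individual = "f1", cross = "c1", arm = "2L") {
  origins <- unlist(lapply(segments, function(s) rep(s$origin, s$n)))
  pos <- start + spacing * (seq_along(origins) - 1L)
  genotype_table(individual, cross, arm, pos, origins)
}

# A callset built directly from per-chromatid crossover point lists:
# points = named list individual -> numeric vector of points.
make_callset <- function(points, arm = "X", cross = "c1",
                         span = c(1L, 30000000L), extra_chromatids = 0L) {
  chroms <- data.frame(
    individual = c(names(points),
                   if (extra_chromatids > 0)
                     sprintf("empty%03d", seq_len(extra_chromatids))),
    cross = cross, arm = arm, span_start = span[1L], span_end = span[2L],
    n_co = c(lengths(points), rep(0L, extra_chromatids)), flagged = FALSE,
    stringsAsFactors = FALSE)
  calls <- NULL
  nonzero <- names(points)[lengths(points) > 0]
  if (length(nonzero)) {
    calls <- do.call(rbind, lapply(nonzero, function(id) {
      pt <- as.integer(sort(points[[id]]))
      data.frame(individual = id, cross = cross, arm = arm,
                 left = pt - 1L, right = pt + 1L, point = pt,
                 index = seq_along(pt), stringsAsFactors = FALSE)
    }))
  }
  crossover_callset(calls = calls, chromatids = chroms)
}

# Crossover positions with minimum pairwise separation and edge margin,
# drawn uniformly by rejection (used for exact-recall caller fixtures).
draw_separated_points <- function(r, span, min_sep = 5e5, margin = 2.5e5) {
  if (r == 0L) return(numeric(0))
  repeat {
    p <- sort(runif(r, span[1L] + margin, span[2L] - margin))
    if (r == 1L || all(diff(p) >= min_sep)) return(p)
  }
}

# Independent grid-search maximiser of the gamma profile log-likelihood
# (scale profiled out analytically); oracle for fit_gamma_shape.
gamma_shape_grid_mle <- function(x, grid = seq(0.05, 60, by = 0.005)) {
  n <- length(x)
  loglik <- vapply(grid, function(a) {
    b <- mean(x) / a
    sum(stats::dgamma(x, shape = a, scale = b, log = TRUE))
  }, numeric(1))
  grid[which.max(loglik)]
}

# Exact-fraction helpers over a common integer denominator, for the
# rational-arithmetic forward/inverse tetrad identity.  A vector is
# represented as integer numerators plus one denominator.
frac_forward_g <- function(E_num, E_den) {
  # g_k = sum_r E_r * C(r, k) / 2^r ; common denominator E_den * 2^rmax
  rmax <- length(E_num) - 1L
  den <- E_den * 2^rmax
  g_num <- vapply(0:rmax, function(k) {
    sum(vapply(k:rmax, function(r)
      E_num[r + 1L] * choose(r, k) * 2^(rmax - r), numeric(1)))
  }, numeric(1))
  list(num = g_num, den = den)
}

frac_inverse_E <- function(g_num, g_den) {
  # E_r = 2^r * sum_{k>=r} (-1)^(k-r) C(k, r) g_k over denominator g_den
  kmax <- length(g_num) - 1L
  E_num <- vapply(0:kmax, function(r) {
    k <- r:kmax
    2^r * sum((-1)^(k - r) * choose(k, r) * g_num[k + 1L])
  }, numeric(1))
  list(num = E_num, den = g_den)
}
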