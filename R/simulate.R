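# Forward simulator of female meiosis: tetrad crossover placement with
# gamma-gap interference, chromatid segregation with optional meiosis-II
# drive, and diagnostic-SNP genotyping with miscall/missing noise.
# Interference is simulated at the tetrad level, where it acts
# biologically; the chromatid-level gamma shape observed downstream emerges
# from segregation and is numerically different from nu_sim.

# Piecewise-constant intensity profile helpers: profile is a list of
# parallel vectors (start, end, rate) in bp and cM/Mb; a scalar rate means
# flat intensity.  Pre-resolved once per arm so the per-meiosis path stays
# allocation-free.
.as_profile <- function(intensity, length_bp) {
  if (is.list(intensity) && !is.null(intensity$cum)) return(intensity)
  if (is.data.frame(intensity)) {
    stopifnot(all(c("start", "end", "rate") %in% names(intensity)))
    if (any(intensity$rate < 0)) stop("intensity must be non-negative")
    start <- as.numeric(intensity$start); end <- as.numeric(intensity$end)
    rate <- as.numeric(intensity$rate)
  } else {
    start <- 0; end <- as.numeric(length_bp); rate <- as.numeric(intensity)
  }
  w <- rate * (end - start)
  total <- sum(w)
  list(start = start, end = end, rate = rate, total = total,
       cum = if (total > 0) cumsum(w) / total else cumsum(w))
}

# Map u in [0,1] on the genetic-map scale to bp by the inverse CDF of the
# (pre-resolved) intensity profile.
.genetic_to_bp <- function(u, profile) {
  cw <- profile$cum
  lo <- c(0, cw[-length(cw)])
  seg <- findInterval(u, cw, left.open = TRUE) + 1L
  seg[seg > length(cw)] <- length(cw)
  frac <- (u - lo[seg]) / (cw[seg] - lo[seg])
  profile$start[seg] + frac * (profile$end[seg] - profile$start[seg])
}

#' Place the crossovers of one tetrad along an arm
#'
#' Crossover positions are drawn on the genetic-map scale `u` in `[0, 1]`
#' (the CDF of the intensity profile) and mapped back to bp by the inverse
#' CDF.  Positive interference is imposed by rejection sampling: a proposed
#' set of `r` iid uniforms is accepted with probability proportional to the
#' product of gamma densities of its `r + 1` gaps (shape `nu_sim`, scale
#' `1/(nu_sim * (r + 1))`), normalised by the configuration maximum (equal
#' gaps).  `nu_sim = 1` reduces to iid placement.  If no proposal is
#' accepted within `max_attempts`, the best-scoring proposal is used and a
#' diagnostic attribute `"fallback"` is set.
#'
#' @param r Number of crossovers (>= 0).
#' @param intensity Scalar rate or piecewise profile data.frame
#'   (`start`, `end`, `rate`).
#' @param nu_sim Tetrad-level interference shape (>= 1; 1 = none).
#' @param length_bp Arm length in bp (needed when `intensity` is scalar).
#' @param max_attempts Rejection-sampling cap (default 10000).
#' @return Sorted numeric vector of `r` positions (bp).
#' @export
place_tetrad_crossovers <- function(r, intensity, nu_sim = 1,
                                    length_bp = NULL, max_attempts = 10000L) {
  if (r < 0) stop("r must be non-negative")
  if (r == 0L) return(numeric(0))
  if (nu_sim < 1) stop("nu_sim must be >= 1")
  profile <- .as_profile(intensity, length_bp)
  if (profile$total <= 0)
    stop("zero intensity everywhere with r > 0")
  if (nu_sim == 1) {
    u <- sort(runif(r))
    return(sort(.genetic_to_bp(u, profile)))
  }
  scale <- 1 / (nu_sim * (r + 1))
  log_wmax <- sum(dgamma(rep(1 / (r + 1), r + 1L), shape = nu_sim,
                         scale = scale, log = TRUE))
  best_u <- NULL; best_lw <- -Inf; accepted <- FALSE
  for (att in seq_len(max_attempts)) {
    u <- sort(runif(r))
    gaps <- diff(c(0, u, 1))
    lw <- sum(dgamma(gaps, shape = nu_sim, scale = scale, log = TRUE))
    if (lw > best_lw) { best_lw <- lw; best_u <- u }
    if (log(runif(1)) < lw - log_wmax) { best_u <- u; accepted <- TRUE; break }
  }
  out <- sort(.genetic_to_bp(best_u, profile))
  if (!accepted) attr(out, "fallback") <- TRUE
  out
}

#' Segregate a tetrad into the retained meiotic product
#'
#' Each crossover is assigned to one of the two sister chromatids of the
#' retained homolog independently with probability 1/2 (meiosis I retains
#' either homolog pair with probability 1/2 and is symmetric).  At meiosis
#' II, when the sister crossover counts differ, the sister carrying more
#' crossovers is retained with probability `drive_beta` (the MD_CO drive;
#' 0.5 = unbiased).
#'
#' @param positions Crossover positions of the tetrad (bp).
#' @param drive_beta Retention bias in `[0.5, 1]`.
#' @return Numeric vector: the retained chromatid's crossover positions.
#' @export
segregate <- function(positions, drive_beta = 0.5) {
  if (drive_beta < 0.5 || drive_beta > 1) stop("drive_beta must be in [0.5, 1]")
  r <- length(positions)
  if (r == 0L) return(numeric(0))
  on_a <- runif(r) < 0.5
  n_a <- sum(on_a); n_b <- r - n_a
  take_a <- if (n_a == n_b) runif(1) < 0.5
            else if (n_a > n_b) runif(1) < drive_beta
            else runif(1) >= drive_beta
  sort(positions[if (take_a) on_a else !on_a])
}

#' Genotype a chromatid on a diagnostic-SNP panel
#'
#' The parent-of-origin alternates at each crossover point; each SNP is
#' independently miscalled (origin flipped) with probability
#' `miscall_rate` and set `MISSING` with probability `missing_rate`.
#'
#' @param co_positions Crossover positions on the chromatid (bp).
#' @param panel Sorted vector of diagnostic-SNP positions (bp, 1-based).
#' @param individual,cross,arm Identifiers for the resulting table.
#' @param miscall_rate,missing_rate Genotyping error rates in `[0, 1]`.
#' @param start_origin Origin of the most proximal segment: `"P1"`,
#'   `"P2"` or `"random"`.
#' @return A [genotype_table()].
#' @export
genotype_chromatid <- function(co_positions, panel, individual = "sim",
                               cross = "c1", arm = "X", miscall_rate = 0,
                               missing_rate = 0,
                               start_origin = c("random", "P1", "P2")) {
  start_origin <- match.arg(start_origin)
  if (start_origin == "random")
    start_origin <- if (runif(1) < 0.5) "P1" else "P2"
  panel <- sort(as.integer(round(panel)))
  n_below <- findInterval(panel, sort(co_positions))
  first <- match(start_origin, c("P1", "P2")) - 1L
  origin <- c("P1", "P2")[((n_below + first) %% 2L) + 1L]
  if (miscall_rate > 0) {
    flip <- runif(length(panel)) < miscall_rate
    origin[flip] <- ifelse(origin[flip] == "P1", "P2", "P1")
  }
  if (missing_rate > 0)
    origin[runif(length(panel)) < missing_rate] <- "MISSING"
  genotype_table(individual, cross, arm, panel, origin)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of a simulated F2 crossover study.
#' Defaults mirror a Drosophila-scale design: diagnostic-SNP density of one
#' SNP per 2 kb, no genotyping noise, no drive, no interference.
#'
#' @param arms Named list; each element a list with `length_bp` and
#'   `intensity` (scalar cM/Mb or a `start`/`end`/`rate` data.frame whose
#'   zero-rate segments encode centromere/telomere suppression).
#' @param E Tetrad crossover-class frequencies `E_0 ... E_rmax` (per arm if
#'   a list, else shared); must sum to 1.  Alternatively give
#'   `mean_co` to use a Poisson-derived class distribution.
#' @param mean_co Optional mean tetrad crossover count; used only when `E`
#'   is `NULL` (truncated Poisson at `rmax = 8`).
#' @param nu_sim Tetrad-level interference shape (>= 1).
#' @param drive_beta Meiosis-II retention bias in `[0.5, 1]`.
#' @param n_meioses Number of F2 individuals to simulate.
#' @param n_crosses Number of crosses; individuals are split evenly and
#'   each cross receives its own diagnostic-SNP panel.
#' @param snp_density SNPs per bp (default `1/2000`).
#' @param miscall_rate,missing_rate Genotyping error rates.
#' @param obligate_co If `TRUE`, resample tetrads drawn with `r = 0`
#'   (crossover assurance).
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(arms, E = NULL, mean_co = NULL, nu_sim = 1,
                       drive_beta = 0.5, n_meioses = 100L, n_crosses = 1L,
                       snp_density = 1 / 2000, miscall_rate = 0,
                       missing_rate = 0, obligate_co = FALSE) {
  if (is.null(names(arms)) || any(!nzchar(names(arms))))
    stop("arms must be a named list")
  for (a in names(arms)) {
    if (is.null(arms[[a]]$length_bp) || arms[[a]]$length_bp <= 0)
      stop("arm ", a, ": invalid length_bp")
    if (is.null(arms[[a]]$intensity)) stop("arm ", a, ": missing intensity")
  }
  if (is.null(E)) {
    if (is.null(mean_co)) stop("supply E or mean_co")
    E <- stats::dpois(0:8, mean_co)
    E <- E / sum(E)
  }
  check_E <- function(e) {
    if (any(e < 0) || abs(sum(e) - 1) > 1e-6)
      stop("E must be a probability vector summing to 1")
  }
  if (is.list(E)) lapply(E, check_E) else check_E(E)
  if (nu_sim < 1) stop("nu_sim must be >= 1")
  if (drive_beta < 0.5 || drive_beta > 1) stop("drive_beta must be in [0.5, 1]")
  if (snp_density <= 0) stop("snp_density must be positive")
  if (miscall_rate < 0 || miscall_rate > 1 || missing_rate < 0 ||
      missing_rate > 1) stop("rates must lie in [0, 1]")
  structure(list(arms = arms, E = E, nu_sim = nu_sim,
                 drive_beta = drive_beta, n_meioses = as.integer(n_meioses),
                 n_crosses = as.integer(n_crosses),
                 snp_density = snp_density, miscall_rate = miscall_rate,
                 missing_rate = missing_rate, obligate_co = obligate_co),
            class = "sim_config")
}

#' Simulate a full F2 crossover study
#'
#' For every meiosis and arm: draw the tetrad crossover count `r` from `E`,
#' place the `r` crossovers along the arm's intensity profile with
#' gamma-gap interference ([place_tetrad_crossovers()]), segregate one
#' chromatid into the meiotic product ([segregate()]), and genotype it on
#' the cross's diagnostic-SNP panel ([genotype_chromatid()]).  Ground truth
#' (per-tetrad `r`, per-chromatid retained crossover positions) is returned
#' for parameter-recovery testing.  Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default 1).
#' @param genotype If `FALSE`, skip diagnostic-SNP genotyping and return
#'   ground truth only (`tables = NULL`); much faster for recovery studies
#'   that work from true crossover positions.
#' @return List with `tables` (list of [genotype_table()], or `NULL`),
#'   `truth` (list `tetrads`: data.frame `individual`, `cross`, `arm`,
#'   `r`; `chromatids`: data.frame `individual`, `cross`, `arm`, `n_co`;
#'   `positions`: data.frame `individual`, `cross`, `arm`, `pos`) and
#'   `config`.
#' @export
simulate_study <- function(config, seed = 1L, genotype = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  arms <- names(config$arms)
  cross_of <- rep(paste0("c", seq_len(config$n_crosses)),
                  length.out = config$n_meioses)
  panels <- if (genotype) lapply(seq_len(config$n_crosses), function(k) {
    lapply(config$arms, function(a) {
      n_snp <- max(2L, round(a$length_bp * config$snp_density))
      sort(sample.int(a$length_bp, n_snp))
    })
  })
  n_rows <- config$n_meioses * length(arms)
  inds <- sprintf("f%05d", seq_len(config$n_meioses))
  profiles <- lapply(config$arms, function(a)
    .as_profile(a$intensity, a$length_bp))
  # tetrad crossover counts drawn vectorized, per arm
  r_draw <- matrix(0L, nrow = config$n_meioses, ncol = length(arms),
                   dimnames = list(NULL, arms))
  for (a in arms) {
    E <- if (is.list(config$E)) config$E[[a]] else config$E
    if (config$obligate_co) E <- c(0, E[-1L]) / sum(E[-1L])
    r_draw[, a] <- sample.int(length(E), config$n_meioses, replace = TRUE,
                              prob = E) - 1L
  }
  tables <- vector("list", n_rows)
  row_ind <- character(n_rows); row_cross <- character(n_rows)
  row_arm <- character(n_rows)
  row_r <- integer(n_rows); row_nco <- integer(n_rows)
  pos_list <- vector("list", n_rows)
  ti <- 0L
  for (m in seq_len(config$n_meioses)) {
    ind <- inds[m]
    cr <- cross_of[m]
    cr_idx <- (m - 1L) %% config$n_crosses + 1L
    for (a in arms) {
      ti <- ti + 1L
      r <- r_draw[m, a]
      tet <- place_tetrad_crossovers(r, profiles[[a]],
                                     nu_sim = config$nu_sim)
      kept <- segregate(tet, config$drive_beta)
      if (genotype)
        tables[[ti]] <- genotype_chromatid(
          kept, panels[[cr_idx]][[a]], individual = ind, cross = cr, arm = a,
          miscall_rate = config$miscall_rate,
          missing_rate = config$missing_rate)
      row_ind[ti] <- ind; row_cross[ti] <- cr; row_arm[ti] <- a
      row_r[ti] <- r; row_nco[ti] <- length(kept)
      if (length(kept)) pos_list[[ti]] <- kept
    }
  }
  if (genotype)
    names(tables) <- paste(row_ind, row_arm, sep = "/")
  n_pos <- lengths(pos_list)
  has <- n_pos > 0L
  positions <- data.frame(
    individual = rep(row_ind[has], n_pos[has]),
    cross = rep(row_cross[has], n_pos[has]),
    arm = rep(row_arm[has], n_pos[has]),
    pos = unlist(pos_list[has], use.names = FALSE),
    stringsAsFactors = FALSE)
  list(tables = if (genotype) tables else NULL,
       truth = list(
         tetrads = data.frame(individual = row_ind, cross = row_cross,
                              arm = row_arm, r = row_r,
                              stringsAsFactors = FALSE),
         chromatids = data.frame(individual = row_ind, cross = row_cross,
                                 arm = row_arm, n_co = row_nco,
                                 stringsAsFactors = FALSE),
         positions = positions),
       config = config)
}

#' Crossover call set from simulator ground truth
#'
#' Builds a [crossover_callset()] directly from the true retained crossover
#' positions of a simulated study, bypassing genotyping and block calling.
#' Useful for recovery studies of downstream statistics (interference,
#' suppression extents, tetrad fits) that should not be confounded by
#' caller behaviour.
#'
#' @param sim Result of [simulate_study()].
#' @return A [crossover_callset()] whose intervals are zero-width-adjacent
#'   (`left = pos - 1`, `right = pos + 1`) around the true points.
#' @export
truth_callset <- function(sim) {
  chr <- sim$truth$chromatids
  arms <- names(sim$config$arms)
  span <- do.call(rbind, lapply(arms, function(a) data.frame(
    arm = a, span_start = 1L,
    span_end = as.integer(sim$config$arms[[a]]$length_bp))))
  chromatids <- merge(chr, span, by = "arm")
  chromatids$flagged <- FALSE
  pos <- sim$truth$positions
  calls <- NULL
  if (!is.null(pos) && nrow(pos)) {
    pos <- pos[order(pos$arm, pos$individual, pos$pos), , drop = FALSE]
    pt <- as.integer(round(pos$pos))
    idx <- stats::ave(pt, paste(pos$individual, pos$arm),
                      FUN = seq_along)
    calls <- data.frame(individual = pos$individual, cross = pos$cross,
                        arm = pos$arm, left = pt - 1L, right = pt + 1L,
                        point = pt, index = as.integer(idx),
                        stringsAsFactors = FALSE)
  }
  crossover_callset(calls = calls,
                    chromatids = chromatids[, c("individual", "cross", "arm",
                                                "span_start", "span_end",
                                                "n_co", "flagged")])
}
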