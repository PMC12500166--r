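test_that("per-arm means, map lengths and the genome-wide sum are exact", {
  cnt <- dsantomea_class_counts()
  m <- mean_crossovers_per_product(cnt)
  expect_equal(m$per_arm[["X"]], 474 / 754)
  expect_equal(m$genome_wide, 490/783 + 169/288 + 556/783 + 599/756 + 474/754)
  expect_equal(round(m$genome_wide, 2), 3.34)
  expect_equal(m$map_cM, 100 * m$per_arm)

  none <- co_class_counts(rbind(X = c(20L, 0L, 0L)))
  expect_equal(mean_crossovers_per_product(none)$genome_wide, 0)
  expect_error(mean_crossovers_per_product(
    co_class_counts(rbind(X = c(0L, 0L)))), "zero")
})

test_that("event-class frequencies sum to one and match the worked example", {
  cnt <- dsantomea_class_counts()
  f <- class_frequencies(cnt, exclude_arms = "2R")
  expect_equal(sum(f$freq), 1)
  expect_equal(round(100 * f$freq[f$class == "NCO"], 1), 44.5)
  expect_equal(round(100 * f$freq[f$class == "multiCO"], 1), 11.8)
  expect_true(all(f$lower <= f$freq & f$freq <= f$upper))

  one <- co_class_counts(rbind(X = c(0L, 1L, 0L)))
  expect_equal(class_frequencies(one)$freq, c(0, 1, 0))
  expect_error(class_frequencies(cnt, exclude_arms = rownames(cnt)),
               "excluded")
})

test_that("window rates follow the cM/Mb definition", {
  # 10 crossovers among 100 chromatids of one cross, all in one 1-Mb window
  pts <- as.list(seq(1.05e6, 1.95e6, length.out = 10))
  names(pts) <- sprintf("f%02d", 1:10)
  cs <- make_callset(pts, span = c(1e6, 5e6), extra_chromatids = 90L)
  tr <- rate_track(cs, "X", arm_span = c(1e6, 5e6), window_bp = 1e6)
  expect_equal(tr$rate_cM_Mb[1L], 10)
  expect_equal(tr$rate_cM_Mb[-1L], rep(0, nrow(tr) - 1L))
  expect_error(rate_track(cs, "X", arm_span = c(1e6, 1.5e6)), "window")
})

test_that("non-overlapping window rates integrate to the map length", {
  set.seed(8)
  pts <- lapply(1:60, function(i) {
    k <- sample(0:3, 1)
    if (k == 0) numeric(0) else sort(runif(k, 1e6, 2.1e7))
  })
  names(pts) <- sprintf("f%02d", 1:60)
  cs <- make_callset(pts, span = c(1e6, 2.1e7))
  tr <- rate_track(cs, "X", arm_span = c(1e6, 2.1e7), window_bp = 1e6)
  map_from_track <- sum(tr$rate_cM_Mb * (tr$end - tr$start) / 1e6)
  cc <- classify_chromatids(cs)
  map_cM <- mean_crossovers_per_product(cc)$map_cM[["X"]]
  expect_equal(map_from_track, map_cM, tolerance = 1e-10)
})

test_that("windowed track mean recovers a flat simulated intensity", {
  # flat 2.5 cM/Mb: mean crossovers per chromatid over 20 Mb = 0.5
  set.seed(14)
  n <- 5000L
  cfg <- sim_config(arms = list(`2L` = list(length_bp = 2e7, intensity = 2.5)),
                    E = c(0, 1), n_meioses = n)
  sim <- simulate_study(cfg, seed = 14, genotype = FALSE)
  cs <- truth_callset(sim)
  tr <- rate_track(cs, "2L", arm_span = c(1, 2e7), window_bp = 1e6)
  # each tetrad has 1 CO retained with p = 1/2: chromatid rate 2.5 cM/Mb
  p <- 0.5 / 20  # per-chromatid probability of a CO in a given 1-Mb window
  se <- 100 * sqrt(p * (1 - p) / n)
  expect_lt(max(abs(tr$rate_cM_Mb - 2.5)), 3.5 * se)
  expect_equal(abs(mean(tr$rate_cM_Mb) - 2.5) < 3 * se / sqrt(nrow(tr) / 3),
               TRUE)
})

test_that("the X/A rate ratio reproduces both published examples", {
  expect_equal(round(xa_ratio(2.57, 2.71), 2), 1.05)
  expect_equal(round(xa_ratio(2.41, 4.07), 2), 1.69)
  expect_equal(xa_ratio(3, 3), 1)
  expect_error(xa_ratio(0, 2), "positive")
  rates <- dsantomea_arm_rates()
  expect_equal(round(xa_ratio(rates$rate_cM_Mb[rates$arm == "autosomes"],
                              rates$rate_cM_Mb[rates$arm == "X"]), 2), 1.05)
})

test_that("interchromosomal ANOVA matches the closed-form F distribution", {
  # identical group means: F = 0, p = 1
  y <- c(a1 = 2, a2 = 3, a3 = 4, b1 = 2, b2 = 3, b3 = 4)
  g <- c(a1 = "INV_HET", a2 = "INV_HET", a3 = "INV_HET",
         b1 = "STANDARD", b2 = "STANDARD", b3 = "STANDARD")
  r0 <- interchromosomal_test(y, g)
  expect_equal(r0$F_statistic, 0)
  expect_equal(r0$p_value, 1)

  # construct an 8-cross design (5 vs 3) tuned to F(1, 6) = 2.10
  base <- c(2.8, 3.0, 3.2, 3.1, 2.9, 2.7, 3.0, 3.3)
  grp <- rep(c("INV_HET", "STANDARD"), c(5, 3))
  names(base) <- names(grp) <- sprintf("c%d", 1:8)
  f_of <- function(d) {
    y <- base + ifelse(grp == "INV_HET", d, 0)
    interchromosomal_test(y, grp)$F_statistic - 2.10
  }
  d <- uniroot(f_of, c(0, 2), tol = 1e-12)$root
  r <- interchromosomal_test(base + ifelse(grp == "INV_HET", d, 0), grp)
  expect_equal(r$F_statistic, 2.10, tolerance = 1e-6)
  expect_equal(r$df, c(1, 6))
  expect_equal(r$p_value, pf(2.10, 1, 6, lower.tail = FALSE), tolerance = 1e-4)
  expect_equal(round(r$p_value, 2), 0.20)

  # label swap leaves F invariant
  swapped <- ifelse(grp == "INV_HET", "STANDARD", "INV_HET")
  names(swapped) <- names(grp)
  r2 <- interchromosomal_test(base + ifelse(grp == "INV_HET", d, 0), swapped)
  expect_equal(r2$F_statistic, r$F_statistic)

  expect_error(interchromosomal_test(y[1:4], g[c(1, 2, 3, 4)]), "2 crosses")
})

test_that("multiscale Spearman correlation behaves at the limits", {
  mk <- function(rates) {
    tr <- data.frame(start = seq(0, by = 1e5, length.out = length(rates)),
                     end = seq(1e5, by = 1e5, length.out = length(rates)),
                     rate_cM_Mb = rates, rate_min = NA, rate_max = NA,
                     n_crosses = 1L)
    attr(tr, "arm") <- "X"; attr(tr, "scheme") <- "NON_OVERLAPPING"
    class(tr) <- c("rate_track", "data.frame")
    tr
  }
  grad <- mk(seq(1, 5, length.out = 40))
  same <- multiscale_spearman(grad, grad, scales = c(1e5, 5e5, 1e6))
  expect_equal(same$rho, rep(1, 3))
  rev_tr <- mk(rev(seq(1, 5, length.out = 40)))
  anti <- multiscale_spearman(grad, rev_tr, scales = c(1e5, 5e5))
  expect_equal(anti$rho, rep(-1, 2))
  # fewer than 3 shared bins: undefined
  tiny <- multiscale_spearman(mk(1:3), mk(3:1), scales = 4e5)
  expect_true(is.na(tiny$rho))
})

test_that("landscape correlation is stronger at broad than at fine scales", {
  set.seed(99)
  mk <- function(shared, noise_sd) {
    rates <- pmax(0, shared + rnorm(length(shared), 0, noise_sd))
    tr <- data.frame(start = seq(0, by = 1e5, length.out = length(rates)),
                     end = seq(1e5, by = 1e5, length.out = length(rates)),
                     rate_cM_Mb = rates, rate_min = NA, rate_max = NA,
                     n_crosses = 1L)
    attr(tr, "arm") <- "X"; attr(tr, "scheme") <- "NON_OVERLAPPING"
    class(tr) <- c("rate_track", "data.frame")
    tr
  }
  # shared 1-Mb-scale signal + independent 100-kb noise in each track
  diffs <- replicate(30, {
    shared <- rep(runif(20, 0.5, 5), each = 10)
    a <- mk(shared, 1.5); b <- mk(shared, 1.5)
    r <- multiscale_spearman(a, b, scales = c(1e5, 1e6))
    diff(r$rho)  # rho(1 Mb) - rho(100 kb)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})
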