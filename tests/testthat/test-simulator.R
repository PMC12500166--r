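test_that("tetrad crossover placement honours r and the intensity profile", {
  expect_length(place_tetrad_crossovers(0, 2.5, length_bp = 1e7), 0L)
  expect_error(place_tetrad_crossovers(2, 0, length_bp = 1e7), "zero intensity")

  set.seed(2)
  # nu = 1, flat intensity: the gap of an r = 2 tetrad is |U1 - U2|,
  # with CDF F(d) = 1 - (1 - d)^2 on the unit (genetic = physical) scale
  gaps <- replicate(4000, diff(place_tetrad_crossovers(2, 1, length_bp = 1e6)))
  ks <- suppressWarnings(
    ks.test(gaps / 1e6, function(q) 1 - (1 - q)^2))
  expect_gt(ks$p.value, 0.01)

  # positive interference regularises spacing: the mean of the middle gap
  # is 1/3 at any nu (the three gaps are exchangeable), but its dispersion
  # shrinks and close double crossovers are suppressed
  set.seed(3)
  gaps10 <- replicate(2000,
    diff(place_tetrad_crossovers(2, 1, nu_sim = 10, length_bp = 1e6)))
  expect_lt(abs(mean(gaps10) - 1e6 / 3), 2e4)
  expect_lt(sd(gaps10), 0.5 * sd(gaps))
  expect_gt(quantile(gaps10, 0.05), quantile(gaps, 0.05))

  # zero-intensity segments receive no crossovers
  profile <- data.frame(start = c(0, 5e6), end = c(5e6, 2e7),
                        rate = c(0, 2.5))
  pts <- place_tetrad_crossovers(500, profile)
  expect_true(all(pts >= 5e6))
})

test_that("segregation reproduces Binomial(r, 1/2) without drive", {
  set.seed(5)
  pos <- c(1e6, 5e6, 9e6)
  counts <- table(factor(replicate(30000, length(segregate(pos, 0.5))),
                         levels = 0:3))
  expected <- 30000 * dbinom(0:3, 3, 0.5)
  chi <- sum((as.integer(counts) - expected)^2 / expected)
  expect_lt(chi, qchisq(0.999, df = 3))

  # full drive with one crossover: the CO chromatid is always retained
  expect_true(all(replicate(200, length(segregate(5e6, 1))) == 1L))
  expect_error(segregate(pos, 0.4), "0.5")
})

test_that("simulated gamete classes match the analytic drive model", {
  # the simulator's segregate() and the closed-form predict_gamete_classes
  # are independent implementations of the same MD_CO model
  E <- c(0.2, 0.45, 0.25, 0.1)
  beta <- 0.8
  n <- 30000L
  set.seed(6)
  r_draw <- sample(0:3, n, replace = TRUE, prob = E)
  k_obs <- vapply(r_draw, function(r)
    length(segregate(seq_len(max(r, 1))[seq_len(r)] * 1e6, beta)), integer(1))
  emp <- tabulate(k_obs + 1L, nbins = 4L) / n
  g <- predict_gamete_classes(E, drive_beta = beta)
  se <- sqrt(g * (1 - g) / n)
  expect_true(all(abs(emp - g) < 3.5 * se + 1e-9))
})

test_that("genotyping encodes crossovers as origin switches", {
  panel <- seq(1000, 2e6, by = 2000)
  gt <- genotype_chromatid(1e6, panel, start_origin = "P1")
  flips <- which(gt$origin[-1L] != gt$origin[-length(gt$origin)])
  expect_length(flips, 1L)
  expect_lt(abs(gt$pos[flips] - 1e6), 2001)
  expect_equal(gt$origin[1L], "P1")

  # miscalls are rare and isolated at realistic rates
  set.seed(7)
  gt2 <- genotype_chromatid(numeric(0), panel, miscall_rate = 0.001,
                            start_origin = "P1")
  expect_lt(sum(gt2$origin == "P2"), 10)
  r <- rle(gt2$origin)
  expect_lt(max(r$lengths[r$values == "P2"], 0), 3)

  gt3 <- genotype_chromatid(numeric(0), panel, missing_rate = 0.5,
                            start_origin = "P1")
  expect_gt(sum(gt3$origin == "MISSING"), 0)
})

test_that("simulated studies are deterministic and internally consistent", {
  cfg <- sim_config(arms = list(X = list(length_bp = 1.5e7, intensity = 3),
                                `2L` = list(length_bp = 2e7, intensity = 2)),
                    E = c(0.2, 0.5, 0.3), n_meioses = 60, n_crosses = 2)
  a <- simulate_study(cfg, seed = 99)
  b <- simulate_study(cfg, seed = 99)
  expect_identical(a$truth, b$truth)
  expect_identical(a$tables, b$tables)
  c2 <- simulate_study(cfg, seed = 100)
  expect_false(identical(a$truth$positions, c2$truth$positions))

  # truth bookkeeping: retained counts never exceed tetrad counts
  m <- merge(a$truth$tetrads, a$truth$chromatids,
             by = c("individual", "arm"))
  expect_true(all(m$n_co <= m$r))
  # mean retained crossovers per product = sum(r E_r) / 2 without drive
  big <- simulate_study(
    sim_config(arms = list(X = list(length_bp = 1.5e7, intensity = 3)),
               E = c(0.2, 0.5, 0.3), n_meioses = 8000),
    seed = 101, genotype = FALSE)
  target <- sum((0:2) * c(0.2, 0.5, 0.3)) / 2
  se <- sd(big$truth$chromatids$n_co) / sqrt(8000)
  expect_lt(abs(mean(big$truth$chromatids$n_co) - target), 3 * se)
  expect_lt(abs(mean(big$truth$tetrads$r) - 2 * target),
            3 * sd(big$truth$tetrads$r) / sqrt(8000))
})

test_that("obligate crossover assurance removes zero-CO tetrads", {
  cfg <- sim_config(arms = list(X = list(length_bp = 1.5e7, intensity = 3)),
                    E = c(0.5, 0.3, 0.2), n_meioses = 500,
                    obligate_co = TRUE)
  sim <- simulate_study(cfg, seed = 8, genotype = FALSE)
  expect_true(all(sim$truth$tetrads$r > 0))
})

test_that("zero-noise simulation round-trips through the caller exactly", {
  # SNP density 1/2 kb, crossovers >= 500 kb apart and >= 250 kb from span
  # edges: calling must recover every chromatid's crossover count
  set.seed(15)
  span <- c(1, 2.2e7)
  tracks <- list(); truth_n <- integer(0)
  for (i in 1:40) {
    r <- (i - 1L) %% 4L
    pts <- draw_separated_points(r, span)
    tracks[[i]] <- genotype_chromatid(
      pts, panel = seq(span[1L], span[2L], by = 2000),
      individual = sprintf("f%03d", i), arm = "X")
    truth_n[i] <- r
  }
  cs <- call_genotype_tables(tracks)
  got <- cs$chromatids$n_co[order(cs$chromatids$individual)]
  expect_identical(got, truth_n)
})

test_that("invalid configurations are rejected before any sampling", {
  arms <- list(X = list(length_bp = 1e7, intensity = 2))
  expect_error(sim_config(arms, E = c(0.5, 0.4)), "sum")
  expect_error(sim_config(arms, E = c(0.5, 0.5), nu_sim = 0.5), "nu_sim")
  expect_error(sim_config(arms, E = c(0.5, 0.5), drive_beta = 0.2), "drive")
  expect_error(sim_config(arms, E = c(0.5, 0.5), miscall_rate = 2), "rates")
  expect_error(sim_config(list(list(length_bp = 1e7, intensity = 2)),
                          E = c(1)), "named")
  # mean_co fallback builds a valid truncated Poisson E
  cfg <- sim_config(arms, mean_co = 1.4)
  expect_equal(sum(cfg$E), 1)
})
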