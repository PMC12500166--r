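test_that("runs failing block thresholds are absorbed, not call-generating", {
  # 30 P1 SNPs over 300 kb, 24 P2 SNPs over 300 kb, 30 P1 SNPs: the P2 run
  # fails the 25-SNP minimum, so a single merged P1 block remains
  # spacing chosen so the 24-SNP run spans ~300 kb: it fails only min_snps
  tr <- make_track(list(list(origin = "P1", n = 30),
                        list(origin = "P2", n = 24),
                        list(origin = "P1", n = 30)), spacing = 13000L)
  b <- detect_blocks(tr)
  expect_equal(nrow(b), 1L)
  expect_equal(b$origin, "P1")
  expect_equal(b$n_snps, 60L)
  expect_equal(nrow(call_crossovers(b)), 0L)

  # homogeneous track: exactly one block
  b2 <- detect_blocks(make_track(list(list(origin = "P1", n = 1000))))
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$n_snps, 1000L)
})

test_that("a 25-SNP run spanning one bp short of the minimum is rejected", {
  # the middle run spans 249,999 bp < 250,000 despite having 25 SNPs
  pos <- c(seq(1e6, by = 10000, length.out = 30),
           seq(2e6, by = 249999 / 24, length.out = 25),
           seq(3e6, by = 10000, length.out = 30))
  ori <- rep(c("P1", "P2", "P1"), c(30, 25, 30))
  gt <- genotype_table("f1", "c1", "3R", round(pos), ori)
  b <- detect_blocks(gt)
  expect_equal(nrow(b), 1L)
  expect_equal(b$origin, "P1")
  # one more bp of span and it is a valid block, giving 2 crossovers
  pos2 <- pos; pos2[31:55] <- round(seq(2e6, by = 250000 / 24, length.out = 25))
  gt2 <- genotype_table("f1", "c1", "3R", round(pos2), ori)
  expect_equal(nrow(detect_blocks(gt2)), 3L)
})

test_that("missing calls do not break origin runs", {
  tr <- make_track(list(list(origin = "P1", n = 15),
                        list(origin = "MISSING", n = 5),
                        list(origin = "P1", n = 15),
                        list(origin = "P2", n = 30)))
  b <- detect_blocks(tr)
  expect_equal(b$origin, c("P1", "P2"))
  expect_equal(b$n_snps[1L], 30L)
})

test_that("crossover calls take the block-gap interval and floored midpoint", {
  blocks <- data.frame(origin = c("P1", "P2"),
                       first_pos = c(100000L, 1300000L),
                       last_pos = c(1000000L, 2000000L),
                       n_snps = c(100L, 100L))
  calls <- call_crossovers(blocks)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$left, 1000000L)
  expect_equal(calls$right, 1300000L)
  expect_equal(calls$point, 1150000L)
})

test_that("close double switches are dropped and flagged; distant ones kept", {
  mk_blocks <- function(gap) {
    # P1, P2, P1 with switch midpoints 'gap' apart
    data.frame(origin = c("P1", "P2", "P1"),
               first_pos = c(1e6, 3e6, 3e6 + gap),
               last_pos = c(3e6 - 2e4, 3e6 + gap - 2e4, 8e6),
               n_snps = 200L)
  }
  far <- call_crossovers(mk_blocks(600000))
  expect_equal(nrow(far), 2L)
  expect_false(attr(far, "flagged"))
  expect_true(diff(far$point) >= 250000)

  near <- call_crossovers(mk_blocks(200000))
  expect_equal(nrow(near), 0L)
  expect_true(attr(near, "flagged"))
  # merge mode also removes both but does not flag
  nearm <- call_crossovers(mk_blocks(200000), close_mode = "merge")
  expect_equal(nrow(nearm), 0L)
  expect_false(attr(nearm, "flagged"))

  expect_error(call_crossovers(
    data.frame(origin = c("P1", "P1"), first_pos = c(1, 10),
               last_pos = c(5, 20), n_snps = 30L)), "identical origin")
})

test_that("chromatid classification matches a brute-force tally", {
  set.seed(5)
  n_chr <- 50L
  pts <- lapply(seq_len(n_chr), function(i) {
    k <- sample(0:5, 1)
    if (k == 0) numeric(0) else sort(sample.int(3e7, k)) * 1.0
  })
  names(pts) <- sprintf("f%02d", seq_len(n_chr))
  cs <- make_callset(pts)
  cc <- classify_chromatids(cs, kmax = 4L)
  brute <- table(factor(pmin(lengths(pts), 4L), levels = 0:4))
  expect_equal(as.integer(cc["X", ]), as.integer(brute))
  expect_equal(sum(cc), n_chr)

  # all-zero case
  cs0 <- make_callset(list(), extra_chromatids = 10L)
  expect_equal(as.integer(classify_chromatids(cs0)["X", ]),
               c(10L, 0L, 0L, 0L, 0L))
})

test_that("the caller is order-independent across individuals", {
  set.seed(21)
  tracks <- lapply(1:6, function(i) {
    segs <- list(list(origin = "P1", n = 40), list(origin = "P2", n = 40),
                 list(origin = "P1", n = 40))
    make_track(segs[seq_len(sample(2:3, 1))], individual = sprintf("f%d", i))
  })
  a <- call_genotype_tables(tracks)
  b <- call_genotype_tables(rev(tracks))
  expect_equal(a$calls, b$calls)
  expect_equal(a$chromatids[order(a$chromatids$individual), ],
               b$chromatids[order(b$chromatids$individual), ],
               ignore_attr = TRUE)
})

test_that("raising thresholds never increases the number of calls", {
  set.seed(33)
  for (rep in 1:5) {
    # noisy random track
    n <- 400L
    pos <- sort(sample.int(2e7, n))
    ori <- rep(c("P1", "P2"), length.out = n)
    blocky <- sample(c("P1", "P2"), n, replace = TRUE, prob = c(0.7, 0.3))
    ori <- ifelse(runif(n) < 0.5, blocky,
                  rep(c("P1", "P2"), each = 100, length.out = n))
    gt <- genotype_table("f1", "c1", "2R", pos, ori)
    base <- nrow(call_crossovers(detect_blocks(gt, 10, 100000), 100000))
    for (ms in c(15, 25)) for (sp in c(150000, 250000)) {
      stricter <- nrow(call_crossovers(detect_blocks(gt, ms, sp),
                                       max(100000, sp)))
      expect_lte(stricter, base)
    }
  }
})

test_that("dot-chromosome tracks use the relaxed block requirement", {
  # 6-SNP blocks: valid on arm 4 (threshold 4), not on a major arm
  segs <- list(list(origin = "P1", n = 6), list(origin = "P2", n = 6))
  dot <- make_track(segs, spacing = 60000L, arm = "4")
  major <- make_track(segs, spacing = 60000L, arm = "2L")
  cs <- call_genotype_tables(list(dot, major))
  expect_equal(cs$chromatids$n_co[cs$chromatids$arm == "4"], 1L)
  expect_equal(cs$chromatids$n_co[cs$chromatids$arm == "2L"], 0L)
})
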