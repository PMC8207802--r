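# Windowed pi, Hudson FST, LSBL, sweep calling and the permutation contrast.

test_that("windowed pi matches the worked example and the pair oracle", {
  # n = 4 alleles, 10-bp window, sites with derived counts 1 and 2
  w <- windowed_pi(pos = c(2L, 7L), derived = c(1L, 2L), called = c(4L, 4L),
                   contig_length = 10L, window = 10L, step = 10L)
  expect_equal(w$pi, (2 * 1 * 3 / 12 + 2 * 2 * 2 / 12) / 10)
  # monomorphic window -> 0
  w0 <- windowed_pi(integer(), integer(), integer(), 10L, 10L, 10L)
  expect_equal(w0$pi, 0)
  # brute force: mean pairwise differences across phased haplotypes
  set.seed(12)
  H <- matrix(rbinom(40 * 8, 1, 0.3), ncol = 8)
  pos <- sort(sample(0:999, 40))
  seg <- rowSums(H) > 0 & rowSums(H) < 8
  a <- rowSums(H)
  w1 <- windowed_pi(pos, a, rep(8L, 40), 1000L, 1000L, 1000L)
  pairs <- utils::combn(8, 2)
  brute <- mean(apply(pairs, 2, function(pr) sum(H[, pr[1]] != H[, pr[2]])))
  expect_equal(w1$pi * 1000, brute, tolerance = 1e-12)
})

test_that("window tiling follows the 50 kb / 25 kb convention", {
  w <- windowed_pi(integer(), integer(), integer(), contig_length = 100000L,
                   window = 50000L, step = 25000L)
  expect_equal(w$start, c(0L, 25000L, 50000L))
  expect_error(windowed_pi(integer(), integer(), integer(), 1e5, 1000L, 2000L),
               "window >= step")
})

test_that("Hudson site FST matches the plug-in example and boundaries", {
  # p1 = 0.8 (n = 10), p2 = 0.2 (n = 10)
  comp <- site_fst(8L, 10L, 2L, 10L)
  expect_equal(comp$num, 0.36 - 0.16 / 9 - 0.16 / 9)
  expect_equal(comp$den, 0.68)
  expect_equal(comp$num / comp$den, 0.4771242, tolerance = 1e-6)
  # fixed difference -> FST 1
  fx <- site_fst(10L, 10L, 0L, 10L)
  expect_equal(fx$num / fx$den, 1)
  # equal frequencies -> numerator <= 0, window clamps to 0
  eq <- site_fst(5L, 10L, 5L, 10L)
  expect_lte(eq$num, 0)
  w <- windowed_fst(0L, 5L, 10L, 5L, 10L, 10L, 10L, 10L)
  expect_equal(w$fst, 0)
  expect_error(site_fst(1L, 1L, 1L, 2L), ">= 2")
})

test_that("window FST of a population against itself is 0 and symmetric", {
  set.seed(3)
  pos <- sort(sample(0:9999, 50))
  d1 <- rbinom(50, 10, 0.4); d2 <- rbinom(50, 12, 0.2)
  self <- windowed_fst(pos, d1, rep(10L, 50), d1, rep(10L, 50), 10000L,
                       10000L, 10000L)
  expect_equal(self$fst, 0)
  ab <- windowed_fst(pos, d1, rep(10L, 50), d2, rep(12L, 50), 10000L,
                     10000L, 10000L)
  ba <- windowed_fst(pos, d2, rep(12L, 50), d1, rep(10L, 50), 10000L,
                     10000L, 10000L)
  expect_equal(ab$fst, ba$fst)
})

test_that("LSBL follows its closed form with clamping", {
  expect_equal(lsbl(0.3, 0.3, 0.3), 0.15)
  expect_equal(lsbl(0.3, 0.4, 0.5), 0.1)
  expect_equal(lsbl(0.1, 0.1, 0.5), 0)       # clamped from -0.15
  expect_error(lsbl(1.2, 0, 0), "\\[0, 1\\]")
})

test_that("sweep calling thresholds and merges windows", {
  win <- data.frame(start = seq(0L, 9000L, 1000L),
                    end = seq(1000L, 10000L, 1000L),
                    lsbl_domestic = seq(0.01, 0.10, 0.01))
  sw <- call_sweeps(win, "lsbl_domestic", 0.9)
  # sort-and-threshold oracle: quantile 0.9 keeps the top two windows here
  thr <- quantile(win$lsbl_domestic, 0.9, names = FALSE)
  expect_equal(nrow(sw$regions), 1)          # adjacent windows merge
  expect_equal(sw$regions$start,
               min(win$start[win$lsbl_domestic >= thr]))
  # quantile 0 selects everything (one merged region)
  sw0 <- call_sweeps(win, "lsbl_domestic", 0)
  expect_equal(sw0$regions, data.frame(start = 0L, end = 10000L))
  expect_error(call_sweeps(win[1:5, ], "lsbl_domestic"), ">= 10")
  win$lsbl_domestic <- NA
  expect_error(call_sweeps(win, "lsbl_domestic"), "missing")
})

test_that("sweep contrast separates enriched from empty regions", {
  sweeps <- structure(list(
    regions = data.frame(start = 0L, end = 1000L),
    threshold = 1, statistic = "lsbl_domestic", quantile = 0.99),
    class = "dc_sweepset")
  # all hSNPs outside the sweep
  out <- sweep_load_contrast(sweeps, hsnp_pos = c(5000L, 6000L, 7000L),
                             contig_length = 100000L, n_perm = 200L, seed = 2)
  expect_equal(out$density_inside_per_mb, 0)
  expect_gt(out$density_outside_per_mb, 0)
  # 100-window toy with all 5 hSNPs inside the single sweep window
  out2 <- sweep_load_contrast(sweeps,
                              hsnp_pos = c(100L, 300L, 500L, 700L, 900L),
                              contig_length = 100000L, n_perm = 1000L,
                              seed = 3)
  expect_lte(out2$p_density, 0.05)
  # sweep covering the whole contig is degenerate
  all_sw <- structure(list(
    regions = data.frame(start = 0L, end = 1000L), threshold = 1,
    statistic = "s", quantile = 0.5), class = "dc_sweepset")
  expect_warning(
    out3 <- sweep_load_contrast(all_sw, hsnp_pos = c(10L, 500L),
                                contig_length = 1000L, n_perm = 10L),
    "degenerate")
  expect_equal(out3$p_density, 1)
  expect_true(out3$degenerate)
  empty <- structure(list(regions = data.frame(start = integer(),
                                               end = integer())),
                     class = "dc_sweepset")
  expect_error(sweep_load_contrast(empty, 1L, NULL, 100L), "empty")
})
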