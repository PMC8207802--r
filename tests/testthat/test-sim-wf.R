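# Wright-Fisher simulator: neutral expectations, determinism, rescaling
# equivalence and the neutral SFS shape.

test_that("no mutation means no variation", {
  cfg <- neutral_config(2)
  cfg$mu <- 0
  sim <- simulate_two_population(cfg)
  expect_equal(nrow(sim$sites), 0)
})

test_that("identical seeds give byte-identical datasets", {
  s1 <- simulate_two_population(neutral_config(7, N = 60L, L = 20000L))
  s2 <- simulate_two_population(neutral_config(7, N = 60L, L = 20000L))
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$haplotypes, s2$haplotypes)
  s3 <- simulate_two_population(neutral_config(8, N = 60L, L = 20000L))
  expect_false(identical(s1$sites, s3$sites))
})

test_that("neutral diversity and segregating sites match closed forms", {
  # E[pi] = theta = 0.002; E[S] = theta * L * a_{n-1}; 100 replicates
  reps <- 100
  res <- vapply(seq_len(reps), function(i) {
    sim <- simulate_two_population(neutral_config(1000 + i, L = 30000L))
    c(pi = sample_pi(sim), S = nrow(sim$sites))
  }, c(pi = 0, S = 0))
  se_pi <- sd(res["pi", ]) / sqrt(reps)
  expect_lt(abs(mean(res["pi", ]) - 0.002), 3 * se_pi)
  exp_S <- 0.002 * 30000 * sum(1 / (1:19))
  se_S <- sd(res["S", ]) / sqrt(reps)
  expect_lt(abs(mean(res["S", ]) - exp_S), 3 * se_S)
})

test_that("rescaled runs reproduce the unscaled diversity", {
  base <- function(seed) neutral_config(seed, N = 120L, L = 15000L,
                                        theta = 0.002, burnin_factor = 10)
  reps <- 60
  pi1 <- vapply(seq_len(reps), function(i)
    sample_pi(simulate_two_population(base(2000 + i))), 0)
  pi5 <- vapply(seq_len(reps), function(i)
    sample_pi(simulate_two_population(rescale(base(4000 + i), 5))), 0)
  se <- sqrt(var(pi1) / reps + var(pi5) / reps)
  expect_lt(abs(mean(pi1) - mean(pi5)), 3 * se)
})

test_that("neutral site frequency spectrum is proportional to 1/i", {
  # chi-square against the theta/i expectation over 200 replicates; sites
  # within a replicate share one genealogy, so each class's variance is
  # estimated across replicates rather than assumed multinomial
  reps <- 200
  n <- 20
  percls <- matrix(0, reps, n - 1)
  for (i in seq_len(reps)) {
    sim <- simulate_two_population(
      neutral_config(6000 + i, N = 80L, L = 15000L, theta = 0.002,
                     burnin_factor = 10))
    if (nrow(sim$sites) == 0) next
    percls[i, ] <- tabulate(rowSums(sim$haplotypes), nbins = n - 1)
  }
  exp_k <- 0.002 * 15000 / (1:(n - 1))
  z <- (colMeans(percls) - exp_k) / (apply(percls, 2, sd) / sqrt(reps))
  X2 <- sum(z^2)
  expect_gt(pchisq(X2, df = n - 1, lower.tail = FALSE), 0.01)
})

test_that("extinct or inconsistent demography is rejected", {
  dem <- demography_truth(100, 0, NULL, NULL)
  cfg <- simulation_config(demography = dem, coding_fraction = 0,
                           sample_sizes = c(wild = 2L, domestic = 0L),
                           seed = 1)
  cfg$demography$N_anc <- 1
  expect_error(simulate_two_population(cfg), "extinct|size")
})

test_that("deleterious mutations carry positive cost and classes match truth", {
  cfg <- rescale(simulation_config(contig_length_bp = 2e5, seed = 31), 2000)
  sim <- simulate_two_population(cfg)
  expect_true(all(sim$sites$s[sim$sites$class %in%
                                c("noncoding", "synonymous")] == 0))
  sel <- sim$sites$class %in% c("missense", "nonsense")
  if (any(sel)) expect_true(all(sim$sites$s[sel] > 0))
  # positions strictly increasing and segregating in the union sample
  expect_true(all(diff(sim$sites$pos) > 0))
  a <- rowSums(sim$haplotypes)
  expect_true(all(a > 0 & a < ncol(sim$haplotypes)))
})
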