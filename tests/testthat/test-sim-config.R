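# Configuration, demography epochs and rescaling invariants.

test_that("rescaling preserves theta, N*s, N*m and t/N and Q=1 is identity", {
  cfg <- simulation_config(seed = 3)
  expect_identical(rescale(cfg, 1), cfg)

  q <- 100
  r <- rescale(cfg, q)
  expect_equal(r$rescale_Q, 100)
  # theta = 4*N*mu invariant
  expect_equal(4 * r$demography$N_anc * r$mu, 4 * cfg$demography$N_anc * cfg$mu)
  # N*s and N*m invariant
  expect_equal(r$demography$N_anc * r$dfe_mean_s,
               cfg$demography$N_anc * cfg$dfe_mean_s)
  expect_equal(r$demography$N_anc * r$demography$m12,
               cfg$demography$N_anc * cfg$demography$m12)
  # t/N invariant
  expect_equal(r$demography$t_split / r$demography$N_anc,
               cfg$demography$t_split / cfg$demography$N_anc)
  # worked numbers: N = 1000, mu = 1e-8, Q = 5
  dem <- demography_truth(1000, 0, NULL, NULL)
  c2 <- simulation_config(mu = 1e-8, demography = dem,
                          sample_sizes = c(wild = 2L, domestic = 0L),
                          coding_fraction = 0, dfe_mean_s = 0, seed = 1)
  r2 <- rescale(c2, 5)
  expect_equal(r2$demography$N_anc, 200)
  expect_equal(r2$mu, 5e-8)
})

test_that("rescaling errors when sizes collapse or migration saturates", {
  dem <- demography_truth(50, 0, NULL, NULL)
  cfg <- simulation_config(demography = dem, coding_fraction = 0,
                           sample_sizes = c(wild = 2L, domestic = 0L),
                           seed = 1)
  expect_error(rescale(cfg, 40), "below 2")

  dem2 <- demography_preset(m12 = 0.1, m21 = 0.1)
  cfg2 <- simulation_config(demography = dem2, seed = 1)
  expect_error(rescale(cfg2, 50), "migration")
})

test_that("demography epochs must tile the split interval", {
  expect_error(demography_truth(100, 100,
    epochs1 = data.frame(t_start = 100, t_end = 10,
                         size_start = 100, size_end = 100),
    epochs2 = data.frame(t_start = 100, t_end = 0,
                         size_start = 100, size_end = 100)),
    "end at the present")
  expect_error(demography_truth(100, 100,
    epochs1 = data.frame(t_start = c(100, 40), t_end = c(50, 0),
                         size_start = c(100, 80), size_end = c(80, 90)),
    epochs2 = data.frame(t_start = 100, t_end = 0,
                         size_start = 100, size_end = 100)),
    "tile")
  expect_error(demography_truth(100, 100,
    epochs1 = data.frame(t_start = 100, t_end = 0,
                         size_start = 1, size_end = 100),
    epochs2 = data.frame(t_start = 100, t_end = 0,
                         size_start = 100, size_end = 100)),
    ">= 2")
})

test_that("sample sizes are checked against final population sizes", {
  dem <- demography_truth(100, 0, NULL, NULL)
  expect_error(simulation_config(demography = dem,
                                 sample_sizes = c(wild = 500L, domestic = 0L),
                                 seed = 1),
               "exceed")
})

test_that("per-generation size interpolation is linear within epochs", {
  dem <- demography_truth(100, 10,
    epochs1 = data.frame(t_start = 10, t_end = 0,
                         size_start = 100, size_end = 200),
    epochs2 = data.frame(t_start = c(10, 5), t_end = c(5, 0),
                         size_start = c(50, 20), size_end = c(20, 80)),
    m12 = 0, m21 = 0)
  s1 <- sizes_per_generation(dem, 1)
  expect_length(s1, 10)
  expect_equal(s1[10], 200)                 # present
  expect_equal(s1[5], 150)                  # halfway
  s2 <- sizes_per_generation(dem, 2)
  expect_equal(s2[5], 20)                   # epoch boundary
  expect_equal(s2[10], 80)
})
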