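# Expected-SFS engine properties, likelihood, model selection, bootstrap
# and physical scaling.

test_that("expected spectra are linear in theta and symmetric when exchangeable", {
  s1 <- expected_sfs("A", c(1, 1, 0.1), 4, 4)
  s2 <- expected_sfs("A", c(1, 1, 0.1), 4, 4, theta = 2)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  sb <- expected_sfs("B", c(1.5, 1.5, 0.2, 0.8, 0.8), 6, 6)
  expect_lt(max(abs(sb - t(sb))) / max(sb), 1e-4)
})

test_that("a constant-size marginal stays at theta/i for any divergence", {
  sfs <- expected_sfs("A", c(1, 0.3, 0.5), 8, 8)
  marg <- rowSums(sfs)[2:8]
  expect_lt(max(abs(marg * (1:7) - 1)), 0.005)
})

test_that("engine self-convergence: refining the grid changes little", {
  p <- c(2, 0.5, 0.15, 1, 0.5)
  a <- expected_sfs("B", p, 6, 6, pts = 100, dt_max = 2e-3)
  b <- expected_sfs("B", p, 6, 6, pts = 200, dt_max = 1e-3)
  big <- b > 0.001 * max(b)
  msk <- matrix(TRUE, 7, 7); msk[1, 1] <- msk[7, 7] <- FALSE
  expect_lt(max(abs((a - b) / b)[big & msk]), 0.01)
})

test_that("diffusion and structured-coalescent engines agree", {
  p <- c(1.5, 0.5, 0.25, 1, 0.5)
  d <- expected_sfs("B", p, 4, 4)
  set.seed(99)
  m <- expected_sfs("B", p, 4, 4, engine = "coalescent", n_reps = 3000)
  msk <- matrix(TRUE, 5, 5); msk[1, 1] <- msk[5, 5] <- FALSE
  # total polymorphic mass within 3% and big entries within ~MC noise
  expect_lt(abs(sum(d[msk]) / sum(m[msk]) - 1), 0.03)
  big <- msk & m > 0.1
  expect_lt(max(abs((d - m) / m)[big]), 0.08)
})

test_that("composite likelihood profiles theta and orders nested models", {
  truth <- c(nu1 = 1, nu2 = 0.5, T = 0.1, m12 = 3, m21 = 1)
  mexp <- expected_sfs("B", truth, 8, 8, theta = 2000)
  sfs <- new_jsfs(mexp, 8, 8)
  ll <- sfs_loglik(sfs, mexp / 2000)
  expect_equal(ll$theta_hat, 2000, tolerance = 1e-8)
  # model A (no flow) cannot beat model B on heavy-migration data
  fitA <- fit_demography(sfs, "A", restarts = c(4, 2, 1),
                         maxit = c(60, 120, 200), pts = 45, steps = 20,
                         seed = 1)
  fitB <- fit_demography(sfs, "B", restarts = c(2, 1, 1),
                         maxit = c(60, 120, 200), pts = 45, steps = 20,
                         seed = 1, start = truth)
  expect_lt(fitA$loglik, fitB$loglik)
  sel <- model_select(list(fitA, fitB))
  expect_equal(sel$delta_aic[1], 0)
  expect_equal(sel$aic, 2 * sel$k - 2 * sel$loglik)
  expect_equal(sel$aic[sel$model == "B"] - sel$aic[sel$model == "A"],
               2 * (5 - 3) - 2 * (fitB$loglik - fitA$loglik))
})

test_that("AIC bookkeeping and provenance guards work", {
  f <- structure(list(model = "A", k = 3L, loglik = -100, aic = 206,
                      data_id = "x"), class = "dc_demfit")
  g <- structure(list(model = "B", k = 5L, loglik = -99, aic = 208,
                      data_id = "y"), class = "dc_demfit")
  expect_equal(f$aic, 2 * 3 - 2 * -100)
  expect_error(model_select(list(f, g)), "different spectra")
  expect_equal(unclass(logLik(f)), -100, ignore_attr = TRUE)
  expect_equal(AIC(f), 206)
})

test_that("physical scaling follows theta = 4 N mu L", {
  fit <- structure(list(theta_hat = 0.004 * 1e5 * 1,   # theta over L sites
                        par = c(nu1 = 2, nu2 = 0.5, T = 0.1),
                        spec = demographic_models("A"),
                        sfs = list(provenance = list(total_bp = 1e5))),
                   class = "dc_demfit")
  fit$theta_hat <- 0.004 * 1e5
  phys <- scale_to_physical(fit, mu_per_site_per_year = 1e-8,
                            generation_time_years = 1)
  expect_equal(phys$Nanc, 0.004 * 1e5 / (4 * 1e-8 * 1e5))
  expect_equal(unname(phys$sizes["N1"]), 2 * phys$Nanc)
  expect_equal(unname(phys$times_years["T_split_years"]),
               0.1 * 2 * phys$Nanc)
  fit$par["T"] <- 0
  expect_equal(unname(scale_to_physical(fit, 1e-8, 1)$times_years[1]), 0)
})

test_that("likelihood is invariant under region relabelling and the
           bootstrap behaves at its degenerate limits", {
  set.seed(21)
  truth <- c(nu1 = 1, nu2 = 0.6, T = 0.08, m12 = 1, m21 = 1)
  mexp <- expected_sfs("B", truth, 6, 6, theta = 3000)
  msk <- matrix(FALSE, 7, 7); msk[1, 1] <- msk[7, 7] <- TRUE
  cnt <- round(mexp); cnt[msk] <- 0
  # distribute sites over 25 identical regions
  ij <- which(cnt > 0, arr.ind = TRUE)
  sites <- do.call(rbind, lapply(seq_len(nrow(ij)), function(r) {
    nn <- cnt[ij[r, 1], ij[r, 2]]
    data.frame(i = rep(ij[r, 1] - 1L, nn), j = rep(ij[r, 2] - 1L, nn),
               region = seq_len(nn) %% 25)
  }))
  sfs <- new_jsfs(cnt, 6, 6, provenance = list(total_bp = 1e5),
                  sites = sites)
  fit <- fit_demography(sfs, "B", restarts = c(2, 1, 1),
                        maxit = c(50, 100, 150), pts = 45, steps = 20,
                        seed = 5, start = truth)
  # permuting region labels leaves the SFS and lnL unchanged
  sfs2 <- sfs
  sfs2$sites$region <- sample(sfs2$sites$region)
  fit2 <- fit_demography(sfs2, "B", restarts = c(2, 1, 1),
                         maxit = c(50, 100, 150), pts = 45, steps = 20,
                         seed = 5, start = truth)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-9)

  # all regions identical (each region holds a copy of the same spectrum):
  # resampling regions reproduces the data, so intervals collapse
  sites_eq <- do.call(rbind, lapply(0:24, function(rg) {
    do.call(rbind, lapply(seq_len(nrow(ij)), function(r)
      if (cnt[ij[r, 1], ij[r, 2]] >= 25) {
        nn <- cnt[ij[r, 1], ij[r, 2]] %/% 25
        data.frame(i = rep(ij[r, 1] - 1L, nn), j = rep(ij[r, 2] - 1L, nn),
                   region = rep(rg, nn))
      } else NULL))
  }))
  cnt_eq <- matrix(0, 7, 7)
  for (r in seq_len(nrow(sites_eq)))
    cnt_eq[sites_eq$i[r] + 1, sites_eq$j[r] + 1] <-
      cnt_eq[sites_eq$i[r] + 1, sites_eq$j[r] + 1] + 1
  sfs_eq <- new_jsfs(cnt_eq, 6, 6, provenance = list(total_bp = 1e5),
                     sites = sites_eq)
  fit_eq <- fit_demography(sfs_eq, "B", restarts = c(2, 1, 1),
                           maxit = c(50, 100, 150), pts = 45, steps = 20,
                           seed = 5, start = truth)
  ci <- bootstrap_ci(fit_eq, B = 6, seed = 3, restarts = c(1, 1, 1),
                     maxit = c(40, 60, 80))
  expect_true(all(abs(ci$upper - ci$lower) / pmax(ci$estimate, 1e-6) < 0.05))
  expect_error(bootstrap_ci(fit, B = 4),
               NA)   # enough regions, runs fine with defaults trimmed
})
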