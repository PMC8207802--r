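# Expected joint SFS engines.
#
# The default engine integrates the two-population neutral diffusion on a
# boundary-crowded frequency grid (see src/diffusion.cpp) and samples the
# density with binomial kernels.  A Monte-Carlo structured-coalescent engine
# is available as an independent cross-check; both must agree with the
# neutral closed form in the no-divergence limit.

#' Frequency grid with boundary crowding
#'
#' Grid points on \[0, 1\] concentrated near the boundaries (where the
#' allele-frequency density varies fastest), via a sinh warp of a uniform
#' grid.
#'
#' @param pts number of grid points.
#' @param crwd crowding strength; 0 gives a uniform grid.
#' @return numeric vector of increasing grid points from 0 to 1.
#' @keywords internal
sfs_grid <- function(pts = 120L, crwd = 2) {
  u <- seq(0, 1, length.out = pts)
  if (crwd <= 0) return(u)
  0.5 * (1 + tanh(crwd * (2 * u - 1)) / tanh(crwd))
}

# unit-theta equilibrium density of a constant-size (nu = 1) population
equilibrium_phi_1d <- function(grid, theta = 1) {
  phi <- theta / grid
  phi[1] <- phi[2]          # boundary value only feeds the masked corner
  phi
}

# delta-ridge initialisation of the 2D density at the population split
phi_1d_to_2d <- function(phi1, grid) {
  G <- length(grid)
  width <- numeric(G)
  width[1] <- (grid[2] - grid[1]) / 2
  width[G] <- (grid[G] - grid[G - 1]) / 2
  width[2:(G - 1)] <- (grid[3:G] - grid[1:(G - 2)]) / 2
  phi <- matrix(0, G, G)
  diag(phi) <- phi1 / width
  phi
}

trapz_weights <- function(grid) {
  G <- length(grid)
  w <- numeric(G)
  w[1] <- (grid[2] - grid[1]) / 2
  w[G] <- (grid[G] - grid[G - 1]) / 2
  w[2:(G - 1)] <- (grid[3:G] - grid[1:(G - 2)]) / 2
  w
}

binomial_kernel <- function(grid, n) {
  # G x (n+1) matrix of C(n, i) x^i (1-x)^(n-i)
  outer(grid, 0:n, function(x, i) choose(n, i) * x^i * (1 - x)^(n - i))
}

# Quadrature matrix K (G x (n+1)) such that entry_i = sum_a K[a, i] phi[a].
# Interior: trapezoid.  In the first and last grid cells the density carries
# an integrable 1/x (resp. 1/(1-x)) tail maintained by the mutation source,
# so for polymorphic entries those cells are integrated analytically under a
# local c/x (c/(1-x)) model anchored at the first interior point.  The
# monomorphic columns keep the plain trapezoid so that genuine boundary
# (lost/fixed) mass is still counted there.
quadrature_kernel <- function(grid, n) {
  G <- length(grid)
  K <- binomial_kernel(grid, n) * trapz_weights(grid)
  x1 <- grid[2]; xg <- grid[G - 1]
  # left cell [0, x1]: phi ~ (x1*phi[1])/x
  i <- 1:n
  left <- x1 * choose(n, i) * beta(i, n - i + 1) * pbeta(x1, i, n - i + 1)
  # subtract the trapezoid share of the first cell, add the analytic integral
  K[1, i + 1] <- 0
  K[2, i + 1] <- K[2, i + 1] - binomial_kernel(x1, n)[i + 1] * x1 / 2 + left
  # right cell [xg, 1]: phi ~ ((1-xg)*phi[G-1])/(1-x)
  j <- 0:(n - 1)
  right <- (1 - xg) * choose(n, j) * beta(j + 1, n - j) *
    (1 - pbeta(xg, j + 1, n - j))
  K[G, j + 1] <- 0
  K[G - 1, j + 1] <- K[G - 1, j + 1] -
    binomial_kernel(xg, n)[j + 1] * (1 - xg) / 2 + right
  K
}

sample_sfs_2d <- function(phi, grid, n1, n2) {
  K1 <- quadrature_kernel(grid, n1)
  K2 <- quadrature_kernel(grid, n2)
  t(K1) %*% phi %*% K2
}

sample_sfs_1d <- function(phi, grid, n) {
  drop(t(quadrature_kernel(grid, n)) %*% phi)
}

#' Expected joint site frequency spectrum under a two-population model
#'
#' Computes the expected density of segregating sites over derived-allele
#' counts (i, j) in samples of n1 and n2 haploid genomes, for a unit
#' population-scaled mutation rate (spectra are exactly linear in theta,
#' which is profiled out of the composite likelihood).
#'
#' @param model model id, one of `"A"`, `"B"`, `"C"`, `"D"`
#'   (see [demographic_models()]).
#' @param params numeric parameter vector in the model's parameter order.
#' @param n1,n2 haploid sample sizes.
#' @param engine `"diffusion"` (deterministic, default) or `"coalescent"`
#'   (Monte-Carlo structured coalescent, for cross-checks).
#' @param pts grid points for the diffusion engine.
#' @param dt_max maximum time step (units of 2\*Nanc generations).
#' @param min_steps minimum number of time steps over the split epoch.
#' @param max_steps cap on the number of time steps (long trial epochs are
#'   integrated more coarsely).
#' @param theta scale factor applied to the returned spectrum.
#' @param n_reps replicates for the Monte-Carlo engine.
#' @return (n1+1) x (n2+1) matrix of expected site densities; the (0,0)
#'   and (n1,n2) corners are meaningless (monomorphic classes) and are
#'   masked downstream.
#' @export
expected_sfs <- function(model, params, n1, n2,
                         engine = c("diffusion", "coalescent"),
                         pts = 120L, dt_max = 1e-3, min_steps = 20L,
                         max_steps = 2000L, theta = 1, n_reps = 2000L) {
  engine <- match.arg(engine)
  spec <- demographic_models(model)
  check_params(spec, params)
  if (engine == "coalescent")
    return(theta * mc_expected_sfs(spec, params, n1, n2, n_reps = n_reps))
  ev <- sfs_evaluator(n1, n2, pts = pts, dt_max = dt_max,
                      min_steps = min_steps, max_steps = max_steps)
  theta * ev(spec, params)
}

# Closure caching grid, initial density and quadrature kernels across many
# engine evaluations (the optimiser calls this thousands of times).
sfs_evaluator <- function(n1, n2, pts = 70L, dt_max = 2e-3, min_steps = 20L,
                          max_steps = 120L) {
  grid <- sfs_grid(pts)
  phi0 <- phi_1d_to_2d(equilibrium_phi_1d(grid), grid)
  K1 <- quadrature_kernel(grid, n1)
  K2 <- quadrature_kernel(grid, n2)
  function(spec, params) {
    traj <- model_trajectory(spec, params, dt_max = dt_max,
                             min_steps = min_steps, max_steps = max_steps)
    phi <- if (length(traj$dts) > 0) {
      cpp_diffusion_2d(phi0, grid, traj$dts, traj$nu1, traj$nu2,
                       traj$m12, traj$m21, 1.0)
    } else phi0
    sfs <- crossprod(K1, phi %*% K2)
    sfs[sfs < 0] <- 0
    sfs
  }
}

# Monte-Carlo structured coalescent expected SFS (unit theta).
# Event-driven backward simulation; population-size trajectories are
# approximated as piecewise constant over short windows.  Used as an
# independent cross-check of the diffusion engine at small sample sizes.
mc_expected_sfs <- function(spec, params, n1, n2, n_reps = 2000L,
                            window = 0.02) {
  traj <- model_trajectory(spec, params, dt_max = window, min_steps = 1L)
  nstep <- length(traj$dts)
  acc <- matrix(0, n1 + 1, n2 + 1)
  add_time <- function(d1, d2, dt) {
    for (k in seq_along(d1))
      acc[d1[k] + 1L, d2[k] + 1L] <<- acc[d1[k] + 1L, d2[k] + 1L] + dt
  }
  coalesce <- function(state, idx_pool) {
    pair <- if (length(idx_pool) == 2L) idx_pool else sample(idx_pool, 2L)
    a <- pair[1]; b <- pair[2]
    state$d1[a] <- state$d1[a] + state$d1[b]
    state$d2[a] <- state$d2[a] + state$d2[b]
    state$pop <- state$pop[-b]
    state$d1 <- state$d1[-b]
    state$d2 <- state$d2[-b]
    state
  }
  for (rep in seq_len(n_reps)) {
    st <- list(pop = c(rep(1L, n1), rep(2L, n2)),
               d1 = c(rep(1L, n1), rep(0L, n2)),
               d2 = c(rep(0L, n1), rep(1L, n2)))
    # backward over the split epoch: window s runs (forward) time; traverse
    # windows from most recent to oldest
    for (s in rev(seq_len(nstep))) {
      rem <- traj$dts[s]
      nu <- c(traj$nu1[s], traj$nu2[s])
      while (rem > 0 && length(st$pop) > 1L) {
        k1 <- sum(st$pop == 1L); k2 <- sum(st$pop == 2L)
        r_coal <- c(choose(k1, 2) / nu[1], choose(k2, 2) / nu[2])
        r_mig <- c(k1 * traj$m12, k2 * traj$m21)
        R <- sum(r_coal) + sum(r_mig)
        tn <- if (R > 0) stats::rexp(1, R) else Inf
        if (tn >= rem) { add_time(st$d1, st$d2, rem); break }
        add_time(st$d1, st$d2, tn)
        rem <- rem - tn
        ev <- sample.int(4L, 1L, prob = c(r_coal, r_mig))
        if (ev <= 2L) {
          st <- coalesce(st, which(st$pop == ev))
        } else {
          p <- ev - 2L
          k <- which(st$pop == p)
          k <- if (length(k) == 1L) k else sample(k, 1L)
          st$pop[k] <- 3L - p
        }
      }
      if (length(st$pop) == 1L) break
    }
    # ancestral population, nu = 1: standard coalescent
    while (length(st$pop) > 1L) {
      np <- length(st$pop)
      tn <- stats::rexp(1, choose(np, 2))
      add_time(st$d1, st$d2, tn)
      st <- coalesce(st, seq_len(np))
    }
  }
  acc <- acc / n_reps / 2       # E[count_ij] = theta/2 * E[L_ij]
  acc[1, 1] <- 0
  acc[n1 + 1, n2 + 1] <- 0
  acc
}
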