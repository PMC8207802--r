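# Joint-SFS demographic model fitting.
#
# The data are a JointSFS (counts of segregating sites over derived-allele
# count pairs); the model is one of the four parameterisations in
# demographic_models().  Sites are treated as independent (composite
# likelihood); theta is profiled out analytically, so the fitted criterion
# is the multinomial log-likelihood over polymorphic, unmasked cells with
# theta_hat = sum(data) / sum(model).

# ---- parameter transforms -------------------------------------------------

par_to_opt <- function(spec, p) {
  z <- log(p)
  z[spec$logit] <- stats::qlogis(p[spec$logit])
  z
}

opt_to_par <- function(spec, z) {
  p <- exp(z)
  p[spec$logit] <- stats::plogis(z[spec$logit])
  setNames(p, spec$par_names)
}

# log-uniform (logit-uniform) draw within bounds
draw_start <- function(spec) {
  u <- runif(spec$k)
  p <- exp(log(spec$lower) + u * (log(spec$upper) - log(spec$lower)))
  p[spec$logit] <- spec$lower[spec$logit] +
    u[spec$logit] * (spec$upper[spec$logit] - spec$lower[spec$logit])
  p
}

# ---- likelihood -----------------------------------------------------------

sfs_mask <- function(obj) {
  m <- matrix(FALSE, obj$n1 + 1, obj$n2 + 1)
  m[1, 1] <- TRUE
  m[obj$n1 + 1, obj$n2 + 1] <- TRUE
  m | is.na(obj$counts)
}

#' Composite log-likelihood of a joint SFS under a model spectrum
#'
#' Multinomial composite log-likelihood over unmasked cells with the theta
#' scale profiled out analytically (`theta_hat = sum(data)/sum(model)`);
#' a Poisson version (same `theta_hat`) is available.
#'
#' @param data a `dc_jsfs` object (see [joint_sfs()]).
#' @param model_sfs expected spectrum matrix at unit theta.
#' @param mode `"multinomial"` or `"poisson"`.
#' @return list with `loglik`, `theta_hat`, `n_sites`.
#' @export
sfs_loglik <- function(data, model_sfs, mode = c("multinomial", "poisson")) {
  mode <- match.arg(mode)
  msk <- sfs_mask(data)
  d <- data$counts[!msk]
  m <- pmax(model_sfs[!msk], 1e-300)
  S <- sum(d)
  theta_hat <- S / sum(m)
  ll <- if (mode == "multinomial") {
    sum(d * log(m / sum(m)))
  } else {
    mu <- theta_hat * m
    sum(d * log(mu) - mu - lgamma(d + 1))
  }
  list(loglik = ll, theta_hat = theta_hat, n_sites = S)
}

# ---- fitting --------------------------------------------------------------

#' Fit a demographic model to a joint SFS
#'
#' Maximises the composite log-likelihood with a three-round derivative-free
#' search in transformed (log / logit) parameter space: (1) coarse
#' Nelder-Mead from random multi-starts drawn log-uniformly within bounds,
#' (2) restarts perturbed around the round-1 best, (3) a final polish with
#' tight tolerance.  All starts, seeds and round traces are recorded.
#'
#' @param sfs a `dc_jsfs` object from [joint_sfs()].
#' @param model model id ("A", "B", "C" or "D").
#' @param restarts integer vector of length 3: starts per round.
#' @param maxit integer vector of length 3: Nelder-Mead iteration caps.
#' @param pts grid resolution of the diffusion engine.
#' @param steps fixed number of time steps used by the engine during the
#'   fit (the trial epoch is always divided into this many steps).
#' @param mode likelihood mode, see [sfs_loglik()].
#' @param seed optional integer seed for the optimiser's random starts.
#' @param start optional named start vector; replaces one random start.
#' @return an object of class `dc_demfit`.
#' @seealso [model_select()], [bootstrap_ci()], [scale_to_physical()]
#' @export
fit_demography <- function(sfs, model = "C", restarts = c(20L, 10L, 1L),
                           maxit = c(150L, 300L, 800L), pts = 70L,
                           steps = 40L, mode = "multinomial", seed = NULL,
                           start = NULL) {
  stopifnot(inherits(sfs, "dc_jsfs"))
  if (!is.null(seed)) set.seed(seed)
  spec <- demographic_models(model)
  n1 <- sfs$n1; n2 <- sfs$n2
  # a fixed step count keeps the objective smooth in T (no discrete jumps
  # in the integration grid), which the quasi-Newton polish requires
  evaluate <- sfs_evaluator(n1, n2, pts = pts, dt_max = Inf,
                            min_steps = steps, max_steps = steps)

  penalty_of <- function(p) {
    # soft box penalty keeps the simplex away from absurd regions without
    # hard walls; capped so the objective stays finite for optim
    lo <- pmax(pmin(spec$lower / p, 1e6) - 1, 0)
    hi <- pmax(pmin(p / spec$upper, 1e6) - 1, 0)
    min(1e4 * sum(lo^2 + hi^2), 1e9)
  }
  nll <- function(z) {
    p <- opt_to_par(spec, z)
    pen <- penalty_of(p)
    pc <- pmin(pmax(p, spec$lower), spec$upper)
    m <- try(evaluate(spec, pc), silent = TRUE)
    if (inherits(m, "try-error") || anyNA(m)) return(1e10)
    ll <- sfs_loglik(sfs, m, mode = mode)$loglik
    if (!is.finite(ll)) return(1e10)
    -ll + pen
  }

  trace <- list()
  run_nm <- function(z0, it, reltol = 1e-8) {
    # optim(maxit = 0) reports the correct value but not the parameters;
    # a zero-iteration round means "evaluate the start only"
    if (it < 1)
      return(list(par = z0, value = nll(z0), convergence = 0L))
    stats::optim(z0, nll, method = "Nelder-Mead",
                 control = list(maxit = it, reltol = reltol))
  }
  # round 1: random multi-start, always including a canonical mid-range
  # start (sizes at the ancestral value, moderate divergence and flow)
  canonical <- setNames(rep(1, spec$k), spec$par_names)
  canonical[spec$par_names == "T"] <- 0.2
  canonical[spec$par_names %in% c("m12", "m21")] <- 0.5
  canonical[spec$logit] <- 0.5
  starts <- replicate(restarts[1], draw_start(spec), simplify = FALSE)
  if (length(starts) >= 1) starts[[1]] <- canonical
  if (!is.null(start)) {
    if (length(starts) >= 2) starts[[2]] <- canonical
    starts[[1]] <- start[spec$par_names]
  }
  r1 <- lapply(starts, function(p) run_nm(par_to_opt(spec, p), maxit[1]))
  best <- r1[[which.min(vapply(r1, `[[`, 0, "value"))]]
  trace$round1 <- data.frame(start = seq_along(r1),
                             value = vapply(r1, `[[`, 0, "value"))
  # round 2: perturbed restarts around the round-1 best
  r2 <- lapply(seq_len(restarts[2]), function(i) {
    z0 <- best$par + stats::rnorm(spec$k, 0, 0.25)
    run_nm(z0, maxit[2])
  })
  r2 <- c(r2, list(best))
  best <- r2[[which.min(vapply(r2, `[[`, 0, "value"))]]
  trace$round2 <- data.frame(start = seq_along(r2),
                             value = vapply(r2, `[[`, 0, "value"))
  # round 3: polish (Nelder-Mead restart, then quasi-Newton with numerical
  # gradients on the smooth objective)
  for (i in seq_len(restarts[3])) {
    cand <- run_nm(best$par, maxit[3], reltol = 1e-12)
    if (cand$value <= best$value) best <- cand
    cand <- try(stats::optim(best$par, nll, method = "BFGS",
                             control = list(maxit = 30, reltol = 1e-12,
                                            ndeps = rep(1e-5, spec$k))),
                silent = TRUE)
    if (!inherits(cand, "try-error") && cand$value <= best$value)
      best <- cand
  }
  trace$round3 <- best$value
  p_hat <- opt_to_par(spec, best$par)
  at_bound <- p_hat <= spec$lower * 1.001 | p_hat >= spec$upper * 0.999

  m_hat <- evaluate(spec, pmin(pmax(p_hat, spec$lower), spec$upper))
  llf <- sfs_loglik(sfs, m_hat, mode = mode)
  structure(list(
    model = spec$id, spec = spec, par = p_hat, loglik = llf$loglik,
    theta_hat = llf$theta_hat, n_sites = llf$n_sites,
    k = spec$k, aic = 2 * spec$k - 2 * llf$loglik,
    expected = llf$theta_hat * m_hat, sfs = sfs,
    at_bound = at_bound, trace = trace, convergence = best$convergence,
    engine = list(pts = pts, steps = steps, mode = mode), seed = seed,
    data_id = sfs$provenance$id
  ), class = "dc_demfit")
}

#' @exportS3Method base::print
print.dc_demfit <- function(x, ...) {
  cat(sprintf("Two-population demographic fit, model %s\n", x$model))
  cat(sprintf("  composite lnL = %.3f  theta_hat = %.4g  AIC = %.2f\n",
              x$loglik, x$theta_hat, x$aic))
  cat("  parameters:\n")
  print(signif(x$par, 4))
  if (any(x$at_bound))
    cat("  NOTE: parameters at bound:",
        paste(names(x$par)[x$at_bound], collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.dc_demfit <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object, resid_summary = summary(as.vector(res)))
  class(out) <- "summary.dc_demfit"
  out
}

#' @exportS3Method base::print
print.summary.dc_demfit <- function(x, ...) {
  print(x$fit)
  cat("  Pearson residuals over unmasked cells:\n")
  print(x$resid_summary)
  invisible(x)
}

#' @exportS3Method stats::coef
coef.dc_demfit <- function(object, ...) object$par

#' @exportS3Method stats::logLik
logLik.dc_demfit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_sites,
            class = "logLik")
}

#' @exportS3Method stats::residuals
residuals.dc_demfit <- function(object, ...) {
  msk <- sfs_mask(object$sfs)
  r <- (object$sfs$counts - object$expected) / sqrt(pmax(object$expected, 1e-12))
  r[msk] <- NA
  r
}

#' Parametric resampling of a fitted spectrum
#'
#' Draws Poisson replicates of the fitted expected spectrum (composite
#' likelihood treats cells independently).
#' @param object a `dc_demfit`.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `dc_jsfs` objects.
#' @export
simulate.dc_demfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  msk <- sfs_mask(object$sfs)
  lapply(seq_len(nsim), function(i) {
    cnt <- object$expected
    cnt[!msk] <- rpois(sum(!msk), object$expected[!msk])
    cnt[msk & !is.na(object$sfs$counts)] <- 0
    out <- object$sfs
    out$counts <- cnt
    out
  })
}

#' @exportS3Method graphics::plot
plot.dc_demfit <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  lg <- function(m) log10(pmax(m, 0.1))
  image(0:x$sfs$n1, 0:x$sfs$n2, lg(x$sfs$counts), xlab = "derived count, pop 1",
        ylab = "derived count, pop 2", main = "observed (log10)")
  image(0:x$sfs$n1, 0:x$sfs$n2, lg(x$expected), xlab = "derived count, pop 1",
        ylab = "derived count, pop 2", main = sprintf("model %s (log10)", x$model))
  r <- residuals(x)
  image(0:x$sfs$n1, 0:x$sfs$n2, r, xlab = "derived count, pop 1",
        ylab = "derived count, pop 2", main = "Pearson residuals")
  invisible(x)
}

# ---- model selection ------------------------------------------------------

#' Rank demographic fits by AIC
#'
#' @param fits list of `dc_demfit` objects fitted to the same spectrum.
#' @return data.frame ranked by ascending AIC with `delta_aic`.
#' @export
model_select <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "dc_demfit")))
  ids <- vapply(fits, function(f) f$data_id, "")
  if (length(unique(ids)) > 1)
    stop("fits were made on different spectra; AIC comparison is invalid")
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    k = vapply(fits, `[[`, 0L, "k"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"))
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab[order(tab$aic), ]
}

# ---- bootstrap ------------------------------------------------------------

#' Block bootstrap confidence intervals for demographic parameters
#'
#' Resamples neutral regions (blocks) with replacement, rebuilds the joint
#' SFS from the per-region site records, and refits the model seeded at the
#' point estimate (rounds 2-3 only).  Percentile intervals are returned.
#'
#' @param fit a `dc_demfit` whose SFS carries per-region site records
#'   (see [joint_sfs()]).
#' @param B bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @param restarts,maxit optimiser schedule for the refits.
#' @return data.frame with point estimate and interval per parameter.
#' @export
bootstrap_ci <- function(fit, B = 100L, level = 0.95, seed = 1L,
                         restarts = c(0L, 2L, 1L), maxit = c(0L, 150L, 300L)) {
  sfs <- fit$sfs
  if (is.null(sfs$sites) || is.null(sfs$sites$region))
    stop("SFS lacks per-region site records; rebuild with joint_sfs(..., regions = )")
  regions <- sort(unique(sfs$sites$region))
  if (length(regions) < 20)
    stop("need at least 20 regions for a region bootstrap")
  set.seed(seed)
  boots <- matrix(NA_real_, B, fit$k, dimnames = list(NULL, fit$spec$par_names))
  dropped <- 0L
  for (b in seq_len(B)) {
    picks <- sample(regions, length(regions), replace = TRUE)
    counts <- matrix(0, sfs$n1 + 1, sfs$n2 + 1)
    tab <- table(picks)
    for (rg in names(tab)) {
      sel <- sfs$sites$region == rg
      if (!any(sel)) next
      idx <- cbind(sfs$sites$i[sel] + 1L, sfs$sites$j[sel] + 1L)
      mult <- as.integer(tab[[rg]])
      for (r in seq_len(nrow(idx)))
        counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + mult
    }
    bs <- sfs
    bs$counts <- counts
    ft <- try(fit_demography(bs, fit$model, restarts = pmax(restarts, c(1L, 0L, 0L)),
                             maxit = pmax(maxit, c(50L, 0L, 0L)),
                             pts = fit$engine$pts, steps = fit$engine$steps,
                             mode = fit$engine$mode, start = fit$par),
              silent = TRUE)
    if (inherits(ft, "try-error")) { dropped <- dropped + 1L; next }
    boots[b, ] <- ft$par
  }
  if (dropped > 0.2 * B)
    stop(sprintf("%d of %d bootstrap refits failed", dropped, B))
  if (dropped > 0)
    warning(sprintf("%d bootstrap refits dropped", dropped))
  a <- (1 - level) / 2
  data.frame(
    parameter = fit$spec$par_names,
    estimate = unname(fit$par),
    lower = apply(boots, 2, quantile, probs = a, na.rm = TRUE),
    upper = apply(boots, 2, quantile, probs = 1 - a, na.rm = TRUE),
    level = level, B = B - dropped, row.names = NULL)
}

# ---- physical units -------------------------------------------------------

#' Convert a fit to physical units
#'
#' Uses theta_hat = 4 Nanc mu_gen L to anchor the ancestral size, then
#' scales relative sizes and times: `N_x = nu_x * Nanc`,
#' `years = T * 2 * Nanc * generation_time`.
#'
#' @param fit a `dc_demfit`.
#' @param mu_per_site_per_year mutation rate per site per year.
#' @param generation_time_years generation time in years.
#' @param L total callable length (bp) behind the SFS; defaults to the
#'   SFS provenance.
#' @return list with `Nanc`, per-population sizes, times in years and the
#'   scaling constants used.
#' @export
scale_to_physical <- function(fit, mu_per_site_per_year = 1.91e-9,
                              generation_time_years = 1,
                              L = NULL) {
  if (is.null(L)) L <- fit$sfs$provenance$total_bp
  stopifnot(is.numeric(L), L > 0, fit$theta_hat > 0)
  mu_gen <- mu_per_site_per_year * generation_time_years
  Nanc <- fit$theta_hat / (4 * mu_gen * L)
  p <- fit$par
  sizes <- p[grep("^nu", names(p))] * Nanc
  names(sizes) <- sub("^nu", "N", names(sizes))
  times <- c(T_split_years = unname(p["T"]) * 2 * Nanc * generation_time_years)
  if ("rT2" %in% names(p))
    times["T_change_years"] <- unname(p["rT2"] * p["T"]) * 2 * Nanc *
      generation_time_years
  list(Nanc = Nanc, sizes = sizes, times_years = times,
       theta_hat = fit$theta_hat,
       constants = list(mu_per_site_per_year = mu_per_site_per_year,
                        generation_time_years = generation_time_years,
                        L = L))
}
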